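#' Per-layer velocity statistics
#'
#' Mean and maximum velocity magnitude over the fluid (non-SOLID) voxels
#' of a scaffold layer, in um/s. Velocities in POROUS voxels are the
#' superficial (Darcy) velocity the solver works with; set
#' `interstitial = TRUE` to divide them by the collagen porosity.
#'
#' @param field a [FlowField-class].
#' @param grid the [LabeledGrid-class].
#' @param layer layer name (e.g. `"chondral"`, `"osseous"`).
#' @param interstitial report pore-scale velocity in POROUS voxels?
#' @param porosity collagen porosity used for the conversion.
#' @return Named numeric `c(mean = , max = )` in um/s.
#' @export
velocityStats <- function(field, grid, layer, interstitial = FALSE,
                          porosity = 0.90) {
  code <- .layerCode(layer)
  sp <- speedArray(field)
  if (interstitial) {
    por <- grid@label == .LABELS[["POROUS"]]
    sp[por] <- sp[por] / porosity
  }
  sel <- grid@layer == code & grid@label != .LABELS[["WALL"]] &
    grid@label != .LABELS[["SOLID"]]
  if (!any(sel)) stop(sprintf("no fluid voxels in layer '%s'", layer))
  v <- sp[sel] * 1e6
  c(mean = mean(v), max = max(v))
}

#' Fluid-induced shear stress on strut surfaces
#'
#' Estimates the viscous shear stress magnitude on the PLA strut
#' surface from the fluid side: surface normals come from the gradient
#' of a smoothed solid-indicator field, the tangential velocity is
#' sampled by trilinear interpolation at one and two voxel spacings
#' along the normal from the wall, and the one-sided two-point
#' difference `tau = mu (4 u_t(h) - u_t(2h)) / (2h)` (exact for linear
#' and quadratic profiles) gives the stress; where the second sample is
#' not in fluid the one-point estimate is used. The scaffold is rigid,
#' so this fluid-side traction is the stress the struts (and cells on
#' them) experience.
#'
#' @param field a [FlowField-class].
#' @param grid the [LabeledGrid-class].
#' @param fluid a [FluidProps-class].
#' @return A [WSSField-class] (`tau` in Pa on surface voxels).
#' @export
wallShearStress <- function(field, grid, fluid = fluidProps()) {
  h <- grid@spacing
  lab <- grid@label
  d <- dim(lab)
  solid <- lab == .LABELS[["SOLID"]]
  fluidm <- lab == .LABELS[["LUMEN"]] | lab == .LABELS[["POROUS"]]
  if (!any(solid)) stop("grid has no SOLID voxels (no strut surface)")
  # surface voxels: solid with a 6-neighbour in fluid
  nb <- array(FALSE, d)
  shift <- function(m, ax, s) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    n <- d[ax]
    if (s > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (s in c(-1, 1)) nb <- nb | shift(fluidm, ax, s)
  surf <- which(solid & nb)
  if (!length(surf)) stop("no strut surface voxels found")

  # outward normals from a smoothed solid indicator
  ind <- gaussBlur3d(array(as.numeric(solid), d), 1)
  gr <- function(a, ax) {  # central difference along `ax`
    (shiftNum(a, ax, 1) - shiftNum(a, ax, -1)) / 2
  }
  gx <- gr(ind, 1); gy <- gr(ind, 2); gz <- gr(ind, 3)
  ijk <- arrayInd(surf, d)
  n1 <- -cbind(gx[surf], gy[surf], gz[surf])  # out of the solid
  nn <- sqrt(rowSums(n1^2))
  nn[nn == 0] <- 1
  n1 <- n1 / nn

  uc <- cellVelocity(field)
  ctr <- sweep((ijk - 0.5) * h, 2, grid@origin, "+")
  wallp <- ctr + n1 * (h / 2)
  tau <- numeric(length(surf))
  sampleUt <- function(pts) {
    ux <- trilinear(uc$ux, h, grid@origin, pts)
    uy <- trilinear(uc$uy, h, grid@origin, pts)
    uz <- trilinear(uc$uz, h, grid@origin, pts)
    un <- ux * n1[, 1] + uy * n1[, 2] + uz * n1[, 3]
    sqrt(pmax((ux - un * n1[, 1])^2 + (uy - un * n1[, 2])^2 +
                (uz - un * n1[, 3])^2, 0))
  }
  labAt <- function(pts) {
    ii <- pmin(pmax(ceiling(sweep(pts, 2, grid@origin) / h), 1),
               matrix(rep(d, each = nrow(pts)), ncol = 3))
    lab[ii]
  }
  p1 <- wallp + n1 * h
  p2 <- wallp + n1 * 2 * h
  t1 <- sampleUt(p1)
  t2 <- sampleUt(p2)
  ok2 <- labAt(p2) %in% c(.LABELS[["LUMEN"]], .LABELS[["POROUS"]])
  mu <- fluid@dynamic_viscosity
  tau[ok2] <- mu * pmax(4 * t1[ok2] - t2[ok2], 0) / (2 * h)
  tau[!ok2] <- mu * t1[!ok2] / h
  out <- array(NA_real_, d)
  out[surf] <- tau
  new("WSSField", tau = out, spacing = h, origin = grid@origin)
}

# signed shift returning a numeric array padded with edge replication
shiftNum <- function(a, ax, s) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[ax]) + s, 1L), d[ax])
  switch(ax,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE]
  )
}

#' Per-layer shear stress statistics
#'
#' Mean and maximum shear stress over the strut-surface voxels of a
#' layer, in mPa, plus the fraction of the layer's surface below 1 mPa.
#'
#' @param wss a [WSSField-class] from [wallShearStress()].
#' @param grid the [LabeledGrid-class].
#' @param layer layer name.
#' @return Named numeric `c(mean = , max = , frac_below_1mPa = )`.
#' @export
fssStats <- function(wss, grid, layer) {
  code <- .layerCode(layer)
  sel <- !is.na(wss@tau) & grid@layer == code
  if (!any(sel)) stop(sprintf("no surface voxels in layer '%s'", layer))
  t_mpa <- wss@tau[sel] * 1e3
  c(mean = mean(t_mpa), max = max(t_mpa),
    frac_below_1mPa = mean(t_mpa < 1))
}

#' Per-layer mean concentration
#'
#' Volume-weighted mean of the normalized media concentration over the
#' fluid (non-SOLID) voxels of a layer.
#'
#' @param conc a [ConcentrationField-class].
#' @param grid the [LabeledGrid-class].
#' @param layer layer name.
#' @return Mean concentration in \[0, 1\].
#' @export
concentrationStats <- function(conc, grid, layer) {
  code <- .layerCode(layer)
  sel <- grid@layer == code & grid@label != .LABELS[["WALL"]] &
    grid@label != .LABELS[["SOLID"]]
  if (!any(sel)) stop(sprintf("no fluid voxels in layer '%s'", layer))
  mean(conc@conc[sel], na.rm = TRUE)
}

#' Sample a field along a straight line
#'
#' Trilinear samples along the segment from `from` to `to` (physical
#' coordinates, m), e.g. from an inlet port to an outlet port, with the
#' normalized arclength as abscissa -- the concentration profile
#' figures of perfusion studies are drawn this way.
#'
#' @param x a [ConcentrationField-class], [FlowField-class] (velocity
#'   magnitude), [GrayVolume-class], or 3-D array with attributes.
#' @param from,to segment end points (length-3, m).
#' @param n number of samples.
#' @param spacing,origin grid convention (only needed for bare arrays).
#' @return data.frame with `s` (normalized arclength), `x`, `y`, `z`,
#'   and `value`.
#' @export
lineProfile <- function(x, from, to, n = 200L, spacing = NULL,
                        origin = NULL) {
  a <- if (is(x, "ConcentrationField")) x@conc
  else if (is(x, "FlowField")) speedArray(x)
  else if (is(x, "GrayVolume")) x@intensity
  else x
  spacing <- spacing %||% x@spacing
  origin <- origin %||% x@origin
  s <- seq(0, 1, length.out = n)
  pts <- cbind(from[1] + s * (to[1] - from[1]),
               from[2] + s * (to[2] - from[2]),
               from[3] + s * (to[3] - from[3]))
  v <- trilinear(a, spacing, origin, pts)
  if (anyNA(v)) stop("line profile exits the fluid domain (NA samples)")
  data.frame(s = s, x = pts[, 1], y = pts[, 2], z = pts[, 3], value = v)
}

#' Assemble the per-layer microenvironment report
#'
#' Runs the per-layer statistics over the chondral and osseous scaffold
#' sections and the outlet mixing fractions, and collects auxiliary
#' scalars (chamber velocity maxima, the fraction of all strut surface
#' below 1 mPa).
#'
#' @param field a [FlowField-class].
#' @param conc a [ConcentrationField-class] (or NULL to skip
#'   concentration columns).
#' @param grid the [LabeledGrid-class].
#' @param fluid a [FluidProps-class].
#' @param wss optionally a precomputed [WSSField-class].
#' @return A [MicroenvReport-class].
#' @export
microenvReport <- function(field, conc, grid, fluid = fluidProps(),
                           wss = wallShearStress(field, grid, fluid)) {
  layers <- c("chondral", "osseous")
  rows <- lapply(layers, function(l) {
    v <- velocityStats(field, grid, l)
    f <- fssStats(wss, grid, l)
    data.frame(
      layer = l, mean_v_um_s = v[["mean"]], max_v_um_s = v[["max"]],
      mean_fss_mpa = f[["mean"]], max_fss_mpa = f[["max"]],
      mean_conc = if (is.null(conc)) NA_real_ else
        concentrationStats(conc, grid, l)
    )
  })
  mixing <- if (is.null(conc)) c(top = NA_real_, bottom = NA_real_) else
    outletMixing(conc, field)
  allt <- wss@tau[!is.na(wss@tau)] * 1e3
  extras <- list(
    top_chamber_max_v_um_s = tryCatch(
      velocityStats(field, grid, "top_chamber")[["max"]],
      error = function(e) NA_real_),
    bottom_chamber_max_v_um_s = tryCatch(
      velocityStats(field, grid, "bottom_chamber")[["max"]],
      error = function(e) NA_real_),
    frac_surface_below_1mPa = mean(allt < 1)
  )
  new("MicroenvReport", table = do.call(rbind, rows), mixing = mixing,
      extras = extras)
}

#' Access the report table / mixing fractions
#' @param x a [MicroenvReport-class].
#' @return `reportTable`: the per-layer data.frame; `mixingFractions`:
#'   named numeric.
#' @export
reportTable <- function(x) x@table

#' @rdname reportTable
#' @export
mixingFractions <- function(x) x@mixing

#' Percent differences between two microenvironment reports
#'
#' Signed percent change `(b - a) / a * 100` for every per-layer
#' statistic and the mixing fractions, with `a` the reference (CAD)
#' run. Entries with a zero reference are flagged `undefined` rather
#' than propagating NaN.
#'
#' @param a,b [MicroenvReport-class] objects with identical layer sets.
#' @param digits rounding for the `pct_diff` column (NULL = none).
#' @return data.frame with `layer`, `metric`, `a`, `b`, `pct_diff`,
#'   `undefined`.
#' @examples
#' # Table-style check: 26.4 -> 60.8 um/s is a +130 % change
#' round((60.8 - 26.4) / 26.4 * 100)
#' @export
compareReports <- function(a, b, digits = NULL) {
  stopifnot(identical(a@table$layer, b@table$layer))
  metrics <- c("mean_v_um_s", "max_v_um_s", "mean_fss_mpa",
               "max_fss_mpa", "mean_conc")
  rows <- list()
  for (i in seq_len(nrow(a@table))) {
    for (m in metrics) {
      av <- a@table[[m]][i]; bv <- b@table[[m]][i]
      undef <- is.na(av) || av == 0
      pct <- if (undef) NA_real_ else (bv - av) / av * 100
      if (!is.null(digits) && !undef) pct <- round(pct, digits)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = a@table$layer[i], metric = m, a = av, b = bv,
        pct_diff = pct, undefined = undef
      )
    }
  }
  for (ch in names(a@mixing)) {
    av <- a@mixing[[ch]]; bv <- b@mixing[[ch]]
    undef <- is.na(av) || av == 0
    pct <- if (undef) NA_real_ else (bv - av) / av * 100
    if (!is.null(digits) && !undef) pct <- round(pct, digits)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = ch, metric = "outlet_mixing", a = av, b = bv,
      pct_diff = pct, undefined = undef
    )
  }
  do.call(rbind, rows)
}

setMethod("show", "MicroenvReport", function(object) {
  cat("MicroenvReport\n")
  print(object@table, row.names = FALSE, digits = 4)
  m <- object@mixing
  cat(sprintf("outlet mixing: top %.1f%%, bottom %.1f%%\n",
              100 * m[["top"]], 100 * m[["bottom"]]))
})

setMethod("show", "WSSField", function(object) {
  v <- object@tau[!is.na(object@tau)]
  cat(sprintf(
    "WSSField: %d surface voxels, tau mean %.3g mPa, max %.3g mPa\n",
    length(v), mean(v) * 1e3, max(v) * 1e3
  ))
})
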