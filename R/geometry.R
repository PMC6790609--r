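#' Construct a scaffold specification
#'
#' Defaults describe the bilayered PLA lattice used throughout the
#' package: a 15 mm diameter, 10 mm tall cylinder whose top (chondral)
#' section is a fine mesh of 500 um struts at 500 um spacing with
#' collagen-filled pores, whose bottom (osseous) section is a coarse mesh
#' of 1000 um struts at 1000-1500 um spacing, and whose two sections are
#' separated by two close-packed layers of 500 um struts. Section heights
#' fill the cylinder exactly: 4 mm osseous (4 strut layers), 1 mm
#' separator, 5 mm chondral (10 strut layers). The grid orientation is
#' the culture orientation: osseous at the bottom, chondral on top.
#'
#' @param cylinder_diameter,cylinder_height scaffold envelope (m).
#' @param chondral_strut_d,chondral_spacing chondral strut diameter and
#'   in-layer gap (m).
#' @param osseous_strut_d,osseous_spacing osseous strut diameter and
#'   in-layer gap (m); `osseous_spacing` defaults to the midpoint of
#'   `osseous_spacing_range`.
#' @param osseous_spacing_range admissible osseous spacing range (m).
#' @param separator_strut_d separator strut diameter (m).
#' @param separator_layers number of close-packed separator layers.
#' @param separator_gap in-layer gap between separator struts (m); a
#'   perfectly touching pack would seal the chambers from each other, so
#'   a small positive default keeps them in communication.
#' @param chondral_height,osseous_height section heights (m).
#' @param layer_height nominal print layer height (m).
#' @param rotation_deg in-plane rotation of the lattice (degrees,
#'   in \[0, 90)).
#' @param collagen_in_chondral_pores fill chondral pores with collagen
#'   (modeled as a porous medium)?
#' @return A validated [ScaffoldSpec-class].
#' @examples
#' spec <- scaffoldSpec()
#' spec
#' @export
scaffoldSpec <- function(cylinder_diameter = 15e-3,
                         cylinder_height = 10e-3,
                         chondral_strut_d = 500e-6,
                         chondral_spacing = 500e-6,
                         osseous_strut_d = 1000e-6,
                         osseous_spacing = mean(osseous_spacing_range),
                         osseous_spacing_range = c(1000e-6, 1500e-6),
                         separator_strut_d = 500e-6,
                         separator_layers = 2L,
                         separator_gap = 20e-6,
                         chondral_height = 5e-3,
                         osseous_height = 4e-3,
                         layer_height = 500e-6,
                         rotation_deg = 0,
                         collagen_in_chondral_pores = TRUE) {
  new("ScaffoldSpec",
    cylinder_diameter = cylinder_diameter,
    cylinder_height = cylinder_height,
    chondral_strut_d = chondral_strut_d,
    chondral_spacing = chondral_spacing,
    osseous_strut_d = osseous_strut_d,
    osseous_spacing = osseous_spacing,
    osseous_spacing_range = osseous_spacing_range,
    separator_strut_d = separator_strut_d,
    separator_layers = as.integer(separator_layers),
    separator_gap = separator_gap,
    chondral_height = chondral_height,
    osseous_height = osseous_height,
    layer_height = layer_height,
    rotation_deg = rotation_deg,
    collagen_in_chondral_pores = collagen_in_chondral_pores
  )
}

#' Construct a chamber specification
#'
#' The chamber dimensions of the physical bioreactor are not published;
#' the defaults here are documented assumptions: a cylindrical chamber
#' with 1 mm diametral clearance around the scaffold, 5 mm plenum above
#' and below, two inlet and two outlet ports of 1.02 mm bore per chamber
#' on opposing sides, and the scaffold perimeter sealed to the wall at
#' separator mid-height.
#'
#' @param scaffold the [ScaffoldSpec-class] the chamber will hold (used
#'   for the default inner diameter and port heights).
#' @param inner_diameter chamber inner diameter (m).
#' @param plenum_top,plenum_bottom plenum heights (m).
#' @param port_diameter port bore (m).
#' @param midplane_seal seal the scaffold-wall annulus at separator
#'   height?
#' @param inlet_angles,outlet_angles azimuthal port positions per chamber
#'   (degrees); the same angles are used for the top and bottom chamber.
#' @param top_inlet_conc,bottom_inlet_conc normalized inlet
#'   concentrations (chondrogenic marker: 1 at the top, 0 at the
#'   bottom).
#' @param ports optional explicit port data.frame (see
#'   [ChamberSpec-class]); overrides the angle-based defaults.
#' @return A validated [ChamberSpec-class].
#' @examples
#' chamberSpec(scaffoldSpec())
#' @export
chamberSpec <- function(scaffold = scaffoldSpec(),
                        inner_diameter = scaffold@cylinder_diameter + 1e-3,
                        plenum_top = 5e-3, plenum_bottom = 5e-3,
                        port_diameter = 1.02e-3,
                        midplane_seal = TRUE,
                        inlet_angles = c(150, 210),
                        outlet_angles = c(30, 330),
                        top_inlet_conc = 1, bottom_inlet_conc = 0,
                        ports = NULL) {
  if (inner_diameter < scaffold@cylinder_diameter) {
    stop("chamber inner_diameter must be >= scaffold cylinder diameter")
  }
  if (is.null(ports)) {
    rc <- inner_diameter / 2
    # ports sit level with the mid-height of the scaffold section each
    # chamber perfuses, so the cross-flow passes the lattice rather
    # than short-circuiting through the plenum (the reported velocity
    # maxima sit right at the inlets of the scaffold sections)
    sep_h <- scaffold@separator_layers * scaffold@separator_strut_d
    zb <- plenum_bottom + scaffold@osseous_height / 2
    zt <- plenum_bottom + scaffold@osseous_height + sep_h +
      scaffold@chondral_height / 2
    mk <- function(angles, role, chamber, zc, conc) {
      th <- angles * pi / 180
      data.frame(
        role = role, chamber = chamber,
        px = rc * cos(th), py = rc * sin(th), pz = zc,
        nx = cos(th), ny = sin(th), nz = 0,
        diameter = port_diameter, profile = "parabolic",
        conc = conc, stringsAsFactors = FALSE
      )
    }
    ports <- rbind(
      mk(inlet_angles, "inlet", "top", zt, top_inlet_conc),
      mk(outlet_angles, "outlet", "top", zt, NA_real_),
      mk(inlet_angles, "inlet", "bottom", zb, bottom_inlet_conc),
      mk(outlet_angles, "outlet", "bottom", zb, NA_real_)
    )
  }
  new("ChamberSpec",
    inner_diameter = inner_diameter, plenum_top = plenum_top,
    plenum_bottom = plenum_bottom, port_diameter = port_diameter,
    midplane_seal = midplane_seal, ports = ports
  )
}

# Section layout derived from a spec, bottom-up. Each section stacks
# strut layers at a vertical pitch equal to its strut diameter.
.sectionPlan <- function(spec) {
  list(
    osseous = list(
      d = spec@osseous_strut_d,
      pitch = spec@osseous_strut_d + spec@osseous_spacing,
      n = max(1L, round(spec@osseous_height / spec@osseous_strut_d)),
      z0 = 0
    ),
    separator = list(
      d = spec@separator_strut_d,
      pitch = spec@separator_strut_d + spec@separator_gap,
      n = spec@separator_layers,
      z0 = spec@osseous_height
    ),
    chondral = list(
      d = spec@chondral_strut_d,
      pitch = spec@chondral_strut_d + spec@chondral_spacing,
      n = max(1L, round(spec@chondral_height / spec@chondral_strut_d)),
      z0 = spec@osseous_height +
        spec@separator_layers * spec@separator_strut_d
    )
  )
}

#' Build the CAD-equivalent strut lattice
#'
#' Generates the capped-cylinder struts of the bilayered lattice in the
#' culture orientation (osseous section at the bottom, chondral on top,
#' z pointing up). Within each section, successive printed layers
#' alternate between 0 and 90 degree strut directions; layers sharing a
#' direction are offset by half a pitch. Strut coordinates are
#' scaffold-local: the cylinder axis is x = y = 0 and the osseous base
#' sits at z = 0.
#'
#' @param spec a [ScaffoldSpec-class].
#' @return A [StrutSet-class].
#' @examples
#' lat <- buildLattice(scaffoldSpec())
#' table(strutTable(lat)$layer)
#' @export
buildLattice <- function(spec) {
  validObject(spec)
  plan <- .sectionPlan(spec)
  R <- spec@cylinder_diameter / 2
  th <- spec@rotation_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rows <- list()
  g <- 0L  # global printed-layer counter, drives direction alternation
  for (name in names(plan)) {
    sec <- plan[[name]]
    r <- sec$d / 2
    for (l in seq_len(sec$n) - 1L) {
      zc <- sec$z0 + (l + 0.5) * sec$d
      dir <- g %% 2L                      # 0: along x, 1: along y
      stag <- ((g %/% 2L) %% 2L) * sec$pitch / 2
      kmax <- floor((R - r - stag) / sec$pitch)
      kmin <- -floor((R - r + stag) / sec$pitch)
      offs <- (kmin:kmax) * sec$pitch + stag
      offs <- offs[abs(offs) <= R - r + 1e-12]
      if (length(offs)) {
        hl <- sqrt(pmax(R^2 - offs^2, 0))
        if (dir == 0L) {
          p0 <- cbind(-hl, offs); p1 <- cbind(hl, offs)
        } else {
          p0 <- cbind(offs, -hl); p1 <- cbind(offs, hl)
        }
        p0 <- p0 %*% t(rot); p1 <- p1 %*% t(rot)
        rows[[length(rows) + 1L]] <- data.frame(
          x0 = p0[, 1], y0 = p0[, 2], z0 = zc,
          x1 = p1[, 1], y1 = p1[, 2], z1 = zc,
          radius = r, layer = name, zscale = 1, rough_amp = 0,
          rough_f1 = 0, rough_p1 = 0, rough_f2 = 0, rough_p2 = 0,
          stringsAsFactors = FALSE
        )
      }
      g <- g + 1L
    }
  }
  new("StrutSet", struts = do.call(rbind, rows), spec = spec)
}

#' Access the strut table of a StrutSet
#' @param x a [StrutSet-class].
#' @return The per-strut data.frame (see [StrutSet-class]).
#' @export
strutTable <- function(x) x@struts

#' Scaffold spec carried by a StrutSet or LabeledGrid
#' @param x a [StrutSet-class] or [LabeledGrid-class].
#' @return The [ScaffoldSpec-class] used to build `x` (or NULL).
#' @export
scaffoldSpecOf <- function(x) {
  if (is(x, "StrutSet")) x@spec else x@meta$scaffold_spec
}

# Mark voxels inside one strut. `xs, ys, zs` are the cell-centre
# coordinate vectors of the grid (strut coordinates already in grid
# frame). Returns integer matrix of voxel indices (i, j, k).
.strutVoxels <- function(strut, xs, ys, zs, spacing) {
  p0 <- c(strut$x0, strut$y0, strut$z0)
  p1 <- c(strut$x1, strut$y1, strut$z1)
  ax <- p1 - p0
  len <- sqrt(sum(ax^2))
  if (len == 0) return(NULL)
  d <- ax / len
  rmax <- (strut$radius + strut$rough_amp) + 1e-12
  lo <- pmin(p0, p1) - rmax
  hi <- pmax(p0, p1) + rmax
  ir <- which(xs >= lo[1] - spacing & xs <= hi[1] + spacing)
  jr <- which(ys >= lo[2] - spacing & ys <= hi[2] + spacing)
  kr <- which(zs >= lo[3] - spacing & zs <= hi[3] + spacing)
  if (!length(ir) || !length(jr) || !length(kr)) return(NULL)
  g <- expand.grid(i = ir, j = jr, k = kr, KEEP.OUT.ATTRS = FALSE)
  qx <- xs[g$i] - p0[1]; qy <- ys[g$j] - p0[2]; qz <- zs[g$k] - p0[3]
  t <- pmin(pmax((qx * d[1] + qy * d[2] + qz * d[3]) / len, 0), 1)
  vx <- qx - t * len * d[1]
  vy <- qy - t * len * d[2]
  vz <- (qz - t * len * d[3]) / strut$zscale  # sag flattens vertically
  rloc <- strut$radius
  if (strut$rough_amp > 0) {
    rloc <- rloc + strut$rough_amp *
      (0.6 * sin(2 * pi * strut$rough_f1 * t + strut$rough_p1) +
         0.4 * sin(2 * pi * strut$rough_f2 * t + strut$rough_p2))
  }
  inside <- vx^2 + vy^2 + vz^2 <= rloc^2
  if (!any(inside)) return(NULL)
  cbind(g$i[inside], g$j[inside], g$k[inside])
}

#' Voxelize the lattice and chamber into a labeled grid
#'
#' Builds the uniform cell-centred voxel grid of the whole computational
#' domain: a one-voxel wall shell encloses the cylindrical chamber
#' cavity; voxels whose centre falls inside a strut become SOLID;
#' non-solid voxels in the chondral band inside the scaffold envelope
#' become POROUS (collagen) when the spec asks for it; everything else in
#' the cavity is LUMEN. Layer tags are assigned from the z-bands of the
#' scaffold sections; the scaffold-wall annulus is tagged as chamber
#' space (and sealed to WALL at separator height when
#' `midplane_seal` is set).
#'
#' @param struts a [StrutSet-class] (may be empty).
#' @param chamber a [ChamberSpec-class].
#' @param voxel_spacing isotropic voxel size (m). A guard warns when it
#'   exceeds one fifth of the smallest strut diameter.
#' @return A [LabeledGrid-class].
#' @examples
#' grid <- voxelize(buildLattice(scaffoldSpec()), chamberSpec(),
#'                  voxel_spacing = 500e-6)
#' porosity(grid, "osseous")
#' @export
voxelize <- function(struts, chamber, voxel_spacing) {
  validObject(chamber)
  spec <- struts@spec
  h <- voxel_spacing
  dmin <- min(spec@chondral_strut_d, spec@osseous_strut_d,
              spec@separator_strut_d)
  if (nrow(struts@struts) && h > dmin / 5) {
    warning(sprintf(
      "voxel spacing %.3g m exceeds min strut diameter / 5 (%.3g m); strut resolution will be poor",
      h, dmin / 5
    ))
  }
  rc <- chamber@inner_diameter / 2
  rs <- spec@cylinder_diameter / 2
  cavity_h <- chamber@plenum_bottom + spec@cylinder_height +
    chamber@plenum_top
  nx <- as.integer(ceiling(2 * rc / h)) + 2L
  ny <- nx
  nz <- as.integer(ceiling(cavity_h / h)) + 2L
  cx <- nx * h / 2; cy <- ny * h / 2
  z0 <- h                       # cavity floor (above 1-voxel bottom wall)
  z1 <- z0 + cavity_h
  xs <- cellCenters(nx, h); ys <- cellCenters(ny, h); zs <- cellCenters(nz, h)
  r2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  inside_xy <- r2 <= rc^2
  inside_z <- zs > z0 & zs < z1
  label <- array(.LABELS[["WALL"]], c(nx, ny, nz))
  interior <- outer(inside_xy, inside_z, FUN = "&")
  dim(interior) <- c(nx, ny, nz)
  label[interior] <- .LABELS[["LUMEN"]]

  # z-bands (absolute grid coordinates)
  zb <- c(
    cavity_bottom = z0,
    scaffold_bottom = z0 + chamber@plenum_bottom,
    osseous_top = z0 + chamber@plenum_bottom + spec@osseous_height,
    separator_top = z0 + chamber@plenum_bottom + spec@osseous_height +
      spec@separator_layers * spec@separator_strut_d,
    scaffold_top = z0 + chamber@plenum_bottom + spec@cylinder_height,
    cavity_top = z1
  )

  # solid struts (strut frame -> grid frame)
  st <- struts@struts
  if (nrow(st)) {
    st$x0 <- st$x0 + cx; st$x1 <- st$x1 + cx
    st$y0 <- st$y0 + cy; st$y1 <- st$y1 + cy
    st$z0 <- st$z0 + zb[["scaffold_bottom"]]
    st$z1 <- st$z1 + zb[["scaffold_bottom"]]
    in_scaffold <- array(FALSE, c(nx, ny, nz))
    kz <- which(zs > zb[["scaffold_bottom"]] & zs < zb[["scaffold_top"]])
    in_scaffold[, , kz] <- rep(r2 <= rs^2, length(kz))
    for (s in seq_len(nrow(st))) {
      vox <- .strutVoxels(st[s, ], xs, ys, zs, h)
      if (!is.null(vox)) {
        keep <- interior[vox] & in_scaffold[vox]
        label[vox[keep, , drop = FALSE]] <- .LABELS[["SOLID"]]
      }
    }
  }

  # seal the scaffold-wall annulus at separator height
  if (chamber@midplane_seal) {
    kz <- which(zs > zb[["osseous_top"]] & zs < zb[["separator_top"]])
    ann <- array(FALSE, c(nx, ny, nz))
    ann[, , kz] <- rep(r2 > rs^2, length(kz))
    label[ann & label != .LABELS[["WALL"]]] <- .LABELS[["WALL"]]
  }

  # layer tags
  layer <- array(.LAYERS[["NONE"]], c(nx, ny, nz))
  sep_mid <- (zb[["osseous_top"]] + zb[["separator_top"]]) / 2
  scaff_xy <- r2 <= rs^2
  for (k in seq_len(nz)) {
    z <- zs[k]
    if (z <= z0 || z >= z1) next
    lay <- matrix(.LAYERS[["NONE"]], nx, ny)
    if (z < zb[["scaffold_bottom"]]) {
      lay[inside_xy] <- .LAYERS[["BOTTOM_CHAMBER"]]
    } else if (z > zb[["scaffold_top"]]) {
      lay[inside_xy] <- .LAYERS[["TOP_CHAMBER"]]
    } else {
      band <- if (z < zb[["osseous_top"]]) {
        .LAYERS[["OSSEOUS"]]
      } else if (z < zb[["separator_top"]]) {
        .LAYERS[["SEPARATOR"]]
      } else .LAYERS[["CHONDRAL"]]
      lay[inside_xy & scaff_xy] <- band
      # annulus around the scaffold belongs to the adjacent chamber
      ann <- inside_xy & !scaff_xy
      lay[ann] <- if (z < sep_mid) .LAYERS[["BOTTOM_CHAMBER"]] else
        .LAYERS[["TOP_CHAMBER"]]
    }
    layer[, , k] <- lay
  }
  layer[label == .LABELS[["WALL"]]] <- .LAYERS[["NONE"]]

  # collagen in chondral pores: defined via the layer tag so the two
  # arrays agree voxel for voxel at the band edges
  if (spec@collagen_in_chondral_pores && nrow(st)) {
    sel <- layer == .LAYERS[["CHONDRAL"]] & label == .LABELS[["LUMEN"]]
    label[sel] <- .LABELS[["POROUS"]]
  }

  ports <- chamber@ports
  if (nrow(ports)) {
    # ports are specified in the scaffold-local frame used by
    # chamberSpec(): x/y about the axis, z = 0 at the cavity floor
    ports$px <- ports$px + cx
    ports$py <- ports$py + cy
    ports$pz <- ports$pz + z0
    bad <- ports$pz <= z0 - h | ports$pz >= z1 + h |
      sqrt((ports$px - cx)^2 + (ports$py - cy)^2) > rc + 2 * h
    if (any(bad)) {
      stop(sprintf("%d port(s) lie outside the chamber wall", sum(bad)))
    }
  }

  new("LabeledGrid",
    spacing = h, origin = c(0, 0, 0), label = label, layer = layer,
    ports = ports,
    meta = list(
      center = c(cx, cy), r_chamber = rc, r_scaffold = rs, zbands = zb,
      scaffold_spec = spec, chamber_spec = chamber
    )
  )
}

#' Per-layer porosity of a labeled grid
#'
#' Fraction of non-wall voxels in a layer that are open to fluid
#' (lumen or collagen): `(LUMEN + POROUS) / (all non-WALL)` within the
#' layer. For the scaffold layers the layer tag already restricts the
#' count to the scaffold's bounding cylinder.
#'
#' @param grid a [LabeledGrid-class].
#' @param layer layer name: one of `"chondral"`, `"separator"`,
#'   `"osseous"`, `"top_chamber"`, `"bottom_chamber"`.
#' @return Porosity in \[0, 1\].
#' @examples
#' grid <- voxelize(buildLattice(scaffoldSpec()), chamberSpec(),
#'                  voxel_spacing = 500e-6)
#' porosity(grid, "chondral")
#' @export
porosity <- function(grid, layer) {
  code <- .layerCode(layer)
  sel <- grid@layer == code & grid@label != .LABELS[["WALL"]]
  n <- sum(sel)
  if (n == 0) stop(sprintf("layer '%s' not present in grid", layer))
  sum(grid@label[sel] %in% c(.LABELS[["LUMEN"]], .LABELS[["POROUS"]])) / n
}

.layerCode <- function(layer) {
  key <- toupper(layer)
  if (!key %in% names(.LAYERS)) {
    stop(sprintf(
      "unknown layer tag '%s' (expected one of %s)", layer,
      paste(tolower(names(.LAYERS)), collapse = ", ")
    ))
  }
  .LAYERS[[key]]
}

#' Grid accessors
#'
#' `voxelSpacing` returns the isotropic voxel size (m); `labelArray` and
#' `layerArray` the integer code arrays (see [gridLabels()]); `gridPorts`
#' the port table consumed by the solvers.
#'
#' @param x a [LabeledGrid-class] (or [GrayVolume-class] /
#'   [FlowField-class] / [ConcentrationField-class] for `voxelSpacing`).
#' @return See description.
#' @export
voxelSpacing <- function(x) x@spacing

#' @rdname voxelSpacing
#' @export
labelArray <- function(x) x@label

#' @rdname voxelSpacing
#' @export
layerArray <- function(x) x@layer

#' @rdname voxelSpacing
#' @export
gridPorts <- function(x) x@ports

setMethod("show", "ScaffoldSpec", function(object) {
  cat(sprintf(
    "ScaffoldSpec: %.1f mm dia x %.1f mm | chondral %d um/%d um, osseous %d um/%d um, %d separator layers, rotation %g deg, collagen=%s\n",
    object@cylinder_diameter * 1e3, object@cylinder_height * 1e3,
    round(object@chondral_strut_d * 1e6),
    round(object@chondral_spacing * 1e6),
    round(object@osseous_strut_d * 1e6),
    round(object@osseous_spacing * 1e6),
    object@separator_layers, object@rotation_deg,
    object@collagen_in_chondral_pores
  ))
})

setMethod("show", "ChamberSpec", function(object) {
  cat(sprintf(
    "ChamberSpec: ID %.1f mm, plenums %.1f/%.1f mm, %d ports (%.2f mm), sealed=%s\n",
    object@inner_diameter * 1e3, object@plenum_bottom * 1e3,
    object@plenum_top * 1e3, nrow(object@ports),
    object@port_diameter * 1e3, object@midplane_seal
  ))
})

setMethod("show", "StrutSet", function(object) {
  tab <- table(object@struts$layer)
  cat(sprintf(
    "StrutSet: %d struts (%s)\n", nrow(object@struts),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
})

setMethod("show", "LabeledGrid", function(object) {
  d <- dim(object@label)
  tab <- table(factor(object@label, levels = .LABELS,
                      labels = names(.LABELS)))
  cat(sprintf(
    "LabeledGrid: %d x %d x %d voxels @ %.0f um\n  %s\n",
    d[1], d[2], d[3], object@spacing * 1e6,
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
})
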