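#' Construct manufacturing-deviation parameters
#'
#' Defaults emulate a fused-deposition print of PLA struts: a 10 percent
#' mean strut over-extrusion with 3 percent strut-to-strut scatter,
#' 15 percent vertical sag of the deposited strands, and 25 um surface
#' roughness. Identity parameters (`mean = 1, sd = 0, sag = 0,
#' rough = 0`) reproduce the CAD lattice exactly.
#'
#' @param diameter_scale_mean,diameter_scale_sd multiplicative strut
#'   diameter error distribution.
#' @param sag_fraction vertical cross-section flattening in \[0, 1).
#' @param roughness_amplitude surface perturbation amplitude (m).
#' @param seed integer RNG seed.
#' @return A validated [ArtifactParams-class].
#' @examples
#' artifactParams(seed = 7)
#' @export
artifactParams <- function(diameter_scale_mean = 1.10,
                           diameter_scale_sd = 0.03,
                           sag_fraction = 0.15,
                           roughness_amplitude = 25e-6,
                           seed = 1L) {
  new("ArtifactParams",
    diameter_scale_mean = diameter_scale_mean,
    diameter_scale_sd = diameter_scale_sd,
    sag_fraction = sag_fraction,
    roughness_amplitude = roughness_amplitude,
    seed = as.integer(seed)
  )
}

#' Inject printing artifacts into a strut lattice
#'
#' Perturbs a CAD-equivalent [StrutSet-class] the way an
#' additive-manufactured part deviates from its CAD: every strut radius
#' is scaled by an independent draw from the diameter-error
#' distribution (non-positive draws are redrawn with truncation and
#' logged), cross-sections are flattened vertically by the sag fraction,
#' and a smooth two-component sinusoidal radius modulation models
#' surface roughness. The result is a pure function of
#' `(struts, params)` via the stored seed.
#'
#' @param struts a [StrutSet-class].
#' @param params an [ArtifactParams-class].
#' @return A perturbed [StrutSet-class].
#' @examples
#' lat <- buildLattice(scaffoldSpec())
#' man <- applyPrintArtifacts(lat, artifactParams(seed = 42))
#' range(strutTable(man)$radius / strutTable(lat)$radius)
#' @export
applyPrintArtifacts <- function(struts, params) {
  validObject(params)
  st <- struts@struts
  n <- nrow(st)
  if (n == 0) return(struts)
  withSeed(params@seed, {
    sc <- rnorm(n, params@diameter_scale_mean, params@diameter_scale_sd)
    bad <- which(sc <= 0)
    tries <- 0L
    while (length(bad) && tries < 100L) {
      sc[bad] <- rnorm(length(bad), params@diameter_scale_mean,
                       params@diameter_scale_sd)
      bad <- which(sc <= 0)
      tries <- tries + 1L
    }
    if (length(bad)) {
      sc[bad] <- params@diameter_scale_mean
    }
    if (tries > 0L) {
      message(sprintf("redrew %s non-positive diameter scale draw(s)",
                      tries))
    }
    st$radius <- st$radius * sc
    st$zscale <- 1 - params@sag_fraction
    if (params@roughness_amplitude > 0) {
      st$rough_amp <- params@roughness_amplitude
      st$rough_f1 <- runif(n, 2, 6)
      st$rough_p1 <- runif(n, 0, 2 * pi)
      st$rough_f2 <- runif(n, 6, 12)
      st$rough_p2 <- runif(n, 0, 2 * pi)
    }
  })
  new("StrutSet", struts = st, spec = struts@spec)
}

#' Render a labeled grid into a synthetic micro-CT grayscale volume
#'
#' Forward model for an X-ray tomographic reconstruction of the
#' manufactured scaffold: PLA (SOLID) voxels map to high intensity and
#' everything else to background -- collagen is radiolucent, so POROUS
#' voxels render as background. A Gaussian blur of width `psf_sigma`
#' models the partial-volume effect, a smooth multiplicative radial bias
#' mimics residual beam hardening, and additive Gaussian noise models
#' detector noise. Deterministic for a fixed seed.
#'
#' @param grid a [LabeledGrid-class].
#' @param psf_sigma point-spread width (m); default half a voxel.
#' @param noise_sd additive noise standard deviation (intensity units;
#'   the solid/background contrast is 1).
#' @param bias_amplitude amplitude of the radial multiplicative bias.
#' @param seed integer RNG seed.
#' @return A [GrayVolume-class].
#' @export
renderGrayscale <- function(grid, psf_sigma = grid@spacing / 2,
                            noise_sd = 0.1, bias_amplitude = 0.05,
                            seed = 1L) {
  stopifnot(psf_sigma >= 0)
  h <- grid@spacing
  img <- array(0, dim(grid@label))
  img[grid@label == .LABELS[["SOLID"]]] <- 1
  if (psf_sigma > 0) img <- gaussBlur3d(img, psf_sigma / h)
  if (bias_amplitude != 0) {
    d <- dim(img)
    ctr <- grid@meta$center %||% c(d[1] * h / 2, d[2] * h / 2)
    xs <- cellCenters(d[1], h) - ctr[1]
    ys <- cellCenters(d[2], h) - ctr[2]
    r2 <- outer(xs^2, ys^2, "+")
    rmax2 <- max(r2)
    bias <- 1 + bias_amplitude * (r2 / rmax2 - 0.5)
    img <- img * rep(bias, dim(img)[3])
  }
  if (noise_sd > 0) {
    img <- img + withSeed(seed, array(rnorm(length(img), 0, noise_sd),
                                      dim(img)))
  }
  new("GrayVolume", intensity = img, spacing = h, origin = grid@origin)
}

#' Edge-preserving bilateral smoothing of a grayscale volume
#'
#' Joint spatial/range Gaussian filter over a spherical voxel
#' neighbourhood of radius three spatial sigmas: voxels contribute in
#' proportion to both their distance and their intensity difference, so
#' noise is averaged away while solid/background edges are preserved.
#' In the `sigma_range -> Inf` limit the filter reduces to plain
#' Gaussian smoothing over the same window.
#'
#' @param vol a [GrayVolume-class].
#' @param sigma_spatial spatial kernel width (m); default one voxel.
#' @param sigma_range intensity kernel width (intensity units).
#' @return A smoothed [GrayVolume-class].
#' @export
smoothBilateral <- function(vol, sigma_spatial = vol@spacing,
                            sigma_range = 0.2) {
  stopifnot(sigma_spatial > 0, sigma_range > 0)
  sv <- sigma_spatial / vol@spacing
  r <- max(1L, as.integer(ceiling(3 * sv)))
  a <- vol@intensity
  d <- dim(a)
  num <- array(0, d); den <- array(0, d)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= r^2 + 1e-9, ]
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  inv2s <- 1 / (2 * sv^2); inv2r <- 1 / (2 * sigma_range^2)
  for (o in seq_len(nrow(offs))) {
    dx <- offs$dx[o]; dy <- offs$dy[o]; dz <- offs$dz[o]
    sh <- a[pmin(pmax(ix + dx, 1L), d[1]),
            pmin(pmax(iy + dy, 1L), d[2]),
            pmin(pmax(iz + dz, 1L), d[3]), drop = FALSE]
    w <- exp(-(dx^2 + dy^2 + dz^2) * inv2s - (sh - a)^2 * inv2r)
    num <- num + w * sh
    den <- den + w
  }
  new("GrayVolume", intensity = num / den, spacing = vol@spacing,
      origin = vol@origin)
}

# Global Otsu threshold of a numeric vector (histogram with `nbins`
# bins). The installed image stack only offers per-frame 2-D
# thresholding, so the 3-D global version is computed here.
otsuThreshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate volume: single-valued histogram")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  hc <- tabulate(
    pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), nbins),
    nbins
  )
  p <- hc / sum(hc)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Segment a grayscale volume by automatic (Otsu) thresholding
#'
#' Computes the global Otsu threshold of the intensity histogram and
#' labels voxels at or above it as SOLID, the rest as LUMEN. When a
#' reference [LabeledGrid-class] is supplied (the CAD grid of the same
#' domain), its WALL voxels, layer tags and chondral-pore collagen
#' (POROUS) are reinstated so that the segmented grid is directly
#' comparable to -- and usable in place of -- the CAD grid in the
#' solvers.
#'
#' @param vol a [GrayVolume-class] with a non-degenerate histogram.
#' @param reference optional [LabeledGrid-class] with identical shape.
#' @return A [LabeledGrid-class].
#' @export
autoThreshold <- function(vol, reference = NULL) {
  thr <- otsuThreshold(as.vector(vol@intensity))
  label <- array(.LABELS[["LUMEN"]], dim(vol@intensity))
  label[vol@intensity >= thr] <- .LABELS[["SOLID"]]
  if (is.null(reference)) {
    layer <- array(.LAYERS[["NONE"]], dim(label))
    return(new("LabeledGrid",
      spacing = vol@spacing, origin = vol@origin, label = label,
      layer = layer, ports = data.frame(),
      meta = list(otsu_threshold = thr)
    ))
  }
  stopifnot(identical(dim(label), dim(reference@label)))
  wall <- reference@label == .LABELS[["WALL"]]
  label[wall] <- .LABELS[["WALL"]]
  spec <- reference@meta$scaffold_spec
  if (!is.null(spec) && spec@collagen_in_chondral_pores) {
    chondral <- reference@layer == .LAYERS[["CHONDRAL"]]
    label[chondral & label == .LABELS[["LUMEN"]]] <- .LABELS[["POROUS"]]
  }
  meta <- reference@meta
  meta$otsu_threshold <- thr
  new("LabeledGrid",
    spacing = vol@spacing, origin = reference@origin, label = label,
    layer = reference@layer, ports = reference@ports, meta = meta
  )
}

#' Crop a labeled grid to an index box
#'
#' Utility for working on sub-volumes (e.g. a quarter scaffold at fine
#' resolution): keeps spacing and shifts the origin; ports and metadata
#' are carried over unchanged.
#'
#' @param grid a [LabeledGrid-class].
#' @param i,j,k integer index ranges to keep.
#' @return A cropped [LabeledGrid-class].
#' @export
cropGrid <- function(grid, i = seq_len(dim(grid@label)[1]),
                     j = seq_len(dim(grid@label)[2]),
                     k = seq_len(dim(grid@label)[3])) {
  new("LabeledGrid",
    spacing = grid@spacing,
    origin = grid@origin +
      c(min(i) - 1L, min(j) - 1L, min(k) - 1L) * grid@spacing,
    label = grid@label[i, j, k, drop = FALSE],
    layer = grid@layer[i, j, k, drop = FALSE],
    ports = grid@ports, meta = grid@meta
  )
}

setMethod("show", "GrayVolume", function(object) {
  d <- dim(object@intensity)
  cat(sprintf(
    "GrayVolume: %d x %d x %d voxels @ %.0f um, intensity [%.3g, %.3g]\n",
    d[1], d[2], d[3], object@spacing * 1e6,
    min(object@intensity), max(object@intensity)
  ))
})

setMethod("show", "ArtifactParams", function(object) {
  cat(sprintf(
    "ArtifactParams: diameter scale %.3f +/- %.3f, sag %.2f, roughness %.0f um, seed %d\n",
    object@diameter_scale_mean, object@diameter_scale_sd,
    object@sag_fraction, object@roughness_amplitude * 1e6, object@seed
  ))
})
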