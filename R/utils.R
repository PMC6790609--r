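# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps the synthetic pathway a pure function
# of its seed without clobbering user RNG.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Cell-centre coordinates along one axis.
cellCenters <- function(n, spacing, origin = 0) {
  origin + (seq_len(n) - 0.5) * spacing
}

# 1-D Gaussian kernel, truncated at 3 sigma, normalized.
gaussKernel1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# Separable 3-D Gaussian blur with replicate-edge padding, applied axis by
# axis. `sigma_vox` is in voxels. Written for 3-D volumes (the installed
# image packages only blur 2-D frames).
gaussBlur3d <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  k <- gaussKernel1d(sigma_vox)
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(a)
  d <- dim(a)
  for (ax in 1:3) {
    n <- d[ax]
    out <- array(0, d)
    for (s in -r:r) {
      idx <- pmin(pmax(seq_len(n) + s, 1L), n)  # replicate edges
      out <- out + k[s + r + 1L] * switch(ax,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE]
      )
    }
    a <- out
  }
  a
}

# Trilinear interpolation of a cell-centred 3-D array at physical points.
# `pts` is an n x 3 matrix (m). Values outside the grid are clamped to the
# nearest cell; NA cells propagate NA.
trilinear <- function(a, spacing, origin, pts) {
  d <- dim(a)
  # continuous index: cell i covers ((i-1)h, i h], centre at (i-0.5)h
  ci <- sweep(pts, 2, origin) / spacing + 0.5
  lo <- pmin(pmax(floor(ci), 1), matrix(rep(d, each = nrow(pts)), ncol = 3))
  hi <- pmin(lo + 1, matrix(rep(d, each = nrow(pts)), ncol = 3))
  fr <- pmin(pmax(ci - lo, 0), 1)
  v <- numeric(nrow(pts))
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    ii <- if (bx) hi[, 1] else lo[, 1]
    jj <- if (by) hi[, 2] else lo[, 2]
    kk <- if (bz) hi[, 3] else lo[, 3]
    w <- (if (bx) fr[, 1] else 1 - fr[, 1]) *
      (if (by) fr[, 2] else 1 - fr[, 2]) *
      (if (bz) fr[, 3] else 1 - fr[, 3])
    v <- v + w * a[cbind(ii, jj, kk)]
  }
  v
}

# Cell-centred velocity components from staggered face arrays.
cellVelocity <- function(field) {
  ux <- field@ux; uy <- field@uy; uz <- field@uz
  d <- dim(field@p)
  list(
    ux = 0.5 * (ux[seq_len(d[1]), , , drop = FALSE] +
                  ux[seq_len(d[1]) + 1L, , , drop = FALSE]),
    uy = 0.5 * (uy[, seq_len(d[2]), , drop = FALSE] +
                  uy[, seq_len(d[2]) + 1L, , drop = FALSE]),
    uz = 0.5 * (uz[, , seq_len(d[3]), drop = FALSE] +
                  uz[, , seq_len(d[3]) + 1L, drop = FALSE])
  )
}

# |u| at cell centres.
speedArray <- function(field) {
  u <- cellVelocity(field)
  sqrt(u$ux^2 + u$uy^2 + u$uz^2)
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 1 means identical masks. Used to score
#' how faithfully the synthetic micro-CT segmentation recovers the
#' CAD-equivalent solid.
#'
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient in \[0, 1\] (1 when both masks are empty).
#' @examples
#' m <- array(c(TRUE, FALSE, TRUE, TRUE), c(2, 2, 1))
#' diceCoefficient(m, m)
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
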