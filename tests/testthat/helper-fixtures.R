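# Shared fixtures. The expensive solves (full-chamber paired run, tube,
# sealed chamber) are computed once per test run and memoized here.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fx)) {
    assign(name, force(expr), envir = .fx)
  }
  get(name, envir = .fx)
}

# --- generic box fixtures -------------------------------------------------

# Rectangular duct: interior nx x ny x nz cells of `fill` label inside a
# one-voxel wall shell; full-face ports at the x ends (or z ends).
boxGrid <- function(nx, ny, nz, h, fill = 1L, ports = NULL, axis = "x",
                    profile = "uniform") {
  d <- c(nx + 2L, ny + 2L, nz + 2L)
  lab <- array(0L, d)
  lab[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- fill
  lay <- array(0L, d)
  lay[lab != 0L] <- gridLayers()[["TOP_CHAMBER"]]
  if (is.null(ports)) {
    big <- 10 * max(ny, nz, nx) * h
    if (axis == "x") {
      ports <- data.frame(
        role = c("inlet", "outlet"), chamber = "top",
        px = c(h, (nx + 1) * h), py = (ny + 2) * h / 2,
        pz = (nz + 2) * h / 2,
        nx = c(-1, 1), ny = 0, nz = 0,
        diameter = big, profile = profile, conc = c(1, NA)
      )
    } else {
      ports <- data.frame(
        role = c("inlet", "outlet"), chamber = "top",
        px = (nx + 2) * h / 2, py = (ny + 2) * h / 2,
        pz = c(h, (nz + 1) * h),
        nx = 0, ny = 0, nz = c(-1, 1),
        diameter = big, profile = profile, conc = c(1, NA)
      )
    }
  }
  new("LabeledGrid", spacing = h, origin = c(0, 0, 0), label = lab,
      layer = lay, ports = ports, meta = list())
}

# An all-zero flow field marked converged (pure-diffusion fixtures).
zeroFlowField <- function(grid) {
  d <- dim(labelArray(grid))
  new("FlowField",
      ux = array(0, d + c(1, 0, 0)), uy = array(0, d + c(0, 1, 0)),
      uz = array(0, d + c(0, 0, 1)), p = array(0, d),
      spacing = voxelSpacing(grid), origin = grid@origin,
      diagnostics = list(converged = TRUE))
}

# Circular tube of radius R (in voxels of size h) bored through solid,
# flowing along z. Used for wall-shear and penalization checks.
tubeGrid <- function(R, h, L) {
  n <- as.integer(ceiling(2 * R / h)) + 2L
  d <- c(n + 2L, n + 2L, L + 2L)
  ctr <- (n + 2) * h / 2
  xs <- (seq_len(n + 2) - 0.5) * h - ctr
  r2 <- outer(xs^2, xs^2, "+")
  lab <- array(0L, d)
  lumen <- r2 <= R^2
  for (k in 2:(L + 1)) {
    s <- matrix(gridLabels()[["SOLID"]], n + 2, n + 2)
    s[lumen] <- gridLabels()[["LUMEN"]]
    lab[, , k] <- s
  }
  lab[1, , ] <- 0L; lab[n + 2, , ] <- 0L
  lab[, 1, ] <- 0L; lab[, n + 2, ] <- 0L
  lab[, , 1] <- 0L; lab[, , L + 2] <- 0L
  lay <- array(0L, d)
  lay[lab == gridLabels()[["LUMEN"]]] <- gridLayers()[["TOP_CHAMBER"]]
  lay[lab == gridLabels()[["SOLID"]]] <- gridLayers()[["OSSEOUS"]]
  ports <- data.frame(
    role = c("inlet", "outlet"), chamber = "top",
    px = ctr, py = ctr, pz = c(h, (L + 1) * h),
    nx = 0, ny = 0, nz = c(-1, 1),
    diameter = 2.5 * R, profile = "parabolic", conc = c(1, NA)
  )
  new("LabeledGrid", spacing = h, origin = c(0, 0, 0), label = lab,
      layer = lay, ports = ports, meta = list())
}

# Fully sealed two-chamber fixture: close-packed separator with every
# non-wall voxel of the separator band forced SOLID (perimeter sealed,
# no cross-path).
sealedChamberGrid <- function(h = 500e-6) {
  spec <- scaffoldSpec(separator_gap = 0)
  g <- suppressWarnings(
    voxelize(buildLattice(spec), chamberSpec(spec), h))
  zb <- g@meta$zbands
  zs <- (seq_len(dim(labelArray(g))[3]) - 0.5) * h
  kz <- which(zs > zb[["osseous_top"]] & zs < zb[["separator_top"]])
  lab <- labelArray(g)
  tmp <- lab[, , kz]
  tmp[tmp != gridLabels()[["WALL"]]] <- gridLabels()[["SOLID"]]
  lab[, , kz] <- tmp
  g@label <- lab
  g
}

# --- memoized expensive solves -------------------------------------------

# Full-chamber paired pipeline at the package's desk-scale default
# (500 um voxels), seed 1.
fxPaired <- function() {
  memo("paired", runPipeline(verbose = FALSE, seed = 1L))
}

# Tube flow + wall shear at 24 cells across the diameter.
fxTube <- function() {
  memo("tube", {
    R <- 0.51e-3
    h <- R / 12
    g <- tubeGrid(R, h, 72L)
    Q <- 0.41e-3 * pi * R^2
    f <- solveFlow(g, bc = flowBC(inlet_flow_rate = c(top = Q)))
    list(grid = g, field = f, wss = wallShearStress(f, g),
         R = R, h = h, ubar = 0.41e-3, Q = Q)
  })
}

fxSealed <- function() {
  memo("sealed", {
    g <- sealedChamberGrid()
    f <- solveFlow(g)
    conc <- solveTransport(f, g)
    list(grid = g, field = f, conc = conc)
  })
}

# Square duct with a parabolic inlet, long enough to develop.
fxSquareDuct <- function() {
  memo("squareduct", {
    g <- boxGrid(64L, 32L, 32L, 1e-4, axis = "x", profile = "parabolic")
    f <- solveFlow(g, bc = flowBC(inlet_flow_rate = c(top = 1e-9)))
    list(grid = g, field = f)
  })
}

# Quasi-2-D plane-Poiseuille channel (32 cells across the gap).
fxPoiseuille <- function() {
  memo("poiseuille", {
    g <- boxGrid(48L, 32L, 3L, 1e-4)
    bc <- flowBC(inlet_flow_rate = c(top = 1e-9),
                 slip_axes = c(FALSE, FALSE, TRUE))
    list(grid = g, field = solveFlow(g, bc = bc), bc = bc)
  })
}

# Tube re-solved at twice the flow (linearity checks).
fxTube2x <- function() {
  memo("tube2x", {
    tube <- fxTube()
    f2 <- solveFlow(tube$grid,
                    bc = flowBC(inlet_flow_rate = c(top = 2 * tube$Q)))
    list(field = f2, wss = wallShearStress(f2, tube$grid))
  })
}

# Default scaffold at the 50 um micro-CT resolution (short plenums:
# only the scaffold matters for the geometry checks).
fxGrid50 <- function() {
  memo("grid50", {
    spec <- scaffoldSpec()
    ch <- chamberSpec(spec, plenum_top = 1e-3, plenum_bottom = 1e-3)
    voxelize(buildLattice(spec), ch, 50e-6)
  })
}

# Zero-artifact synthetic micro-CT round trip on a quarter scaffold at
# the 50 um default resolution.
fxRoundTrip50 <- function() {
  memo("roundtrip50", {
    g <- fxGrid50()
    d <- dim(labelArray(g))
    zb <- g@meta$zbands
    h <- voxelSpacing(g)
    kz <- which((seq_len(d[3]) - 0.5) * h > zb[["scaffold_bottom"]] &
                  (seq_len(d[3]) - 0.5) * h < zb[["scaffold_top"]])
    q <- cropGrid(g, i = (d[1] %/% 2):d[1], j = (d[2] %/% 2):d[2],
                  k = kz)
    vol <- renderGrayscale(q, psf_sigma = 0.5 * h, noise_sd = 0.05,
                           bias_amplitude = 0.05, seed = 4L)
    vol <- smoothBilateral(vol, sigma_spatial = h, sigma_range = 0.2)
    seg <- autoThreshold(vol, reference = q)
    list(ref = q, seg = seg)
  })
}

# --- independent oracles --------------------------------------------------

# Monte-Carlo point-in-strut-set porosity oracle, written independently
# of the package's voxelizer: samples points uniformly in the layer's
# bounding cylinder and tests them against each capped cylinder
# directly.
mcPorosityOracle <- function(struts, R, z0, z1, n = 1e6, seed = 99) {
  st <- strutTable(struts)
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  rr <- R * sqrt(runif(n))
  px <- rr * cos(th); py <- rr * sin(th)
  pz <- runif(n, z0, z1)
  inside <- rep(FALSE, n)
  for (s in seq_len(nrow(st))) {
    p0 <- c(st$x0[s], st$y0[s], st$z0[s])
    p1 <- c(st$x1[s], st$y1[s], st$z1[s])
    ax <- p1 - p0
    len2 <- sum(ax^2)
    t <- ((px - p0[1]) * ax[1] + (py - p0[2]) * ax[2] +
            (pz - p0[3]) * ax[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (p0[1] + t * ax[1])
    dy <- py - (p0[2] + t * ax[2])
    dz <- (pz - (p0[3] + t * ax[3])) / st$zscale[s]
    inside <- inside | (dx^2 + dy^2 + dz^2 <= st$radius[s]^2)
  }
  1 - mean(inside)
}

# Series solution for laminar flow in a square duct (side 2a): the
# ratio of centreline to mean velocity. Independent closed form.
squareDuctCenterlineRatio <- function(nterms = 101) {
  ns <- seq(1, nterms, by = 2)
  # velocity profile terms at the centre (y = 0, z = 0)
  uc <- sum((-1)^((ns - 1) / 2) / ns^3 * (1 - 1 / cosh(ns * pi / 2)))
  # mean velocity: integrate the series over the cross-section
  um <- sum(1 / ns^4 * (2 / pi) *
              (1 - (2 / (ns * pi)) * tanh(ns * pi / 2)))
  uc / um
}

# 1-D advection-diffusion two-point boundary solution on [0, L] with
# c(0) = 1, c(L) = 0.
advDiffProfile <- function(x, U, D, L) {
  (exp(U * x / D) - exp(U * L / D)) / (1 - exp(U * L / D))
}
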