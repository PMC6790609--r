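test_that("velocity statistics on uniform and quiescent fields", {
  g <- boxGrid(8L, 8L, 8L, 1e-4)
  f <- zeroFlowField(g)
  expect_equal(unname(velocityStats(f, g, "top_chamber")), c(0, 0))
  f@ux[, , ] <- 1e-4  # uniform plug, 100 um/s
  v <- velocityStats(f, g, "top_chamber")
  expect_equal(v[["mean"]], 100)
  expect_equal(v[["max"]], 100)
  expect_error(velocityStats(f, g, "chondral"), "no fluid voxels")
})

test_that("plane Poiseuille layer statistics give max/mean of 1.5", {
  h <- 1e-4
  g <- boxGrid(48L, 32L, 3L, h)
  f <- solveFlow(g, bc = flowBC(inlet_flow_rate = c(top = 1e-9),
                                slip_axes = c(FALSE, FALSE, TRUE)))
  # restrict to the developed region to avoid entrance effects
  gsub <- cropGrid(g, i = 25:45)
  fsub <- new("FlowField",
              ux = f@ux[25:46, , , drop = FALSE],
              uy = f@uy[25:45, , , drop = FALSE],
              uz = f@uz[25:45, , , drop = FALSE],
              p = f@p[25:45, , , drop = FALSE],
              spacing = h, origin = gsub@origin,
              diagnostics = list(converged = TRUE))
  v <- velocityStats(fsub, gsub, "top_chamber")
  expect_equal(v[["max"]] / v[["mean"]], 1.5, tolerance = 0.02)
})

test_that("interstitial velocity rescales porous voxels by porosity", {
  g <- boxGrid(8L, 8L, 8L, 1e-4, fill = gridLabels()[["POROUS"]])
  g@layer[labelArray(g) != 0L] <- gridLayers()[["CHONDRAL"]]
  f <- zeroFlowField(g)
  f@ux[, , ] <- 9e-5
  sup <- velocityStats(f, g, "chondral")
  int <- velocityStats(f, g, "chondral", interstitial = TRUE,
                       porosity = 0.9)
  expect_equal(int[["mean"]], sup[["mean"]] / 0.9)
})

test_that("plane Couette shear is recovered exactly", {
  h <- 1e-4
  nz <- 20L
  d <- c(6L, 6L, nz + 4L)
  lab <- array(gridLabels()[["LUMEN"]], d)
  lab[, , 1:2] <- gridLabels()[["SOLID"]]
  lay <- array(gridLayers()[["TOP_CHAMBER"]], d)
  lay[lab == gridLabels()[["SOLID"]]] <- gridLayers()[["OSSEOUS"]]
  g <- new("LabeledGrid", spacing = h, origin = c(0, 0, 0), label = lab,
           layer = lay, ports = data.frame(), meta = list())
  U <- 1e-3
  gap <- nz * h
  f <- zeroFlowField(g)
  zc <- (seq_len(d[3]) - 0.5) * h
  for (k in seq_len(d[3])) {
    f@ux[, , k] <- U * max(zc[k] - 2 * h, 0) / gap
  }
  w <- wallShearStress(f, g)
  tau <- w@tau[3, 3, ]
  tau <- tau[!is.na(tau)]
  expect_equal(tau, 1e-3 * U / gap, tolerance = 1e-10)
  st <- fssStats(w, g, "osseous")
  expect_equal(st[["mean"]], 1e-3 * U / gap * 1e3, tolerance = 1e-6)
  expect_equal(st[["max"]], st[["mean"]], tolerance = 1e-6)
})

test_that("quiescent flow produces zero shear stress", {
  tube <- fxTube()
  f0 <- zeroFlowField(tube$grid)
  w0 <- wallShearStress(f0, tube$grid)
  expect_equal(max(w0@tau, na.rm = TRUE), 0)
  expect_error(fssStats(w0, tube$grid, "chondral"), "no surface voxels")
})

test_that("Poiseuille tube wall shear matches 4 mu ubar / R", {
  tube <- fxTube()
  kmid <- 37L
  ring <- tube$wss@tau[, , kmid]
  ring <- ring[!is.na(ring)]
  tau_ref <- 4 * 1e-3 * tube$ubar / tube$R
  expect_equal(mean(ring), tau_ref, tolerance = 0.10)
})

test_that("shear statistics scale linearly with the flow rate", {
  tube <- fxTube()
  t2 <- fxTube2x()
  f2 <- t2$field
  w2 <- t2$wss
  s1 <- fssStats(tube$wss, tube$grid, "osseous")
  s2 <- fssStats(w2, tube$grid, "osseous")
  expect_equal(s2[["mean"]] / s1[["mean"]], 2, tolerance = 1e-6)
  expect_equal(s2[["max"]] / s1[["max"]], 2, tolerance = 1e-6)
  v1 <- velocityStats(tube$field, tube$grid, "top_chamber")
  v2 <- velocityStats(f2, tube$grid, "top_chamber")
  expect_equal(v2[["mean"]] / v1[["mean"]], 2, tolerance = 1e-6)
  expect_equal(v2[["max"]] / v1[["max"]], 2, tolerance = 1e-6)
})

test_that("concentration statistics are volume means over fluid voxels", {
  g <- boxGrid(8L, 8L, 8L, 1e-4)
  cf <- new("ConcentrationField",
            conc = array(1, dim(labelArray(g))), spacing = 1e-4,
            origin = c(0, 0, 0), diagnostics = list())
  expect_equal(concentrationStats(cf, g, "top_chamber"), 1.0)
  # linear diffusion slab spanning the layer symmetrically
  zc <- (seq_len(dim(labelArray(g))[3]) - 0.5) / 8 - 1.5 / 8
  for (k in seq_along(zc)) cf@conc[, , k] <- min(max(zc[k], 0), 1)
  expect_equal(concentrationStats(cf, g, "top_chamber"),
               mean(pmin(pmax(zc[2:9], 0), 1)))
})

test_that("line profiles sample constant, linear, and slab fields", {
  h <- 1e-4
  nz <- 40L
  ports <- data.frame(
    role = "inlet", chamber = c("bottom", "top"),
    px = 3 * h, py = 3 * h, pz = c(h, (nz + 1) * h),
    nx = 0, ny = 0, nz = c(-1, 1),
    diameter = 40 * h, profile = "uniform", conc = c(0, 1)
  )
  g <- boxGrid(4L, 4L, nz, h, ports = ports)
  cf <- solveTransport(zeroFlowField(g), g)
  from <- c(3 * h, 3 * h, 1.5 * h)   # cell-centre endpoints
  to <- c(3 * h, 3 * h, 39.5 * h)
  pr <- lineProfile(cf, from, to, n = 77L)
  # linear slab: the sampled line is linear and endpoint values match
  expect_equal(pr$value[1], cf@conc[3, 3, 2])
  expect_equal(tail(pr$value, 1), cf@conc[3, 3, 40])
  fit <- lm(value ~ s, data = pr)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  # constant field: flat profile
  cf@conc[!is.na(cf@conc)] <- 0.25
  pr2 <- lineProfile(cf, from, to, n = 10L)
  expect_equal(pr2$value, rep(0.25, 10))
  # segment exiting the domain errors
  expect_error(
    lineProfile(cf, from, c(3 * h, 3 * h, (nz + 10) * h)),
    "exits"
  )
})

test_that("report comparison reproduces signed percent differences", {
  tab <- function(mv_ch, mv_os, mx_ch = 400, mx_os = 1500) {
    data.frame(
      layer = c("chondral", "osseous"),
      mean_v_um_s = c(mv_ch, mv_os), max_v_um_s = c(mx_ch, mx_os),
      mean_fss_mpa = c(0.03, 0.14), max_fss_mpa = c(12, 13),
      mean_conc = c(0.96, 0.2)
    )
  }
  a <- new("MicroenvReport", table = tab(5.57, 26.4, 322, 1320),
           mixing = c(top = 0.05, bottom = 0.2), extras = list())
  # identical reports: all-zero differences
  self <- compareReports(a, a)
  expect_true(all(self$pct_diff == 0))
  # the documented CAD -> manufactured changes: 26.4 -> 60.8 is +130 %,
  # 322 -> 176 is -45 %
  b <- new("MicroenvReport", table = tab(4.06, 60.8, 176, 919),
           mixing = c(top = 0.05, bottom = 0.2), extras = list())
  cmp <- compareReports(a, b, digits = 0)
  expect_equal(
    cmp$pct_diff[cmp$layer == "osseous" & cmp$metric == "mean_v_um_s"],
    130)
  expect_equal(
    cmp$pct_diff[cmp$layer == "chondral" & cmp$metric == "max_v_um_s"],
    -45)
  # zero reference entries are flagged, not NaN-propagated
  z <- a
  z@table$mean_fss_mpa[1] <- 0
  cmp2 <- compareReports(z, b)
  row <- cmp2[cmp2$layer == "chondral" & cmp2$metric == "mean_fss_mpa", ]
  expect_true(row$undefined)
  expect_true(is.na(row$pct_diff))
})

test_that("report invariants hold on the full pipeline output", {
  rep <- fxPaired()$cad$report
  t <- reportTable(rep)
  expect_true(all(t$max_v_um_s >= t$mean_v_um_s))
  expect_true(all(t$max_fss_mpa >= t$mean_fss_mpa))
  expect_true(all(t$mean_conc >= 0 & t$mean_conc <= 1))
  mx <- mixingFractions(rep)
  expect_true(all(mx >= 0 & mx <= 1))
})
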