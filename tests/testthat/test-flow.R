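test_that("inlet velocity reproduces the pump operating point", {
  # 0.02 ml/min through the 1.02 mm tubing bore
  v <- inletVelocity(mlPerMin(0.02), 1.02e-3)
  expect_equal(v * 1e3, 0.41, tolerance = 0.005 / 0.41)
  # area scaling: doubling the diameter quarters the velocity
  expect_equal(inletVelocity(mlPerMin(0.02), 2.04e-3), v / 4)
  # unit round trip: 0.02 ml/min is 1/3 mm^3/s
  expect_equal(mlPerMin(0.02), 0.02 / 60 * 1e-6)
  expect_equal(mlPerMin(0.02) * 1e9, 1 / 3, tolerance = 1e-12)
})

test_that("Reynolds number flags the flow regime", {
  re <- reynoldsNumber(fluidProps(), 0.41e-3, 1.02e-3)
  expect_equal(re, 1000 * 0.41e-3 * 1.02e-3 / 1e-3, tolerance = 1e-12)
  expect_equal(re, 0.42, tolerance = 0.01)
  expect_equal(reynoldsNumber(fluidProps(), 0, 1e-3), 0)
  thick <- fluidProps(dynamic_viscosity = 1e9)
  expect_lt(reynoldsNumber(thick, 1, 1), 1e-5)
  expect_warning(reynoldsNumber(fluidProps(), 0.1, 1e-2), "Stokes|laminar")
})

test_that("plane Poiseuille: parabolic profile with umax/umean = 1.5", {
  px <- fxPoiseuille()
  prof <- px$field@ux[36, 2:33, 3]
  expect_equal(max(prof) / mean(prof), 1.5, tolerance = 0.02)
  # mass conservation to solver tolerance
  mc <- checkMassConservation(px$field, px$grid, px$bc)
  expect_lt(mc$global, 1e-6)
})

test_that("square duct centerline velocity matches the series solution", {
  sd <- fxSquareDuct()
  # far enough downstream to be fully developed
  sl <- sd$field@ux[52, 2:33, 2:33]
  ratio <- sl[16, 16] / mean(sl)
  expect_equal(ratio, squareDuctCenterlineRatio(), tolerance = 0.02)
})

test_that("Darcy slab pressure drop matches mu L V / k", {
  h <- 1e-4
  g <- boxGrid(24L, 8L, 8L, h, fill = gridLabels()[["POROUS"]])
  k <- 1e-12
  V <- 1e-5
  Q <- V * (8 * h)^2
  bc <- flowBC(inlet_flow_rate = c(top = Q),
               slip_axes = c(FALSE, TRUE, TRUE))
  f <- solveFlow(g, porous = porousProps(permeability = k), bc = bc)
  p <- f@p[2:25, 5, 5]
  dp_per_m <- -(p[24] - p[1]) / (23 * h)
  expect_equal(dp_per_m * 1e-3, 1e-3 * 1e-3 * V / k,
               tolerance = 0.03)   # mu L V / k = 10 Pa over 1 mm
})

test_that("zero inflow gives a quiescent field at outlet pressure", {
  g <- boxGrid(12L, 8L, 8L, 1e-4)
  f <- solveFlow(g, bc = flowBC(inlet_flow_rate = c(top = 0)))
  expect_equal(max(abs(f@ux)), 0)
  expect_equal(max(abs(f@uz)), 0)
  expect_true(all(abs(f@p[!is.na(f@p)]) < 1e-12))
})

test_that("high-permeability Brinkman recovers the open-lumen solution", {
  h <- 1e-4
  bc <- flowBC(inlet_flow_rate = c(top = 1e-9),
               slip_axes = c(FALSE, FALSE, TRUE))
  g_open <- boxGrid(32L, 16L, 3L, h)
  g_por <- boxGrid(32L, 16L, 3L, h, fill = gridLabels()[["POROUS"]])
  f_open <- solveFlow(g_open, bc = bc)
  f_por <- solveFlow(g_por, porous = porousProps(permeability = 1e-4),
                     bc = bc)
  scale <- max(abs(f_open@ux))
  expect_lt(max(abs(f_por@ux - f_open@ux)) / scale, 0.01)
})

test_that("penalization confines velocity inside struts", {
  tube <- fxTube()
  sp <- speedArray(tube$field)
  lab <- labelArray(tube$grid)
  solid <- lab == gridLabels()[["SOLID"]]
  # voxels >= 2 cells from any fluid: erode the solid mask twice
  deep <- solid
  for (rep in 1:2) {
    er <- deep
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      idx <- pmin(pmax(seq_len(dim(deep)[ax]) + s, 1L), dim(deep)[ax])
      er <- er & switch(ax, deep[idx, , ], deep[, idx, ], deep[, , idx])
    }
    deep <- er
  }
  u_in <- inletVelocity(tube$Q, 2 * tube$R)
  expect_lt(max(sp[deep]) / u_in, 1e-4)
})

test_that("mirror-symmetric geometry yields a mirror-symmetric solution", {
  h <- 1e-4
  g <- boxGrid(24L, 16L, 16L, h, profile = "parabolic")
  f <- solveFlow(g, bc = flowBC(inlet_flow_rate = c(top = 1e-9)))
  ny <- dim(f@ux)[2]
  flipped <- f@ux[, rev(seq_len(ny)), ]
  expect_lt(max(abs(f@ux - flipped)) / max(abs(f@ux)), 1e-6)
})

test_that("velocity error decreases monotonically under refinement", {
  # plane-Poiseuille umax/umean ratio error at 8, 16, 32 cells
  errs <- vapply(c(8L, 16L, 32L), function(ny) {
    g <- boxGrid(3L * ny, ny, 3L, 1e-4)
    f <- solveFlow(g, bc = flowBC(
      inlet_flow_rate = c(top = 1e-9),
      slip_axes = c(FALSE, FALSE, TRUE)))
    prof <- f@ux[as.integer(2.5 * ny), 2:(ny + 1), 3]
    abs(max(prof) / mean(prof) - 1.5)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_gt(log2(errs[1] / errs[3]) / 2, 1)  # observed order >= 1
})

test_that("a sealed two-chamber domain conserves mass per chamber", {
  s <- fxSealed()
  mc <- checkMassConservation(s$field, s$grid, flowBC())
  expect_lt(mc$global, 1e-6)
  expect_true(all(mc$per_chamber < 1e-6))
})

test_that("an unconverged solve reports rather than hides the imbalance", {
  g <- boxGrid(24L, 12L, 12L, 1e-4)
  expect_error(
    solveFlow(g, bc = flowBC(inlet_flow_rate = c(top = 1e-9)),
              max_iter = 1L),
    "did not converge"
  )
})

test_that("a grid with no ports is refused as sealed", {
  g <- boxGrid(8L, 8L, 8L, 1e-4)
  g@ports <- data.frame()
  expect_error(solveFlow(g), "sealed|ports")
})
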