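test_that("lattice matches the printed strut dimensions and pitches", {
  spec <- scaffoldSpec()
  st <- strutTable(buildLattice(spec))
  expect_setequal(unique(round(st$radius * 1e6)), c(250, 500))
  # chondral in-layer pitch = strut + spacing = 1000 um
  ch <- st[st$layer == "chondral", ]
  lay1 <- ch[abs(ch$z0 - min(ch$z0)) < 1e-9, ]
  offs <- sort(lay1$y0)
  expect_equal(unique(round(diff(offs) * 1e6)), 1000)
  # osseous pitch at the default midpoint spacing: 1000 + 1250 = 2250 um
  os <- st[st$layer == "osseous", ]
  lay2 <- os[abs(os$z0 - min(os$z0)) < 1e-9, ]
  pitches <- round(diff(sort(unique(c(lay2$y0, lay2$x0)[
    abs(c(lay2$y0, lay2$x0)) < 6e-3]))) * 1e6)
  expect_true(2250 %in% pitches)
  # culture orientation: osseous at the bottom, chondral on top
  expect_lt(max(os$z0), min(ch$z0))
})

test_that("over-tall section stack is rejected with a message", {
  expect_error(
    scaffoldSpec(chondral_height = 8e-3, osseous_height = 8e-3),
    "exceed"
  )
})

test_that("close-packed layer solid fraction approaches pi/4", {
  spec <- scaffoldSpec(chondral_spacing = 0)
  st <- strutTable(buildLattice(spec))
  lay1 <- st[st$layer == "chondral" &
               abs(st$z0 - min(st$z0[st$layer == "chondral"])) < 1e-9, ]
  lens <- sqrt((lay1$x1 - lay1$x0)^2 + (lay1$y1 - lay1$y0)^2)
  vol <- sum(pi * lay1$radius^2 * lens)
  R <- spec@cylinder_diameter / 2
  slab <- pi * R^2 * spec@chondral_strut_d
  expect_equal(vol / slab, pi / 4, tolerance = 0.06)
})

test_that("empty strut set voxelizes to an all-lumen cavity", {
  spec <- scaffoldSpec(collagen_in_chondral_pores = FALSE)
  empty <- new("StrutSet",
               struts = strutTable(buildLattice(spec))[0, ], spec = spec)
  g <- voxelize(empty, chamberSpec(spec), 500e-6)
  lab <- labelArray(g)
  expect_setequal(unique(as.vector(lab)),
                  gridLabels()[c("WALL", "LUMEN")])
})

test_that("voxelized single-strut volume matches the analytic cylinder", {
  # capped cylinder (hemispherical ends) fully inside the envelope
  spec <- scaffoldSpec(
    cylinder_diameter = 4e-3, cylinder_height = 4e-3,
    chondral_height = 2e-3, osseous_height = 1e-3,
    separator_layers = 1L
  )
  r <- 0.4e-3
  st <- data.frame(
    x0 = -1e-3, y0 = 0, z0 = 2e-3, x1 = 1e-3, y1 = 0, z1 = 2e-3,
    radius = r, layer = "osseous", zscale = 1, rough_amp = 0,
    rough_f1 = 0, rough_p1 = 0, rough_f2 = 0, rough_p2 = 0
  )
  struts <- new("StrutSet", struts = st, spec = spec)
  h <- r / 10
  g <- suppressWarnings(voxelize(
    struts, chamberSpec(spec, plenum_top = 1e-3, plenum_bottom = 1e-3), h))
  vox <- sum(labelArray(g) == gridLabels()[["SOLID"]]) * h^3
  analytic <- pi * r^2 * 2e-3 + 4 / 3 * pi * r^3
  expect_equal(vox, analytic, tolerance = 0.03)
})

test_that("close-packed separator is denser than the osseous mesh", {
  g <- suppressWarnings(
    voxelize(buildLattice(scaffoldSpec()), chamberSpec(), 250e-6))
  solidFrac <- function(layer) 1 - porosity(g, layer)
  expect_lt(solidFrac("osseous"), solidFrac("separator"))
})

test_that("porosity is 1 in open layers, 0 in solid ones, errors on unknown tags", {
  g <- boxGrid(6L, 6L, 6L, 1e-4)
  expect_equal(porosity(g, "top_chamber"), 1.0)
  lab <- labelArray(g)
  lab[lab == 1L] <- gridLabels()[["SOLID"]]
  g@label <- lab
  expect_equal(porosity(g, "top_chamber"), 0.0)
  expect_error(porosity(g, "mantle"), "unknown layer")
  expect_error(porosity(g, "chondral"), "not present")
})

test_that("voxelized chondral porosity agrees with the Monte-Carlo oracle", {
  spec <- scaffoldSpec()
  lat <- buildLattice(spec)
  g <- fxGrid50()
  # oracle works in scaffold-local coordinates
  mc <- mcPorosityOracle(
    lat, R = spec@cylinder_diameter / 2,
    z0 = spec@osseous_height + spec@separator_layers *
      spec@separator_strut_d,
    z1 = spec@cylinder_height, n = 1e6
  )
  expect_equal(porosity(g, "chondral"), mc, tolerance = 0.03)
})

test_that("labels and layers partition the grid", {
  g <- fxPaired()$cad$grid
  expect_true(all(labelArray(g) %in% gridLabels()))
  expect_true(all(layerArray(g) %in% gridLayers()))
  # every non-wall voxel carries a real layer tag and vice versa
  expect_true(all(
    (labelArray(g) == gridLabels()[["WALL"]]) ==
      (layerArray(g) == gridLayers()[["NONE"]])
  ))
})

test_that("in-plane lattice rotation leaves per-layer porosity unchanged", {
  # at the 50 um default resolution the remaining differences are
  # voxelization aliasing, bounded at 2 porosity points
  ch <- chamberSpec(scaffoldSpec(), plenum_top = 1e-3,
                    plenum_bottom = 1e-3)
  g0 <- fxGrid50()
  g30 <- voxelize(buildLattice(scaffoldSpec(rotation_deg = 30)), ch,
                  50e-6)
  for (layer in c("chondral", "separator", "osseous")) {
    expect_lt(abs(porosity(g30, layer) - porosity(g0, layer)), 0.02)
  }
})

test_that("voxelized solid volume converges to the strut-set volume", {
  spec <- scaffoldSpec(
    cylinder_diameter = 4e-3, cylinder_height = 4e-3,
    chondral_height = 2e-3, osseous_height = 1e-3,
    separator_layers = 1L
  )
  r <- 0.4e-3
  st <- data.frame(
    x0 = -1e-3, y0 = 0.1e-3, z0 = 2e-3, x1 = 1e-3, y1 = 0.1e-3,
    z1 = 2e-3, radius = r, layer = "osseous", zscale = 1,
    rough_amp = 0, rough_f1 = 0, rough_p1 = 0, rough_f2 = 0,
    rough_p2 = 0
  )
  struts <- new("StrutSet", struts = st, spec = spec)
  analytic <- pi * r^2 * 2e-3 + 4 / 3 * pi * r^3
  ch <- chamberSpec(spec, plenum_top = 1e-3, plenum_bottom = 1e-3)
  errs <- vapply(c(r / 4, r / 8, r / 16), function(h) {
    g <- suppressWarnings(voxelize(struts, ch, h))
    abs(sum(labelArray(g) == gridLabels()[["SOLID"]]) * h^3 - analytic) /
      analytic
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # observed order >= 1: halving h at least halves the error (with slack)
  expect_gt(log2(errs[1] / errs[3]) / 2, 0.9)
})

test_that("resolution guard warns on coarse voxels and ports must sit on the wall", {
  spec <- scaffoldSpec()
  lat <- buildLattice(spec)
  expect_warning(voxelize(lat, chamberSpec(spec), 500e-6), "resolution")
  bad <- chamberSpec(spec)
  bad@ports$pz <- bad@ports$pz + 1  # 1 m above the chamber
  expect_error(suppressWarnings(voxelize(lat, bad, 500e-6)),
               "outside the chamber wall")
})
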