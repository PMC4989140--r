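test_that("default rasterization resolves the vessel layers exactly", {
  geo <- aorta_geometry()
  dom <- build_domain(geo, grid_spacing = 2.5e-4)
  g <- dom$grid
  mid <- which.min(abs(g$xc))
  col <- dom$material[mid, ]
  # 1.5 mm wall at 0.25 mm spacing spans exactly 6 cell rows per side
  expect_equal(sum(col == 2L & g$yc > 0), 6L)
  expect_equal(sum(col == 2L & g$yc < 0), 6L)
  # 12 mm vessel strip: 9 mm lumen + two 1.5 mm walls
  expect_equal(sum(col == 1L) * 2.5e-4, 0.009)
  expect_equal((sum(col == 1L) + sum(col == 2L)) * 2.5e-4, 0.012)
})

test_that("cell-area bookkeeping matches the analytic rectangle areas", {
  geo <- small_geometry()
  for (h in c(5e-4, 2.5e-4)) {
    dom <- build_domain(geo, grid_spacing = h)
    areas <- outer(dom$grid$dx, dom$grid$dy)
    a_blood <- sum(areas[dom$material == 1L])
    a_wall <- sum(areas[dom$material == 2L])
    exact_blood <- geo$lumen_diameter * geo$vessel_length
    exact_wall <- 2 * geo$wall_thickness * geo$vessel_length
    # within one interface cell row of the exact value
    slack <- h * geo$vessel_length + h * geo$muscle_height
    expect_lt(abs(a_blood - exact_blood), slack)
    expect_lt(abs(a_wall - exact_wall), slack)
    a_total <- sum(areas)
    expect_equal(a_total, geo$muscle_width * geo$muscle_height,
                 tolerance = 1e-12)
  }
})

test_that("invalid geometry and resolution are rejected", {
  expect_error(aorta_geometry(vessel_diameter = 0.012, muscle_height = 0.01),
               "geometry error")
  expect_error(aorta_geometry(vessel_diameter = 0.002,
                              wall_thickness = 0.0015), "geometry error")
  expect_error(build_domain(small_geometry(), grid_spacing = 1e-3),
               "resolution error")
})

test_that("endovascular electrodes are placed symmetrically with alternating polarity", {
  cfg <- electrode_configuration(1, 4, spacing = 0.013)
  expect_equal(cfg$potentials, c(40, 0, 40, 0))
  expect_equal(diff(range(cfg$x_centers)), 0.039)
  dom <- build_model(small_geometry(), cfg, grid_spacing = 5e-4)
  g <- dom$grid
  for (k in 1:4) {
    cells <- which(dom$electrode_id == k, arr.ind = TRUE)
    expect_equal(mean(g$xc[cells[, 1]]), cfg$x_centers[k], tolerance = 1e-9)
    expect_equal(mean(g$yc[cells[, 2]]), 0, tolerance = 1e-9)
  }
  # group centered on the vessel midpoint for a range of n and d
  for (n in 2:4) for (d in c(0.004, 0.01)) {
    cfg2 <- electrode_configuration(1, n, spacing = d)
    dom2 <- build_model(small_geometry(), cfg2, grid_spacing = 5e-4)
    xs <- dom2$grid$xc[which(rowSums(dom2$electrode_id > 0) > 0)]
    expect_equal(mean(range(xs)), 0, tolerance = 1e-9)
  }
})

test_that("odd scheme-1 counts have an active center and even counts balance", {
  cfg3 <- electrode_configuration(1, 3, spacing = 0.017)
  expect_equal(cfg3$potentials, c(0, 40, 0))
  for (n in c(2, 4)) {
    p <- electrode_configuration(1, n, spacing = 0.01)$potentials
    expect_equal(sum(p > 0), n / 2)
  }
})

test_that("overlapping or oversized electrode requests fail loudly", {
  expect_error(electrode_configuration(1, 2, spacing = 0),
               "configuration error")
  expect_error(electrode_configuration(1, 2, spacing = 5e-4),
               "configuration error")
  expect_error(electrode_configuration(1, 1), "configuration error")
  geo <- small_geometry()
  cfg <- electrode_configuration(1, 4, spacing = 0.05)  # span 150 mm
  expect_error(build_model(geo, cfg, grid_spacing = 5e-4), "placement error")
})

test_that("scheme 3 builds the extended domain with the remote return", {
  cfg <- electrode_configuration(3, 1)
  dom <- build_model(aorta_geometry(), cfg, grid_spacing = 5e-4)
  g <- dom$grid
  # domain top contains a plate whose lower face is 40 cm above the wall
  expect_gte(max(g$y), 0.006 + 0.4 + 0.015 - 1e-9)
  ret <- which(dom$electrode_id == 2L, arr.ind = TRUE)
  expect_true(all(g$yc[ret[, 2]] > 0.4))
  areas <- outer(g$dx, g$dy)
  expect_equal(sum(areas[dom$electrode_id == 2L]), 0.15 * 0.015,
               tolerance = 0.02)
  # single 1x1 mm active electrode in the lumen
  act <- which(dom$electrode_id == 1L, arr.ind = TRUE)
  expect_equal(sum(areas[dom$electrode_id == 1L]), 1e-6, tolerance = 1e-9)
  expect_true(all(abs(g$yc[act[, 2]]) < dom$geometry$r_lumen))
})

test_that("scheme 2 places returns above and below the wall at the midpoint", {
  cfg <- electrode_configuration(2, 3, spacing = 0.0145)
  dom <- build_model(small_geometry(), cfg, grid_spacing = 5e-4)
  g <- dom$grid
  ys <- numeric(0)
  for (k in 4:5) {
    cells <- which(dom$electrode_id == k, arr.ind = TRUE)
    expect_equal(mean(g$xc[cells[, 1]]), 0, tolerance = 1e-6)
    ys <- c(ys, mean(g$yc[cells[, 2]]))
  }
  expect_equal(sort(ys), c(-0.009, 0.009), tolerance = 1e-4)
  expect_equal(dom$electrode_potential[4:5], c(0, 0))
})

test_that("halving the spacing preserves material areas to O(h)", {
  geo <- small_geometry()
  d1 <- build_domain(geo, 5e-4)
  d2 <- build_domain(geo, 2.5e-4)
  for (code in 1:3) {
    a1 <- sum(outer(d1$grid$dx, d1$grid$dy)[d1$material == code])
    a2 <- sum(outer(d2$grid$dx, d2$grid$dy)[d2$material == code])
    expect_lt(abs(a1 - a2) / a2, 0.06)
  }
})
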