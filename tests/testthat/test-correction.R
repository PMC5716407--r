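test_that("correction factors on identical grids are exactly 1", {
  g <- dose_grid(array(runif(27) + 1, c(3, 3, 3)), array(0, c(3, 3, 3)),
                 c(2, 2, 2), c(0, 0, 0))
  expect_equal(cf_smc(g, g, c(2, 2, 2)), 1)
  expect_equal(cf_pba(g, g, c(2, 2, 2)), 1)
})

test_that("SMC correction factor hits 1.0 in the plateau and 1/0.73 at the peak", {
  res <- water_pristine_run()
  cf_plateau <- cf_smc(res$ppic, res$mosfet, c(0, 0, 30))
  expect_equal(cf_plateau, 1, tolerance = 1e-6)
  z_peak <- 236.5
  cf_peak <- cf_smc(res$ppic, res$mosfet, c(0, 0, z_peak))
  # 1/0.73 = 1.370 within statistical error + voxel averaging
  expect_equal(cf_peak, 1 / 0.73, tolerance = 0.03)
  # in-field CF never drops below 1 for a sensitivity <= 1 model
  infield <- res$ppic$dose > 0.1 * max(res$ppic$dose)
  expect_true(all(res$ppic$dose[infield] >= res$mosfet$dose[infield] - 1e-12))
  # out-of-field point is rejected
  expect_error(cf_smc(res$ppic, res$mosfet, c(55, 55, 250)), "out of field")
})

test_that("CF is invariant to the global normalization of the grids", {
  res <- water_pristine_run()
  p <- c(0, 0, 200)
  scaled <- res
  scaled$ppic$dose <- res$ppic$dose * 37
  scaled$mosfet$dose <- res$mosfet$dose * 37
  expect_equal(cf_smc(scaled$ppic, scaled$mosfet, p),
               cf_smc(res$ppic, res$mosfet, p))
})

test_that("PBA and SMC correction factors agree in water", {
  fx <- fix190_sobp()
  smc <- water_sobp_run()
  beam <- beam_spec(nominal_range = 239, sobp_width = 50, range_shifter = 7.5,
                    field_radius = 20)
  pba <- run_pba(water_tank_2mm(), beam, fx$dd, fx$do)
  for (z in c(195, 205, 215)) {   # mid-SOBP points
    p <- c(0, 0, z)
    expect_equal(cf_pba(pba$ppic, pba$mosfet, p),
                 cf_smc(smc$ppic, smc$mosfet, p), tolerance = 0.02)
  }
})

test_that("PBA and SMC correction factors separate behind heterogeneity", {
  # cached head fixture: behind the lateral bone-plate edge the deterministic
  # straight-axis PBA and the scattering SMC disagree
  eng <- head_engine_run()
  pba <- head_pba_run()
  pts <- fixture_points()
  seps <- vapply(seq_len(nrow(pts)), function(i) {
    p <- c(pts$x[i], pts$y[i], pts$z[i])
    abs(cf_pba(pba$ppic, pba$mosfet, p) - cf_smc(eng$ppic, eng$mosfet, p))
  }, 0)
  expect_gt(max(seps), 0.01)
})

test_that("depth correction matches the axial SMC factor in water", {
  fx <- fix190()
  expect_equal(cf_depth(fx$dd, fx$do, 0), 1)
  z_peak <- fx$dd$depths[which.max(fx$dd$values)]
  expect_equal(cf_depth(fx$dd, fx$do, z_peak), 1 / 0.73, tolerance = 1e-6)
  expect_error(cf_depth(fx$dd, fx$do, 500), "beyond")
  res <- water_pristine_run()
  for (z in c(100, 200, 230)) {
    expect_equal(cf_depth(fx$dd, fx$do, z),
                 cf_smc(res$ppic, res$mosfet, c(0, 0, z)), tolerance = 0.02)
  }
})

test_that("MOSFET calibration follows the five-exposure protocol arithmetic", {
  rec <- calibrate(rep(400, 5), delivered_cGy = 200)
  expect_equal(rec$factor, 0.5)
  expect_equal(raw_dose(400, rec), 200)
  expect_equal(length(rec$readings), 5)
  rec2 <- calibrate(c(380, 390, 400, 410, 420), 200)
  expect_equal(rec2$factor, 200 / 400)
  expect_error(calibrate(c(400, -1)), "> 0")
  expect_error(raw_dose(0, rec), "> 0")
})

test_that("simulated measurement closes the loop exactly with zero noise", {
  res <- water_pristine_run()
  rec <- calibrate(rep(400, 5))
  p <- c(0, 0, 150)
  reading <- simulate_measurement(res$mosfet, p, rec, noise_sd = 0)
  raw <- raw_dose(reading, rec)
  expect_equal(raw, trilinear_at(res$mosfet, p))
  corrected <- cf_smc(res$ppic, res$mosfet, p) * raw
  expect_equal(corrected, trilinear_at(res$ppic, p))
  expect_error(simulate_measurement(res$mosfet, c(55, 55, 250), rec),
               "out of field")
})

test_that("setup uncertainty extrema follow the cavity geometry", {
  uni <- dose_grid(array(7, c(9, 9, 9)), array(0, c(9, 9, 9)),
                   c(2, 2, 2), c(-8, -8, -8))
  expect_equal(setup_uncertainty(uni, c(0, 0, 0)), c(min = 7, max = 7))
  # pure axial gradient g per mm over a 5 mm cavity: d -+ 2.5 g
  d <- dim(uni$dose)
  grad <- uni
  zc <- grad$origin[3] + (seq_len(d[3]) - 1) * grad$voxel_size[3]
  grad$dose <- array(rep(100 + 3 * zc, each = 81), dim = d)
  ext <- setup_uncertainty(grad, c(0, 0, 0))
  expect_equal(unname(ext), c(100 - 2.5 * 3, 100 + 2.5 * 3), tolerance = 1e-9)
  # steep-gradient fixture point: > 5%/mm gives half-width > 12.5%
  steep <- grad
  steep$dose <- array(rep(100 * 1.06^zc, each = 81), dim = d)
  ext2 <- setup_uncertainty(steep, c(0, 0, 0))
  expect_gt((ext2[2] - ext2[1]) / 2 / 100, 0.125)
})

test_that("total uncertainty combines in quadrature", {
  expect_equal(total_uncertainty(0, 0.02), 0.02)
  expect_equal(total_uncertainty(0.03, 0.04), 0.05)
  expect_equal(total_uncertainty(0.07, 0), 0.07)
  expect_error(total_uncertainty(-0.1, 0), ">= 0")
})

test_that("correction_result assembles the record invariants", {
  res <- water_pristine_run()
  p <- c(0, 0, 200)
  cf <- cf_smc(res$ppic, res$mosfet, p)
  row <- correction_result(p, raw = 90, cf = cf, grid = res$ppic,
                           statistical = 0.02, method = "smc")
  expect_equal(row$corrected_dose, cf * 90)
  expect_equal(row$total_uncertainty,
               sqrt(row$setup_uncertainty^2 + 0.02^2))
  expect_error(correction_result(p, 90, cf = -1, method = "smc"), "cf")
})
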