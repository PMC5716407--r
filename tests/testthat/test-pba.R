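test_that("pencil dose follows the closed-form Gaussian kernel", {
  fx <- fix190()
  dd <- fx$dd
  sig <- 4
  phi <- 2.5
  z <- 100
  on_axis <- pencil_dose(3, -2, z, c(3, -2), dd, sig, z, phi)
  expect_equal(on_axis, phi * lookup_curve(dd, z) / (2 * pi * sig^2))
  # 3 sigma off axis: e^-4.5 of the on-axis value
  off <- pencil_dose(3 + 3 * sig, -2, z, c(3, -2), dd, sig, z, phi)
  expect_equal(off / on_axis, exp(-4.5))
  # lateral integral over the plane returns phi * DD exactly
  g <- seq(-30, 30, by = 0.25)
  vals <- outer(g, g, function(x, y) {
    phi * lookup_curve(dd, z) * exp(-((x - 3)^2 + (y + 2)^2) / (2 * sig^2)) /
      (2 * pi * sig^2)
  })
  expect_equal(sum(vals) * 0.25^2, phi * lookup_curve(dd, z), tolerance = 1e-6)
  expect_error(pencil_dose(0, 0, z, c(0, 0), dd, 0, z), "sigma")
  # identity response: output contribution equals dose contribution
  do_id <- apply_response(particle_curve(dd), identity_response())
  expect_equal(pencil_output(1, 1, z, c(0, 0), do_id, sig, z),
               pencil_dose(1, 1, z, c(0, 0), particle_curve(dd), sig, z))
})

test_that("lateral sigma is positive, monotone and source-term dominated at entry", {
  hf <- head_fixture()
  ls <- lateral_sigma(hf$phantom, hf$beam, c(0, 0), seq(5, 260, by = 15))
  expect_true(all(ls$sigma_mm > 0))
  expect_true(all(diff(ls$sigma_mm) >= 0))
  expect_equal(ls$sigma_mm[1], hf$beam$spot_sigma, tolerance = 0.1)
  expect_true(all(diff(ls$wed_mm) >= 0))
})

test_that("PBA reproduces the broad-beam curve in water within 1%", {
  fx <- fix190()
  ph <- water_tank_2mm()
  beam <- water_beam_pristine()
  pba <- run_pba(ph, beam, fx$dd, fx$do)
  g <- pba$ppic
  d <- dim(g$dose)
  icx <- ceiling(d[1] / 2)
  zc <- g$origin[3] + (seq_len(d[3]) - 1) * g$voxel_size[3]
  prof <- g$dose[icx, icx, ]
  dd <- lookup_curve(fx$dd, zc)
  sc <- sum(prof * dd) / sum(dd^2)
  err <- (prof - sc * dd) / max(sc * dd)
  expect_lt(max(abs(err[zc < 0.9 * 239])), 0.01)
  # deterministic
  pba2 <- run_pba(ph, beam, fx$dd, fx$do)
  expect_identical(pba$ppic$dose, pba2$ppic$dose)
})

test_that("PBA is exactly linear in the fluence", {
  fx <- fix190()
  ph <- make_water_tank(c(30, 30, 40), voxel_size = c(3, 3, 3))
  beam1 <- beam_spec(nominal_range = 100, field_radius = 10,
                     fluence = function(x, y) rep(1, length(x)))
  beam2 <- beam_spec(nominal_range = 100, field_radius = 10,
                     fluence = function(x, y) rep(2, length(x)))
  a <- run_pba(ph, beam1, fx$dd, fx$do)
  b <- run_pba(ph, beam2, fx$dd, fx$do)
  expect_equal(b$ppic$dose, 2 * a$ppic$dose, tolerance = 1e-12)
})

test_that("PBA matches the SMC in homogeneous water within 3% of peak", {
  fx <- fix190()
  smc <- water_pristine_run()
  pba <- run_pba(water_tank_2mm(), water_beam_pristine(), fx$dd, fx$do)
  ps <- axis_profile(smc$ppic)
  pp <- axis_profile(pba$ppic)
  sel <- ps$z < 0.9 * 239
  sc <- sum(ps$dose * pp$dose) / sum(pp$dose^2)
  err <- (ps$dose - sc * pp$dose) / max(ps$dose)
  expect_lt(max(abs(err[sel])), 0.03)
})

test_that("PBA and SMC disagree behind a lateral bone edge", {
  fx <- fix190()
  ph <- make_slab_phantom(
    make_water_tank(c(60, 60, 130), voxel_size = c(2, 2, 2)),
    list(list(lo = c(0, -60, 60), hi = c(60, 60, 90),
              material = "cortical_bone")))
  beam <- water_beam_pristine()
  presc <- list(point = c(-10, 0, 150), dose = 100)
  smc <- run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = 3e5, seed = 61,
                 batches = 5, prescription = presc)
  pba <- run_pba(ph, beam, fx$dd, fx$do, prescription = presc)
  # behind the edge (x ~ 0, z beyond the slab) the straight-axis PBA misses
  # the lateral disequilibrium the SMC tracks
  probe <- expand.grid(x = seq(-6, 6, by = 2), y = 0,
                       z = seq(180, 225, by = 5))
  diffs <- vapply(seq_len(nrow(probe)), function(i) {
    p <- c(probe$x[i], probe$y[i], probe$z[i])
    (trilinear_at(pba$ppic, p) - trilinear_at(smc$ppic, p)) / 100
  }, 0)
  expect_gt(max(abs(diffs)), 0.05)
})

test_that("coarse pencil spacing warns about ripple", {
  fx <- fix190()
  ph <- make_water_tank(c(20, 20, 30), voxel_size = c(3, 3, 3))
  beam <- beam_spec(nominal_range = 60, field_radius = 8, spot_sigma = 1)
  expect_warning(run_pba(ph, beam, fx$dd, fx$do, spacing = 4), "ripple")
})
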