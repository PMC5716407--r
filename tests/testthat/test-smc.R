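test_that("source sampling honours the effective source model", {
  beam <- beam_spec(nominal_range = 239, range_shifter = 7.5, field_radius = 10,
                    angular_sigma = 0, spot_sigma = 0)
  set.seed(1)
  st <- sample_source(beam, 1000)
  expect_true(all(st[, "dx"] == 0 & st[, "dy"] == 0 & st[, "dz"] == 1))
  expect_true(all(st[, "x"]^2 + st[, "y"]^2 <= 100 + 1e-9))
  expect_true(all(st[, "resid"] == 239 - 7.5))

  # CLT bound on the mean slope: 4 sd / sqrt(n)
  beam2 <- beam_spec(nominal_range = 239, field_radius = 10,
                     angular_sigma = 0.004, spot_sigma = 0)
  set.seed(2)
  st2 <- sample_source(beam2, 1e5)
  slope_x <- st2[, "dx"] / st2[, "dz"]
  expect_lt(abs(mean(slope_x)), 4 * 0.004 / sqrt(1e5))
  expect_equal(sd(slope_x), 0.004, tolerance = 0.02)

  # determinism for a fixed seed
  set.seed(3); a <- sample_source(beam2, 100)
  set.seed(3); b <- sample_source(beam2, 100)
  expect_identical(a, b)

  # fluence profile weighting: centre-heavy Gaussian profile
  beam3 <- beam_spec(nominal_range = 239, field_radius = 10, spot_sigma = 0,
                     fluence = function(x, y) exp(-(x^2 + y^2) / 50))
  set.seed(4)
  st3 <- sample_source(beam3, 2e4)
  r2 <- st3[, "x"]^2 + st3[, "y"]^2
  expect_lt(mean(r2), 50)   # uniform disc would give E[r^2] = 50
})

test_that("modulated source samples component ranges with straggling", {
  beam <- fixture_beam_190()
  mod <- beam_modulation(beam)
  expect_true(all(diff(mod$ranges) < 0))
  set.seed(5)
  st <- sample_source(beam, 2e4, modulation = mod, straggling_mm = 2)
  expect_true(all(st[, "curve_Z"] %in% mod$ranges))
  # deepest component (largest weight) most frequent
  expect_equal(unname(sort(table(st[, "curve_Z"]), decreasing = TRUE)[1]),
               sum(st[, "curve_Z"] == 239))
  resid_dev <- st[, "resid"] - (st[, "curve_Z"] - 7.5)
  expect_equal(sd(resid_dev), 2, tolerance = 0.05)
})

test_that("single-proton transport reproduces the curve in water without scattering", {
  fx <- fix190()
  ph <- make_water_tank(c(20, 20, 130), voxel_size = c(3, 3, 2))
  dd <- particle_curve(fx$pristine_dd)
  do <- particle_curve(fx$pristine_do)
  tr <- transport_proton(c(0, 0, 0, 0, 0, 1, 239), ph, dd, do, 239,
                         step = 1, scatter = FALSE)
  # deposits at depth z equal lookup(dd, z) * step within one-step quadrature
  mid <- tr$z > 2 & tr$z < 230
  z_half <- tr$z[mid]
  expect_lt(max(abs(tr$dose[mid] - lookup_curve(dd, z_half))),
            max(abs(diff(lookup_curve(dd, seq(0, 239, by = 1))))))
  # total water path equals the initial residual range within one step
  expect_equal(max(tr$z), 239, tolerance = 1.5)
  # paired scoring: output deposit never exceeds dose deposit
  expect_true(all(tr$output <= tr$dose + 1e-12))
  # a spent proton deposits nothing
  tr0 <- transport_proton(c(0, 0, 0, 0, 0, 1, 0), ph, dd, do, 239)
  expect_equal(nrow(tr0), 0)
})

test_that("compiled kernel agrees with the R reference transport", {
  fx <- fix190()
  ph <- make_water_tank(c(20, 20, 130), voxel_size = c(3, 3, 2))
  beam <- beam_spec(nominal_range = 239, field_radius = 5,
                    angular_sigma = 0, spot_sigma = 0)
  cg <- mosfetcf:::calc_geometry(ph, 2L)
  tab_step <- 0.25
  dd_tab <- mosfetcf:::curve_table(particle_curve(fx$pristine_dd), tab_step)
  do_tab <- mosfetcf:::curve_table(particle_curve(fx$pristine_do), tab_step)
  pvt <- mosfetcf:::pv_table(300)
  st <- matrix(c(1, 2, 0, 0, 0, 1, 230), 1, 7)
  nv <- prod(cg$shape)
  bd <- numeric(nv); bo <- numeric(nv)
  # suppress scattering deterministically by zeroing the rng draws is not
  # possible; instead compare against the R reference fed the same RNG state
  set.seed(99)
  mosfetcf:::smc_transport_batch(st, as.vector(ph$rsp), dim(ph$rsp),
                                 ph$voxel_size, ph$origin, cg$shape,
                                 cg$voxel_size, cg$origin, dd_tab, do_tab,
                                 tab_step, 239, pvt$pv, pvt$step, 1,
                                 mosfetcf:::X0_WATER_MM, bd, bo)
  set.seed(99)
  tr <- transport_proton(c(1, 2, 0, 0, 0, 1, 230), ph,
                         particle_curve(fx$pristine_dd),
                         particle_curve(fx$pristine_do), 239, step = 1)
  expect_equal(sum(bd), sum(tr$dose), tolerance = 1e-6)
  expect_equal(sum(bo), sum(tr$output), tolerance = 1e-6)
})

test_that("SMC reproduces the measured pristine curve on the central axis", {
  fx <- fix190()
  res <- water_pristine_run()            # 1e6 histories, seed 11
  prof <- axis_profile(res$ppic)
  sel <- prof$z < 0.9 * 239
  dd <- lookup_curve(fx$dd, prof$z)
  sc <- sum(prof$dose * dd) / sum(dd^2)
  err <- (prof$dose - sc * dd) / max(sc * dd)
  expect_lt(max(abs(err[sel])), 0.02)
  # MOSFET/PPIC voxel ratio in the entrance plateau is 1 (paired scoring;
  # the response plateau covers the shallow region exactly)
  mos <- axis_profile(res$mosfet)
  plateau <- prof$z < 150
  expect_equal(mos$dose[plateau] / prof$dose[plateau],
               rep(1, sum(plateau)), tolerance = 1e-9)
})

test_that("paired scoring keeps the output grid below the dose grid", {
  res <- water_pristine_run()
  expect_true(all(res$mosfet$dose <= res$ppic$dose + 1e-12))
})

test_that("scored energy matches the per-proton curve integrals", {
  fx <- fix190()
  ph <- make_water_tank(c(40, 40, 130), voxel_size = c(3, 3, 2))
  beam <- beam_spec(nominal_range = 239, field_radius = 10,
                    angular_sigma = 0, spot_sigma = 0)
  n <- 2e4
  res <- run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = n, seed = 21,
                 batches = 2)
  # every proton has residual range 239 and stays inside laterally, so the
  # expected total is n * integral of the ideal curve over [0, 239]
  z <- seq(0, 239, by = 0.05)
  v <- lookup_curve(particle_curve(fx$pristine_dd), z)
  expected <- n * sum((v[-1] + v[-length(v)]) / 2 * diff(z))
  expect_equal(sum(res$ppic$dose), expected, tolerance = 0.01)
})

test_that("lateral spread follows the Fermi-Eyges accumulation of Highland sigma", {
  fx <- fix190()
  ph <- make_water_tank(c(60, 60, 80), voxel_size = c(1.5, 1.5, 3))
  beam <- beam_spec(nominal_range = 239, field_radius = 0.05,
                    angular_sigma = 0, spot_sigma = 0)
  res <- run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = 1e5, seed = 31,
                 batches = 2)
  g <- res$ppic
  d <- dim(g$dose)
  xc <- g$origin[1] + (seq_len(d[1]) - 1) * g$voxel_size[1]
  zc <- g$origin[3] + (seq_len(d[3]) - 1) * g$voxel_size[3]
  ana <- lateral_sigma(ph, beam, c(0, 0), zc)   # analytic integral, R side
  # depths below 80% of the range where sigma exceeds the scoring voxel
  # (the discrete-bin variance correction is only valid there)
  for (zt in c(150, 175, 190)) {
    k <- which.min(abs(zc - zt))
    slab <- apply(g$dose[, , k], 1, sum)
    mu <- sum(xc * slab) / sum(slab)
    sig2 <- sum((xc - mu)^2 * slab) / sum(slab) - g$voxel_size[1]^2 / 12
    expect_equal(sqrt(sig2), ana$sigma_mm[k], tolerance = 0.05)
  }
})

test_that("statistical error estimator behaves per contract", {
  # constructed grid: dose 100 everywhere, per-voxel se 2% -> 2.0
  g <- dose_grid(array(100, c(3, 3, 3)), array(4, c(3, 3, 3)),
                 c(1, 1, 1), c(0, 0, 0), n_histories = 10, batches = 10)
  expect_equal(statistical_error(g, array(TRUE, c(3, 3, 3))), 2.0)
  # zero variance (identical batches) -> 0
  g0 <- dose_grid(array(100, c(3, 3, 3)), array(0, c(3, 3, 3)),
                  c(1, 1, 1), c(0, 0, 0), n_histories = 10, batches = 10)
  expect_equal(statistical_error(g0, array(TRUE, c(3, 3, 3))), 0)
  g1 <- g; g1$batches <- 1
  expect_error(statistical_error(g1, TRUE), "2 batches")
  expect_error(statistical_error(g, array(FALSE, c(3, 3, 3))), "empty")
  gz <- g; gz$dose[1] <- 0
  expect_error(statistical_error(gz, array(TRUE, c(3, 3, 3))), "zero dose")
})

test_that("statistical error scales as one over root N", {
  fx <- fix190()
  ph <- make_water_tank(c(30, 30, 65), voxel_size = c(4, 4, 4))
  beam <- beam_spec(nominal_range = 239, field_radius = 15)
  e <- sapply(c(5e4, 2e5), function(n) {
    res <- run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = n, seed = 41,
                   batches = 10)
    reg <- res$ppic$dose > 0.5 * max(res$ppic$dose)
    statistical_error(res$ppic, reg)
  })
  # quadrupling N should halve the error, within 20%
  expect_equal(e[1] / e[2], 2, tolerance = 0.2)
})

test_that("runs are bit-reproducible for a fixed seed", {
  fx <- fix190()
  ph <- make_water_tank(c(20, 20, 65), voxel_size = c(4, 4, 4))
  beam <- beam_spec(nominal_range = 239, field_radius = 10)
  a <- run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = 2e4, seed = 51,
               batches = 4)
  b <- run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = 2e4, seed = 51,
               batches = 4)
  expect_identical(a$ppic$dose, b$ppic$dose)
  expect_identical(a$mosfet$variance, b$mosfet$variance)
  c <- run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = 2e4, seed = 52,
               batches = 4)
  expect_false(identical(a$ppic$dose, c$ppic$dose))
})

test_that("run_smc validates its preconditions", {
  fx <- fix190()
  ph <- make_water_tank(c(10, 10, 20), voxel_size = c(4, 4, 4))
  beam <- beam_spec(nominal_range = 60, field_radius = 5)
  expect_error(run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = 1,
                       seed = 1, batches = 2), "n >= batches")
  expect_warning(run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = 100,
                         seed = 1, batches = 2, step = 10), "step")
  expect_error(run_smc(ph, beam, fx$pristine_dd, fx$pristine_do, n = 100,
                       seed = 1, batches = 2,
                       prescription = list(point = c(0, 0, 1000), dose = 100)),
               "prescription")
})
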