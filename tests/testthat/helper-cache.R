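# Shared expensive fixtures, computed once per test run.  Seeds are part of
# the stated fixture world, not tuning knobs.

.run_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (is.null(.run_cache[[key]])) assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

# pristine 190 MeV fixture curves (cheap but used everywhere)
fix190 <- function() cache_get("fix190", function() fixture_curves_190(0))
fix190_sobp <- function() cache_get("fix190_sobp", function() fixture_curves_190(50))

water_tank_2mm <- function() {
  cache_get("tank", function() make_water_tank(c(60, 60, 130), voxel_size = c(2, 2, 2)))
}

# pristine 190 MeV beam, 1e6 histories in water: the self-consistency /
# cross-engine / correction-factor workhorse
water_pristine_run <- function() {
  cache_get("water_pristine", function() {
    fx <- fix190()
    beam <- beam_spec(nominal_range = 239, field_radius = 20)
    run_smc(water_tank_2mm(), beam, fx$pristine_dd, fx$pristine_do,
            n = 1e6, seed = 11, batches = 10)
  })
}

# 50 mm SOBP in water, moderate statistics
water_sobp_run <- function() {
  cache_get("water_sobp", function() {
    fx <- fix190_sobp()
    beam <- beam_spec(nominal_range = 239, sobp_width = 50,
                      range_shifter = 7.5, field_radius = 20)
    run_smc(water_tank_2mm(), beam, fx$pristine_dd, fx$pristine_do,
            n = 4e5, seed = 12, batches = 10)
  })
}

water_beam_pristine <- function() beam_spec(nominal_range = 239, field_radius = 20)

# head-like fixture at the packaged history count: "engine" run (seed 7,
# also acceptance criterion 4) and an independent "truth" run
head_fixture <- function() {
  cache_get("head_fix", function() {
    list(phantom = make_head_like(seed = 7), beam = fixture_beam_190(),
         fx = fix190_sobp(),
         prescription = list(point = c(0, 0, 206.5), dose = 100))
  })
}

head_engine_run <- function() {
  cache_get("head_engine", function() {
    hf <- head_fixture()
    run_smc(hf$phantom, hf$beam, hf$fx$pristine_dd, hf$fx$pristine_do,
            n = smc_default_histories(), seed = 7, batches = 10,
            prescription = hf$prescription)
  })
}

head_truth_run <- function() {
  cache_get("head_truth", function() {
    hf <- head_fixture()
    run_smc(hf$phantom, hf$beam, hf$fx$pristine_dd, hf$fx$pristine_do,
            n = smc_default_histories(), seed = 1007, batches = 10,
            prescription = hf$prescription)
  })
}

head_pba_run <- function() {
  cache_get("head_pba", function() {
    hf <- head_fixture()
    run_pba(hf$phantom, hf$beam, hf$fx$dd, hf$fx$do,
            prescription = hf$prescription)
  })
}

# central-axis profile of a grid: mean over the in-plane voxels within
# `radius_mm` of the axis, per z slice; returns data.frame(z, dose)
axis_profile <- function(grid, radius_mm = 6) {
  d <- dim(grid$dose)
  xc <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$voxel_size[1]
  yc <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$voxel_size[2]
  zc <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$voxel_size[3]
  ix <- which(abs(xc) <= radius_mm)
  iy <- which(abs(yc) <= radius_mm)
  data.frame(z = zc, dose = apply(grid$dose[ix, iy, , drop = FALSE], 3, mean))
}
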