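# End-to-end desk-scale experiments: Bragg-curve comparison and the
# seven-point in vivo protocol on the head-like fixture.

#' Experiment configuration
#'
#' Bundles everything a reproducible experiment needs.  All numeric
#' parameters have fixture defaults; every output table embeds the seed and
#' a hash of this configuration.
#'
#' @param seed integer master seed.
#' @param n_histories SMC histories (default [smc_default_histories()]).
#' @param batches SMC batches (default 10).
#' @param sobp_width,range_shifter,field_radius beam fixture parameters.
#' @param pencil_spacing PBA pencil spacing in mm.
#' @param prescription_cGy prescription dose per fraction at the isocenter
#'   (default 100).
#' @param fractions number of fractions (default 3; fractions scale dose
#'   linearly).
#' @param noise_sd relative reading reproducibility of the simulated MOSFET
#'   (default 0.015).
#' @param peak_ratio response-model calibration anchor passed to
#'   [fixture_curves_190()] (default 0.73; 1 = identity detector).
#' @param points evaluation points, as from [fixture_points()] (`NULL` =
#'   fixture defaults).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 7, n_histories = smc_default_histories(),
                              batches = 10L, sobp_width = 50,
                              range_shifter = 7.5, field_radius = 15,
                              pencil_spacing = 2, prescription_cGy = 100,
                              fractions = 3L, noise_sd = 0.015,
                              peak_ratio = 0.73, points = NULL) {
  cfg <- list(seed = as.integer(seed), n_histories = n_histories,
              batches = as.integer(batches), sobp_width = sobp_width,
              range_shifter = range_shifter, field_radius = field_radius,
              pencil_spacing = pencil_spacing,
              prescription_cGy = prescription_cGy,
              fractions = as.integer(fractions), noise_sd = noise_sd,
              peak_ratio = peak_ratio, points = points)
  structure(cfg, class = "experiment_config")
}

# water-equivalent depth from the entrance face to a point, along +z
wed_to_point <- function(phantom, point) {
  z0 <- phantom_bounds(phantom)["lo", 3]
  w <- wed_along_ray(phantom, c(point[1], point[2], z0), c(0, 0, 1), step = 0.5)
  stats::approx(w$geometric_mm, w$wed_mm, xout = point[3] - z0, rule = 2)$y
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable fold of the JSON text (no digest dependency)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %% .Machine$integer.max)
}

#' Bragg-curve comparison experiment
#'
#' Generates the packaged 190 MeV pristine depth-dose and depth-output
#' fixture curves, both normalized at the entrance, and tabulates their
#' ratio against depth; records the plateau (depth 0) and Bragg-peak
#' ratios.
#'
#' @param config an [experiment_config()] (only the seed is used here).
#' @param out optional CSV path for the table.
#' @return A list with `table` (depth, dd, do, ratio), `peak_ratio`,
#'   `plateau_ratio`, `peak_depth_mm`, `seed` and `config_hash`.
#' @export
experiment_bragg_comparison <- function(config = experiment_config(),
                                        out = NULL) {
  fx <- fixture_curves_190(sobp_width = 0)
  dd <- normalize_curve(fx$dd)
  do <- normalize_curve(fx$do)
  ratio <- ifelse(dd$values > 0, do$values / dd$values, NA_real_)
  tab <- data.frame(depth_mm = dd$depths, dd = dd$values, do = do$values,
                    ratio = ratio)
  ipk <- which.max(dd$values)
  res <- list(table = tab,
              peak_ratio = ratio[ipk],
              plateau_ratio = tab$ratio[tab$depth_mm == 0],
              peak_depth_mm = tab$depth_mm[ipk],
              seed = config$seed, config_hash = config_hash(config))
  if (!is.null(out)) write_experiment_csv(tab, out, config)
  res
}

write_experiment_csv <- function(tab, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mosfetcf %s seed=%d config=%s",
                     as.character(utils::packageVersion("mosfetcf")),
                     config$seed, config_hash(config)), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Seven-point in vivo dosimetry experiment
#'
#' The full closed-loop pipeline on the head-like fixture: build the SOBP
#' beam and curves; run an independent truth SMC (sub-seed 1), the engine
#' SMC (sub-seed 2) and the PBA, all normalized to the prescription at the
#' isocenter; simulate a MOSFET reading at each point from the truth output
#' grid; and correct it with the SMC, PBA and legacy depth factors,
#' attaching setup/statistical error bars.  Deterministic for a fixed seed.
#'
#' @param config an [experiment_config()].
#' @param out optional CSV path.
#' @return A list with `table` (one row per point and correction method),
#'   `grids` (truth/engine/pba run results), `seed` and `config_hash`.
#' @export
experiment_point_doses <- function(config = experiment_config(), out = NULL) {
  beam <- fixture_beam_190(sobp_width = config$sobp_width,
                           range_shifter = config$range_shifter,
                           field_radius = config$field_radius)
  fx <- fixture_curves_190(sobp_width = config$sobp_width,
                           peak_ratio = config$peak_ratio)
  phantom <- make_head_like(seed = config$seed)
  distal <- beam$nominal_range - beam$range_shifter
  iso <- c(0, 0, distal - config$sobp_width / 2)
  presc <- list(point = iso, dose = config$prescription_cGy)
  pts <- if (is.null(config$points)) fixture_points(beam) else config$points

  truth <- run_smc(phantom, beam, fx$pristine_dd, fx$pristine_do,
                   n = config$n_histories,
                   seed = config$seed * 2L + 1L, batches = config$batches,
                   prescription = presc)
  engine <- run_smc(phantom, beam, fx$pristine_dd, fx$pristine_do,
                    n = config$n_histories,
                    seed = config$seed * 2L + 2L, batches = config$batches,
                    prescription = presc)
  pba <- run_pba(phantom, beam, fx$dd, fx$do, spacing = config$pencil_spacing,
                 prescription = presc)
  record <- calibrate(rep(400, 5), delivered_cGy = 200)

  set.seed(config$seed * 2L + 3L)
  rows <- list()
  for (i in seq_len(nrow(pts))) {
    p <- c(pts$x[i], pts$y[i], pts$z[i])
    truth_dose <- trilinear_at(truth$ppic, p)
    infield <- trilinear_at(truth$mosfet, p) >= 0.01 * max(truth$mosfet$dose)
    if (!infield) {
      rows[[length(rows) + 1]] <- data.frame(
        label = pts$label[i], x = p[1], y = p[2], z = p[3], method = NA,
        truth_dose = truth_dose, raw_dose = NA, cf = NA, corrected_dose = NA,
        setup_uncertainty = NA, statistical_uncertainty = NA,
        total_uncertainty = NA, flag = "out_of_field",
        stringsAsFactors = FALSE)
      next
    }
    reading <- simulate_measurement(truth$mosfet, p, record,
                                    noise_sd = config$noise_sd)
    raw <- raw_dose(reading, record)
    stat_comb <- sqrt(stat_error_at(engine$ppic, p)^2 +
                      stat_error_at(engine$mosfet, p)^2 +
                      stat_error_at(truth$mosfet, p)^2)
    res <- rbind(
      correction_result(p, raw, cf_smc(engine$ppic, engine$mosfet, p),
                        grid = engine$ppic, statistical = stat_comb,
                        method = "smc"),
      correction_result(p, raw, cf_pba(pba$ppic, pba$mosfet, p),
                        grid = pba$ppic,
                        statistical = stat_error_at(truth$mosfet, p),
                        method = "pba"),
      correction_result(p, raw,
                        cf_depth(fx$dd, fx$do,
                                 config$range_shifter + wed_to_point(phantom, p)),
                        grid = NULL,
                        statistical = stat_error_at(truth$mosfet, p),
                        method = "depth"))
    res <- cbind(label = pts$label[i], res, truth_dose = truth_dose,
                 flag = "ok", stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- res
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(c("label", "x", "y", "z", "method", "truth_dose", "raw_dose",
                "cf", "corrected_dose", "setup_uncertainty",
                "statistical_uncertainty", "total_uncertainty", "flag"),
              names(r))] <- NA
    r[, c("label", "x", "y", "z", "method", "truth_dose", "raw_dose", "cf",
          "corrected_dose", "setup_uncertainty", "statistical_uncertainty",
          "total_uncertainty", "flag")]
  }))
  if (!is.null(out)) write_experiment_csv(tab, out, config)
  list(table = tab, grids = list(truth = truth, engine = engine, pba = pba),
       beam = beam, curves = fx, phantom = phantom, isocenter = iso,
       seed = config$seed, config_hash = config_hash(config))
}
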