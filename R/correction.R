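# Correction factors (SMC, PBA and legacy depth-based), MOSFET calibration,
# simulated readings and the measurement-uncertainty model.

cf_from_grids <- function(num_grid, den_grid, point) {
  num <- trilinear_at(num_grid, point)
  den <- trilinear_at(den_grid, point)
  if (den < 0.01 * max(den_grid$dose)) {
    stop("point lies out of field (output < 1% of maximum); no correction factor")
  }
  num / den
}

#' SMC correction factor at a point
#'
#' Ratio of the SMC-computed dose (PPIC curve) to the SMC-computed MOSFET
#' output at a point, both trilinearly interpolated from paired grids.  With
#' a sensitivity <= 1 response model the factor is >= 1 in-field.
#'
#' @param smc_ppic,smc_mosfet paired [dose_grid()]s from [run_smc()].
#' @param point mm position `c(x, y, z)`.
#' @return Dimensionless correction factor.
#' @export
cf_smc <- function(smc_ppic, smc_mosfet, point) {
  stopifnot(identical(dim(smc_ppic$dose), dim(smc_mosfet$dose)))
  cf_from_grids(smc_ppic, smc_mosfet, point)
}

#' PBA correction factor at a point
#'
#' As [cf_smc()] on the deterministic pencil-beam grids.
#'
#' @param pba_ppic,pba_mosfet [dose_grid()]s from [run_pba()].
#' @param point mm position `c(x, y, z)`.
#' @return Dimensionless correction factor.
#' @export
cf_pba <- function(pba_ppic, pba_mosfet, point) {
  stopifnot(identical(dim(pba_ppic$dose), dim(pba_mosfet$dose)))
  cf_from_grids(pba_ppic, pba_mosfet, point)
}

#' Legacy depth-based correction factor
#'
#' The simple dose-weighted correction: the ratio of the broad-beam
#' depth-dose to depth-output curves at a penetration depth, ignoring where
#' in the field the point lies.
#'
#' @param dd,do broad-beam dose and output [depth_curve()]s.
#' @param depth_mm penetration depth in mm (water-equivalent).
#' @return Dimensionless correction factor.
#' @export
cf_depth <- function(dd, do, depth_mm) {
  den <- lookup_curve(do, depth_mm)
  if (den <= 0) stop("depth beyond the output curve; no correction factor")
  lookup_curve(dd, depth_mm) / den
}

#' Calibrate a MOSFET detector
#'
#' The dose calibration factor is the delivered dose divided by the mean of
#' the readings; the packaged protocol is five exposures of 200 cGy in a
#' low-LET (plateau) geometry.
#'
#' @param readings_mV detector readings in mV (> 0).
#' @param delivered_cGy delivered dose per exposure in cGy (default 200).
#' @return An object of class `calibration_record` with fields `readings`,
#'   `delivered_dose` and `factor` (cGy/mV).
#' @export
calibrate <- function(readings_mV, delivered_cGy = 200) {
  if (any(readings_mV <= 0)) stop("readings must be > 0")
  structure(list(readings = readings_mV, delivered_dose = delivered_cGy,
                 factor = delivered_cGy / mean(readings_mV)),
            class = "calibration_record")
}

#' Raw MOSFET dose from a reading
#'
#' Product of the reading (mV) and the dose calibration factor (cGy/mV).
#'
#' @param reading_mV detector reading in mV.
#' @param record a [calibrate()] record.
#' @return Raw (uncorrected) dose in cGy.
#' @export
raw_dose <- function(reading_mV, record) {
  stopifnot(inherits(record, "calibration_record"))
  if (any(reading_mV <= 0)) stop("reading must be > 0")
  reading_mV * record$factor
}

#' Simulate a MOSFET reading at a point
#'
#' Synthetic stand-in for the physical detector: the reading is the
#' response-weighted dose (the MOSFET grid of a truth run) at the point,
#' divided by the calibration factor, with optional multiplicative Gaussian
#' noise.  With zero noise, `cf x raw_dose` recovers the truth-grid dose up
#' to statistical error.
#'
#' @param truth_mosfet the MOSFET-output [dose_grid()] of a truth run, in
#'   dose units (cGy).
#' @param point mm position (must be in-field: output >= 1% of maximum).
#' @param record a [calibrate()] record.
#' @param noise_sd relative standard deviation of multiplicative reading
#'   noise (default 0; uses R's RNG).
#' @return Simulated reading in mV.
#' @export
simulate_measurement <- function(truth_mosfet, point, record, noise_sd = 0) {
  out <- trilinear_at(truth_mosfet, point)
  if (out < 0.01 * max(truth_mosfet$dose)) stop("point lies out of field")
  reading <- out / record$factor
  if (noise_sd > 0) reading <- reading * (1 + stats::rnorm(1, 0, noise_sd))
  reading
}

#' Setup-uncertainty dose extrema in a cavity
#'
#' Extrema of the trilinearly interpolated dose over a sphere (default 5 mm
#' diameter) around the point, sampled on a <= 0.25 mm lattice -- the
#' detector setup-uncertainty model used for measurement error bars.
#'
#' @param grid a [dose_grid()].
#' @param point cavity centre (mm).
#' @param cavity_diameter_mm sphere diameter in mm (default 5).
#' @param lattice_mm sampling lattice pitch (default 0.25).
#' @return `c(min, max)` dose over the in-field part of the cavity.
#' @export
setup_uncertainty <- function(grid, point, cavity_diameter_mm = 5,
                              lattice_mm = 0.25) {
  r <- cavity_diameter_mm / 2
  g <- seq(-r, r, by = lattice_mm)
  offs <- as.matrix(expand.grid(x = g, y = g, z = g))
  offs <- offs[rowSums(offs^2) <= r^2, , drop = FALSE]
  vals <- apply(offs, 1, function(o) trilinear_at(grid, point + o))
  infield <- vals >= 0.01 * max(grid$dose)
  if (!all(infield)) {
    warning("cavity extends out of field; extrema taken over the in-field part")
    vals <- vals[infield]
    if (length(vals) == 0) stop("entire cavity is out of field")
  }
  c(min = min(vals), max = max(vals))
}

#' Combine setup and statistical uncertainty
#'
#' Quadrature sum of the setup half-width and the statistical error, both as
#' fractions.
#'
#' @param setup_halfwidth fractional setup-uncertainty half-width (>= 0).
#' @param statistical fractional statistical error (>= 0).
#' @return Combined fractional uncertainty.
#' @export
total_uncertainty <- function(setup_halfwidth, statistical) {
  if (any(setup_halfwidth < 0) || any(statistical < 0)) stop("inputs must be >= 0")
  sqrt(setup_halfwidth^2 + statistical^2)
}

#' Correct a raw MOSFET dose at a point
#'
#' Applies a correction factor to a raw dose and assembles the uncertainty
#' budget (setup cavity half-width, statistical error of the grids at the
#' point, quadrature total).
#'
#' @param point mm position.
#' @param raw raw MOSFET dose in cGy.
#' @param cf correction factor at the point.
#' @param grid the dose grid used to evaluate the setup half-width
#'   (typically the engine's PPIC grid), or `NULL` to skip.
#' @param statistical fractional statistical error at the point (0 for
#'   deterministic engines).
#' @param method one of `"smc"`, `"pba"`, `"depth"`.
#' @return A one-row data.frame: point, method, raw, cf, corrected dose and
#'   fractional uncertainties.
#' @export
correction_result <- function(point, raw, cf, grid = NULL, statistical = 0,
                              method = c("smc", "pba", "depth")) {
  method <- match.arg(method)
  stopifnot(cf > 0)
  setup <- 0
  if (!is.null(grid)) {
    ext <- setup_uncertainty(grid, point)
    at <- trilinear_at(grid, point)
    setup <- max(abs(ext - at)) / at
  }
  data.frame(x = point[1], y = point[2], z = point[3], method = method,
             raw_dose = raw, cf = cf, corrected_dose = cf * raw,
             setup_uncertainty = setup, statistical_uncertainty = statistical,
             total_uncertainty = total_uncertainty(setup, statistical),
             stringsAsFactors = FALSE)
}

# fractional statistical error of a grid at a point (trilinear on variance)
stat_error_at <- function(grid, point) {
  d <- trilinear_at(grid, point)
  if (d <= 0) return(0)
  sqrt(trilinear_at(grid, point, what = "variance")) / d
}
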