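# Packaged synthetic fixtures: the 190 MeV beam/curve set and the head-like
# irradiation geometry.  These replace the hospital's measured inputs; the
# numbers they are built to reproduce are the printed anchors (range ~239 mm,
# peak output/dose ratio 0.73, 50 mm SOBP, 7.5 mm range shifter).

FIXTURE_RANGE_190 <- 239    # clinical range of the 190 MeV beam, mm

#' Packaged history count for the SMC fixtures
#'
#' The number of histories at which the packaged head-like SOBP run reaches
#' a mean statistical error of <= 2% rms over the target volume (with 10
#' batches).  Chosen once from the fixture geometry, not per run.
#'
#' @return Integer history count.
#' @export
smc_default_histories <- function() 2000000L

#' 190 MeV fixture curves
#'
#' Generates the packaged curve set.  The response model is calibrated once
#' on the pristine 190 MeV curve (output/dose ratio 0.73 at its Bragg peak,
#' 1.0 at the entrance) -- the single measured detector curve that is reused
#' across irradiation conditions.  For an SOBP beam the broad-beam curves
#' are assembled component-wise ([sobp_output()]), while the pristine curves
#' plus the modulation (ranges, weights) drive the per-particle SMC.
#'
#' @param sobp_width SOBP modulation width in mm; 0 (default) gives the
#'   pristine Bragg fixture.
#' @param peak_ratio output/dose ratio the response model is calibrated to
#'   at the pristine Bragg peak (default 0.73); 1 gives an LET-independent
#'   (identity) detector.
#' @return A list with `dd`/`do` (broad-beam dose/output curves of the
#'   requested beam, for the PBA and the depth correction),
#'   `pristine_dd`/`pristine_do` (the per-particle curves for the SMC),
#'   `model` (the calibrated [response_model()]), `modulation`
#'   (`list(ranges, weights)`, `NULL` for a pristine beam) and `range_mm`.
#' @export
fixture_curves_190 <- function(sobp_width = 0, peak_ratio = 0.73) {
  pristine <- pristine_bragg(FIXTURE_RANGE_190)
  model <- if (peak_ratio >= 1) identity_response() else
    calibrate_response(pristine, peak_ratio = peak_ratio)
  pristine_do <- apply_response(pristine, model)
  if (sobp_width > 0) {
    s <- build_sobp(FIXTURE_RANGE_190, sobp_width)
    dd <- s$curve
    do <- sobp_output(s, model)
    modulation <- list(ranges = s$ranges, weights = s$weights)
  } else {
    dd <- pristine
    do <- pristine_do
    modulation <- NULL
  }
  list(dd = dd, do = do, pristine_dd = pristine, pristine_do = pristine_do,
       model = model, modulation = modulation, range_mm = FIXTURE_RANGE_190)
}

#' 190 MeV fixture beam
#'
#' @param sobp_width SOBP width in mm (default 50, the treatment fixture).
#' @param range_shifter range shifter thickness in mm water (default 7.5).
#' @param field_radius aperture radius in mm (default 15).
#' @return A [beam_spec()].
#' @export
fixture_beam_190 <- function(sobp_width = 50, range_shifter = 7.5,
                             field_radius = 15) {
  beam_spec(nominal_range = FIXTURE_RANGE_190, sobp_width = sobp_width,
            range_shifter = range_shifter, field_radius = field_radius)
}

#' Default measurement points in the head-like fixture
#'
#' Seven points (labelled A-G, mirroring a seven-point in vivo protocol)
#' inside or near the SOBP target volume of the head-like fixture, including
#' at least two in steep-gradient regions (near the distal edge and behind
#' the lateral bone-plate edge).
#'
#' @param beam the fixture [beam_spec()]; used to place the SOBP span.
#' @return A data.frame with columns `label`, `x`, `y`, `z` (mm).
#' @export
fixture_points <- function(beam = fixture_beam_190()) {
  distal <- beam$nominal_range - beam$range_shifter
  mid <- distal - beam$sobp_width / 2
  data.frame(
    label = LETTERS[1:7],
    x = c(0,    5,   -6,    0,    6,   -4,    0),
    y = c(0,    0,    3,    8,   -5,   -8,    0),
    z = c(mid, mid + 12, mid - 12, mid - 18, mid + 5, mid + 18, distal - 3),
    stringsAsFactors = FALSE)
}
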