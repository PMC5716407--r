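#' Beam specification
#'
#' Describes the broad proton beam as delivered to the phantom entrance
#' plane: nominal range, SOBP modulation, upstream range shifter, a hard
#' circular aperture, the fluence profile across the aperture, and the
#' effective source model (standard deviation of the initial angular
#' distribution, plus a Gaussian entrance spot blur shared by both engines).
#'
#' @param nominal_range distal-80% range in mm of water (before the range
#'   shifter).
#' @param sobp_width SOBP modulation width in mm (0 = pristine beam).
#' @param range_shifter upstream absorber thickness in mm water equivalent.
#' @param field_radius aperture radius in mm (> 0); the aperture is a hard
#'   binary mask.
#' @param angular_sigma standard deviation of the initial angular
#'   distribution in radians (per projection), from the effective source
#'   model; default 4 mrad.
#' @param spot_sigma Gaussian blur (mm) applied to entrance positions,
#'   representing the finite effective source; default 1.5 mm.
#' @param source_to_iso effective source-to-isocenter distance in mm
#'   (metadata; default 2000).
#' @param fluence optional function `f(x, y)` giving the relative fluence
#'   profile over the entrance plane (values in `[0, 1]` after scaling);
#'   `NULL` means uniform.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(nominal_range, sobp_width = 0, range_shifter = 0,
                      field_radius = 25, angular_sigma = 0.004,
                      spot_sigma = 2, source_to_iso = 2000, fluence = NULL) {
  stopifnot(nominal_range > 0, sobp_width >= 0, range_shifter >= 0,
            field_radius > 0, angular_sigma >= 0, spot_sigma >= 0)
  if (!is.null(fluence)) stopifnot(is.function(fluence))
  structure(list(nominal_range = nominal_range, sobp_width = sobp_width,
                 range_shifter = range_shifter, field_radius = field_radius,
                 angular_sigma = angular_sigma, spot_sigma = spot_sigma,
                 source_to_iso = source_to_iso, fluence = fluence),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf(
    "<beam_spec> range %.1f mm, SOBP %.0f mm, shifter %.1f mm, aperture r=%.0f mm, ang sigma %.1f mrad\n",
    x$nominal_range, x$sobp_width, x$range_shifter, x$field_radius,
    1000 * x$angular_sigma))
  invisible(x)
}
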