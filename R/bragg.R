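# Gaussian smoothing of a tabulated curve (discrete renormalized kernel,
# proximal end padded with the entrance value, distal end with 0)
convolve_gauss <- function(values, grid_step, sigma) {
  if (sigma <= 0) return(values)
  half <- ceiling(5 * sigma / grid_step)
  kern <- stats::dnorm(seq(-half, half) * grid_step, sd = sigma)
  kern <- kern / sum(kern)
  padded <- c(rep(values[1], half), values, rep(0, half))
  pmax(stats::convolve(padded, rev(kern), type = "filter"), 0)
}

#' Analytic pristine Bragg curve
#'
#' Builds a pristine (mono-energetic) Bragg curve numerically.  The
#' *ideal* (per-particle) depth-dose is the exact cell-averaged energy
#' deposition from the Bethe range-energy relation -- the curve one proton
#' of exactly nominal range deposits.  The *measured* broad-beam curve is
#' the ideal curve convolved with a Gaussian range-straggling kernel of
#' width `sigma = 0.012 * R^0.935` (R in cm).  The pair is what the
#' simplified Monte Carlo needs: per-particle deposits follow the ideal
#' curve while the sampled range spread reconstructs the measured one.
#' The curve is shifted so the measured distal-80% depth equals `range_mm`
#' (the clinical range definition), then normalized to 1 at the entrance.
#'
#' @param range_mm clinical (distal-80%) range in mm of water, in `[10, 350]`.
#' @param straggling_mm Gaussian range-straggling sigma in mm; default the
#'   empirical scaling above.
#' @param grid_step tabulation step in mm (default 0.5).
#' @return A normalized [depth_curve()] of kind `"dose"` with
#'   `range_mm = range_mm`, carrying the extra fields `ideal` (per-particle
#'   values on the same grid and scale) and `straggling_mm`.
#' @export
pristine_bragg <- function(range_mm, straggling_mm = NULL, grid_step = 0.5) {
  if (!is.numeric(range_mm) || range_mm <= 0) stop("range must be positive")
  if (range_mm < 10 || range_mm > 350) stop("range must lie in [10, 350] mm")
  if (is.null(straggling_mm)) straggling_mm <- 10 * 0.012 * (range_mm / 10)^0.935

  build <- function(r_internal) {
    z <- seq(0, range_mm + 10 * straggling_mm + 5, by = grid_step)
    # exact cell-averaged energy deposition: (E at cell entry - E at cell
    # exit) / cell width; alias-free even though the un-straggled peak is
    # much sharper than the grid
    e_left <- energy_from_range(r_internal - (z - grid_step / 2))
    e_right <- energy_from_range(r_internal - (z + grid_step / 2))
    ideal <- pmax(e_left - e_right, 0) / grid_step
    smooth <- convolve_gauss(ideal, grid_step, straggling_mm)
    cv <- depth_curve(z, smooth, kind = "dose", normalization_depth = 0,
                      range_mm = range_mm)
    cv$ideal <- ideal
    cv$straggling_mm <- straggling_mm
    cv
  }

  # corrective iterations so the distal-80% depth lands on range_mm
  r_int <- range_mm
  for (i in 1:4) {
    cv <- build(r_int)
    d80 <- distal_level_depth(cv, 0.8)
    if (abs(d80 - range_mm) < 0.05) break
    r_int <- r_int + (range_mm - d80)
  }
  v0 <- lookup_curve(cv, cv$normalization_depth)
  cv$values <- cv$values / v0
  cv$ideal <- cv$ideal / v0
  cv
}

# per-particle (ideal) tabulation of a curve: the un-straggled values when
# the pair is available, the plain values otherwise
particle_values <- function(curve) {
  if (!is.null(curve$ideal)) curve$ideal else curve$values
}

#' Per-particle view of a depth curve
#'
#' Returns the un-straggled (per-particle) [depth_curve()] of a
#' [pristine_bragg()]-style pair, or the curve itself when no pair is
#' stored.  This is the curve a single proton deposits in the simplified
#' Monte Carlo; the measured curve is its range-straggling convolution.
#'
#' @param curve a [depth_curve()].
#' @return A [depth_curve()].
#' @export
particle_curve <- function(curve) {
  if (is.null(curve$ideal)) return(curve)
  depth_curve(curve$depths, curve$ideal, kind = curve$kind,
              normalization_depth = curve$normalization_depth,
              range_mm = curve$range_mm)
}

# straggling sigma associated with a curve (0 when unknown)
curve_straggling <- function(curve) {
  if (!is.null(curve$straggling_mm)) curve$straggling_mm else 0
}

# Lawson-Hanson non-negative least squares: minimize ||A w - b|| s.t. w >= 0.
nnls_fit <- function(A, b, tol = 1e-10, maxit = 10 * ncol(A)) {
  n <- ncol(A)
  w <- numeric(n)
  passive <- logical(n)
  grad <- crossprod(A, b - A %*% w)
  it <- 0
  while (any(!passive & grad > tol) && it < maxit) {
    it <- it + 1
    j <- which.max(ifelse(passive, -Inf, grad))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) { w <- s; break }
      neg <- passive & s <= tol
      alpha <- min(w[neg] / (w[neg] - s[neg]))
      w <- w + alpha * (s - w)
      passive[passive & w <= tol] <- FALSE
      w[!passive] <- 0
    }
    grad <- crossprod(A, b - A %*% w)
  }
  as.numeric(w)
}

# range-shift a curve proximally by `delta` mm (values taken from depth
# z + delta), keeping the tabulation grid and the ideal/measured pairing
shift_curve <- function(curve, delta) {
  out <- depth_curve(curve$depths, lookup_curve(curve, curve$depths + delta),
                     kind = curve$kind,
                     normalization_depth = curve$normalization_depth,
                     range_mm = curve$range_mm - delta)
  if (!is.null(curve$ideal)) {
    out$ideal <- stats::approx(curve$depths, curve$ideal,
                               xout = curve$depths + delta,
                               yleft = curve$ideal[1], yright = 0)$y
    out$straggling_mm <- curve$straggling_mm
  }
  out
}

#' Synthesize a spread-out Bragg peak (SOBP)
#'
#' Emulates a ridge filter: a weighted sum of range-shifted copies of the
#' pristine Bragg curve (an upstream absorber step is exactly a range
#' shift), with non-negative weights found by constrained least squares so
#' that the summed curve is flat across the modulated region
#' `[distal - width, distal - distal_margin]`.  The distal margin excludes
#' the intrinsic distal falloff of the deepest peak from the flatness
#' objective.
#'
#' @param distal_range_mm distal-80% range of the deepest peak, mm.
#' @param width_mm SOBP modulation width in mm (>= 0); 0 returns the single
#'   deepest pristine peak unchanged.
#' @param peak_spacing_mm spacing between component ranges (default 2.5 mm).
#' @param distal_margin_mm distal part of the modulated region excluded from
#'   the flatness fit (default 3 mm).
#' @param flatness_tol maximum allowed relative deviation from the plateau
#'   mean over the fitted region (default 0.02); exceeding it is an error
#'   reporting the achieved flatness.
#' @return A list with elements `curve` (normalized [depth_curve()], kind
#'   `"dose"`, `range_mm = distal_range_mm`, with per-particle `ideal`
#'   values), `ranges` and `weights` of the component peaks, `peaks` (the
#'   shifted component curves) and `pristine` (the deepest pristine curve).
#' @export
build_sobp <- function(distal_range_mm, width_mm, peak_spacing_mm = 2.5,
                       distal_margin_mm = 3, flatness_tol = 0.02) {
  if (width_mm < 0) stop("width must be >= 0")
  deepest <- pristine_bragg(distal_range_mm)
  if (width_mm == 0) {
    return(list(curve = deepest, ranges = distal_range_mm, weights = 1,
                peaks = list(deepest), pristine = deepest))
  }
  ranges <- seq(distal_range_mm, distal_range_mm - width_mm - 2 * peak_spacing_mm,
                by = -peak_spacing_mm)
  if (min(ranges) < 10) stop("SOBP width too large for the distal range")
  peaks <- lapply(ranges, function(r) shift_curve(deepest, distal_range_mm - r))
  z <- deepest$depths
  fit_z <- z[z >= distal_range_mm - width_mm & z <= distal_range_mm - distal_margin_mm]
  A <- vapply(peaks, function(p) lookup_curve(p, fit_z), numeric(length(fit_z)))
  w <- nnls_fit(A, rep(1, length(fit_z)))
  vals <- rowSums(vapply(peaks, function(p) p$values, numeric(length(z))) *
                  rep(w, each = length(z)))
  ideal <- rowSums(vapply(peaks, function(p) p$ideal, numeric(length(z))) *
                   rep(w, each = length(z)))
  plateau <- as.numeric(A %*% w)
  flat <- max(abs(plateau / mean(plateau) - 1))
  if (flat > flatness_tol) {
    stop(sprintf(
      "SOBP flatness %.3f exceeds tolerance %.3f at spacing %.1f mm; use a finer spacing",
      flat, flatness_tol, peak_spacing_mm))
  }
  cv <- depth_curve(z, vals, kind = "dose", normalization_depth = 0,
                    range_mm = distal_range_mm)
  v0 <- lookup_curve(cv, 0)
  cv$values <- cv$values / v0
  cv$ideal <- ideal / v0
  cv$straggling_mm <- deepest$straggling_mm
  list(curve = cv, ranges = ranges, weights = w, peaks = peaks,
       pristine = deepest)
}

#' Broad-beam depth-output curve of an SOBP
#'
#' The depth-output curve a MOSFET would measure in an SOBP is the
#' component-wise sum of response-weighted pristine curves: each component
#' carries its own residual range, so the depression persists across the
#' modulated region (protons stopping mid-SOBP have low residual range).
#' The response is applied to the per-particle (ideal) curve *before* the
#' straggling convolution, matching what the per-particle SMC scores.
#' Normalized at the entrance like the dose curve.
#'
#' @param sobp result of [build_sobp()].
#' @param model a [response_model()].
#' @return A [depth_curve()] of kind `"output"` (with per-particle `ideal`
#'   values).
#' @export
sobp_output <- function(sobp, model) {
  do_pristine <- apply_response(sobp$pristine, model)
  z <- sobp$curve$depths
  vals <- numeric(length(z))
  ideal <- numeric(length(z))
  for (k in seq_along(sobp$ranges)) {
    sh <- shift_curve(do_pristine, sobp$pristine$range_mm - sobp$ranges[k])
    vals <- vals + sobp$weights[k] * sh$values
    ideal <- ideal + sobp$weights[k] * sh$ideal
  }
  cv <- depth_curve(z, vals, kind = "output", normalization_depth = 0,
                    range_mm = sobp$curve$range_mm)
  v0 <- lookup_curve(cv, 0)
  cv$values <- cv$values / v0
  cv$ideal <- ideal / v0
  cv$straggling_mm <- sobp$pristine$straggling_mm
  cv
}
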