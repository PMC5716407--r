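#' Dose grid
#'
#' Per-voxel accumulated dose (or detector output) with per-voxel
#' statistical variance from the batch method.
#'
#' @param dose 3-D array of accumulated values.
#' @param variance 3-D array of statistical variance of `dose` (0 for
#'   deterministic engines).
#' @param voxel_size,origin calculation-grid geometry (mm).
#' @param n_histories number of histories (0 for deterministic engines).
#' @param batches number of statistical batches.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose, variance, voxel_size, origin, n_histories = 0,
                      batches = 0) {
  stopifnot(is.array(dose), length(dim(dose)) == 3,
            identical(dim(dose), dim(variance)))
  if (any(dose < 0) || any(variance < 0)) stop("dose and variance must be >= 0")
  structure(list(dose = dose, variance = variance,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 n_histories = n_histories, batches = batches),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$dose)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, %g histories in %d batches, max %.3g\n",
              d[1], d[2], d[3], x$n_histories, x$batches, max(x$dose)))
  invisible(x)
}

# calculation grid geometry: phantom grid downsampled `ds` x in-plane
calc_geometry <- function(phantom, downsample = 2L) {
  d <- dim(phantom$rsp)
  shape <- c(ceiling(d[1] / downsample), ceiling(d[2] / downsample), d[3])
  vs <- c(phantom$voxel_size[1] * downsample,
          phantom$voxel_size[2] * downsample, phantom$voxel_size[3])
  org <- c(phantom$origin[1] + (downsample - 1) / 2 * phantom$voxel_size[1],
           phantom$origin[2] + (downsample - 1) / 2 * phantom$voxel_size[2],
           phantom$origin[3])
  list(shape = as.integer(shape), voxel_size = vs, origin = org)
}

# resample a depth curve onto the uniform table used by the kernels
curve_table <- function(curve, tab_step = 0.25) {
  zmax <- max(curve$depths)
  lookup_curve(curve, seq(0, zmax, by = tab_step))
}

#' Sample protons from the effective source
#'
#' Entrance positions are drawn from the fluence profile inside the hard
#' circular aperture (uniform by default) and blurred by the Gaussian spot
#' of the effective source; per-proton slopes are two independent normal
#' deviates with the source model's angular standard deviation; the initial
#' residual range is the nominal range minus the range-shifter water
#' equivalent.  Uses R's RNG (seed with [set.seed()]).
#'
#' For a modulated (SOBP) beam each proton additionally draws a ridge-filter
#' component: its full range `curve_Z` is sampled from the modulation
#' weights and its residual range set accordingly.
#'
#' @param beam a [beam_spec()].
#' @param n number of protons (> 0).
#' @param entry_z z of the entrance plane in mm (default 0).
#' @param modulation `NULL` (pristine beam) or `list(ranges, weights)` from
#'   [build_sobp()].
#' @param straggling_mm Gaussian range-straggling sigma (mm) added to each
#'   proton's residual range; with per-particle (ideal) deposit curves the
#'   sampled spread reconstructs the measured broad-beam curve.
#' @return An `n x 8` matrix with columns
#'   `x, y, z, dx, dy, dz, resid, curve_Z`.
#' @export
sample_source <- function(beam, n, entry_z = 0, modulation = NULL,
                          straggling_mm = 0) {
  stopifnot(inherits(beam, "beam_spec"), n > 0)
  R <- beam$field_radius
  if (is.null(beam$fluence)) {
    r <- R * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    x <- r * cos(th); y <- r * sin(th)
  } else {
    # rejection sampling against the profile's maximum over the aperture
    g <- seq(-R, R, length.out = 41)
    M <- max(outer(g, g, function(a, b) ifelse(a^2 + b^2 <= R^2, beam$fluence(a, b), 0)))
    if (M <= 0) stop("fluence profile vanishes over the aperture")
    x <- numeric(0); y <- numeric(0)
    while (length(x) < n) {
      m <- 2L * (n - length(x)) + 16L
      r <- R * sqrt(stats::runif(m)); th <- stats::runif(m, 0, 2 * pi)
      cx <- r * cos(th); cy <- r * sin(th)
      keep <- stats::runif(m) * M <= beam$fluence(cx, cy)
      x <- c(x, cx[keep]); y <- c(y, cy[keep])
    }
    x <- x[seq_len(n)]; y <- y[seq_len(n)]
  }
  if (beam$spot_sigma > 0) {
    x <- x + stats::rnorm(n, 0, beam$spot_sigma)
    y <- y + stats::rnorm(n, 0, beam$spot_sigma)
  }
  tx <- stats::rnorm(n, 0, beam$angular_sigma)
  ty <- stats::rnorm(n, 0, beam$angular_sigma)
  nrm <- sqrt(tx^2 + ty^2 + 1)
  curve_z <- if (is.null(modulation)) {
    rep(beam$nominal_range, n)
  } else {
    stopifnot(length(modulation$ranges) == length(modulation$weights),
              all(modulation$weights >= 0))
    sample(modulation$ranges, n, replace = TRUE, prob = modulation$weights)
  }
  resid <- curve_z - beam$range_shifter
  if (straggling_mm > 0) resid <- resid + stats::rnorm(n, 0, straggling_mm)
  cbind(x = x, y = y, z = rep(entry_z, n),
        dx = tx / nrm, dy = ty / nrm, dz = 1 / nrm,
        resid = pmax(resid, 0),
        curve_Z = curve_z)
}

# default transport step: 1 mm capped at half the smallest voxel dimension
default_step <- function(phantom) min(1, min(phantom$voxel_size) / 2)

#' Ridge-filter modulation implied by a beam spec
#'
#' `NULL` for a pristine beam; otherwise the component ranges and weights of
#' the SOBP synthesis ([build_sobp()]) for the beam's distal range and
#' modulation width.
#'
#' @param beam a [beam_spec()].
#' @return `NULL` or `list(ranges, weights)`.
#' @export
beam_modulation <- function(beam) {
  if (beam$sobp_width <= 0) return(NULL)
  s <- build_sobp(beam$nominal_range, beam$sobp_width)
  list(ranges = s$ranges, weights = s$weights)
}

#' Transport a single proton (reference implementation)
#'
#' Pure-R reference for the per-step transport rule used by the compiled
#' kernel: per geometric step, water-equivalent loss `dwed = rsp * step`,
#' deposits `DD(Z - r) * dwed` and `DO(Z - r) * dwed` looked up at the
#' water-equivalent depth corresponding to the mid-step residual range
#' (Z is the beam's nominal range), followed by a Highland
#' multiple-scattering kick per projection.  Tracking stops when the
#' residual range reaches 0 or the proton leaves the phantom.
#'
#' @param state length-7 numeric `(x, y, z, dx, dy, dz, resid)` as produced
#'   by [sample_source()].
#' @param phantom a [voxel_phantom()].
#' @param dd,do dose and output [depth_curve()]s.
#' @param curve_Z nominal range of the beam in mm (depth origin of the
#'   curves).
#' @param step step length in mm; default [default_step()] of the phantom.
#' @param scatter logical; `FALSE` disables multiple scattering (useful for
#'   deterministic checks).
#' @return A data.frame with one row per deposit: calc-free phantom position
#'   (`x, y, z` of the step midpoint), `dose` and `output` deposits, and the
#'   residual range after the step.
#' @export
transport_proton <- function(state, phantom, dd, do, curve_Z,
                             step = default_step(phantom), scatter = TRUE) {
  stopifnot(length(state) == 7, step > 0)
  b <- phantom_bounds(phantom)
  d <- dim(phantom$rsp)
  pos <- state[1:3]; dir <- state[4:6]; resid <- state[7]
  out <- list()
  while (resid > 1e-9) {
    mid <- pos + dir * step / 2
    idx <- floor((mid - phantom$origin) / phantom$voxel_size + 0.5) + 1
    if (any(idx < 1) || any(idx > d)) break
    rv <- phantom$rsp[idx[1], idx[2], idx[3]]
    step_geom <- step
    dwed <- rv * step
    if (dwed >= resid) {
      step_geom <- if (rv > 0) step * resid / dwed else step
      dwed <- resid
    }
    if (dwed > 0) {
      depth <- curve_Z - (resid - dwed / 2)
      out[[length(out) + 1]] <- c(mid, lookup_curve(dd, depth) * dwed,
                                  lookup_curve(do, depth) * dwed, resid - dwed)
    }
    pos <- pos + dir * step_geom
    resid <- resid - dwed
    if (scatter && resid > 1e-9 && rv > 1e-6) {
      lo <- step_geom * rv / X0_WATER_MM
      e <- energy_from_range(resid)
      pv <- e * (e + 2 * PROTON_MASS_MEV) / (e + PROTON_MASS_MEV)
      th0 <- max(0, 14.1 / pv * sqrt(lo) * (1 + log10(lo) / 9))
      kick <- stats::rnorm(2, 0, th0)
      a <- if (abs(dir[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
      e1 <- c(dir[2] * a[3] - dir[3] * a[2],
              dir[3] * a[1] - dir[1] * a[3],
              dir[1] * a[2] - dir[2] * a[1])
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
              dir[3] * e1[1] - dir[1] * e1[3],
              dir[1] * e1[2] - dir[2] * e1[1])
      dir <- dir + kick[1] * e1 + kick[2] * e2
      dir <- dir / sqrt(sum(dir^2))
    }
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(numeric(0), 0, 6)
  stats::setNames(as.data.frame(m), c("x", "y", "z", "dose", "output", "resid"))
}

#' Run the simplified Monte Carlo engine
#'
#' Tracks `n` protons through the phantom, scoring the depth-dose curve
#' (PPIC) and the depth-output curve (MOSFET) along the *same* trajectories
#' (paired scoring), on the calculation grid (the phantom grid downsampled
#' 2x in-plane).  The per-voxel statistical variance is estimated by the
#' batch method; batch k reseeds the RNG with a sub-seed derived from
#' `seed`.  If a prescription is given, both grids are rescaled by the one
#' constant that brings the PPIC dose at the prescription point to the
#' prescribed value.
#'
#' @param phantom a [voxel_phantom()].
#' @param beam a [beam_spec()].
#' @param dd,do the per-particle (pristine, broad-beam measured) dose and
#'   output [depth_curve()]s; under SOBP modulation every component indexes
#'   these same curves through its own residual range.
#' @param n total number of histories (`n >= batches >= 2`).
#' @param seed integer RNG seed.
#' @param batches number of batches (default 10).
#' @param step transport step in mm; default [default_step()].
#' @param downsample in-plane calculation-grid downsampling factor
#'   (default 2, i.e. "2 pixels").
#' @param prescription `NULL`, or `list(point = c(x, y, z), dose = cGy)`.
#' @param modulation `NULL` for a pristine beam, or `list(ranges, weights)`
#'   (e.g. from [build_sobp()]) describing the ridge filter; defaults to the
#'   synthesis implied by `beam$sobp_width`.
#' @return A list with `ppic` and `mosfet` [dose_grid()]s.
#' @export
run_smc <- function(phantom, beam, dd, do, n, seed, batches = 10L,
                    step = default_step(phantom), downsample = 2L,
                    prescription = NULL,
                    modulation = beam_modulation(beam)) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(beam, "beam_spec"),
            n >= batches, batches >= 2)
  if (step > min(phantom$voxel_size)) {
    warning("transport step exceeds the smallest voxel dimension; accuracy degrades")
  }
  cg <- calc_geometry(phantom, downsample)
  tab_step <- 0.25
  # per-particle deposit tables; the sampled range straggling reconstructs
  # the measured curves in aggregate
  dd_tab <- curve_table(particle_curve(dd), tab_step)
  do_tab <- curve_table(particle_curve(do), tab_step)
  straggle <- curve_straggling(dd)
  pvt <- pv_table(max_range_mm = beam$nominal_range + 50)
  entry_z <- phantom_bounds(phantom)["lo", 3]
  nv <- prod(cg$shape)
  sum_d <- numeric(nv); sum_o <- numeric(nv)
  ssq_d <- numeric(nv); ssq_o <- numeric(nv)
  set.seed(seed)
  batch_seeds <- sample.int(.Machine$integer.max - 1L, batches)
  per <- diff(round(seq(0, n, length.out = batches + 1)))
  for (k in seq_len(batches)) {
    set.seed(batch_seeds[k])
    st <- sample_source(beam, per[k], entry_z = entry_z,
                        modulation = modulation, straggling_mm = straggle)
    bd <- numeric(nv); bo <- numeric(nv)
    smc_transport_batch(st[, 1:7, drop = FALSE], as.vector(phantom$rsp),
                        as.integer(dim(phantom$rsp)), phantom$voxel_size,
                        phantom$origin, cg$shape, cg$voxel_size, cg$origin,
                        dd_tab, do_tab, tab_step, curve_range(dd),
                        pvt$pv, pvt$step, step, X0_WATER_MM, bd, bo)
    sum_d <- sum_d + bd; ssq_d <- ssq_d + bd^2
    sum_o <- sum_o + bo; ssq_o <- ssq_o + bo^2
  }
  B <- batches
  var_tot <- function(s, sq) pmax(0, (sq - s^2 / B) * B / (B - 1))
  mk <- function(s, sq) {
    dose_grid(array(s, dim = cg$shape), array(var_tot(s, sq), dim = cg$shape),
              cg$voxel_size, cg$origin, n_histories = n, batches = B)
  }
  ppic <- mk(sum_d, ssq_d)
  mosfet <- mk(sum_o, ssq_o)
  if (!is.null(prescription)) {
    at <- trilinear_at(ppic, prescription$point)
    if (at <= 0) stop("zero dose at the prescription point; cannot normalize")
    cst <- prescription$dose / at
    ppic$dose <- ppic$dose * cst; ppic$variance <- ppic$variance * cst^2
    mosfet$dose <- mosfet$dose * cst; mosfet$variance <- mosfet$variance * cst^2
  }
  list(ppic = ppic, mosfet = mosfet)
}

#' Trilinear interpolation of a dose grid at a point
#'
#' @param grid a [dose_grid()] (or any list with `dose`, `voxel_size`,
#'   `origin`).
#' @param point mm position `c(x, y, z)`.
#' @param what `"dose"` or `"variance"`.
#' @return Interpolated value (0 outside the grid).
#' @export
trilinear_at <- function(grid, point, what = "dose") {
  a <- grid[[what]]
  d <- dim(a)
  u <- (point - grid$origin) / grid$voxel_size   # voxel-center coordinates
  i0 <- floor(u)
  f <- u - i0
  val <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ii <- i0 + c(cx, cy, cz) + 1
    w <- prod(ifelse(c(cx, cy, cz) == 1, f, 1 - f))
    if (w == 0) next
    if (any(ii < 1) || any(ii > d)) next
    val <- val + w * a[ii[1], ii[2], ii[3]]
  }
  val
}

#' Mean statistical error over a region
#'
#' Root-mean-square over the region voxels of the per-voxel relative batch
#' standard error, in percent.
#'
#' @param grid a [dose_grid()] produced by [run_smc()].
#' @param region logical array (same shape as the grid) or voxel indices.
#' @return Percent rms statistical error.
#' @export
statistical_error <- function(grid, region) {
  stopifnot(inherits(grid, "dose_grid"))
  if (grid$batches < 2) stop("need at least 2 batches for a variance estimate")
  dsel <- grid$dose[region]
  vsel <- grid$variance[region]
  if (length(dsel) == 0) stop("empty region")
  if (any(dsel <= 0)) stop("region contains voxels with zero dose")
  sqrt(mean(vsel / dsel^2)) * 100
}
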