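# Pencil-beam algorithm: central-axis water-equivalent depth lookup with a
# single lateral Gaussian, superposed over a regular entrance pencil grid.

#' Lateral spread model along a pencil's central axis
#'
#' Builds sigma(z) for one pencil: the Fermi-Eyges accumulation of Highland
#' multiple scattering along the central axis (heterogeneity sampled on the
#' axis only -- the PBA's documented limitation), added in quadrature with
#' the source terms: the entrance spot blur and the angular spread times the
#' travelled distance.
#'
#' @param phantom a [voxel_phantom()].
#' @param beam a [beam_spec()].
#' @param pencil_xy entrance position `c(x0, y0)` in mm.
#' @param z_eval z positions (mm) at which sigma and the central-axis
#'   water-equivalent depth are needed.
#' @param sub_step integration step in mm (default 1).
#' @return A list with `sigma_mm` (> 0, monotone non-decreasing) and
#'   `wed_mm`, both at `z_eval`.
#' @export
lateral_sigma <- function(phantom, beam, pencil_xy, z_eval, sub_step = 1) {
  b <- phantom_bounds(phantom)
  z0 <- b["lo", 3]
  zt <- seq(z0 + sub_step / 2, max(z_eval) + sub_step, by = sub_step)
  d <- dim(phantom$rsp)
  idx <- cbind(
    as.integer(floor((pencil_xy[1] - phantom$origin[1]) / phantom$voxel_size[1] + 0.5)) + 1L,
    as.integer(floor((pencil_xy[2] - phantom$origin[2]) / phantom$voxel_size[2] + 0.5)) + 1L,
    as.integer(floor((zt - phantom$origin[3]) / phantom$voxel_size[3] + 0.5)) + 1L)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
            idx[, 3] >= 1 & idx[, 3] <= d[3]
  rsp <- numeric(length(zt))
  rsp[inside] <- phantom$rsp[idx[inside, , drop = FALSE]]
  wed <- cumsum(rsp * sub_step)
  resid <- beam$nominal_range - beam$range_shifter - wed
  e <- energy_from_range(pmax(resid, 0))
  pv <- e * (e + 2 * PROTON_MASS_MEV) / (e + PROTON_MASS_MEV)
  lo <- rsp * sub_step / X0_WATER_MM
  th0 <- ifelse(lo > 0 & resid > 0,
                pmax(0, 14.1 / pv * sqrt(lo) * (1 + log10(lo) / 9)), 0)
  # Fermi-Eyges: sigma_MCS^2(z) = sum over upstream steps of theta0^2 (z-t)^2
  sig2 <- vapply(z_eval, function(z) {
    up <- zt < z
    sum(th0[up]^2 * (z - zt[up])^2)
  }, 0)
  src2 <- beam$spot_sigma^2 + (beam$angular_sigma * pmax(z_eval - z0, 0))^2
  wed_at <- stats::approx(zt + sub_step / 2, wed, xout = z_eval, rule = 2)$y
  list(sigma_mm = sqrt(sig2 + src2), wed_mm = wed_at)
}

#' Dose contribution of a single pencil beam at a point
#'
#' `phi * DD(z_wed) * exp(-rho^2 / (2 sigma^2)) / (2 pi sigma^2)` where
#' `rho` is the lateral distance from the pencil axis and `z_wed` the
#' water-equivalent depth along the pencil's central axis (plus the range
#' shifter).
#'
#' @param x,y,z evaluation point (mm); `z_wed` and `sigma` must correspond
#'   to this z.
#' @param pencil_xy pencil entrance position `c(x0, y0)` (mm).
#' @param curve the depth-dose (or depth-output) [depth_curve()].
#' @param sigma_mm lateral spread at z (> 0).
#' @param z_wed_mm water-equivalent lookup depth at z.
#' @param phi pencil fluence weight (default 1).
#' @return Dose (or output) contribution.
#' @export
pencil_dose <- function(x, y, z, pencil_xy, curve, sigma_mm, z_wed_mm, phi = 1) {
  if (any(sigma_mm <= 0)) stop("sigma must be > 0")
  rho2 <- (x - pencil_xy[1])^2 + (y - pencil_xy[2])^2
  phi * lookup_curve(curve, z_wed_mm) *
    exp(-rho2 / (2 * sigma_mm^2)) / (2 * pi * sigma_mm^2)
}

#' Output contribution of a single pencil beam at a point
#'
#' Identical to [pencil_dose()] with the depth-output curve in place of the
#' depth-dose curve.
#'
#' @inheritParams pencil_dose
#' @export
pencil_output <- function(x, y, z, pencil_xy, curve, sigma_mm, z_wed_mm, phi = 1) {
  stopifnot(curve$kind == "output")
  pencil_dose(x, y, z, pencil_xy, curve, sigma_mm, z_wed_mm, phi)
}

#' Run the pencil-beam algorithm
#'
#' Superposes [pencil_dose()] / [pencil_output()] contributions of a regular
#' grid of pencils covering the aperture onto the calculation grid
#' (phantom grid downsampled 2x in-plane, as for [run_smc()]).
#' Deterministic; exactly linear in the fluence.
#'
#' @inheritParams run_smc
#' @param spacing pencil grid spacing in mm (default 2); a warning is issued
#'   if it exceeds the entrance sigma.
#' @return A list with `ppic` and `mosfet` [dose_grid()]s (variance 0).
#' @export
run_pba <- function(phantom, beam, dd, do, spacing = 2, downsample = 2L,
                    prescription = NULL) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(beam, "beam_spec"))
  cg <- calc_geometry(phantom, downsample)
  b <- phantom_bounds(phantom)
  sigma0 <- beam$spot_sigma
  if (spacing > max(sigma0, 1e-6)) {
    warning(sprintf(
      "pencil spacing %.1f mm exceeds the entrance sigma %.1f mm; expect plateau ripple of order exp(-2 pi^2 sigma^2 / spacing^2)",
      spacing, sigma0))
  }
  g <- seq(-beam$field_radius, beam$field_radius, by = spacing)
  pencils <- expand.grid(x = g, y = g)
  pencils <- pencils[pencils$x^2 + pencils$y^2 <= beam$field_radius^2, ]
  xc <- cg$origin[1] + (seq_len(cg$shape[1]) - 1) * cg$voxel_size[1]
  yc <- cg$origin[2] + (seq_len(cg$shape[2]) - 1) * cg$voxel_size[2]
  zc <- cg$origin[3] + (seq_len(cg$shape[3]) - 1) * cg$voxel_size[3]
  dosea <- array(0, dim = cg$shape)
  outa <- array(0, dim = cg$shape)
  for (p in seq_len(nrow(pencils))) {
    p0 <- c(pencils$x[p], pencils$y[p])
    phi <- if (is.null(beam$fluence)) 1 else beam$fluence(p0[1], p0[2])
    if (phi <= 0) next
    ls <- lateral_sigma(phantom, beam, p0, zc)
    depth <- beam$range_shifter + ls$wed_mm
    ddv <- lookup_curve(dd, depth)
    dov <- lookup_curve(do, depth)
    for (iz in seq_along(zc)) {
      if (ddv[iz] <= 0 && dov[iz] <= 0) next
      s <- ls$sigma_mm[iz]
      win <- 4.5 * s
      ix <- which(abs(xc - p0[1]) <= win)
      iy <- which(abs(yc - p0[2]) <= win)
      if (!length(ix) || !length(iy)) next
      gx <- exp(-(xc[ix] - p0[1])^2 / (2 * s^2))
      gy <- exp(-(yc[iy] - p0[2])^2 / (2 * s^2))
      lat <- phi * outer(gx, gy) / (2 * pi * s^2)
      dosea[ix, iy, iz] <- dosea[ix, iy, iz] + ddv[iz] * lat
      outa[ix, iy, iz] <- outa[ix, iy, iz] + dov[iz] * lat
    }
  }
  zero <- array(0, dim = cg$shape)
  ppic <- dose_grid(dosea, zero, cg$voxel_size, cg$origin)
  mosfet <- dose_grid(outa, zero, cg$voxel_size, cg$origin)
  if (!is.null(prescription)) {
    at <- trilinear_at(ppic, prescription$point)
    if (at <= 0) stop("zero dose at the prescription point; cannot normalize")
    cst <- prescription$dose / at
    ppic$dose <- ppic$dose * cst
    mosfet$dose <- mosfet$dose * cst
  }
  list(ppic = ppic, mosfet = mosfet)
}
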