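# Physical constants (MeV unless noted)
PROTON_MASS_MEV <- 938.272
ELECTRON_MASS_MEV <- 0.5109989
K_BETHE <- 0.307075            # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
X0_WATER_MM <- 360.8           # radiation length of water, mm

#' Construct a material
#'
#' A material carries the quantities the transport and conversion code needs:
#' mass density, relative stopping power (RSP, water = 1), the ratio Z/A used
#' by the Bethe formula, and the mean excitation energy I.
#'
#' @param name identifier.
#' @param density mass density in g/cm^3 (> 0).
#' @param rsp relative stopping power, dimensionless (> 0; water is exactly 1).
#' @param z_over_a ratio of atomic number to atomic mass, mol/g.
#' @param mean_excitation_energy mean excitation energy I in eV.
#' @return An object of class `material`.
#' @export
material <- function(name, density, rsp, z_over_a, mean_excitation_energy) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (!is.numeric(rsp) || rsp <= 0) stop("rsp must be > 0")
  if (identical(name, "water") && rsp != 1) stop("water must have rsp = 1")
  structure(
    list(name = name, density = density, rsp = rsp, z_over_a = z_over_a,
         mean_excitation_energy = mean_excitation_energy),
    class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: density %.4g g/cm^3, RSP %.4g, Z/A %.4g, I %.4g eV\n",
              x$name, x$density, x$rsp, x$z_over_a, x$mean_excitation_energy))
  invisible(x)
}

# Catalog of the materials used by the fixtures.  The polyethylene RSP is
# pinned at the operational value 1.02 (not derived from composition) so WET
# conversions are bit-reproducible; bone and air RSP values match the HU
# calibration table endpoints.
.material_defs <- list(
  water        = list(density = 1.000,  rsp = 1.000, z_over_a = 0.55509, I = 75.0),
  polyethylene = list(density = 0.940,  rsp = 1.020, z_over_a = 0.57034, I = 57.4),
  soft_tissue  = list(density = 1.000,  rsp = 1.000, z_over_a = 0.55512, I = 75.3),
  cortical_bone = list(density = 1.920, rsp = 1.600, z_over_a = 0.51478, I = 112.0),
  air          = list(density = 0.0012, rsp = 0.001, z_over_a = 0.49919, I = 85.7)
)

#' Look up a packaged material by name
#'
#' @param name one of `"water"`, `"polyethylene"`, `"soft_tissue"`,
#'   `"cortical_bone"`, `"air"`.
#' @return A [material()] object.
#' @export
pt_material <- function(name) {
  d <- .material_defs[[name]]
  if (is.null(d)) {
    stop("unknown material '", name, "'; available: ",
         paste(names(.material_defs), collapse = ", "))
  }
  material(name, d$density, d$rsp, d$z_over_a, d$I)
}

#' Water-equivalent thickness of a material slab
#'
#' Multiplies the physical thickness by the material's relative stopping
#' power; a polyethylene slab converts with the factor 1.02 and water is the
#' identity.
#'
#' @param thickness_mm physical thickness in mm (>= 0); vectorized.
#' @param material a [material()] object.
#' @return Water-equivalent thickness in mm.
#' @export
water_equivalent_thickness <- function(thickness_mm, material) {
  stopifnot(inherits(material, "material"))
  if (any(thickness_mm < 0)) stop("thickness must be >= 0")
  thickness_mm * material$rsp
}

#' Electronic mass stopping power of a proton (Bethe formula)
#'
#' Plain Bethe formula without shell or Barkas corrections, with the exact
#' maximum energy transfer to a free electron.  Adequate to ~1-2% over the
#' therapeutic range; the validity window is enforced as 1-300 MeV.
#'
#' @param energy_mev proton kinetic energy in MeV, in `[1, 300]`; vectorized.
#' @param material a [material()] object (default water).
#' @return Mass stopping power in MeV cm^2/g.
#' @export
stopping_power <- function(energy_mev, material = pt_material("water")) {
  stopifnot(inherits(material, "material"))
  if (any(energy_mev < 1 | energy_mev > 300)) {
    stop("energy must lie in [1, 300] MeV")
  }
  gamma <- 1 + energy_mev / PROTON_MASS_MEV
  beta2 <- 1 - 1 / gamma^2
  me_over_mp <- ELECTRON_MASS_MEV / PROTON_MASS_MEV
  # maximum energy transfer to a free electron, MeV
  wmax <- 2 * ELECTRON_MASS_MEV * beta2 * gamma^2 /
    (1 + 2 * gamma * me_over_mp + me_over_mp^2)
  i_mev <- material$mean_excitation_energy * 1e-6
  log_term <- 0.5 * log(2 * ELECTRON_MASS_MEV * beta2 * gamma^2 * wmax / i_mev^2)
  K_BETHE * material$z_over_a / beta2 * (log_term - beta2)
}

#' Linear energy transfer in keV/um
#'
#' Mass stopping power times density, converted to keV per micrometre
#' (1 MeV/cm = 0.1 keV/um).  For 157 MeV protons in water this evaluates to
#' ~0.53 keV/um, i.e. 0.5 after rounding to one decimal.
#'
#' @inheritParams stopping_power
#' @return LET in keV/um.
#' @export
let_keV_per_um <- function(energy_mev, material = pt_material("water")) {
  stopping_power(energy_mev, material) * material$density * 0.1
}

# Cached range-energy table for water, built once per session by integrating
# 1/S(E) (CSDA in the continuous-slowing-down sense, Bethe only).  Ranges in
# mm of water; energies in MeV.
.pt_cache <- new.env(parent = emptyenv())

range_energy_table <- function() {
  tab <- .pt_cache$range_energy
  if (is.null(tab)) {
    e <- seq(1, 300, by = 0.1)
    s <- stopping_power(e)                 # MeV cm^2/g; water density 1
    inv <- 1 / s                           # cm per MeV
    r_cm <- cumsum(c(0, diff(e) * (inv[-1] + inv[-length(inv)]) / 2))
    tab <- list(energy = e, range_mm = r_cm * 10)
    .pt_cache$range_energy <- tab
  }
  tab
}

#' CSDA range of a proton in water
#'
#' @param energy_mev kinetic energy in MeV, `[1, 300]`; vectorized.
#' @return Range in mm of water (measured from the 1 MeV endpoint; the
#'   residual sub-millimetre below 1 MeV is neglected).
#' @export
proton_range_water <- function(energy_mev) {
  tab <- range_energy_table()
  stats::approx(tab$energy, tab$range_mm, xout = energy_mev, rule = 2)$y
}

#' Proton kinetic energy from residual range in water
#'
#' Inverse of [proton_range_water()]; residual ranges below the 1 MeV range
#' return 1 MeV, energies are capped at 300 MeV.
#'
#' @param range_mm residual range in mm of water; vectorized.
#' @return Kinetic energy in MeV.
#' @export
energy_from_range <- function(range_mm) {
  tab <- range_energy_table()
  stats::approx(tab$range_mm, tab$energy, xout = pmax(range_mm, 0), rule = 2)$y
}

# pv = p*v = E(E + 2m) / (E + m), the kinematic factor in the Highland
# formula, as a function of residual range in water.  Returned as a uniform
# table for fast interpolation inside the transport kernel.
pv_table <- function(max_range_mm = 400, step_mm = 0.5) {
  r <- seq(0, max_range_mm, by = step_mm)
  e <- energy_from_range(r)
  pv <- e * (e + 2 * PROTON_MASS_MEV) / (e + PROTON_MASS_MEV)
  list(step = step_mm, pv = pv)
}

# Default HU -> RSP calibration: 5-point piecewise-linear, monotone,
# water-anchored at HU = 0.  The clinical calibration is scanner specific;
# this table is a documented stand-in.
.hu_table <- list(
  hu  = c(-1000, 0, 100, 1000, 3000),
  rsp = c(0.001, 1.0, 1.07, 1.6, 2.4)
)

#' Convert Hounsfield units to relative stopping power
#'
#' Piecewise-linear, monotone non-decreasing calibration anchored at
#' HU 0 -> RSP 1 (water).  Values outside `[-1024, 3000]` are clamped with a
#' warning.
#'
#' @param hu Hounsfield units; vectorized.
#' @param table optional replacement calibration,
#'   `list(hu = ..., rsp = ...)` with strictly increasing `hu` and
#'   non-decreasing `rsp`.
#' @return Relative stopping power, dimensionless.
#' @export
hu_to_rsp <- function(hu, table = .hu_table) {
  stopifnot(length(table$hu) == length(table$rsp),
            !is.unsorted(table$hu, strictly = TRUE),
            !is.unsorted(table$rsp))
  if (any(hu < -1024 | hu > 3000)) {
    warning("HU outside [-1024, 3000] clamped to the calibration range")
    hu <- pmin(pmax(hu, -1024), 3000)
  }
  stats::approx(table$hu, table$rsp, xout = hu, rule = 2)$y
}
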