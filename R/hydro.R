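#' Solvent conditions for hydrodynamic calculations
#'
#' Bundles the absolute temperature, solvent density and solvent viscosity
#' under which sedimentation and diffusion coefficients are interpreted.
#' All internal computation is in CGS units (cm, g, s, erg); the Svedberg
#' (1e-13 s) appears only at input/output boundaries.
#'
#' @param temperature Absolute temperature, K.
#' @param density Solvent density, g/ml.
#' @param viscosity Solvent viscosity, poise (g/(cm s)).
#' @return An object of class `solution_conditions`.
#' @seealso [water20()] for standard water at 20 degrees C.
#' @export
solution_conditions <- function(temperature, density, viscosity) {
  stopifnot(temperature > 0, density > 0, viscosity > 0)
  structure(list(temperature = temperature, density = density,
                 viscosity = viscosity),
            class = "solution_conditions")
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf("solution conditions: T = %.2f K, rho = %.5f g/ml, eta = %.4g P\n",
              x$temperature, x$density, x$viscosity))
  invisible(x)
}

#' Standard conditions: water at 20 degrees C
#'
#' The reference state in which s(20,w) and D(20,w) values are quoted.
#'
#' @return A `solution_conditions` object (293.15 K, 0.99823 g/ml, 1.002e-2 P).
#' @export
water20 <- function() solution_conditions(293.15, 0.99823, 1.002e-2)

#' Typical Tris/NaCl AUC buffer conditions
#'
#' Water viscosity at 20 degrees C but the measured buffer density of
#' 1.005 g/ml typical of 20 mM Tris, 150 mM NaCl.
#'
#' @return A `solution_conditions` object (293.15 K, 1.005 g/ml, 1.002e-2 P).
#' @export
buffer_tris150 <- function() solution_conditions(293.15, 1.005, 1.002e-2)

#' Describe one sedimenting species
#'
#' A container for the hydrodynamic description of a single ideal species.
#' `s` and `D` may be supplied directly, or derived from mass and frictional
#' ratio with [sD_from_M()].
#'
#' @param molar_mass Molar mass of the sedimenting particle, g/mol.
#' @param vbar Partial specific volume, ml/g.
#' @param s Sedimentation coefficient, seconds (1 S = 1e-13 s).
#' @param D Diffusion coefficient, cm^2/s.
#' @param ff0 Frictional ratio f/f0 (dimensionless, >= 1 for physical
#'   particles).
#' @param extinction_280 Molar extinction coefficient at 280 nm,
#'   1/(M cm), per sedimenting particle.
#' @param loading_concentration Loading (particle) concentration, mol/L.
#' @return An object of class `species_hydro`.
#' @export
species_hydro <- function(molar_mass, vbar, s = NA_real_, D = NA_real_,
                          ff0 = NA_real_, extinction_280 = NA_real_,
                          loading_concentration = NA_real_) {
  stopifnot(molar_mass > 0, vbar > 0)
  if (!is.na(s)) stopifnot(s > 0)
  if (!is.na(D)) stopifnot(D > 0)
  structure(list(molar_mass = molar_mass, vbar = vbar, s = s, D = D,
                 ff0 = ff0, extinction_280 = extinction_280,
                 loading_concentration = loading_concentration),
            class = "species_hydro")
}

#' @export
print.species_hydro <- function(x, ...) {
  cat(sprintf("species: M = %.0f g/mol, vbar = %.3f ml/g, s = %s S, D = %s cm2/s, f/f0 = %s\n",
              x$molar_mass, x$vbar,
              ifelse(is.na(x$s), "?", sprintf("%.3f", x$s / .const$svedberg)),
              ifelse(is.na(x$D), "?", sprintf("%.3g", x$D)),
              ifelse(is.na(x$ff0), "?", sprintf("%.2f", x$ff0))))
  invisible(x)
}

buoyancy <- function(vbar, cond) 1 - vbar * cond$density

#' Molar mass from the Svedberg equation
#'
#' M = s R T / (D (1 - vbar rho)). This is the relation behind
#' weight-average masses reported from paired (s, D) estimates of
#' discrete-species sedimentation velocity analysis.
#'
#' @param s Sedimentation coefficient, seconds.
#' @param D Diffusion coefficient, cm^2/s.
#' @param vbar Partial specific volume, ml/g.
#' @param cond A [solution_conditions()] object.
#' @return Molar mass in g/mol.
#' @examples
#' # the PFV Gag-NtD dimer: ~47 kD from s = 3.08 S, D = 5.96e-7 cm2/s
#' svedberg_mass(3.08e-13, 5.96e-7, 0.731, buffer_tris150())
#' @export
svedberg_mass <- function(s, D, vbar, cond) {
  stopifnot(s > 0, D > 0)
  b <- buoyancy(vbar, cond)
  if (b <= 0)
    stop("buoyancy term (1 - vbar*rho) <= 0: species does not sediment")
  s * .const$R_erg * cond$temperature / (D * b)
}

#' Friction coefficient of the equivalent anhydrous sphere
#'
#' f0 = 6 pi eta r0 with r0 the radius of an anhydrous (unhydrated) sphere
#' of the same mass and partial specific volume:
#' r0 = (3 M vbar / (4 pi N_A))^(1/3).
#'
#' @inheritParams svedberg_mass
#' @param M Molar mass, g/mol.
#' @return Friction coefficient in g/s.
#' @export
sphere_friction_f0 <- function(M, vbar, cond) {
  stopifnot(M > 0, vbar > 0)
  r0 <- (3 * M * vbar / (4 * pi * .const$N_A))^(1 / 3)
  6 * pi * cond$viscosity * r0
}

#' Frictional ratio from the sedimentation coefficient
#'
#' The measured friction f = M (1 - vbar rho) / (N_A s) divided by the
#' anhydrous-sphere reference [sphere_friction_f0()]. Values below 1 are
#' unphysical for real particles and are returned with a warning (they can
#' arise from mutually inconsistent inputs).
#'
#' @inheritParams svedberg_mass
#' @param M Molar mass, g/mol.
#' @return Dimensionless frictional ratio f/f0.
#' @examples
#' frictional_ratio_from_s(3.08e-13, 46700, 0.731, buffer_tris150()) # 1.48
#' @export
frictional_ratio_from_s <- function(s, M, vbar, cond) {
  stopifnot(s > 0, M > 0)
  b <- buoyancy(vbar, cond)
  if (b <= 0)
    stop("buoyancy term (1 - vbar*rho) <= 0: species does not sediment")
  f <- M * b / (.const$N_A * s)
  ratio <- f / sphere_friction_f0(M, vbar, cond)
  if (ratio < 1)
    warning("frictional ratio < 1 is unphysical; check input consistency")
  ratio
}

#' Frictional ratio from the diffusion coefficient
#'
#' Uses the Stokes-Einstein friction f = kB T / D over the
#' anhydrous-sphere reference.
#'
#' @inheritParams frictional_ratio_from_s
#' @param D Diffusion coefficient, cm^2/s.
#' @return Dimensionless frictional ratio f/f0.
#' @export
frictional_ratio_from_d <- function(D, M, vbar, cond) {
  stopifnot(D > 0, M > 0)
  f <- .const$kB_erg * cond$temperature / D
  ratio <- f / sphere_friction_f0(M, vbar, cond)
  if (ratio < 1)
    warning("frictional ratio < 1 is unphysical; check input consistency")
  ratio
}

#' Forward model: (s, D) from mass and frictional ratio
#'
#' Computes the Svedberg-consistent pair (s, D) for a particle of given
#' molar mass and shape (frictional ratio) under stated conditions. This is
#' the forward model used by the sedimentation simulators; by construction
#' `svedberg_mass(s, D, vbar, cond)` returns `M` exactly.
#'
#' @inheritParams frictional_ratio_from_s
#' @param ff0 Frictional ratio f/f0, >= 1.
#' @return A list with elements `s` (seconds) and `D` (cm^2/s).
#' @examples
#' sD_from_M(45426, 1.48, 0.731, water20()) # ~3.1 S
#' @export
sD_from_M <- function(M, ff0, vbar, cond) {
  stopifnot(M > 0, ff0 >= 1)
  f <- sphere_friction_f0(M, vbar, cond) * ff0
  list(s = M * buoyancy(vbar, cond) / (.const$N_A * f),
       D = .const$kB_erg * cond$temperature / f)
}

# Inverse of the c(s) parameterization: molar mass implied by a
# sedimentation coefficient at fixed frictional ratio.
# s = M (1-vbar rho) / (N_A f0(M) ff0) with f0 ~ M^(1/3)  =>  M ~ s^(3/2).
mass_from_s <- function(s, ff0, vbar, cond) {
  k <- 6 * pi * cond$viscosity * (3 * vbar / (4 * pi * .const$N_A))^(1 / 3)
  (s * .const$N_A * k * ff0 / buoyancy(vbar, cond))^(3 / 2)
}

# Diffusion coefficient for grid point s under shared frictional ratio,
# the standard c(s) scaling relation.
diffusion_from_s <- function(s, ff0, vbar, cond) {
  M <- mass_from_s(s, ff0, vbar, cond)
  sD_from_M(M, ff0, vbar, cond)$D
}

#' Hydrodynamic summary table for a set of species
#'
#' Reproduces, for each species, the derived quantities conventionally
#' reported from sedimentation analysis: Svedberg mass from (s, D) and
#' frictional ratios computed from s and from D separately.
#'
#' @param species A list of [species_hydro()] objects (each needs `s`, `D`).
#' @param cond A [solution_conditions()] object.
#' @return A data.frame with one row per species.
#' @export
hydro_table <- function(species, cond) {
  stopifnot(length(species) > 0)
  rows <- lapply(species, function(sp) {
    data.frame(
      M_input = sp$molar_mass,
      s_S = sp$s / .const$svedberg,
      D_cm2s = sp$D,
      M_svedberg = svedberg_mass(sp$s, sp$D, sp$vbar, cond),
      ff0_from_s = frictional_ratio_from_s(sp$s, sp$molar_mass, sp$vbar, cond),
      ff0_from_d = frictional_ratio_from_d(sp$D, sp$molar_mass, sp$vbar, cond)
    )
  })
  do.call(rbind, rows)
}
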