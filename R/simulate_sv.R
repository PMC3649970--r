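#' Sector cell geometry
#'
#' @param meniscus Meniscus radius, cm.
#' @param base Base radius, cm.
#' @param pathlength Optical pathlength, cm (12 mm standard centrepiece;
#'   3 mm used for strongly absorbing samples).
#' @param sector_angle Sector angle, radians.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(meniscus = 6.0, base = 7.2, pathlength = 1.2,
                          sector_angle = 2.5 * pi / 180) {
  stopifnot(base > meniscus, meniscus > 0, pathlength > 0, sector_angle > 0)
  structure(list(meniscus = meniscus, base = base, pathlength = pathlength,
                 sector_angle = sector_angle),
            class = "cell_geometry")
}

# Interference fringe displacement per unit mass concentration:
# fringes = fringe_coef * l[cm] * c[mg/ml]; 3.3 fringes ml/(mg cm) is the
# community-standard refractive increment for proteins at 675 nm.
.default_fringe_coef <- 3.3

# Signal produced by 1 mol/L of a species over pathlength l, by channel.
signal_coef <- function(sp, channel, pathlength,
                        fringe_coef = .default_fringe_coef) {
  switch(channel,
    absorbance280 = sp$extinction_280 * pathlength,
    interference = fringe_coef * pathlength * sp$molar_mass,
    stop("unknown channel: ", channel))
}

# Raw normalized Lamm solution (uniform initial concentration 1) for one
# species on the cell geometry, evaluated at the scan times.
lamm_profiles <- function(s, D, omega, scan_times, geometry,
                          n_cells = 200, dt_max = NULL) {
  stopifnot(s > 0, D >= 0, omega > 0, all(diff(scan_times) >= 0))
  h <- (geometry$base - geometry$meniscus) / n_cells
  v_max <- s * omega^2 * geometry$base
  # Courant-limited default step; Crank-Nicolson is unconditionally stable
  # but large advective steps ring, so cap the cell Courant number at ~0.4.
  if (is.null(dt_max)) dt_max <- max(1, min(30, 0.4 * h / v_max))
  if (dt_max * v_max / h > 2)
    stop("time step violates the advective stability margin ",
         "(Courant number > 2); refine dt_max or the mesh")
  radius <- geometry$meniscus + (seq_len(n_cells) - 0.5) * h
  sig <- lamm_solve_cpp(geometry$meniscus, geometry$base, n_cells,
                        s, D, omega, as.numeric(scan_times), dt_max)
  list(radius = radius, conc = sig)
}

#' Simulate a sedimentation velocity experiment
#'
#' Solves the Lamm transport equation for each species on a sector-shaped
#' cell with zero-flux ends (conservative finite-volume discretization,
#' Crank-Nicolson stepping), converts concentrations to the optical signal
#' of the requested channel, sums species and adds i.i.d. Gaussian noise.
#'
#' @param species List of [species_hydro()] objects; each must carry
#'   Svedberg-consistent `s` and `D` (see [sD_from_M()]) and a
#'   `loading_concentration` in mol/L (plus `extinction_280` for the
#'   absorbance channel).
#' @param cond A [solution_conditions()] object (recorded for provenance).
#' @param rpm Rotor speed, revolutions per minute.
#' @param scan_times Scan times in seconds (ascending).
#' @param geometry A [cell_geometry()] object.
#' @param noise_sigma Standard deviation of added Gaussian noise, signal
#'   units.
#' @param seed Integer seed for reproducible noise; `NULL` leaves the RNG
#'   state alone.
#' @param channel `"absorbance280"` or `"interference"`.
#' @param n_cells Number of radial finite-volume cells.
#' @param dt_max Maximum solver time step, s (default: Courant-limited).
#' @param fringe_coef Interference signal per mg/ml per cm.
#' @return An object of class `sv_scan_set`: radius grid, scan times, a
#'   scans x radii signal matrix, channel, geometry and metadata.
#' @export
simulate_sv <- function(species, cond, rpm, scan_times, geometry,
                        noise_sigma = 0.006, seed = NULL,
                        channel = c("interference", "absorbance280"),
                        n_cells = 200, dt_max = NULL,
                        fringe_coef = .default_fringe_coef) {
  channel <- match.arg(channel)
  if (inherits(species, "species_hydro")) species <- list(species)
  omega <- rpm_to_omega(rpm)
  if (!is.null(seed)) set.seed(seed)

  signal <- NULL
  radius <- NULL
  for (sp in species) {
    stopifnot(!is.na(sp$s), !is.na(sp$D), !is.na(sp$loading_concentration))
    lp <- lamm_profiles(sp$s, sp$D, omega, scan_times, geometry,
                        n_cells = n_cells, dt_max = dt_max)
    coef <- signal_coef(sp, channel, geometry$pathlength, fringe_coef)
    contrib <- lp$conc * (coef * sp$loading_concentration)
    signal <- if (is.null(signal)) contrib else signal + contrib
    radius <- lp$radius
  }
  if (noise_sigma > 0)
    signal <- signal + matrix(rnorm(length(signal), sd = noise_sigma),
                              nrow = nrow(signal))
  structure(list(radius = radius, scan_times = as.numeric(scan_times),
                 signal = signal, channel = channel, rpm = rpm,
                 omega = omega, geometry = geometry, cond = cond,
                 noise_sigma = noise_sigma, species = species),
            class = "sv_scan_set")
}

#' @export
print.sv_scan_set <- function(x, ...) {
  cat(sprintf("sv_scan_set: %d scans x %d radii, %s channel, %.0f rpm, t = %.0f..%.0f s\n",
              nrow(x$signal), ncol(x$signal), x$channel, x$rpm,
              min(x$scan_times), max(x$scan_times)))
  invisible(x)
}

# Total signal-weighted mass in the cell, per scan: integral of c r dr
# (proportional to sector mass). Used for conservation checks.
cell_mass_integral <- function(scans) {
  h <- diff(scans$radius[1:2])
  as.numeric(scans$signal %*% (scans$radius * h))
}
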