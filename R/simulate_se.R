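#' Simulate multi-speed sedimentation equilibrium profiles
#'
#' At sedimentation equilibrium an ideal single species forms the
#' exponential gradient
#' \deqn{c(r) = c(r0) \exp[\sigma (r^2 - r0^2)/2],
#'   \quad \sigma = M (1-\bar\nu\rho)\omega^2 / (R T)}
#' The amplitude is set so that the sector-integrated mass equals the
#' loading concentration (mass conservation in a closed cell). One profile
#' is produced for every (speed, loading) combination.
#'
#' @param M Molar mass of the species, g/mol.
#' @param vbar Partial specific volume, ml/g.
#' @param cond A [solution_conditions()] object.
#' @param rpms Vector of rotor speeds, rpm.
#' @param loadings Vector of loading concentrations, mol/L.
#' @param geometry A [cell_geometry()] object; equilibrium experiments use
#'   short solution columns (default 6.9-7.2 cm).
#' @param noise_sigma Gaussian noise standard deviation, signal units.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param channel `"interference"` or `"absorbance280"`.
#' @param extinction_280 Molar extinction (needed for absorbance channel).
#' @param n_points Radial points per profile.
#' @param fringe_coef Interference signal per mg/ml per cm.
#' @return An object of class `se_profile_set`: a list of profiles, each
#'   with rpm, omega, loading, radius, signal and the reference radius
#'   (the meniscus).
#' @export
simulate_se <- function(M, vbar, cond, rpms, loadings,
                        geometry = cell_geometry(6.9, 7.2),
                        noise_sigma = 0.005, seed = NULL,
                        channel = c("interference", "absorbance280"),
                        extinction_280 = NA_real_, n_points = 80,
                        fringe_coef = .default_fringe_coef) {
  channel <- match.arg(channel)
  stopifnot(M > 0, all(rpms > 0), all(loadings > 0))
  if (!is.null(seed)) set.seed(seed)
  r <- seq(geometry$meniscus, geometry$base, length.out = n_points)
  coef <- switch(channel,
    absorbance280 = extinction_280 * geometry$pathlength,
    interference = fringe_coef * geometry$pathlength * M)
  if (!is.finite(coef)) stop("extinction_280 required for absorbance channel")

  profiles <- list()
  for (rpm in rpms) {
    omega <- rpm_to_omega(rpm)
    sigma <- M * buoyancy(vbar, cond) * omega^2 /
      (.const$R_erg * cond$temperature)
    for (c0 in loadings) {
      # amplitude from sector mass conservation:
      # mean of K exp(sigma r^2/2) weighted by r equals c0
      rm2 <- geometry$meniscus^2; rb2 <- geometry$base^2
      if (abs(sigma) < 1e-12) {
        K <- c0
        conc <- rep(K, n_points)
      } else {
        denom <- (exp(sigma * rb2 / 2) - exp(sigma * rm2 / 2)) / sigma
        K <- c0 * (rb2 - rm2) / (2 * denom)
        conc <- K * exp(sigma * r^2 / 2)
      }
      signal <- conc * coef
      if (noise_sigma > 0) signal <- signal + rnorm(n_points, sd = noise_sigma)
      profiles[[length(profiles) + 1]] <-
        list(rpm = rpm, omega = omega, loading = c0, radius = r,
             signal = signal, reference_radius = geometry$meniscus)
    }
  }
  structure(list(profiles = profiles, geometry = geometry, cond = cond,
                 vbar = vbar, channel = channel, noise_sigma = noise_sigma,
                 M_true = M),
            class = "se_profile_set")
}

#' @export
print.se_profile_set <- function(x, ...) {
  cat(sprintf("se_profile_set: %d profiles (%s channel)\n",
              length(x$profiles), x$channel))
  invisible(x)
}
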