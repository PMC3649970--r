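#' Describe a co-sedimentation binding experiment
#'
#' Pairs the C(S) distribution of a protein-peptide mixture with that of a
#' protein-only control recorded at matched loading concentration,
#' pathlength and channel, together with the concentrations and the
#' peptide extinction coefficient needed to convert the excess integrated
#' absorbance of the fast boundary into a bound-peptide fraction.
#'
#' @param csd_mixture `cs_distribution` of the equimolar mixture
#'   (absorbance channel).
#' @param csd_protein_only `cs_distribution` of the protein-only control.
#' @param Lt Total peptide concentration, mol/L.
#' @param Pt Total protein binding sites (monomer-equivalent), mol/L.
#' @param epsilon_L Peptide molar extinction at 280 nm, 1/(M cm).
#' @param pathlength Optical pathlength, cm.
#' @param peak_window s-window (Svedberg) that isolates the fast protein
#'   boundary; default 2-4 S around the ~3 S dimer.
#' @return An object of class `binding_experiment`.
#' @export
binding_experiment <- function(csd_mixture, csd_protein_only, Lt, Pt,
                               epsilon_L = 11400, pathlength = 0.3,
                               peak_window = c(2, 4)) {
  stopifnot(inherits(csd_mixture, "cs_distribution"),
            inherits(csd_protein_only, "cs_distribution"),
            Lt > 0, Pt > 0, epsilon_L > 0, pathlength > 0,
            length(peak_window) == 2, peak_window[2] > peak_window[1])
  structure(list(csd_mixture = csd_mixture,
                 csd_protein_only = csd_protein_only,
                 Lt = Lt, Pt = Pt, epsilon_L = epsilon_L,
                 pathlength = pathlength, peak_window = peak_window),
            class = "binding_experiment")
}

#' Fraction of peptide bound from integrated C(S) absorbance
#'
#' theta = \[A(mixture peak) - A(protein-only peak)\] / (eps_L l Lt):
#' the excess integrated absorbance of the fast boundary over the
#' protein-only control, expressed as a fraction of the absorbance the
#' total peptide would contribute if fully co-sedimenting. Values are
#' clipped to \[0, 1\]; clipping by more than 2% triggers a warning, and a
#' strongly negative raw value signals a control mismatch.
#'
#' @param exp A [binding_experiment()].
#' @return theta in \[0, 1\], with the raw (unclipped) value as attribute
#'   `"raw"`.
#' @export
bound_fraction <- function(exp) {
  stopifnot(inherits(exp, "binding_experiment"))
  w <- exp$peak_window
  a_mix <- integrate_peak(exp$csd_mixture, w[1], w[2])
  a_ctl <- integrate_peak(exp$csd_protein_only, w[1], w[2])
  denom <- exp$epsilon_L * exp$pathlength * exp$Lt
  raw <- (a_mix - a_ctl) / denom
  if (raw < -0.05)
    warning(sprintf("raw bound fraction %.3f well below 0: mixture/control mismatch?",
                    raw))
  theta <- min(max(raw, 0), 1)
  if (abs(theta - raw) > 0.02)
    warning(sprintf("bound fraction clipped from %.3f to %.3f", raw, theta))
  attr(theta, "raw") <- raw
  theta
}

#' Association constant from the general mass-action expression
#'
#' For P + L = PL with theta = \[PL\]/Lt at total concentrations Pt and Lt:
#' K_a = theta / \[(1 - theta)(Pt - theta Lt)\].
#'
#' @param theta Fraction of ligand bound, in \[0, 1).
#' @param Lt Total ligand, mol/L.
#' @param Pt Total binding sites, mol/L.
#' @return Association constant, 1/M.
#' @export
ka_general <- function(theta, Lt, Pt) {
  stopifnot(theta >= 0, theta < 1, Lt > 0, Pt > 0)
  free_sites <- Pt - theta * Lt
  if (free_sites <= 0)
    stop("theta*Lt >= Pt: super-stoichiometric binding (model violation)")
  theta / ((1 - theta) * free_sites)
}

#' Association constant for an equimolar mixture
#'
#' The equimolar (Lt = Pt) reduction of [ka_general()]:
#' K_a = theta / \[(1 - theta)^2 Lt\]. Diverges as theta approaches 1;
#' values beyond the saturation cap are evaluated at the cap with a
#' warning (the assay carries no information there).
#'
#' @inheritParams ka_general
#' @param theta_cap Saturation cap on theta.
#' @return Association constant, 1/M.
#' @export
ka_equimolar <- function(theta, Lt, theta_cap = 1 - 1e-6) {
  stopifnot(theta >= 0, theta <= 1, Lt > 0)
  if (theta > theta_cap) {
    warning("theta at saturation; K_a evaluated at the cap is a lower bound")
    theta <- theta_cap
  }
  theta / ((1 - theta)^2 * Lt)
}

#' Quantify a binding experiment: theta and K_a
#'
#' Composes [bound_fraction()] with the mass-action expressions: the
#' equimolar form when Lt = Pt, the general form otherwise. A first-order
#' uncertainty is propagated from the two C(S) fit rmsd values (a rough
#' scale, not a confidence interval).
#'
#' @param exp A [binding_experiment()].
#' @return An object of class `binding_result`: `theta`, `Ka` (1/M), `Kd`
#'   (M), `theta_sd`, `Ka_sd`, and a `saturated` flag.
#' @export
quantify_binding <- function(exp) {
  theta <- bound_fraction(exp)
  raw <- attr(theta, "raw")
  theta <- as.numeric(theta)
  equimolar <- abs(exp$Lt - exp$Pt) < 1e-12 * exp$Lt
  saturated <- theta > 1 - 1e-6
  Ka <- if (theta >= 1) {
    warning("theta at saturation; K_a is a lower bound")
    ka_equimolar(1, exp$Lt)
  } else if (equimolar) ka_equimolar(theta, exp$Lt)
  else ka_general(theta, exp$Lt, exp$Pt)

  # first-order error propagation from the C(S) fit residuals
  denom <- exp$epsilon_L * exp$pathlength * exp$Lt
  sd_int <- sqrt(exp$csd_mixture$fit_rmsd^2 + exp$csd_protein_only$fit_rmsd^2)
  theta_sd <- sd_int / denom
  th <- min(theta, 1 - 1e-6)
  dka_dtheta <- if (equimolar) (1 + th) / ((1 - th)^3 * exp$Lt)
  else {
    h <- 1e-6
    (ka_general(min(th + h, 1 - 1e-9), exp$Lt, exp$Pt) -
       ka_general(max(th - h, 0), exp$Lt, exp$Pt)) / (2 * h)
  }
  structure(list(theta = theta, theta_raw = raw, Ka = Ka, Kd = 1 / Ka,
                 theta_sd = theta_sd, Ka_sd = abs(dka_dtheta) * theta_sd,
                 saturated = saturated, equimolar = equimolar),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("binding_result: theta = %.3f +/- %.3f, Ka = %.3g +/- %.2g 1/M (Kd = %.3g M)%s\n",
              x$theta, x$theta_sd, x$Ka, x$Ka_sd, x$Kd,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}
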