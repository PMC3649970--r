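# Dictionary of normalized Lamm solutions, one column per grid s-value,
# with the diffusion coefficient tied to s through a shared frictional
# ratio (the standard c(s) scaling).  Cached because the dictionary
# depends only on grid, shape, geometry, rotor speed and scan times.
.cs_cache <- new.env(parent = emptyenv())

cs_dictionary <- function(s_grid_sec, ff0, vbar, cond, omega, scan_times,
                          geometry, radius, n_cells) {
  key <- paste(signif(c(s_grid_sec, ff0, vbar, cond$temperature,
                        cond$density, cond$viscosity, omega, scan_times,
                        geometry$meniscus, geometry$base, n_cells), 10),
               collapse = ",")
  hit <- .cs_cache[[key]]
  if (!is.null(hit)) return(hit)
  n_obs <- length(scan_times) * length(radius)
  B <- matrix(0, n_obs, length(s_grid_sec))
  for (j in seq_along(s_grid_sec)) {
    D <- diffusion_from_s(s_grid_sec[j], ff0, vbar, cond)
    lp <- lamm_profiles(s_grid_sec[j], D, omega, scan_times, geometry,
                        n_cells = n_cells)
    sig <- lp$conc
    if (length(lp$radius) != length(radius) ||
        max(abs(lp$radius - radius)) > 1e-9) {
      sig <- t(apply(sig, 1, function(row)
        approx(lp$radius, row, xout = radius, rule = 2)$y))
    }
    B[, j] <- as.vector(t(sig))
  }
  if (length(.cs_cache) > 20) rm(list = ls(.cs_cache), envir = .cs_cache)
  .cs_cache[[key]] <- B
  B
}

# Remove systematic offsets by algebraic projection applied identically to
# the data and every dictionary column: radius-invariant (per-scan) offsets
# correspond to row means of the scan matrix, time-invariant (per-radius)
# offsets to column means across scans.
project_offsets <- function(mat, ti = FALSE, ri = FALSE) {
  if (ri) mat <- mat - rowMeans(mat)
  if (ti) mat <- sweep(mat, 2, colMeans(mat))
  mat
}

nnls_solve <- function(B, y, lambda, Dmat) {
  if (lambda > 0) {
    Ba <- rbind(B, sqrt(lambda) * Dmat)
    ya <- c(y, rep(0, nrow(Dmat)))
  } else {
    Ba <- B; ya <- y
  }
  w <- pracma::lsqnonneg(Ba, ya)$x
  res <- y - B %*% w
  list(w = w, rmsd = sqrt(mean(res^2)))
}

#' Fit a continuous sedimentation coefficient distribution C(S)
#'
#' Inverts a sedimentation velocity scan set into a non-negative
#' distribution c(s) over a grid of sedimentation coefficients, with the
#' diffusion coefficient of each grid species tied to s through a shared
#' frictional ratio. The fit is Tikhonov-regularized (second-difference
#' smoothness penalty) with the strength chosen by the discrepancy
#' principle: the weakest regularization whose residual rmsd reaches the
#' noise estimate. Systematic time-invariant (per-radius) and
#' radius-invariant (per-scan) offsets can be removed by algebraic
#' projection, as required for interference optics.
#'
#' @param scans An `sv_scan_set`.
#' @param s_grid Grid of sedimentation coefficients in Svedberg (default
#'   0.2-10 S in 0.1 S steps, covering free peptide through the dimer).
#' @param ff0 Shared frictional ratio: a number to fix it, or `"fit"` to
#'   optimize it in an outer 1-D search over \[1, 4\].
#' @param vbar Partial specific volume, ml/g.
#' @param cond A [solution_conditions()] object.
#' @param target_rmsd Residual rmsd targeted by the discrepancy principle;
#'   defaults to the scan set's noise level (known for synthetic data,
#'   otherwise estimated from second differences along radius).
#' @param lambda Fixed regularization strength; overrides the discrepancy
#'   search when supplied.
#' @param ti_noise,ri_noise Remove time-invariant / radius-invariant
#'   offsets. Defaults: both for interference data, neither for absorbance.
#' @param n_cells Radial cells for the dictionary solutions.
#' @return An object of class `cs_distribution`: `s_grid` (S), `c`
#'   (signal per S, non-negative), `ff0`, `lambda`, `fit_rmsd`,
#'   `total_signal` and the window-integral helpers work on it.
#' @seealso [integrate_peak()], [weight_average_s()]
#' @export
fit_cs <- function(scans, s_grid = seq(0.2, 10, by = 0.1), ff0 = "fit",
                   vbar, cond, target_rmsd = NULL, lambda = NULL,
                   ti_noise = NULL, ri_noise = NULL, n_cells = 200) {
  stopifnot(inherits(scans, "sv_scan_set"))
  interference <- scans$channel == "interference"
  if (is.null(ti_noise)) ti_noise <- interference
  if (is.null(ri_noise)) ri_noise <- interference
  s_sec <- s_grid * .const$svedberg

  Yp <- project_offsets(scans$signal, ti = ti_noise, ri = ri_noise)
  y <- as.vector(t(Yp))
  nsc <- nrow(scans$signal)
  project_cols <- function(B) {
    if (!ti_noise && !ri_noise) return(B)
    apply(B, 2, function(col) {
      m <- matrix(col, nrow = nsc, byrow = TRUE)
      as.vector(t(project_offsets(m, ti = ti_noise, ri = ri_noise)))
    })
  }

  if (is.null(target_rmsd)) {
    target_rmsd <- if (!is.null(scans$noise_sigma) &&
                       is.finite(scans$noise_sigma))
      scans$noise_sigma
    else {
      # robust high-frequency noise estimate from second differences along
      # radius (median-based, so steep boundary regions do not inflate it)
      d2 <- abs(as.vector(t(diff(t(scans$signal), differences = 2))))
      stats::median(d2) * 1.4826 / sqrt(6)
    }
  }

  nsg <- length(s_sec)
  Dmat <- diff(diag(nsg), differences = 2)
  # scale the penalty so lambda is comparable to the data block
  Dmat <- Dmat * sqrt(length(y) / nsg)

  dict <- function(ff) project_cols(
    cs_dictionary(s_sec, ff, vbar, cond, scans$omega, scans$scan_times,
                  scans$geometry, scans$radius, n_cells))

  if (identical(ff0, "fit")) {
    obj <- function(ff) nnls_solve(dict(ff), y, 1e-4, Dmat)$rmsd
    ff0 <- optimize(obj, c(1.05, 4), tol = 0.01)$minimum
  }
  B <- dict(ff0)

  if (is.null(lambda)) {
    # discrepancy principle: smallest lambda with rmsd >= target
    f <- function(l) nnls_solve(B, y, l, Dmat)$rmsd - target_rmsd
    lo <- 0; hi <- NULL
    base <- f(0)
    if (base >= 0) {
      lambda <- 0
    } else {
      l <- 1e-6
      while (f(l) < 0 && l < 1e6) l <- l * 10
      hi <- l; lo <- l / 10
      for (i in 1:25) {
        mid <- sqrt(lo * hi)
        if (f(mid) < 0) lo <- mid else hi <- mid
        if (hi / lo < 1.05) break
      }
      lambda <- sqrt(lo * hi)
    }
  }
  sol <- nnls_solve(B, y, lambda, Dmat)
  if (all(sol$w == 0))
    warning("all-zero C(S) solution: over-regularized or empty signal")

  ds <- diff(s_grid)
  ds <- c(ds[1], (ds[-length(ds)] + ds[-1]) / 2, ds[length(ds)])
  structure(list(s_grid = s_grid, c = sol$w / ds, amplitudes = sol$w,
                 ff0 = ff0, lambda = lambda, fit_rmsd = sol$rmsd,
                 target_rmsd = target_rmsd,
                 total_signal = sum(sol$w), channel = scans$channel),
            class = "cs_distribution")
}

#' @export
print.cs_distribution <- function(x, ...) {
  cat(sprintf("cs_distribution: %d grid points (%.1f-%.1f S), f/f0 = %.2f, rmsd = %.4g, total = %.4g\n",
              length(x$s_grid), min(x$s_grid), max(x$s_grid), x$ff0,
              x$fit_rmsd, x$total_signal))
  invisible(x)
}

#' Integrate a C(S) peak over an s window
#'
#' Trapezoidal integral of c(s) ds over \[s_lo, s_hi\]; this is the
#' integrated signal (loading signal) of the species sedimenting in the
#' window.
#'
#' @param csd A `cs_distribution`.
#' @param s_lo,s_hi Window bounds in Svedberg.
#' @return Integrated signal in the scan set's signal units.
#' @export
integrate_peak <- function(csd, s_lo, s_hi) {
  stopifnot(inherits(csd, "cs_distribution"), s_hi >= s_lo)
  idx <- which(csd$s_grid >= s_lo & csd$s_grid <= s_hi)
  if (length(idx) < 2) {
    warning("integration window contains fewer than 2 grid points; returning 0")
    return(0)
  }
  s <- csd$s_grid[idx]; c <- csd$c[idx]
  sum(diff(s) * (head(c, -1) + tail(c, -1)) / 2)
}

#' Signal-weighted average sedimentation coefficient of a window
#'
#' @inheritParams integrate_peak
#' @return Weight-average s in Svedberg (NA for an empty window).
#' @export
weight_average_s <- function(csd, s_lo = min(csd$s_grid),
                             s_hi = max(csd$s_grid)) {
  idx <- which(csd$s_grid >= s_lo & csd$s_grid <= s_hi)
  w <- csd$amplitudes[idx]
  if (sum(w) <= 0) return(NA_real_)
  sum(w * csd$s_grid[idx]) / sum(w)
}

#' Discrete-species fit of sedimentation velocity data
#'
#' Nonlinear least squares of the scan set against a sum of a small number
#' of independently sedimenting ideal species. Each species is
#' parameterized by (s, f/f0); its diffusion coefficient follows from the
#' Svedberg-consistent relations and its loading signal enters linearly
#' (solved by non-negative least squares inside the outer optimization).
#' Reported masses are Svedberg masses from the fitted (s, D) pairs.
#'
#' @param scans An `sv_scan_set`.
#' @param n_species Number of species to fit.
#' @param vbar Partial specific volume, ml/g.
#' @param cond A [solution_conditions()] object.
#' @param init_s Initial s guesses, Svedberg (defaults spread over 1-4 S).
#' @param init_ff0 Initial frictional ratio guesses.
#' @param n_cells Radial cells for the forward model.
#' @return An object of class `discrete_fit`: a per-species data.frame
#'   (`s` in S, `D`, `M`, `signal`), `rmsd` and a `converged` flag.
#' @export
fit_discrete <- function(scans, n_species = 1, vbar, cond,
                         init_s = NULL, init_ff0 = NULL, n_cells = 200) {
  stopifnot(inherits(scans, "sv_scan_set"), n_species >= 1)
  if (nrow(scans$signal) < 2)
    stop("need at least 2 scans spanning boundary movement")
  if (is.null(init_s))
    init_s <- seq(1, 4, length.out = n_species)
  if (is.null(init_ff0)) init_ff0 <- rep(1.5, n_species)
  y <- as.vector(t(scans$signal))

  basis_for <- function(s_sec, ff0) {
    sapply(seq_along(s_sec), function(k) {
      D <- sD_from_M(mass_from_s(s_sec[k], ff0[k], vbar, cond),
                     ff0[k], vbar, cond)$D
      lp <- lamm_profiles(s_sec[k], D, scans$omega, scans$scan_times,
                          scans$geometry, n_cells = n_cells)
      sig <- lp$conc
      if (length(lp$radius) != length(scans$radius) ||
          max(abs(lp$radius - scans$radius)) > 1e-9)
        sig <- t(apply(sig, 1, function(row)
          approx(lp$radius, row, xout = scans$radius, rule = 2)$y))
      as.vector(t(sig))
    })
  }
  unpack <- function(p) {
    list(s = exp(p[seq_len(n_species)]),
         ff0 = 1 + exp(p[n_species + seq_len(n_species)]))
  }
  ssr <- function(p) {
    q <- unpack(p)
    if (any(q$s <= 0) || any(q$ff0 > 10)) return(1e10)
    B <- basis_for(q$s * .const$svedberg, q$ff0)
    w <- pracma::lsqnonneg(B, y)$x
    sum((y - B %*% w)^2)
  }
  p0 <- c(log(init_s), log(pmax(init_ff0 - 1, 0.05)))
  opt <- optim(p0, ssr, method = "Nelder-Mead",
               control = list(maxit = 1000, reltol = 1e-12))
  # polish: restart the simplex at the optimum, then a gradient step
  opt <- optim(opt$par, ssr, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-14))
  opt2 <- tryCatch(optim(opt$par, ssr, method = "BFGS",
                         control = list(maxit = 100, reltol = 1e-14)),
                   error = function(e) opt)
  if (opt2$value < opt$value) opt <- opt2
  q <- unpack(opt$par)
  ord <- order(q$s)
  s_sec <- q$s[ord] * .const$svedberg
  ff0 <- q$ff0[ord]
  B <- basis_for(s_sec, ff0)
  w <- pracma::lsqnonneg(B, y)$x
  rmsd <- sqrt(mean((y - B %*% w)^2))
  D <- sapply(seq_along(s_sec), function(k)
    sD_from_M(mass_from_s(s_sec[k], ff0[k], vbar, cond), ff0[k], vbar, cond)$D)
  species <- data.frame(
    s = s_sec / .const$svedberg, D = D, ff0 = ff0,
    M = mapply(function(sv, Dv) svedberg_mass(sv, Dv, vbar, cond), s_sec, D),
    signal = w)
  structure(list(species = species, rmsd = rmsd,
                 converged = opt$convergence == 0),
            class = "discrete_fit")
}

#' @export
print.discrete_fit <- function(x, ...) {
  cat(sprintf("discrete_fit: %d species, rmsd = %.4g%s\n",
              nrow(x$species), x$rmsd,
              if (x$converged) "" else " (NOT converged)"))
  print(x$species, row.names = FALSE)
  invisible(x)
}
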