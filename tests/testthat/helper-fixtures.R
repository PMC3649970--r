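# Shared fixtures: the Gag-NtD dimer / Env leader peptide study system
# and small synthetic structures, all built in code.

pfv_cond <- function() buffer_tris150()

# The obligate Gag-NtD dimer: 2 x 22,713 g/mol, vbar 0.731 ml/g,
# elongated coiled-coil shape (f/f0 1.48), eps280 19,200 per monomer.
pfv_dimer <- function(loading = 37.5e-6, cond = pfv_cond()) {
  sd <- sD_from_M(45426, 1.48, 0.731, cond)
  species_hydro(45426, 0.731, s = sd$s, D = sd$D, ff0 = 1.48,
                extinction_280 = 2 * 19200,
                loading_concentration = loading)
}

# Env leader peptide: ~2.2 kDa 20-mer, strongly absorbing (eps 11,400).
env_peptide <- function() {
  species_hydro(2249, 0.73, ff0 = 1.15, extinction_280 = 11400)
}

# protein species as passed to simulate_binding_mixture (extinction per
# binding site = per monomer)
pfv_binding_protein <- function(cond = pfv_cond()) {
  sd <- sD_from_M(45426, 1.48, 0.731, cond)
  species_hydro(45426, 0.731, s = sd$s, D = sd$D, ff0 = 1.48,
                extinction_280 = 19200, loading_concentration = NA)
}

sv_times <- function() seq(900, 14400, by = 900)

# canonical binding-assay conditions: equimolar 75 uM in a 3 mm cell
binding_conditions <- function() {
  list(Lt = 75e-6, Pt = 75e-6, eps_L = 11400, pathlength = 0.3)
}

run_binding_pipeline <- function(Ka, seed, noise = 0.006,
                                 cond = pfv_cond()) {
  bc <- binding_conditions()
  prot <- pfv_binding_protein(cond)
  pep <- env_peptide()
  mix <- simulate_binding_mixture(prot, pep, Ka = Ka, Lt = bc$Lt,
                                  Pt = bc$Pt, cond,
                                  scan_times = sv_times(),
                                  noise_sigma = noise, seed = seed)
  ctl <- simulate_binding_mixture(prot, pep, Ka = 0, Lt = 0, Pt = bc$Pt,
                                  cond, scan_times = sv_times(),
                                  noise_sigma = noise, seed = seed + 1000)
  cm <- fit_cs(mix, ff0 = 1.48, vbar = 0.731, cond = cond)
  cc <- fit_cs(ctl, ff0 = 1.48, vbar = 0.731, cond = cond)
  quantify_binding(binding_experiment(cm, cc, Lt = bc$Lt, Pt = bc$Pt,
                                      epsilon_L = bc$eps_L,
                                      pathlength = bc$pathlength))
}

# independent oracle for the equimolar bound fraction: bisection on
# Ka * Lt * (1 - theta)^2 = theta
theta_bisect <- function(Ka, Lt, tol = 1e-12) {
  f <- function(th) Ka * Lt * (1 - th)^2 - th
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
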