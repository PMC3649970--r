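cond <- pfv_cond()
geo <- cell_geometry()

test_that("Lamm solution starts from the uniform loading profile", {
  sp <- pfv_dimer()
  scans <- simulate_sv(sp, cond, 1000, c(0), geo, noise_sigma = 0,
                       channel = "interference")
  expected <- signif(3.3 * 1.2 * 45426 * 37.5e-6, 10)
  expect_equal(unname(scans$signal[1, ]),
               rep(expected, length(scans$radius)), tolerance = 1e-9)
})

test_that("Lamm solver conserves sector mass and stays non-negative", {
  sp <- pfv_dimer()
  scans <- simulate_sv(sp, cond, 50000, sv_times(), geo, noise_sigma = 0,
                       channel = "interference")
  mi <- foamygag:::cell_mass_integral(scans)
  expect_lt(max(abs(mi / mi[1] - 1)), 1e-3)
  expect_true(all(scans$signal >= -1e-12))
})

test_that("mesh refinement is converged below the instrument noise floor", {
  sp <- pfv_dimer()
  sim <- function(nc) simulate_sv(sp, cond, 50000, sv_times(), geo,
                                  noise_sigma = 0,
                                  channel = "interference", n_cells = nc)
  s4 <- sim(400); s8 <- sim(800)
  fine <- t(apply(s8$signal, 1, function(row)
    approx(s8$radius, row, xout = s4$radius)$y))
  expect_lt(max(abs(fine - s4$signal)), 0.006)
})

test_that("simulators are reproducible bit-for-bit under a fixed seed", {
  sp <- pfv_dimer()
  a <- simulate_sv(sp, cond, 50000, sv_times()[1:4], geo, seed = 99)
  b <- simulate_sv(sp, cond, 50000, sv_times()[1:4], geo, seed = 99)
  expect_identical(a$signal, b$signal)
  ti1 <- simulate_itc(seed = 3)
  ti2 <- simulate_itc(seed = 3)
  expect_identical(ti1$heats, ti2$heats)
  se1 <- simulate_se(45426, 0.731, cond, 14000, 50e-6, seed = 5)
  se2 <- simulate_se(45426, 0.731, cond, 14000, 50e-6, seed = 5)
  expect_identical(se1$profiles[[1]]$signal, se2$profiles[[1]]$signal)
})

test_that("an over-coarse explicit time step is refused, not integrated", {
  sp <- pfv_dimer()
  expect_error(
    simulate_sv(sp, cond, 50000, c(600, 1200), geo, noise_sigma = 0,
                n_cells = 50, dt_max = 5000),
    "stability")
})

test_that("equilibrium gradients follow the closed-form exponential exactly", {
  se <- simulate_se(45426, 0.731, cond, rpms = 14000, loadings = 50e-6,
                    noise_sigma = 0)
  p <- se$profiles[[1]]
  sigma <- 45426 * (1 - 0.731 * cond$density) * p$omega^2 /
    (8.31446e7 * cond$temperature)
  ratio <- p$signal[length(p$signal)] / p$signal[1]
  expect_equal(ratio,
               exp(sigma * (max(p$radius)^2 - min(p$radius)^2) / 2),
               tolerance = 1e-9)
})

test_that("a neutrally buoyant species gives a flat equilibrium profile", {
  cond1 <- solution_conditions(293.15, 1.0, 1.002e-2)
  se <- simulate_se(45426, 1.0, cond1, rpms = 14000, loadings = 50e-6,
                    noise_sigma = 0)
  expect_equal(diff(range(se$profiles[[1]]$signal)), 0, tolerance = 1e-9)
})

test_that("binding mixtures partition peptide by the mass-action quadratic", {
  bc <- binding_conditions()
  for (Ka in c(1e3, 2e4, 1.3e5, 1e7)) {
    th <- theta_from_ka(Ka, bc$Lt, bc$Pt)
    expect_equal(th, theta_bisect(Ka, bc$Lt), tolerance = 1e-8)
  }
  # the assay conditions reproduce the known operating points
  expect_equal(theta_from_ka(1.3e5, 75e-6), 0.727, tolerance = 1e-3)
  expect_equal(theta_from_ka(2.0e4, 75e-6), 0.451, tolerance = 1e-3)
})

test_that("at Ka = 0 the mixture's fast boundary equals the protein-only control", {
  prot <- pfv_binding_protein()
  pep <- env_peptide()
  times <- sv_times()[1:5]
  mix <- simulate_binding_mixture(prot, pep, Ka = 0, Lt = 75e-6, Pt = 75e-6,
                                  cond, scan_times = times, noise_sigma = 0)
  ctl <- simulate_binding_mixture(prot, pep, Ka = 0, Lt = 0, Pt = 75e-6,
                                  cond, scan_times = times, noise_sigma = 0)
  # subtract the free-peptide contribution: in the late plateau region the
  # slow peptide is still present, so compare the full signal minus a
  # peptide-only run instead
  pep_only <- simulate_sv(
    species_hydro(2249, 0.73,
                  s = sD_from_M(2249, 1.15, 0.73, cond)$s,
                  D = sD_from_M(2249, 1.15, 0.73, cond)$D,
                  extinction_280 = 11400, loading_concentration = 75e-6),
    cond, 50000, times, cell_geometry(pathlength = 0.3), noise_sigma = 0,
    channel = "absorbance280")
  expect_equal(mix$signal - pep_only$signal, ctl$signal, tolerance = 1e-8)
  expect_equal(attr(mix, "theta_true"), 0)
})

test_that("saturating binding adds exactly the peptide's absorbance to the load", {
  prot <- pfv_binding_protein()
  pep <- env_peptide()
  mix <- simulate_binding_mixture(prot, pep, Ka = 1e12, Lt = 75e-6,
                                  Pt = 75e-6, cond, scan_times = 0,
                                  noise_sigma = 0)
  ctl <- simulate_binding_mixture(prot, pep, Ka = 0, Lt = 0, Pt = 75e-6,
                                  cond, scan_times = 0, noise_sigma = 0)
  # at t = 0 both are uniform; the saturated mixture carries eps_L l Lt
  # more absorbance (0.257 AU at 11,400 1/(M cm), 0.3 cm, 75 uM); at
  # Ka = 1e12 the residual free fraction is 1/sqrt(Ka Lt) ~ 1e-4
  extra <- mean(mix$signal[1, ] - ctl$signal[1, ])
  expect_equal(extra, 11400 * 0.3 * 75e-6, tolerance = 1e-3)
  expect_equal(attr(mix, "theta_true"), 1, tolerance = 1e-3)
})

test_that("uninformative saturation warns", {
  prot <- pfv_binding_protein()
  expect_warning(
    simulate_binding_mixture(prot, env_peptide(), Ka = 1e20, Lt = 75e-6,
                             Pt = 75e-6, cond, scan_times = 0,
                             noise_sigma = 0),
    "uninformative")
})

test_that("ITC forward model: zero enthalpy means zero heats", {
  ti <- simulate_itc(dH = 0, noise_prop = 0, noise_add = 0)
  expect_equal(ti$heats, rep(0, 20))
})

test_that("ITC heats sum to the total binding enthalpy at saturation", {
  # drive far past equivalence with tight binding; the sum approaches
  # n Mt0 V0 dH up to the few-percent loss from perfusion dilution of the
  # cell contents before saturation
  V0 <- 0.2026; Mt0 <- 50e-6
  q <- itc_heats(1, 1e11, -8000, V0, Mt0, 1e-3, rep(1e-3, 20))
  total_expected <- 1 * Mt0 * (V0 / 1000) * -8000 * 1e6  # ucal
  expect_equal(sum(q), total_expected, tolerance = 0.03)
})
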