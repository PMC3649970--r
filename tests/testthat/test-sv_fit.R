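cond <- pfv_cond()
geo <- cell_geometry()

test_that("discrete fit self-inverts noise-free single-species data", {
  sp <- pfv_dimer()
  scans <- simulate_sv(sp, cond, 50000, sv_times(), geo, noise_sigma = 0,
                       channel = "interference")
  fit <- fit_discrete(scans, 1, vbar = 0.731, cond = cond,
                      init_s = 2.5, init_ff0 = 1.4)
  expect_true(fit$converged)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$species$s, sp$s / 1e-13, tolerance = 1e-4)
  expect_equal(fit$species$M, 45426, tolerance = 1e-3)
})

test_that("discrete fit recovers s within 1% and M within 3% at rmsd-range noise", {
  sp <- pfv_dimer()
  scans <- simulate_sv(sp, cond, 50000, sv_times(), geo,
                       noise_sigma = 0.006, seed = 21,
                       channel = "interference")
  fit <- fit_discrete(scans, 1, vbar = 0.731, cond = cond,
                      init_s = 2.5, init_ff0 = 1.4)
  expect_lt(abs(fit$species$s / (sp$s / 1e-13) - 1), 0.01)
  expect_lt(abs(fit$species$M / 45426 - 1), 0.03)
})

test_that("discrete fit separates two well-spaced species within 2%", {
  sd1 <- sD_from_M(8000, 1.2, 0.73, cond)
  slow <- species_hydro(8000, 0.73, s = sd1$s, D = sd1$D, ff0 = 1.2,
                        loading_concentration = 40e-6)
  fast <- pfv_dimer()
  scans <- simulate_sv(list(slow, fast), cond, 50000, sv_times(), geo,
                       noise_sigma = 0.004, seed = 31,
                       channel = "interference")
  fit <- fit_discrete(scans, 2, vbar = 0.731, cond = cond,
                      init_s = c(0.8, 2.6), init_ff0 = c(1.3, 1.4))
  expect_equal(fit$species$s[1], sd1$s / 1e-13, tolerance = 0.02)
  expect_equal(fit$species$s[2], fast$s / 1e-13, tolerance = 0.02)
})

test_that("C(S) of noise-free data concentrates on the true s", {
  sp <- pfv_dimer()
  scans <- simulate_sv(sp, cond, 50000, sv_times(), geo, noise_sigma = 0,
                       channel = "interference")
  csd <- fit_cs(scans, ff0 = 1.48, vbar = 0.731, cond = cond)
  s_true <- sp$s / 1e-13
  expect_lt(abs(weight_average_s(csd, 2, 4) - s_true), 0.1)
  near <- integrate_peak(csd, s_true - 0.3, s_true + 0.3)
  expect_gt(near / csd$total_signal, 0.95)
})

test_that("C(S) integral matches the plateau loading signal within 2%", {
  sp <- pfv_dimer()
  scans <- simulate_sv(sp, cond, 50000, sv_times(), geo,
                       noise_sigma = 0.006, seed = 41,
                       channel = "interference")
  csd <- fit_cs(scans, ff0 = 1.48, vbar = 0.731, cond = cond)
  loading_signal <- 3.3 * 1.2 * 45426 * 37.5e-6
  expect_lt(abs(csd$total_signal / loading_signal - 1), 0.02)
})

test_that("the 3 S peak of an absorbance run obeys Beer-Lambert", {
  # 75 uM monomer-equivalent at eps 19,200 over 0.3 cm: 0.432 AU
  prot <- pfv_binding_protein()
  ctl <- simulate_binding_mixture(prot, env_peptide(), Ka = 0, Lt = 0,
                                  Pt = 75e-6, cond,
                                  scan_times = sv_times(), noise_sigma = 0)
  csd <- fit_cs(ctl, ff0 = 1.48, vbar = 0.731, cond = cond)
  expect_equal(integrate_peak(csd, 2, 4), 19200 * 0.3 * 75e-6,
               tolerance = 0.02)
})

test_that("peak integration windows behave at the edges", {
  prot <- pfv_binding_protein()
  ctl <- simulate_binding_mixture(prot, env_peptide(), Ka = 0, Lt = 0,
                                  Pt = 75e-6, cond,
                                  scan_times = sv_times()[1:6],
                                  noise_sigma = 0)
  csd <- fit_cs(ctl, ff0 = 1.48, vbar = 0.731, cond = cond)
  whole <- integrate_peak(csd, min(csd$s_grid), max(csd$s_grid))
  expect_equal(whole, csd$total_signal, tolerance = 1e-6)
  expect_equal(integrate_peak(csd, 7, 10), 0, tolerance = 1e-9)
  expect_warning(out <- integrate_peak(csd, 10.5, 11), "fewer than 2")
  expect_equal(out, 0)
})

test_that("regularization path: rmsd non-decreasing, peak position stable", {
  sp <- pfv_dimer()
  scans <- simulate_sv(sp, cond, 50000, sv_times(), geo,
                       noise_sigma = 0.006, seed = 51,
                       channel = "interference")
  lambdas <- c(1e-3, 1e-2, 1e-1)
  fits <- lapply(lambdas, function(l)
    fit_cs(scans, ff0 = 1.48, vbar = 0.731, cond = cond, lambda = l))
  rmsds <- vapply(fits, `[[`, numeric(1), "fit_rmsd")
  expect_true(all(diff(rmsds) >= -1e-12))
  peaks <- vapply(fits, function(f) f$s_grid[which.max(f$c)], numeric(1))
  expect_lt(max(peaks) - min(peaks), 0.1 + 1e-9)
})

test_that("discrete and C(S) weight-average s agree within 1%", {
  sp <- pfv_dimer()
  scans <- simulate_sv(sp, cond, 50000, sv_times(), geo,
                       noise_sigma = 0.005, seed = 61,
                       channel = "interference")
  dfit <- fit_discrete(scans, 1, vbar = 0.731, cond = cond,
                       init_s = 2.5, init_ff0 = 1.4)
  csd <- fit_cs(scans, ff0 = 1.48, vbar = 0.731, cond = cond)
  expect_lt(abs(weight_average_s(csd, 2, 4) / dfit$species$s - 1), 0.01)
})

test_that("fitting the frictional ratio recovers the elongated dimer shape", {
  sp <- pfv_dimer()
  scans <- simulate_sv(sp, cond, 50000, sv_times(), geo,
                       noise_sigma = 0.004, seed = 71,
                       channel = "interference")
  csd <- fit_cs(scans, ff0 = "fit", vbar = 0.731, cond = cond)
  expect_lt(abs(csd$ff0 - 1.48), 0.1)
})
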