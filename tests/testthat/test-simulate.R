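# Synthetic data generator: determinism, degenerate cases, parameter
# recovery and unbiasedness of downstream estimates.

test_that("simulation is deterministic for a fixed seed", {
  spec <- sim_spec("r", "NS-1738", 20, c_true = 0.561, seed = 123)
  a <- simulate_cells(spec)
  b <- simulate_cells(spec)
  expect_identical(a, b)
  other <- simulate_cells(sim_spec("r", "NS-1738", 20, c_true = 0.561,
                                   seed = 124))
  expect_false(identical(a$p_modulated, other$p_modulated))
})

test_that("noise-free degenerate spec yields identical cells at the exact
          saturating value", {
  spec <- sim_spec("r", "NS-1738", 8, p_background_mean = 0.05,
                   p_background_sd = 0, p_constitutive_sd = 0,
                   c_true = 0.561, measurement_cv = 0, seed = 1)
  prof <- simulate_cells(spec)
  expect_equal(unique(prof$p_background), 0.05)
  expect_equal(prof$p_modulated,
               rep(saturating_state_function(0.05, 0.561, 2), 8),
               tolerance = 1e-12)
  expect_true(all(prof$protocol == "potentiation"))
})

test_that("constitutively active specs run the direct-activation protocol
          with the constitutive level as control", {
  spec <- sim_spec("mut", "NS-1738", 10, p_constitutive_mean = 0.25,
                   p_constitutive_sd = 0.05, c_true = 2.0, seed = 6)
  prof <- simulate_cells(spec)
  expect_true(all(prof$protocol == "direct_activation"))
  expect_equal(background_pa(prof), prof$p_constitutive)
  # inhibitor: modulated below control
  expect_true(all(modulation_percent(prof) < 100))
})

test_that("per-cell efficacy estimates recover the ground truth across the
          efficacy range", {
  for (c_true in c(0.1, 0.3, 0.56, 0.72, 1.0, 2.0)) {
    spec <- sim_spec("r", "NS-1738", 200, c_true = c_true,
                     measurement_cv = 0.05, seed = 1000 + round(100 * c_true))
    est <- efficacy_summary(simulate_cells(spec))$summary
    expect_lt(abs(est$c_mean - c_true) / c_true, 0.05)
  }
})

test_that("simulated study summaries feed the mutant cycle and estimated
          ddG is unbiased", {
  ctx <- energy_context()
  dg_wt <- -0.70; dg_mut <- 0.30
  reps <- 200
  est <- vapply(seq_len(reps), function(i) {
    wt <- sim_spec("wt", "NS-1738", 12, c_true =
                     efficacy_from_energy(dg_wt, 2, ctx), seed = 2 * i)
    mut <- sim_spec("mut", "NS-1738", 12, c_true =
                      efficacy_from_energy(dg_mut, 2, ctx),
                    seed = 2 * i + 1)
    s <- simulate_study(list(wt, mut), ctx = ctx)$summary
    ddg(s[s$receptor == "mut", ], s[s$receptor == "wt", ])$ddG
  }, numeric(1))
  expect_lt(abs(mean(est) - (dg_mut - dg_wt)), 0.05)
})

test_that("minimum-n study completes with wide intervals", {
  specs <- list(
    sim_spec("wt", "NS-1738", 2, c_true = 0.561, seed = 1),
    sim_spec("mut", "NS-1738", 2, c_true = 1.5, seed = 2)
  )
  s <- simulate_study(specs)$summary
  r <- ddg(s[s$receptor == "mut", ], s[s$receptor == "wt", ])
  expect_true(is.finite(r$se))
  expect_gt(r$ci_high - r$ci_low, 0)
})

test_that("amplitude simulation errors on degenerate anchors and respects
          zero-activation cells", {
  spec <- sim_spec("r", "NS-1738", 4, c_true = 0.5, seed = 3)
  expect_error(simulate_amplitudes(spec, full_anchor = -50,
                                   zero_anchor = -50), "degenerate")
  # near-zero probabilities sit at the zero anchor
  quiet <- sim_spec("r", "NS-1738", 4, p_background_mean = 0.006,
                    p_background_sd = 0, p_constitutive_mean = 0.001,
                    p_constitutive_sd = 0, c_true = 1,
                    measurement_cv = 0, seed = 3)
  amps <- simulate_amplitudes(quiet, full_anchor = -4000,
                              zero_anchor = -50)
  const <- amps$amplitude_nA[amps$condition == "constitutive"]
  expect_true(all(abs(const - (-50)) < abs(-4000 - (-50)) * 0.002))
})

test_that("preset specs mirror the bundled reference groups", {
  spec <- sim_preset("alpha1beta2gamma2L", "NS-1738", seed = 4)
  expect_equal(spec$n_cells, 25L)
  expect_equal(spec$N, 2L)
  # ground-truth efficacy implied by the reference group energy
  expect_equal(free_energy(spec$c_true, 2), -0.70, tolerance = 1e-9)
  direct <- sim_preset("gamma2L(F304C)", "NS-1738", seed = 4)
  expect_equal(direct$p_constitutive_mean, 0.15)
  expect_error(sim_preset("nonexistent", "NS-1738"), "no reference group")
})
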