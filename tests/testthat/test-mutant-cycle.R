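# ddG propagation, summation conventions and the additivity verdict,
# checked against the bundled reference summaries and a Monte-Carlo oracle.

ns_wt <- group_summary("alpha1beta2gamma2L", "NS-1738", -0.70, 0.23, 25)
ns_muts <- list(
  group_summary("beta2(F289T)", "NS-1738", 1.22, 0.47, 5),
  group_summary("alpha1(Y293C)", "NS-1738", 0.31, 0.14, 5),
  group_summary("gamma2L(F304C)", "NS-1738", 0.74, 0.29, 5)
)
pam_wt <- group_summary("alpha1beta2gamma2L", "PAM-2", -0.39, 0.10, 25)
pam_muts <- list(
  group_summary("beta2(F289T)", "PAM-2", 0.05, 0.23, 8),
  group_summary("alpha1(Y293C)", "PAM-2", -0.13, 0.03, 6),
  group_summary("gamma2L(F304C)", "PAM-2", 0.66, 0.28, 5)
)

test_that("ddG point estimates and normal-approximation CIs reproduce the
          reference interface analysis", {
  r1 <- ddg(ns_muts[[1]], ns_wt)
  expect_equal(r1$ddG, 1.92, tolerance = 1e-9)
  expect_equal(r1$ci_low, 1.50, tolerance = 0.005)
  expect_equal(r1$ci_high, 2.34, tolerance = 0.005)
  r2 <- ddg(pam_muts[[2]], pam_wt)
  expect_equal(r2$ddG, 0.26, tolerance = 1e-9)
  expect_lt(abs(r2$ci_low - 0.21), 0.01)
  expect_lt(abs(r2$ci_high - 0.31), 0.01)
  # self-comparison: zero, symmetric interval
  r0 <- ddg(ns_wt, ns_wt)
  expect_equal(r0$ddG, 0)
  expect_equal(r0$ci_low, -r0$ci_high)
  expect_error(ddg(pam_muts[[1]], ns_wt), "different compounds")
})

test_that("ddG sign convention: potentiation-reducing mutations give
          positive ddG", {
  reduced <- ddg(group_summary("m", "NS-1738", -0.15, 0.06, 5), ns_wt)
  expect_gt(reduced$ddG, 0)
  enhanced <- ddg(group_summary("m", "NS-1738", -1.40, 0.16, 5), ns_wt)
  expect_lt(enhanced$ddG, 0)
})

test_that("summed ddGs and intervals match the reference sums and yield
          non-additive verdicts", {
  ns_sum <- additivity_sum(lapply(ns_muts, ddg, wildtype = ns_wt))
  expect_equal(ns_sum$ddG, 4.37, tolerance = 1e-9)
  expect_equal(c(ns_sum$ci_low, ns_sum$ci_high), c(3.85, 4.89),
               tolerance = 0.005)
  expect_false(additivity_test(ns_sum, ns_wt)$additive)

  pam_sum <- additivity_sum(lapply(pam_muts, ddg, wildtype = pam_wt))
  expect_equal(pam_sum$ddG, 1.75, tolerance = 1e-9)
  expect_equal(c(pam_sum$ci_low, pam_sum$ci_high), c(1.45, 2.05),
               tolerance = 0.005)
  expect_false(additivity_test(pam_sum, pam_wt)$additive)
})

test_that("additivity verdict is boundary-inclusive containment of
          -dG(wild type)", {
  fake <- structure(list(compound = "NS-1738", ddG = 0.70, se = 0.15,
                         ci_low = 0.40, ci_high = 1.00, z = 1.96,
                         var_mutant = 0.01, var_wildtype = 0.01),
                    class = "coupling_result")
  expect_true(additivity_test(fake, ns_wt)$additive)
  boundary <- fake; boundary$ci_low <- 0.70
  expect_true(additivity_test(boundary, ns_wt)$additive)
})

test_that("summation is permutation-invariant and associative in the
          variances", {
  res <- lapply(ns_muts, ddg, wildtype = ns_wt)
  s1 <- additivity_sum(res)
  s2 <- additivity_sum(res[c(3, 1, 2)])
  expect_equal(s1$ddG, s2$ddG)
  expect_equal(s1$se, s2$se)
  part <- additivity_sum(list(additivity_sum(res[1:2]), res[[3]]))
  expect_equal(part$ddG, s1$ddG, tolerance = 1e-12)
  expect_equal(part$se, s1$se, tolerance = 1e-12)
  single <- additivity_sum(res[1])
  expect_equal(single$ddG, res[[1]]$ddG)
  expect_equal(single$se, res[[1]]$se)
  expect_error(additivity_sum(list()), "empty")
})

test_that("covariance-aware mode widens the sum interval when the
          wild-type group is shared", {
  res <- lapply(ns_muts, ddg, wildtype = ns_wt)
  indep <- additivity_sum(res)
  aware <- additivity_sum(res, covariance_aware = TRUE)
  expect_equal(aware$ddG, indep$ddG)
  # k^2 vs k copies of the wild-type variance, k = 3
  expect_gt(aware$se, indep$se)
  expect_equal(aware$se^2 - indep$se^2, (9 - 3) * 0.23^2 / 25,
               tolerance = 1e-12)
})

test_that("analytic CIs agree with a Monte-Carlo percentile oracle", {
  set.seed(99)
  mc_ci <- function(mut, wt, draws = 20000) {
    d <- rnorm(draws, mut$mean_dG, mut$sd_dG / sqrt(mut$n)) -
      rnorm(draws, wt$mean_dG, wt$sd_dG / sqrt(wt$n))
    quantile(d, c(0.025, 0.975))
  }
  for (mut in ns_muts[1:2]) {
    r <- ddg(mut, ns_wt)
    ci <- mc_ci(mut, ns_wt)
    expect_equal(unname(ci[1]), r$ci_low, tolerance = 0.02)
    expect_equal(unname(ci[2]), r$ci_high, tolerance = 0.02)
  }
})

test_that("the end-to-end report reproduces the reference analysis from
          the bundled summary table", {
  tab <- reference_summaries("pam")
  rep_ns <- mutant_cycle_report(
    tab, compound = "NS-1738", wildtype = "alpha1beta2gamma2L",
    mutants = c("beta2(F289T)", "alpha1(Y293C)", "gamma2L(F304C)"))
  expect_equal(rep_ns$sum$ddG, 4.37, tolerance = 1e-9)
  expect_false(rep_ns$verdict$additive)
  expect_equal(nrow(rep_ns$table), 4)  # three interfaces + sum row
  expect_error(
    mutant_cycle_report(tab, "NS-1738", "alpha1beta2gamma2L",
                        mutants = character(0)), "no mutant")
  expect_error(
    mutant_cycle_report(tab, "NS-1738", "not-a-receptor"), "not found")
})
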