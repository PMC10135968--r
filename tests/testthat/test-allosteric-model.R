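# Closed-form two-state model arithmetic and its inversion.

test_that("state function reduces to the background at zero concentration
          or neutral efficacy", {
  params <- modulator_params("x", K_R = 1e-6, c = 0.3, N = 2)
  expect_equal(state_function(0.05, 0, params), 0.05, tolerance = 1e-12)
  neutral <- modulator_params("x", K_R = 1e-6, c = 1, N = 2)
  for (conc in c(0, 1e-7, 1e-3)) {
    expect_equal(state_function(0.30, conc, neutral), 0.30,
                 tolerance = 1e-12)
  }
})

test_that("saturating limit matches hand-evaluated values", {
  # 1/(1 + 19 * 0.01) and 1/(1 + 3 * 2.161^2), evaluated by hand
  expect_equal(saturating_state_function(0.05, c = 0.1, N = 2),
               1 / 1.19, tolerance = 1e-9)
  expect_equal(saturating_state_function(0.25, c = 2.161, N = 2),
               0.0666, tolerance = 1e-3)
  expect_equal(saturating_state_function(0.5, c = 1, N = 2), 0.5)
  # a near-saturating concentration (1000 x K_R) approximates the limit
  params <- modulator_params("x", K_R = 2e-6, c = 0.1, N = 2)
  expect_equal(state_function(0.05, 1000 * params$K_R, params),
               saturating_state_function(0.05, c = 0.1, N = 2),
               tolerance = 1e-3)
})

test_that("state function is monotone in concentration with the sign of
          1 - c", {
  conc <- 10^seq(-9, -2, length.out = 50)
  for (cc in c(0.1, 0.5)) {
    p <- state_function(0.1, conc,
                        modulator_params("x", K_R = 1e-6, c = cc, N = 2))
    expect_true(all(diff(p) > 0))
  }
  for (cc in c(2, 10)) {
    p <- state_function(0.1, conc,
                        modulator_params("x", K_R = 1e-6, c = cc, N = 2))
    expect_true(all(diff(p) < 0))
  }
})

test_that("efficacy inversion is the exact right-inverse of the saturating
          state function", {
  set.seed(41)
  for (N in c(1L, 2L, 4L)) {
    p_bg <- runif(200, 0.001, 0.999)
    c_true <- exp(runif(200, log(0.01), log(100)))
    p_mod <- saturating_state_function(p_bg, c = c_true, N = N)
    c_back <- efficacy_from_activation(p_bg, p_mod, N = N)
    expect_equal(c_back, c_true, tolerance = 1e-9)
  }
})

test_that("efficacy examples: no modulation gives c = 1; inhibition gives
          c > 1", {
  expect_equal(efficacy_from_activation(0.2, 0.2, N = 2), 1)
  expect_equal(efficacy_from_activation(0.08, 0.10, N = 2),
               sqrt((1 / 0.10 - 1) / ((1 - 0.08) / 0.08)),
               tolerance = 1e-12)
  expect_gt(efficacy_from_activation(0.25, 0.10, N = 2), 1)
})

test_that("free energy is N RT ln(c), log-additive, and signed by c - 1", {
  ctx <- energy_context()
  expect_equal(free_energy(1, N = 2, ctx), 0)
  expect_lt(free_energy(0.5, N = 2, ctx), 0)
  expect_gt(free_energy(2, N = 2, ctx), 0)
  set.seed(7)
  c1 <- exp(runif(50, -2, 2)); c2 <- exp(runif(50, -2, 2))
  expect_equal(free_energy(c1 * c2, N = 1, ctx),
               free_energy(c1, N = 1, ctx) + free_energy(c2, N = 1, ctx),
               tolerance = 1e-12)
  # round trip with the inverse transform
  expect_equal(efficacy_from_energy(free_energy(0.37, N = 4, ctx), N = 4,
                                    ctx), 0.37, tolerance = 1e-12)
})

test_that("fold-potentiation declines with background for a stabilizer and
          approaches 1 at the ceiling", {
  grid <- seq(0.005, 0.995, length.out = 100)
  tab <- fold_potentiation_curve(0.1, N = 2, p_background_grid = grid)
  expect_true(all(diff(tab$fold) < 0))
  expect_equal(tab$fold[1], saturating_state_function(grid[1], 0.1, 2) /
                 grid[1], tolerance = 1e-12)
  expect_lt(abs(tab$fold[length(grid)] - 1), 0.02)
  # hand-checked point: p_bg 0.05 -> 0.8403 / 0.05
  one <- fold_potentiation_curve(0.1, 2, p_background_grid = 0.05)
  expect_equal(one$fold, 16.81, tolerance = 1e-3)
  # neutral compound: fold identically 1
  flat <- fold_potentiation_curve(1, 2, p_background_grid = grid)
  expect_equal(flat$fold, rep(1, length(grid)), tolerance = 1e-12)
})

test_that("domain errors are raised for invalid probabilities and
          parameters", {
  expect_error(saturating_state_function(-0.1, 0.5, 2), "\\[0, 1\\]")
  expect_error(saturating_state_function(1.2, 0.5, 2), "\\[0, 1\\]")
  expect_error(saturating_state_function(0.5, -1, 2), "> 0")
  expect_error(free_energy(0, N = 2), "> 0")
  expect_error(modulator_params("x", K_R = -1, c = 0.5), "positive")
  expect_error(efficacy_from_activation(0.5, 0.5, N = 0), "positive")
  # boundary measurements are clamped, not rejected
  expect_true(is.finite(efficacy_from_activation(0, 1, N = 2)))
})
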