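test_that("basic accumulator follows its noise-free closed form", {
  cfg <- basic_accumulator_config(target = 0.9, rate = 0.5, sigma = 0)
  expect_equal(basic_step(0.9, cfg), 0.9) # fixed point
  expect_equal(basic_step(0, basic_accumulator_config(target = 1, rate = 0.5,
                                                      sigma = 0)), 0.5)
  # n noise-free steps from x0: T - (T - x0)(1 - r)^n, vs the iterated oracle
  x <- 0.3
  for (n in 1:25) x <- basic_step(x, cfg)
  expect_equal(x, 0.9 - (0.9 - 0.3) * 0.5^25, tolerance = 1e-12)
})

test_that("noise-free two-accumulator dynamics are bistable without switches", {
  cfg <- accumulator_config(5, sigma_against = 1e-12, sigma_for = 1e-13)
  p_s <- segregation_probability(Inf, 5)
  for (first in c("I", "S")) {
    st <- accumulator_state(first, cfg)
    switched_ever <- FALSE
    for (t in 1:300) {
      st <- eva_step(st, 1 - p_s, p_s, cfg)
      res <- detect_switch(st, cfg)
      switched_ever <- switched_ever || res$switched
      st <- res$state
    }
    expect_false(switched_ever)
    t_a <- cfg$t_against[[paste0("a", first, "1")]]
    if (first == "I") {
      expect_equal(st$x_s, t_a, tolerance = 1e-6)
      expect_equal(st$x_i, cfg$t_for, tolerance = 1e-6)
    } else {
      expect_equal(st$x_i, t_a, tolerance = 1e-6)
      expect_equal(st$x_s, cfg$t_for, tolerance = 1e-6)
    }
  }
})

test_that("switch resets both accumulators to the for-value and swaps roles", {
  cfg <- accumulator_config(5)
  st <- accumulator_state("I", cfg)
  st$x_s <- 1.02
  st$x_i <- 0.61
  res <- detect_switch(st, cfg)
  expect_true(res$switched)
  expect_equal(res$state$dominant, "S")
  expect_false(res$state$is_first)
  expect_equal(res$state$x_i, 0.61)
  expect_equal(res$state$x_s, 0.61)
  # below threshold: untouched
  st2 <- accumulator_state("I", cfg)
  res2 <- detect_switch(st2, cfg)
  expect_false(res2$switched)
  expect_identical(res2$state, st2)
})

test_that("for-accumulator crossings are disregarded via the clamp", {
  cfg <- accumulator_config(5)
  st <- accumulator_state("I", cfg)
  st$x_i <- 0.999 # for-accumulator about to cross
  withr::with_seed(1, {
    for (k in 1:200) {
      st2 <- eva_step(st, 0.4, 0.6, cfg)
      expect_lt(st2$x_i, cfg$threshold)
    }
  })
})

test_that("accumulator moments match the AR(1) closed form (Monte Carlo vs oracle)", {
  t_a <- 0.9288
  t_f <- 0.6
  p <- 0.6
  sigma <- 0.085
  n_steps <- 8
  n_rep <- 20000
  withr::with_seed(11, {
    x <- rep(t_f, n_rep)
    for (k in seq_len(n_steps)) {
      x <- x + (t_a - x) * p + sigma * rnorm(n_rep)
    }
  })
  mom <- ar1_moments(t_a, t_f, p, sigma, n_steps)
  expect_lt(abs(mean(x) - mom$mean), 3 * sqrt(mom$var / n_rep))
  expect_equal(var(x), mom$var, tolerance = 0.05)
})

test_that("AR(1) closed form agrees with the brute-force moment recursion", {
  # oracle: propagate mean/variance through the recursion directly
  t_a <- 0.9
  t_f <- 0.6
  p <- 0.4
  sigma <- 0.085
  e <- t_f
  v <- 0
  for (k in 1:12) {
    e <- e + (t_a - e) * p
    v <- (1 - p)^2 * v + sigma^2
  }
  mom <- ar1_moments(t_a, t_f, p, sigma, 12)
  expect_equal(mom$mean, e, tolerance = 1e-12)
  expect_equal(mom$var, v, tolerance = 1e-12)
  # endpoints
  m0 <- ar1_moments(t_a, t_f, p, sigma, 0)
  expect_equal(m0$mean, t_f)
  expect_equal(m0$var, 0)
  minf <- ar1_moments(t_a, t_f, p, sigma, 1e6)
  expect_equal(minf$mean, t_a)
  expect_equal(minf$var, sigma^2 / (1 - (1 - p)^2))
  expect_error(ar1_moments(t_a, t_f, 1.2, sigma, 3), "increment rate")
})

test_that("switching noise bound takes its closed form and limits", {
  expect_lt(abs(sigma_min(0.9, 0.75) - 0.022), 0.001)
  expect_equal(sigma_min(1, 0.75), 0)
  expect_equal(sigma_min(0.9, 1 - 1e-12), 0, tolerance = 1e-5)
})

test_that("below the noise bound switches are (almost) absent", {
  bound <- sigma_min(0.9, 0.75)
  cfg <- accumulator_config(
    5, t_against = c(aI1 = 0.9, aS1 = 0.9, aI2 = 0.9, aS2 = 0.9),
    sigma_against = bound * 0.8, sigma_for = 0.002)
  ex <- run_experiment(5, n_trials = 675, config = cfg, seed = 21)
  n_switches <- sum(ex$complete)
  expect_lte(n_switches, 2) # essentially none in 675 trials below the bound
})

test_that("accumulators never run away above threshold", {
  cfg <- accumulator_config(5)
  st <- accumulator_state("I", cfg)
  p_s <- segregation_probability(Inf, 5)
  top <- cfg$threshold + 5 * cfg$sigma_against
  worst <- -Inf
  withr::with_seed(31, {
    for (t in 1:2000) {
      st <- eva_step(st, 1 - p_s, p_s, cfg)
      worst <- max(worst, st$x_i, st$x_s)
      st <- detect_switch(st, cfg)$state
    }
  })
  expect_lt(worst, top)
})

test_that("configuration invariants are enforced", {
  expect_error(accumulator_config(5, sigma_against = 0.02, sigma_for = 0.03),
               "sigma_against")
  expect_error(accumulator_config(5, t_against = c(aI1 = 1.01, aS1 = 0.9,
                                                   aI2 = 0.9, aS2 = 0.9)),
               "sub-threshold")
  expect_silent(accumulator_config(5, t_against = c(aI1 = 1.01, aS1 = 0.9,
                                                    aI2 = 0.9, aS2 = 0.9),
                                   drift_dominated = TRUE))
  expect_error(accumulator_config(5, t_for = 0.95), "t_for")
  expect_error(accumulator_config(4), "no default target table")
})
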