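test_that("normalization divides by the group mean", {
  d <- tibble::tibble(duration_s = c(2, 4))
  out <- normalize_durations(d)
  expect_equal(out$d_tilde, c(2 / 3, 4 / 3))
  expect_equal(mean(out$d_tilde), 1)
  # two groups with different means each normalize to unit mean
  d2 <- tibble::tibble(subject = rep(c("a", "b"), each = 4),
                       duration_s = c(1, 2, 3, 4, 10, 20, 30, 40))
  out2 <- normalize_durations(d2, by = "subject")
  means <- tapply(out2$d_tilde, out2$subject, mean)
  expect_equal(as.numeric(means), c(1, 1))
  expect_error(normalize_durations(tibble::tibble(duration_s = numeric(0))),
               "no durations")
  expect_error(normalize_durations(tibble::tibble(duration_s = c(1, -1))),
               "positive")
})

test_that("gamma MLE recovers known shapes", {
  withr::with_seed(1, {
    exp_draws <- rgamma(1e4, shape = 1, scale = 1)
    gam_draws <- rgamma(1e4, shape = 2.6, scale = 1 / 2.6)
  })
  f1 <- gamma_mle(exp_draws)
  expect_gt(f1$alpha, 0.9)
  expect_lt(f1$alpha, 1.1)
  f2 <- gamma_mle(gam_draws)
  expect_gt(f2$alpha, 2.4)
  expect_lt(f2$alpha, 2.8)
  expect_equal(f2$mu_tilde, 1, tolerance = 0.05)
  # optimizer contract: at least as good as the moment start
  expect_gte(f2$log_lik, f2$start_log_lik)
  expect_error(gamma_mle(c(1, 2)), "at least")
})

test_that("gamma MLE agrees with an independent fitting routine", {
  skip_if_not_installed("fitdistrplus")
  withr::with_seed(8, d <- rgamma(3000, shape = 2.2, scale = 0.45))
  ours <- gamma_mle(d)
  ref <- fitdistrplus::fitdist(d, "gamma", method = "mle")
  expect_equal(ours$alpha, unname(ref$estimate["shape"]), tolerance = 1e-3)
  # our mean parametrization: mu = shape/rate
  expect_equal(ours$mu_tilde,
               unname(ref$estimate["shape"] / ref$estimate["rate"]),
               tolerance = 1e-3)
})

test_that("tidy and glance expose the fit with its scaling identities", {
  withr::with_seed(2, f <- gamma_mle(rgamma(500, 2, scale = 0.5)))
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "mu_tilde"))
  gl <- glance(f)
  expect_equal(gl$cv, 1 / sqrt(gl$alpha))
  expect_equal(gl$skewness, 2 * gl$cv) # skewness = 2 CV for any gamma
})

test_that("bootstrap goodness of fit accepts gamma data and rejects bimodal data", {
  withr::with_seed(3, good <- rgamma(300, shape = 2.6, scale = 1 / 2.6))
  fit <- gamma_mle(good)
  fit <- bootstrap_gof(fit, n_boot = 200, seed = 4)
  expect_gte(fit$p_value, 0.05)
  withr::with_seed(5, bad <- c(rnorm(200, 0.2, 0.02), rnorm(200, 3, 0.05)))
  fit_bad <- bootstrap_gof(gamma_mle(bad), n_boot = 200, statistic = "ks",
                           seed = 6)
  expect_lt(fit_bad$p_value, 0.05)
  # the likelihood-level statistic is blind to shape misfit: the maximized
  # gamma log-likelihood is a function of the matched sufficient statistics,
  # so it centres near 0.5 even here
  fit_ll <- bootstrap_gof(gamma_mle(bad), n_boot = 200, seed = 6)
  expect_gt(fit_ll$p_value, 0.05)
  expect_error(bootstrap_gof(fit, n_boot = 0), "n_boot")
})

test_that("bootstrap p-values are roughly calibrated under the null", {
  # data generated from the fitted gamma should rarely be rejected
  ps <- vapply(1:10, function(i) {
    withr::with_seed(100 + i, d <- rgamma(150, shape = 2, scale = 0.5))
    bootstrap_gof(gamma_mle(d), n_boot = 120, seed = 200 + i)$p_value
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.9)
})

test_that("buildup fractions partition unity and start at zero", {
  ex <- run_experiment(5, n_trials = 150, seed = 17)
  bu <- buildup(ex, n_boot = 100, seed = 18)
  expect_equal(bu$p_seg + bu$p_int + bu$p_lat, rep(1, nrow(bu)))
  expect_equal(bu$p_seg[1], 0)
  expect_true(all(bu$ci_low <= bu$p_seg + 1e-12))
  expect_true(all(bu$ci_high >= bu$p_seg - 1e-12))
  # all-I trials give an identically zero curve
  cfg <- accumulator_config(5, sigma_against = 1e-9, sigma_for = 1e-10)
  quiet <- run_experiment(5, n_trials = 20, config = cfg, p_first_seg = 0,
                          seed = 19)
  expect_true(all(buildup(quiet, n_boot = 0)$p_seg == 0))
})

test_that("buildup plateau matches the alternating-renewal prediction", {
  ex <- run_experiment(5, n_trials = 675, seed = 23)
  bu <- buildup(ex, n_boot = 0)
  plateau <- buildup_plateau(bu)
  subs <- percept_durations(ex) |> dplyr::filter(ordinal == "subsequent")
  mu <- tapply(subs$duration_s, subs$label, mean)
  renewal <- mu[["S"]] / (mu[["I"]] + mu[["S"]])
  expect_equal(plateau, renewal, tolerance = 0.05)
})

test_that("group means average subjects without weighting", {
  d <- tibble::tibble(subject = c("a", "a", "a", "b"),
                      duration_s = c(2, 2, 2, 4))
  gm <- group_means(d)
  expect_equal(gm$mean, 3) # unweighted despite a contributing 3 durations
  d15 <- tibble::tibble(subject = rep(1:15, each = 2),
                        duration_s = rep(5, 30))
  gm15 <- group_means(d15)
  expect_equal(gm15$se, 0)
  expect_warning(gm1 <- group_means(tibble::tibble(subject = "a",
                                                   duration_s = 1:3)),
                 "single subject")
  expect_true(is.na(gm1$se))
})

test_that("key-press fixtures round-trip through the duration pipeline", {
  rec <- simulate_keypress_records(n_subjects = 3, n_trials = 30, seed = 31)
  expect_named(rec, c("subject", "trial", "df", "press_time_s", "label"))
  durs <- keypress_durations(rec)
  expect_true(all(durs$duration_s > 0))
  # labels alternate within each trial
  alt <- durs |>
    dplyr::group_by(subject, trial) |>
    dplyr::summarise(ok = all(label != dplyr::lag(label),
                              na.rm = TRUE), .groups = "drop")
  expect_true(all(alt$ok))
  # per-subject normalized means are 1 and the gamma shape is recovered
  comp <- durs |>
    dplyr::filter(complete, ordinal == "subsequent") |>
    normalize_durations(by = c("subject", "label"))
  fit <- gamma_mle(comp$d_tilde)
  expect_gt(fit$alpha, 1.8)
  expect_lt(fit$alpha, 3.6)
})
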