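test_that("region classification bands are applied in order", {
  expect_equal(classify_region(2.6, 2.6), "G")
  expect_equal(classify_region(1.0, 2.6), "E")
  expect_equal(classify_region(10, 2.6), "N")
  expect_equal(classify_region(4, 2.6), "other")
  # relaxed band for the narrow integration case
  expect_equal(classify_region(3.3, 2.6, rel_tol = 0.3), "G")
  expect_error(classify_region(-1, 2.6))
})

test_that("reference table carries the behavioural means and shapes", {
  refs <- reference_stats()
  expect_equal(nrow(refs), 12)
  r <- dplyr::filter(refs, df == 5, label == "I", ordinal == "subsequent")
  expect_equal(r$mu_exp, 3.4)
  expect_equal(r$alpha_exp, 2.6)
  expect_equal(r$se_exp, 0.6 * 3.4 / sqrt(15))
  expect_true(all(refs$se_approx))
})

test_that("sweep maps the na / long / matching / short progression in noise", {
  sw <- sweep_eva(5, label = "I", ordinal = "subsequent",
                  t_a_grid = 0.9288,
                  sigma_a_grid = c(0.01, 0.045, 0.085, 0.3),
                  n_trials = 120, seed = 61)
  expect_s3_class(sw, "eva_sweep")
  expect_equal(sw$region[1], "na") # below the switching bound
  expect_true(is.na(sw$mu[1]))
  mus <- sw$mu[-1]
  expect_true(all(diff(mus) < 0)) # mean durations shrink with noise
  expect_gt(sw$mu_ratio[2], 1) # moderate noise: percepts too long
  # printed parameters land in the matching band
  expect_lt(abs(sw$mu_ratio[3] - 1), 0.25)
  # strong noise: short, exponential-like durations. With means of a few
  # 0.5-s triplets the continuous-gamma shape of even exactly geometric
  # (discrete-exponential) durations floors well above 1, so
  # exponential-likeness is checked against a matched-mean geometric oracle
  expect_lt(sw$mu_ratio[4], 0.6)
  mean_triplets <- sw$mu[4] / 0.5
  withr::with_seed(1, {
    geo <- rgeom(5000, 1 / mean_triplets) + 1
  })
  alpha_geo <- gamma_mle(geo / mean(geo))$alpha
  expect_lt(abs(sw$alpha[4] / alpha_geo - 1), 0.25)
  expect_error(sweep_eva(5, t_a_grid = numeric(0), sigma_a_grid = 0.1),
               "empty")
})

test_that("sweep respects the analytic switching bound", {
  p_m <- max(segregation_probability(Inf, 5), 1 - segregation_probability(Inf, 5))
  sw <- sweep_eva(5, label = "I", ordinal = "subsequent",
                  t_a_grid = c(0.88, 0.93),
                  sigma_a_grid = c(0.012, 0.085),
                  n_trials = 100, seed = 67)
  for (i in seq_len(nrow(sw))) {
    if (sw$sigma_a[i] < sigma_min(sw$t_a[i], 0.75)) {
      expect_equal(sw$region[i], "na")
    }
  }
})

test_that("target selection obeys the 10%-SE gate and tie-breaks", {
  refs <- reference_stats()
  base <- tibble::tibble(df = 5, label = "I", ordinal = "subsequent")
  mk <- function(...) {
    out <- dplyr::bind_cols(base, tibble::tibble(...))
    class(out) <- c("eva_sweep", class(out))
    out
  }
  r <- dplyr::filter(refs, df == 5, label == "I", ordinal == "subsequent")
  gate <- 0.1 * r$se_exp
  sw <- mk(t_a = c(0.90, 0.92, 0.94),
           sigma_a = 0.085,
           mu = c(3.4 + gate / 2, 3.4 - gate / 2, 9),
           alpha = c(2.0, 2.5, 2.6),
           n_switches = 100, region = "G",
           mu_ratio = 1, within_1se = TRUE)
  pick <- select_t_a(sw, refs)
  expect_true(attr(pick, "matched"))
  expect_equal(pick$t_a, 0.92) # closest shape among gated cells
  # tie in shape error: smaller target wins
  sw2 <- mk(t_a = c(0.92, 0.90), sigma_a = 0.085,
            mu = 3.4, alpha = 2.5, n_switches = 100,
            region = "G", mu_ratio = 1, within_1se = TRUE)
  expect_equal(select_t_a(sw2, refs)$t_a, 0.90)
  # empty candidate set: nearest-miss diagnostics
  sw3 <- mk(t_a = 0.9, sigma_a = 0.085, mu = 30, alpha = 2,
            n_switches = 100, region = "other", mu_ratio = 10,
            within_1se = FALSE)
  miss <- select_t_a(sw3, refs)
  expect_false(attr(miss, "matched"))
  expect_true("mu_err" %in% names(miss))
})

test_that("printed target for subsequent integration lies in the matching band", {
  sw <- sweep_eva(5, label = "I", ordinal = "subsequent",
                  t_a_grid = c(0.91, 0.9288, 0.95),
                  sigma_a_grid = 0.085,
                  n_trials = 400, seed = 71)
  pick <- select_t_a(sw, se_frac = 1) # 1 SE gate at reduced trial counts
  expect_true(attr(pick, "matched"))
  # the printed target's cell mean is close to the behavioural 3.4 s
  cell <- dplyr::filter(sw, abs(t_a - 0.9288) < 1e-9)
  expect_lt(abs(cell$mu - 3.4), 0.55)
})
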