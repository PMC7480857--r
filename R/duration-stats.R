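#' Normalize percept durations
#'
#' Divides each duration by the mean of its normalization group (a subject
#' in behavioural data; pooled per condition/percept cell for simulated
#' data, which has no subjects). By construction every group's normalized
#' mean is exactly 1.
#'
#' @param data A data frame of durations.
#' @param duration Column holding durations (tidy-eval); default
#'   `duration_s`.
#' @param by Character vector of grouping columns (e.g. `"subject"`), or
#'   `NULL` for pooled normalization.
#' @return `data` with an added `d_tilde` column.
#' @export
normalize_durations <- function(data, duration = duration_s, by = NULL) {
  dur <- enquo(duration)
  vals <- dplyr::pull(data, !!dur)
  if (length(vals) == 0) abort("no durations to normalize")
  if (any(vals <= 0)) abort("durations must be positive")
  if (is.null(by)) {
    dplyr::mutate(data, d_tilde = !!dur / mean(!!dur))
  } else {
    data %>%
      group_by(across(all_of(by))) %>%
      mutate(d_tilde = !!dur / mean(!!dur)) %>%
      ungroup()
  }
}

# log-likelihood of the shape/mean gamma parametrization:
# f(d | alpha, mu) has shape alpha and mean mu (scale mu/alpha)
gamma_loglik <- function(d, alpha, mu) {
  sum((alpha - 1) * log(d) - alpha * d / mu + alpha * log(alpha / mu) -
        lgamma(alpha))
}

#' Gamma fit of normalized durations by maximum likelihood
#'
#' Fits the shape/mean gamma density
#' \deqn{f(\tilde D \mid \alpha, \tilde\mu) =
#'   \frac{\alpha/\tilde\mu}{\Gamma(\alpha)}
#'   (\alpha \tilde D/\tilde\mu)^{\alpha-1} e^{-\alpha \tilde D/\tilde\mu}}
#' by maximising the log-likelihood with a derivative-free simplex
#' (Nelder-Mead on log-parameters) from the moment start
#' `alpha0 = 1/CV^2`, `mu0 = mean`. For normalized data `mu_tilde` is close
#' to 1 and the shape alone fixes the coefficient of variation
#' (`1/sqrt(alpha)`) and skewness (`2/sqrt(alpha)`).
#'
#' @param d_tilde Positive durations (normalized or raw).
#' @param min_n Minimal sample size accepted.
#' @param reltol Convergence tolerance on the log-likelihood.
#' @return An object of class `gamma_fit`: list with `alpha`, `mu_tilde`,
#'   `log_lik`, `n`, `converged`, `p_value` (`NA` until
#'   [bootstrap_gof()] is run) and the data.
#' @examples
#' fit <- gamma_mle(rgamma(500, shape = 2.6, scale = 1 / 2.6))
#' tidy(fit)
#' @export
gamma_mle <- function(d_tilde, min_n = 5, reltol = 1e-8) {
  d_tilde <- d_tilde[!is.na(d_tilde)]
  if (length(d_tilde) < min_n) {
    abort(paste0("need at least ", min_n, " durations to fit"))
  }
  if (any(d_tilde <= 0)) abort("durations must be positive")
  mu0 <- mean(d_tilde)
  cv0 <- sd(d_tilde) / mu0
  alpha0 <- if (is.finite(cv0) && cv0 > 0) 1 / cv0^2 else 1
  start_ll <- gamma_loglik(d_tilde, alpha0, mu0)
  opt <- optim(log(c(alpha0, mu0)),
               function(p) -gamma_loglik(d_tilde, exp(p[1]), exp(p[2])),
               method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = 2000))
  structure(
    list(alpha = exp(opt$par[1]),
         mu_tilde = exp(opt$par[2]),
         log_lik = -opt$value,
         start_log_lik = start_ll,
         n = length(d_tilde),
         converged = opt$convergence == 0,
         p_value = NA_real_,
         data = d_tilde),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("<gamma_fit> n =", x$n, "\n")
  cat(sprintf("  alpha = %.3f  mu = %.3f  logLik = %.2f\n",
              x$alpha, x$mu_tilde, x$log_lik))
  cat(sprintf("  CV = %.3f  skewness = %.3f", 1 / sqrt(x$alpha),
              2 / sqrt(x$alpha)))
  if (!is.na(x$p_value)) cat(sprintf("  GoF p = %.3f", x$p_value))
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname gamma_mle
#' @param x A `gamma_fit`.
#' @param ... Unused.
#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble(term = c("alpha", "mu_tilde"),
         estimate = c(x$alpha, x$mu_tilde))
}

#' @rdname gamma_mle
#' @export
glance.gamma_fit <- function(x, ...) {
  tibble(alpha = x$alpha, mu_tilde = x$mu_tilde,
         cv = 1 / sqrt(x$alpha), skewness = 2 / sqrt(x$alpha),
         log_lik = x$log_lik, n = x$n, p_value = x$p_value,
         converged = x$converged)
}

#' Parametric-bootstrap goodness of fit for a gamma fit
#'
#' Simulates `n_boot` samples of size `n` from the fitted gamma, refits each
#' by maximum likelihood, and locates the observed statistic in the
#' bootstrap distribution. With the default `statistic = "loglik"` the
#' statistic is the maximal log-likelihood and the one-sided p-value is the
#' probability of a bootstrap log-likelihood at or below the observed one.
#' Note that the maximized gamma log-likelihood is a function of the sample
#' mean and mean log alone, which the fitted gamma matches by construction,
#' so this statistic is well calibrated under the null but nearly
#' insensitive to shape misfit; `statistic = "ks"` bootstraps the
#' Kolmogorov-Smirnov distance instead (p-value: fraction of bootstrap
#' distances at or above the observed one), which does detect misfit.
#' Either way the gamma hypothesis is rejected at 5% when `p < 0.05`.
#'
#' @param fit A [gamma_mle()] fit.
#' @param n_boot Bootstrap replicates (10000 for publication-grade tests;
#'   use a few hundred for quick checks).
#' @param statistic `"loglik"` (maximized log-likelihood) or `"ks"`
#'   (Kolmogorov-Smirnov distance to the refitted gamma).
#' @param seed Optional seed.
#' @return The fit with `p_value` filled in; the bootstrap statistics are
#'   kept in attribute `"boot_stat"`.
#' @export
bootstrap_gof <- function(fit, n_boot = 10000,
                          statistic = c("loglik", "ks"), seed = NULL) {
  stopifnot(inherits(fit, "gamma_fit"))
  statistic <- match.arg(statistic)
  if (n_boot < 1) abort("n_boot must be >= 1")
  stat_of <- function(d) {
    f <- gamma_mle(d)
    if (statistic == "loglik") {
      f$log_lik
    } else {
      x <- sort(d)
      p <- stats::pgamma(x, shape = f$alpha, scale = f$mu_tilde / f$alpha)
      i <- seq_along(x)
      max(pmax(abs(i / f$n - p), abs((i - 1) / f$n - p)))
    }
  }
  obs <- stat_of(fit$data)
  seeds <- derive_seeds(seed, n_boot)
  boot <- vapply(seq_len(n_boot), function(b) {
    d <- with_seed(seeds[b],
                   rgamma(fit$n, shape = fit$alpha,
                          scale = fit$mu_tilde / fit$alpha))
    stat_of(d)
  }, numeric(1))
  fit$p_value <- if (statistic == "loglik") {
    mean(boot <= obs)
  } else {
    mean(boot >= obs)
  }
  attr(fit, "boot_stat") <- boot
  fit
}

#' Buildup function with bootstrap confidence band
#'
#' Trial-averaged probability of segregation as a function of time since
#' stimulus onset: at each time point, the fractions of trials reporting S,
#' reporting I, or still in the latency period (`p_seg + p_int + p_lat = 1`).
#' The latency period counts as non-S, so the curve always starts at 0. A
#' 95% confidence band for `p_seg` comes from bootstrap resampling of
#' trials.
#'
#' @param x An `eva_experiment`, or a binary time-course matrix from
#'   [to_binary_timecourse()].
#' @param resolution Sampling step in seconds.
#' @param n_boot Bootstrap resamples for the confidence band (0 skips it).
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return A tibble of class `eva_buildup` with `time_s`, `p_seg`, `p_int`,
#'   `p_lat`, `ci_low`, `ci_high`.
#' @export
buildup <- function(x, resolution = 0.5, n_boot = 500, conf = 0.95,
                    seed = NULL) {
  mat <- if (is.matrix(x)) x else to_binary_timecourse(x, resolution)
  time_s <- attr(mat, "time_s") %||% (seq_len(ncol(mat)) * resolution)
  seg <- !is.na(mat) & mat == 1
  int <- !is.na(mat) & mat == 0
  p_seg <- colMeans(seg)
  p_int <- colMeans(int)
  p_lat <- colMeans(is.na(mat))
  lo <- hi <- rep(NA_real_, ncol(mat))
  if (n_boot > 0) {
    qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    boot <- with_seed(seed, {
      idx <- matrix(sample.int(nrow(mat), nrow(mat) * n_boot, replace = TRUE),
                    ncol = n_boot)
      apply(idx, 2, function(i) colMeans(seg[i, , drop = FALSE]))
    })
    ci <- apply(boot, 1, quantile, probs = qs)
    lo <- ci[1, ]
    hi <- ci[2, ]
  }
  out <- tibble(time_s = time_s, p_seg = p_seg, p_int = p_int,
                p_lat = p_lat, ci_low = lo, ci_high = hi)
  class(out) <- c("eva_buildup", class(out))
  out
}

#' Asymptotic buildup level
#'
#' Mean of the buildup curve over a late-time window (default: the last
#' 15 s of a 30-s trial), the quantity matched to the behavioural
#' asymptotes 0.45/0.6/0.65.
#'
#' @param bu An `eva_buildup` tibble.
#' @param window Time window in seconds.
#' @return A probability.
#' @export
buildup_plateau <- function(bu, window = c(15, 30)) {
  sel <- bu$time_s > window[1] & bu$time_s <= window[2]
  mean(bu$p_seg[sel])
}

#' Group mean durations across subjects
#'
#' Behavioural convention for reporting mean durations: a per-subject mean
#' first, then the unweighted average across subjects, so fast switchers
#' (who contribute more durations) do not dominate. The standard error is
#' the SD of the subject means over `sqrt(n_subjects)`.
#'
#' @param data A data frame of durations.
#' @param duration Duration column (tidy-eval); default `duration_s`.
#' @param subject Name of the subject column.
#' @return A one-row tibble with `mean`, `se`, `ci95`, `n_subjects`;
#'   `se` is `NA` (flagged by a warning) with a single subject.
#' @export
group_means <- function(data, duration = duration_s, subject = "subject") {
  dur <- enquo(duration)
  per <- data %>%
    group_by(across(all_of(subject))) %>%
    summarise(mu_i = mean(!!dur), .groups = "drop")
  if (nrow(per) == 0) abort("no subjects")
  n_s <- nrow(per)
  se <- if (n_s > 1) sd(per$mu_i) / sqrt(n_s) else NA_real_
  if (n_s == 1) warn("single subject: standard error undefined")
  tibble(mean = mean(per$mu_i), se = se, ci95 = 1.96 * se, n_subjects = n_s)
}

#' Generate behavioural-format key-press records
#'
#' Alternating-renewal sampler emulating the key-press format of the
#' behavioural task: per subject and trial, a latency period followed by
#' alternating I/S percepts with gamma-distributed durations, reported as
#' press times with percept labels. Intended as a fixture generator for the
#' behavioural-format readers and the statistics suite; it reproduces the
#' renewal structure of responses, not any subject-specific behaviour.
#'
#' @param n_subjects,n_trials Subjects and trials per subject.
#' @param df Condition label stored in the output.
#' @param mean_i,mean_s Mean percept durations in seconds.
#' @param alpha Gamma shape of the duration distributions.
#' @param p_first_seg Probability the first percept is S.
#' @param latency_s Latency before the first press.
#' @param trial_s Trial length in seconds.
#' @param seed Optional seed.
#' @return A tibble with `subject`, `trial`, `df`, `press_time_s`, `label`;
#'   one row per reported percept onset.
#' @export
simulate_keypress_records <- function(n_subjects = 5, n_trials = 20, df = 5,
                                      mean_i = 3.4, mean_s = 5.2,
                                      alpha = 2.6,
                                      p_first_seg = first_seg_probability(df),
                                      latency_s = 2, trial_s = 30,
                                      seed = NULL) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      purrr::map_dfr(seq_len(n_trials), function(tr) {
        lab <- if (runif(1) < p_first_seg) "S" else "I"
        t <- latency_s
        times <- numeric()
        labs <- character()
        while (t < trial_s) {
          times <- c(times, t)
          labs <- c(labs, lab)
          mu <- if (lab == "I") mean_i else mean_s
          t <- t + rgamma(1, shape = alpha, scale = mu / alpha)
          lab <- if (lab == "I") "S" else "I"
        }
        tibble(subject = s, trial = tr, df = df,
               press_time_s = times, label = labs)
      })
    })
  })
}

#' Convert key-press records to percept durations
#'
#' Turns behavioural-format press records (one row per percept onset) into
#' the interval format used by the statistics suite. The interval cut off
#' by the end of the trial is flagged incomplete.
#'
#' @param records A tibble as from [simulate_keypress_records()] (columns
#'   `subject`, `trial`, `press_time_s`, `label`).
#' @param trial_s Trial length in seconds.
#' @return A tibble with `subject`, `trial`, `df` (if present), `label`,
#'   `ordinal`, `start_s`, `duration_s`, `complete`.
#' @export
keypress_durations <- function(records, trial_s = 30) {
  records %>%
    group_by(.data$subject, .data$trial) %>%
    arrange(.data$press_time_s, .by_group = TRUE) %>%
    mutate(ordinal = ifelse(dplyr::row_number() == 1, "first", "subsequent"),
           start_s = .data$press_time_s,
           duration_s = c(diff(.data$press_time_s),
                          trial_s - .data$press_time_s[dplyr::n()]),
           complete = dplyr::row_number() < dplyr::n()) %>%
    ungroup() %>%
    select(-"press_time_s")
}
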