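#' Per-triplet signal-detection classification
#'
#' The classical baseline: each triplet of each trial is classified
#' independently, with no memory, by comparing the mean spike count of one
#' pool of `n_in` Poisson units to the threshold `c_th` — segregation if the
#' pooled mean is below threshold, integration otherwise. Equivalent to the
#' full model observed at the input layer with a single sampler.
#'
#' @param df Frequency separation in semitones.
#' @param n_trials Number of trials.
#' @param config A [sampler_config()] (only `n_in`, `c_th` used).
#' @param model A [spike_mean_model()].
#' @param n_triplets Trial length in triplets.
#' @param seed Optional seed.
#' @return A logical matrix (`n_trials` x `n_triplets`), `TRUE` where the
#'   triplet is classified S.
#' @export
sdt_classify <- function(df, n_trials = 675, config = sampler_config(),
                         model = spike_mean_model(),
                         n_triplets = model$n_triplets, seed = NULL) {
  m <- vapply(seq_len(n_triplets), function(t) mean_spike_count(t, df, model),
              numeric(1))
  with_seed(seed, {
    seg <- vapply(seq_len(n_triplets), function(t) {
      pooled <- rpois(n_trials, config$n_in * m[t])
      pooled < config$n_in * config$c_th
    }, logical(n_trials))
    matrix(seg, nrow = n_trials)
  })
}

#' Run lengths of identically classified triplets
#'
#' Groups adjacent same-label triplets of each trial into "percept" phases
#' and returns their durations. The trailing run cut off by the end of the
#' trial is dropped by default, matching the convention for simulated
#' percept durations; the leading run is kept (this baseline has no latency
#' period).
#'
#' @param seg Logical matrix from [sdt_classify()] (or a logical vector for
#'   one trial).
#' @param drop_final Drop the final, truncated run of each trial.
#' @return A tibble with `trial`, `label` ("I"/"S"), `n_triplets`,
#'   `duration_s`.
#' @export
run_lengths <- function(seg, drop_final = TRUE) {
  if (!is.matrix(seg)) seg <- matrix(seg, nrow = 1)
  purrr::map_dfr(seq_len(nrow(seg)), function(i) {
    r <- rle(seg[i, ])
    keep <- if (drop_final && length(r$lengths) > 0) {
      seq_len(length(r$lengths) - 1L)
    } else {
      seq_along(r$lengths)
    }
    tibble(trial = i,
           label = ifelse(r$values[keep], "S", "I"),
           n_triplets = r$lengths[keep],
           duration_s = r$lengths[keep] * 0.5)
  })
}

#' Analytic run-length probabilities under independent classification
#'
#' With asymptotic segregation probability `p` and independent triplets,
#' the probability that an S phase consists of `n` triplets is
#' `p^n (1 - p)` and that an I phase consists of `n` triplets is
#' `p (1 - p)^n` — exponential in `n`, the root of the baseline's
#' unrealistically short, exponential-like durations. `normalized = TRUE`
#' returns the properly normalized geometric law
#' `p^(n-1) (1 - p)` (mean run `1/(1-p)`) used when comparing against
#' empirical run-length histograms.
#'
#' @param p Asymptotic probability of segregation, in (0, 1).
#' @param n Run length in triplets (>= 1); vectorised.
#' @param label `"S"` or `"I"`.
#' @param normalized Return the normalized geometric pmf instead of the
#'   raw product form.
#' @return Probabilities, same length as `n`.
#' @export
exponential_run_pmf <- function(p, n, label = c("S", "I"),
                                normalized = FALSE) {
  label <- match.arg(label)
  stopifnot(p > 0, p < 1, all(n >= 1))
  q <- if (label == "S") p else 1 - p
  if (normalized) q^(n - 1) * (1 - q) else q^n * (1 - q)
}

#' Neurometric buildup curve
#'
#' Trial-averaged fraction of S-classified triplets as a function of time —
#' the "neurometric" function of the signal-detection baseline. With
#' `n_trials = Inf` the analytic expectation ([segregation_probability()])
#' is returned instead of a Monte-Carlo average.
#'
#' @inheritParams sdt_classify
#' @return A tibble with `t`, `time_s`, `df`, `p_seg`.
#' @export
neurometric_curve <- function(df, n_trials = 675, config = sampler_config(),
                              model = spike_mean_model(),
                              n_triplets = model$n_triplets, seed = NULL) {
  t <- seq_len(n_triplets)
  p <- if (is.infinite(n_trials)) {
    segregation_probability(t, df, config, model)
  } else {
    colMeans(sdt_classify(df, n_trials, config, model, n_triplets, seed))
  }
  tibble(t = t, time_s = t * 0.5, df = df, p_seg = p)
}

#' Fit the classification threshold to behavioural buildup targets
#'
#' Grid search for the `c_th` minimising the squared error between the
#' analytic neurometric curves and target values over a triplet window —
#' the last 30 triplets against asymptotic levels by default, or any
#' user-supplied target curves (e.g. digitized behavioural transients with
#' an early window).
#'
#' @param targets Either a named numeric vector of asymptotic levels per DF
#'   (recycled over the window) or a named list of per-triplet target
#'   vectors covering `triplets`.
#' @param n_in Pool size held fixed during the fit.
#' @param c_th_grid Candidate thresholds.
#' @param triplets Triplet window of the fit.
#' @param model A [spike_mean_model()].
#' @return A tibble with the best `c_th` and `sse`; full grid in attribute
#'   `"grid"`.
#' @export
fit_cth <- function(targets = c("3" = 0.45, "5" = 0.6, "7" = 0.65),
                    n_in = 5,
                    c_th_grid = seq(3.5, 5, by = 0.01),
                    triplets = 31:60,
                    model = spike_mean_model()) {
  if (length(c_th_grid) == 0) abort("empty c_th grid")
  dfs <- as.numeric(names(targets))
  grid <- tibble(c_th = sort(c_th_grid))
  grid$sse <- vapply(grid$c_th, function(ct) {
    cfg <- sampler_config(n_in = n_in, c_th = ct)
    sum(vapply(seq_along(dfs), function(i) {
      p0 <- segregation_probability(triplets, dfs[i], cfg, model)
      tgt <- if (is.list(targets)) targets[[i]] else targets[i]
      sum((p0 - tgt)^2)
    }, numeric(1)))
  }, numeric(1))
  best <- grid %>% arrange(.data$sse, .data$c_th) %>% slice(1)
  attr(best, "grid") <- grid
  best
}
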