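#' Sampler-layer configuration
#'
#' The sampler layer converts pooled spike counts into binary "votes". Each of
#' `n_sl` sampler units averages the counts of its own pool of `n_in` input
#' units and compares the average to the threshold `c_th` (spikes/triplet):
#' mean count >= `c_th` votes 1 (favouring integration), otherwise 0
#' (favouring segregation). The defaults are the values obtained by
#' least-squares fit of the analytic vote probability to the asymptotic
#' behavioural buildup levels 0.45/0.6/0.65 at DF = 3/5/7.
#'
#' @param n_in Input units pooled per sampler.
#' @param c_th Spike-count threshold (real-valued, spikes/triplet).
#' @param n_sl Number of sampler units.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_in = 5, c_th = 4.21, n_sl = 20) {
  stopifnot(n_in >= 1, n_sl >= 1, c_th > 0)
  structure(list(n_in = as.integer(n_in), c_th = c_th, n_sl = as.integer(n_sl)),
            class = "sampler_config")
}

#' Named sampler configuration for the 1/3/6/9-semitone data set
#'
#' The pool size and threshold reported for the four-condition (DF = 1, 3, 6,
#' 9) configuration of the signal-detection fit. Exposed for documentation
#' and exploration; the behavioural fit behind it is not reproducible from
#' printed values alone.
#'
#' @return A `sampler_config` with `n_in = 30`, `c_th = 4.64`.
#' @export
sampler_config_df1369 <- function() sampler_config(n_in = 30, c_th = 4.64)

#' @export
print.sampler_config <- function(x, ...) {
  cat("<sampler_config> n_in =", x$n_in, ", c_th =", x$c_th,
      ", n_sl =", x$n_sl, "\n")
  invisible(x)
}

#' Binary sampler vote
#'
#' Heaviside classification of one pool: vote 1 iff the mean of `counts` is
#' at or above `c_th`. With integer count sums and a non-integer
#' `n_in * c_th` (as for the default 5 x 4.21 = 21.05) exact equality cannot
#' occur, so the boundary convention is unobservable at default parameters.
#'
#' @param counts Integer spike counts of one pool.
#' @param c_th Threshold (spikes/triplet).
#' @return 0 or 1.
#' @export
sampler_vote <- function(counts, c_th) {
  if (length(counts) == 0) abort("empty spike-count pool")
  as.integer(mean(counts) >= c_th)
}

#' Analytic probability that a sampler votes for segregation
#'
#' A pool of `n_in` independent Poisson units with mean `m` has a Poisson
#' pooled count with rate `n_in * m`, so the probability of a 0-vote (mean
#' count strictly below `c_th`) is the Poisson CDF
#' `P(K <= ceiling(n_in * c_th) - 1)` at that rate. This is the analytic
#' counterpart of the Monte-Carlo vote fractions produced by [layer_step()],
#' and the per-triplet segregation probability of the signal-detection
#' baseline.
#'
#' @param t Triplet index; vectorised. `Inf` gives the asymptotic value.
#' @param df Frequency separation in semitones.
#' @param config A [sampler_config()].
#' @param model A [spike_mean_model()].
#' @return Probabilities, same length as `t`.
#' @examples
#' segregation_probability(Inf, 3) # ~ 0.40
#' segregation_probability(Inf, 5) # ~ 0.62
#' @export
segregation_probability <- function(t, df, config = sampler_config(),
                                    model = spike_mean_model()) {
  m <- mean_spike_count(t, df, model)
  k_max <- ceiling(config$n_in * config$c_th) - 1
  ppois(k_max, config$n_in * m)
}

# draw vote fractions for many trials at once at a single triplet:
# returns vector of p_s (fraction of 0-votes) of length n_trials
draw_vote_fractions <- function(m, config, n_trials = 1) {
  n <- n_trials * config$n_sl
  pooled <- rpois(n, config$n_in * m) # pooled Poisson count of each pool
  votes <- pooled >= config$n_in * config$c_th
  p_i <- colMeans(matrix(votes, nrow = config$n_sl, ncol = n_trials))
  1 - p_i
}

#' One sampler-layer step
#'
#' Draws `n_sl` independent pools of `n_in` Poisson spike counts at triplet
#' `t`, applies the threshold vote to each, and returns the vote fractions
#' that drive the accumulators.
#'
#' @inheritParams segregation_probability
#' @param seed Optional seed.
#' @return A list with `t`, `p_i` (fraction voting 1), `p_s` (fraction
#'   voting 0, equal to `1 - p_i`), and the binary `votes`.
#' @export
layer_step <- function(t, df, config = sampler_config(),
                       model = spike_mean_model(), seed = NULL) {
  stopifnot(length(t) == 1)
  m <- mean_spike_count(t, df, model)
  with_seed(seed, {
    counts <- matrix(rpois(config$n_sl * config$n_in, m),
                     nrow = config$n_sl)
    votes <- as.integer(rowMeans(counts) >= config$c_th)
    list(t = t, p_i = mean(votes), p_s = 1 - mean(votes), votes = votes)
  })
}

#' Tabulate analytic and empirical sampler probabilities
#'
#' @param df Separations to tabulate.
#' @param t Triplet indices.
#' @param config A [sampler_config()].
#' @param model A [spike_mean_model()].
#' @param empirical If `TRUE`, add one Monte-Carlo vote fraction per row.
#' @param seed Optional seed for the empirical draw.
#' @return A tibble with `t`, `df`, `p_0` (analytic) and, if requested,
#'   `p_s`, `p_i` (empirical).
#' @export
sampler_probability_table <- function(df = c(3, 5, 7), t = NULL,
                                      config = sampler_config(),
                                      model = spike_mean_model(),
                                      empirical = FALSE, seed = NULL) {
  if (is.null(t)) t <- seq_len(model$n_triplets)
  out <- purrr::map_dfr(df, function(d) {
    tibble(t = t, df = d,
           p_0 = segregation_probability(t, d, config, model))
  })
  if (empirical) {
    seeds <- derive_seeds(seed, nrow(out))
    emp <- purrr::map2_dbl(out$t, seq_len(nrow(out)), function(tt, i) {
      layer_step(tt, out$df[i], config, model, seed = seeds[i])$p_s
    })
    out$p_s <- emp
    out$p_i <- 1 - emp
  }
  out
}

#' Fit pool size and threshold to asymptotic buildup levels
#'
#' Grid search for the `(n_in, c_th)` pair minimising the summed squared
#' difference between the analytic segregation probability and per-DF target
#' levels over a late-triplet window (default: the last 30 triplets, i.e. the
#' final 15 s of a 60-triplet trial). Ties break towards the smallest
#' `n_in`, then the smallest `c_th`.
#'
#' @param targets Named numeric vector of asymptotic P(S) levels, names are
#'   DF values (e.g. `c("3" = 0.45, "5" = 0.6, "7" = 0.65)`).
#' @param n_in_grid,c_th_grid Candidate grids.
#' @param model A [spike_mean_model()].
#' @param triplets Triplet window over which the fit is evaluated.
#' @return A tibble with the best `n_in`, `c_th` and its `sse`, plus the
#'   full grid as attribute `"grid"`.
#' @export
fit_sampler_params <- function(targets = c("3" = 0.45, "5" = 0.6, "7" = 0.65),
                               n_in_grid = 2:10,
                               c_th_grid = seq(3.5, 5.5, by = 0.01),
                               model = spike_mean_model(),
                               triplets = 31:60) {
  if (length(n_in_grid) == 0 || length(c_th_grid) == 0) {
    abort("empty parameter grid")
  }
  stopifnot(all(targets > 0 & targets < 1), !is.null(names(targets)))
  dfs <- as.numeric(names(targets))
  grid <- tidyr::expand_grid(n_in = sort(n_in_grid), c_th = sort(c_th_grid))
  grid$sse <- purrr::map2_dbl(grid$n_in, grid$c_th, function(ni, ct) {
    cfg <- sampler_config(n_in = ni, c_th = ct)
    sum(vapply(seq_along(dfs), function(i) {
      p0 <- segregation_probability(triplets, dfs[i], cfg, model)
      sum((p0 - targets[i])^2)
    }, numeric(1)))
  })
  best <- grid %>% arrange(.data$sse, .data$n_in, .data$c_th) %>% slice(1)
  attr(best, "grid") <- grid
  best
}
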