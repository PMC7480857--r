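#' Default probability that the first percept is segregation
#'
#' Behavioural proportions of trials whose first reported percept was
#' segregation: 103, 137 and 220 out of 675 trials at DF = 3, 5 and 7.
#'
#' @param df Frequency separation in semitones (3, 5 or 7).
#' @return A probability.
#' @export
first_seg_probability <- function(df) {
  tab <- c(`3` = 103 / 675, `5` = 137 / 675, `7` = 220 / 675)
  key <- as.character(df)
  if (!key %in% names(tab)) {
    abort(paste0("no behavioural first-percept proportion for df = ", df,
                 "; supply p_first_seg explicitly"))
  }
  unname(tab[key])
}

#' Simulate one streaming trial
#'
#' Runs the full three-layer dynamics for one 30-s trial: the accumulators
#' sit at baseline through the latency period (triplets strictly before
#' `latency_triplets`); at `t = latency_triplets` the first percept label is
#' drawn (Bernoulli with probability `p_first_seg` of segregation) and the
#' accumulator dynamics begin. Each subsequent triplet draws sampler vote
#' fractions, updates both accumulators ([eva_step()]) and checks for a
#' threshold crossing ([detect_switch()]). Percept durations are the gaps,
#' in triplets, between successive crossings; the first duration is measured
#' from the end of latency to the first crossing, and the trailing interval
#' cut off by the end of the stimulus is flagged incomplete.
#'
#' @param df Frequency separation in semitones.
#' @param config An [accumulator_config()]; defaults to the per-DF table.
#' @param sampler A [sampler_config()].
#' @param model A [spike_mean_model()].
#' @param n_triplets Trial length in triplets.
#' @param p_first_seg Probability the first percept is S; behavioural
#'   default per DF.
#' @param seed Optional seed (the trial is fully reproducible given it).
#' @return A tibble with one row per percept interval: `label` ("I"/"S"),
#'   `ordinal` ("first"/"subsequent"), `start_triplet`, `n_triplets`,
#'   `duration_s`, `complete`. Attributes: `first_label`,
#'   `latency_triplets`, `df`.
#' @examples
#' run_trial(5, seed = 1)
#' @export
run_trial <- function(df,
                      config = accumulator_config(df),
                      sampler = sampler_config(),
                      model = spike_mean_model(),
                      n_triplets = model$n_triplets,
                      p_first_seg = first_seg_probability(df),
                      seed = NULL) {
  m <- vapply(seq_len(n_triplets), function(t) mean_spike_count(t, df, model),
              numeric(1))
  with_seed(seed, run_trial_impl(df, config, sampler, m, n_triplets,
                                 p_first_seg))
}

# core loop, assumes RNG state already set; `m` is the per-triplet mean table
run_trial_impl <- function(df, config, sampler, m, n_triplets, p_first_seg) {
  t_lat <- config$latency_triplets
  stopifnot(t_lat >= 1, t_lat < n_triplets)
  first_label <- if (runif(1) < p_first_seg) "S" else "I"
  state <- accumulator_state(first_label, config)
  labels <- character()
  ordinals <- character()
  starts <- integer()
  lengths <- integer()
  start <- t_lat
  for (t in t_lat:(n_triplets - 1)) {
    p_s <- draw_vote_fractions(m[t], sampler, 1)
    state <- eva_step(state, 1 - p_s, p_s, config)
    res <- detect_switch(state, config)
    if (res$switched) {
      labels <- c(labels, state$dominant) # label before flip
      ordinals <- c(ordinals, if (state$is_first) "first" else "subsequent")
      starts <- c(starts, start)
      lengths <- c(lengths, t + 1L - start)
      start <- t + 1L
      state <- res$state
    }
  }
  # trailing interval, truncated by the stimulus end
  labels <- c(labels, state$dominant)
  ordinals <- c(ordinals, if (state$is_first) "first" else "subsequent")
  starts <- c(starts, start)
  lengths <- c(lengths, n_triplets + 1L - start)
  out <- tibble(label = labels, ordinal = ordinals,
                start_triplet = starts, n_triplets = lengths,
                duration_s = lengths * 0.5,
                complete = c(rep(TRUE, length(labels) - 1L), FALSE))
  attr(out, "first_label") <- first_label
  attr(out, "latency_triplets") <- t_lat
  attr(out, "df") <- df
  out
}

#' Simulate a full experiment
#'
#' Runs `n_trials` independent trials (behavioural batch size: 675 per DF),
#' optionally replicated `n_mc` times as Monte-Carlo repeats of the whole
#' experiment. Each trial gets its own RNG stream derived from `seed`, so
#' results are reproducible and order-independent.
#'
#' @inheritParams run_trial
#' @param n_trials Trials per experiment.
#' @param n_mc Monte-Carlo replicates of the whole experiment.
#' @param seed Master seed.
#' @return A tibble of class `eva_experiment` with columns `replicate`,
#'   `trial`, `first_label`, plus the per-interval columns of [run_trial()].
#' @examples
#' ex <- run_experiment(5, n_trials = 20, seed = 1)
#' percept_durations(ex)
#' @export
run_experiment <- function(df,
                           n_trials = 675,
                           n_mc = 1,
                           config = accumulator_config(df),
                           sampler = sampler_config(),
                           model = spike_mean_model(),
                           n_triplets = model$n_triplets,
                           p_first_seg = first_seg_probability(df),
                           seed = NULL) {
  m <- vapply(seq_len(n_triplets), function(t) mean_spike_count(t, df, model),
              numeric(1))
  seeds <- matrix(derive_seeds(seed, n_trials * n_mc), nrow = n_trials)
  out <- purrr::map_dfr(seq_len(n_mc), function(rep) {
    purrr::map_dfr(seq_len(n_trials), function(i) {
      tr <- with_seed(seeds[i, rep],
                      run_trial_impl(df, config, sampler, m, n_triplets,
                                     p_first_seg))
      tr$replicate <- rep
      tr$trial <- i
      tr$first_label <- attr(tr, "first_label")
      tr
    })
  })
  out <- out %>%
    select("replicate", "trial", "first_label", dplyr::everything())
  class(out) <- c("eva_experiment", class(out))
  attr(out, "df") <- df
  attr(out, "n_trials") <- n_trials
  attr(out, "n_mc") <- n_mc
  attr(out, "n_triplets") <- n_triplets
  attr(out, "latency_triplets") <- config$latency_triplets
  attr(out, "seed") <- seed
  out
}

#' Completed percept durations of an experiment
#'
#' Drops intervals truncated by the end of the stimulus (and, defensively,
#' anything starting beyond it), which are excluded from all duration
#' statistics.
#'
#' @param x An `eva_experiment` or any tibble with `complete`,
#'   `start_triplet` columns.
#' @param n_triplets Stimulus length used for the defensive bound.
#' @return The filtered tibble.
#' @export
percept_durations <- function(x, n_triplets = attr(x, "n_triplets") %||% 60) {
  limit <- n_triplets # avoid masking by the n_triplets column
  x %>% filter(.data$complete, .data$start_triplet <= .env$limit)
}

#' Convert trials to binary percept time courses
#'
#' Codes each trial as a step function on the triplet grid: `NA` during the
#' latency period, 0 while integration is dominant and 1 while segregation
#' is dominant. The model is piecewise constant on 0.5-s triplets, so finer
#' resolutions only upsample.
#'
#' @param x An `eva_experiment` (or single-trial tibble from [run_trial()]).
#' @param resolution Sampling step in seconds; must divide 0.5.
#' @return A numeric matrix, one row per trial, `30 / resolution` columns;
#'   column times (s, interval midpoint convention: end of each sample) in
#'   attribute `"time_s"`.
#' @export
to_binary_timecourse <- function(x, resolution = 0.5) {
  if (abs(0.5 / resolution - round(0.5 / resolution)) > 1e-9) {
    abort("resolution must divide 0.5 s")
  }
  n_triplets <- attr(x, "n_triplets") %||% 60
  t_lat <- attr(x, "latency_triplets") %||% 4
  if (!"trial" %in% names(x)) {
    x$trial <- 1L
  }
  if (!"replicate" %in% names(x)) {
    x$replicate <- 1L
  }
  keys <- dplyr::distinct(as_tibble(x)[c("replicate", "trial")])
  per <- as.integer(round(0.5 / resolution))
  n_col <- n_triplets * per
  mat <- matrix(NA_real_, nrow = nrow(keys), ncol = n_col)
  grp <- dplyr::group_split(dplyr::group_by(as_tibble(x),
                                            .data$replicate, .data$trial))
  for (g in seq_along(grp)) {
    tr <- grp[[g]]
    v <- rep(NA_real_, n_triplets)
    for (k in seq_len(nrow(tr))) {
      idx <- seq(tr$start_triplet[k],
                 min(n_triplets, tr$start_triplet[k] + tr$n_triplets[k] - 1L))
      v[idx] <- if (tr$label[k] == "S") 1 else 0
    }
    mat[g, ] <- rep(v, each = per)
  }
  attr(mat, "time_s") <- seq_len(n_col) * resolution
  mat
}
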