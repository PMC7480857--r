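#' Mean spike-count model for A1-like input units
#'
#' Parameters of the triplet- and frequency-separation-dependent mean spike
#' count of tone-A-selective primary-auditory-cortex (A1) units responding to
#' the B tone of an `ABA_` triplet. Counts at the base frequency separations
#' (DF, in semitones) decay exponentially from a first-triplet value
#' `m_first[DF]` to an asymptote `m_asym[DF]`:
#'
#' \deqn{m_{t,DF} = m^*_{DF} + (m_{1,DF} - m^*_{DF})\, e^{-1.1 (t - 1)}}
#'
#' Values at non-base separations are obtained by per-triplet power-law
#' interpolation (see [interpolate_mean()]). The defaults are the multi-unit
#' macaque A1 estimates used throughout the simulator.
#'
#' @param base_df Base frequency separations in semitones at which first and
#'   asymptotic means are specified.
#' @param m_first Mean spike count at triplet 1 for each base DF
#'   (spikes/triplet).
#' @param m_asym Asymptotic mean spike count for each base DF
#'   (spikes/triplet).
#' @param decay_rate Exponential decay constant of adaptation, per triplet.
#' @param n_triplets Stimulus length in triplets (60 triplets = 30 s at
#'   500 ms per triplet).
#'
#' @return An object of class `spike_mean_model`.
#' @examples
#' model <- spike_mean_model()
#' mean_spike_count(1, 3, model) # 6.25 spikes/triplet
#' @export
spike_mean_model <- function(base_df = c(1, 3, 6, 9),
                             m_first = c(7.25, 6.25, 6, 5.25),
                             m_asym = c(6.09, 4.57, 3.95, 3.44),
                             decay_rate = 1.1,
                             n_triplets = 60) {
  stopifnot(length(base_df) == length(m_first),
            length(base_df) == length(m_asym))
  if (any(m_first <= m_asym)) {
    abort("adaptation must decrease counts: need m_first > m_asym at every base DF")
  }
  if (any(diff(m_asym[order(base_df)]) >= 0)) {
    abort("m_asym must strictly decrease with DF")
  }
  structure(
    list(base_df = as.numeric(base_df),
         m_first = as.numeric(m_first),
         m_asym = as.numeric(m_asym),
         decay_rate = decay_rate,
         n_triplets = as.integer(n_triplets)),
    class = "spike_mean_model"
  )
}

#' @export
print.spike_mean_model <- function(x, ...) {
  cat("<spike_mean_model>\n")
  cat("  base DF (st):", x$base_df, "\n")
  cat("  m_first     :", x$m_first, "\n")
  cat("  m_asym      :", x$m_asym, "\n")
  cat("  decay rate  :", x$decay_rate, "per triplet;",
      x$n_triplets, "triplets\n")
  invisible(x)
}

# exponential adaptation curve at a base DF; t may be a vector, Inf allowed
eq_decay <- function(t, i, model) {
  model$m_asym[i] +
    (model$m_first[i] - model$m_asym[i]) * exp(-model$decay_rate * (t - 1))
}

#' Mean spike count at a given triplet and frequency separation
#'
#' Evaluates the adaptation curve at the base separations and falls back to
#' power-law interpolation ([interpolate_mean()]) for separations strictly
#' inside the base range (e.g. DF = 5, 7 with the default base set 1, 3, 6,
#' 9). `t = Inf` returns the asymptote.
#'
#' @param t Triplet index (>= 1); vectorised.
#' @param df Frequency separation in semitones.
#' @param model A [spike_mean_model()].
#' @return Mean spike counts (spikes/triplet), same length as `t`.
#' @examples
#' mean_spike_count(Inf, 3) # 4.57
#' mean_spike_count(1:5, 5) # interpolated adaptation curve at DF = 5
#' @export
mean_spike_count <- function(t, df, model = spike_mean_model()) {
  stopifnot(length(df) == 1)
  if (any(t < 1)) abort("triplet index must be >= 1")
  if (df < min(model$base_df) || df > max(model$base_df)) {
    abort(paste0("df = ", df, " outside the modelled range [",
                 min(model$base_df), ", ", max(model$base_df), "]"))
  }
  i <- match(df, model$base_df)
  if (!is.na(i)) {
    eq_decay(t, i, model)
  } else {
    interpolate_mean(t, df, model)
  }
}

# closed-form log-log least squares power fit m = a * df^b to >= 2 points
power_fit <- function(df, m) {
  if (length(df) < 2) abort("power-law fit needs at least 2 base points")
  f <- lm.fit(cbind(1, log(df)), log(m))
  c(a = unname(exp(f$coefficients[1])), b = unname(f$coefficients[2]))
}

#' Power-law interpolation of mean spike counts across DF
#'
#' At a fixed triplet `t`, fits `m = a * DF^b` by ordinary least squares in
#' log-log space to the base-DF means and evaluates the fit at `df_query`.
#' This carries the adaptation curves measured at DF = 1, 3, 6, 9 over to the
#' intermediate separations (5 and 7 semitones) used in the behavioural
#' conditions.
#'
#' @param t Triplet index; vectorised (each triplet gets its own fit).
#' @param df_query Separation in semitones, strictly inside the base range.
#' @param model A [spike_mean_model()].
#' @return Interpolated mean spike counts, same length as `t`.
#' @export
interpolate_mean <- function(t, df_query, model = spike_mean_model()) {
  stopifnot(length(df_query) == 1)
  if (any(t < 1)) abort("triplet index must be >= 1")
  if (df_query <= min(model$base_df) || df_query >= max(model$base_df)) {
    abort("df_query must lie strictly inside the base DF range")
  }
  vapply(t, function(tt) {
    mb <- vapply(seq_along(model$base_df), function(i) eq_decay(tt, i, model),
                 numeric(1))
    cf <- power_fit(model$base_df, mb)
    cf[["a"]] * df_query^cf[["b"]]
  }, numeric(1))
}

#' Draw Poisson spike counts for a pool of input units
#'
#' Independent Poisson draws at rate `mean_spike_count(t, df, model)`,
#' mimicking trial-to-trial and unit-to-unit variability of the A1-like
#' input layer at one triplet.
#'
#' @param t Triplet index (scalar).
#' @param df Frequency separation in semitones.
#' @param n_units Number of units to draw.
#' @param model A [spike_mean_model()].
#' @param seed Optional seed for a reproducible draw.
#' @return Integer vector of length `n_units`.
#' @export
sample_counts <- function(t, df, n_units, model = spike_mean_model(),
                          seed = NULL) {
  stopifnot(length(t) == 1, n_units >= 1)
  rate <- mean_spike_count(t, df, model)
  if (rate < 0) abort("negative Poisson rate")
  with_seed(seed, rpois(n_units, rate))
}

#' Tabulate mean spike counts
#'
#' @param df Separations to tabulate.
#' @param t Triplet indices.
#' @param model A [spike_mean_model()].
#' @return A tibble with columns `t`, `df`, `mean` (spikes/triplet).
#' @export
spike_mean_table <- function(df = c(3, 5, 7), t = NULL,
                             model = spike_mean_model()) {
  if (is.null(t)) t <- seq_len(model$n_triplets)
  purrr::map_dfr(df, function(d) {
    tibble(t = t, df = d, mean = mean_spike_count(t, d, model))
  })
}
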