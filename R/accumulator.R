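#' Basic saturating-accumulator configuration
#'
#' The single-accumulator form of the model: activity drifts toward a
#' sub-threshold target `T` with state-dependent increments proportional to
#' `T - X` at rate `r`, plus Gaussian noise,
#' \deqn{X_{n+1} = X_n + (T - X_n) r + \varepsilon_{n+1}.}
#' Threshold crossings define percept durations; after a crossing the state
#' resets to `x_reset`.
#'
#' @param target Saturation target `T` (sub-threshold in the saturating
#'   regime).
#' @param rate Increment rate `r` in (0, 1).
#' @param sigma Noise standard deviation.
#' @param x0 Initial value.
#' @param x_reset Reset value after a threshold crossing.
#' @param threshold Decision threshold (1 by convention).
#' @return An object of class `basic_accumulator_config`.
#' @export
basic_accumulator_config <- function(target = 0.9, rate = 0.6, sigma = 0.085,
                                     x0 = 0.7, x_reset = 0.6, threshold = 1) {
  stopifnot(rate > 0, rate < 1, sigma >= 0)
  structure(list(target = target, rate = rate, sigma = sigma, x0 = x0,
                 x_reset = x_reset, threshold = threshold),
            class = "basic_accumulator_config")
}

#' One step of the basic accumulator
#'
#' @param x Current activity; vectorised (independent noise per element).
#' @param config A [basic_accumulator_config()].
#' @param seed Optional seed.
#' @return Next activity value(s).
#' @export
basic_step <- function(x, config = basic_accumulator_config(), seed = NULL) {
  with_seed(seed,
            x + (config$target - x) * config$rate +
              rnorm(length(x), 0, config$sigma))
}

# Per-DF target-against tables, fine-tuned per percept class:
# aI1 = against integration, first percept; aS1 = against segregation, first;
# aI2/aS2 = the subsequent-percept analogues.
target_against_defaults <- function() {
  list(`3` = c(aI1 = 0.8273, aS1 = 0.9273, aI2 = 0.8924, aS2 = 0.8924),
       `5` = c(aI1 = 0.9000, aS1 = 0.8909, aI2 = 0.9288, aS2 = 0.9106),
       `7` = c(aI1 = 0.9348, aS1 = 0.8773, aI2 = 0.9242, aS2 = 0.9318))
}

#' Two-accumulator (EVA) configuration
#'
#' Parameters of the accumulation layer: two units gather evidence for and
#' against the current percept. The "against" unit targets a class-dependent
#' level `t_against` just below the decision threshold under noise
#' `sigma_against`; the "for" unit targets the lower `t_for` under weaker
#' noise `sigma_for`, so switches are (almost surely) triggered by the
#' against-unit. `t_against` is a named vector with entries `aI1`, `aS1`,
#' `aI2`, `aS2` (against integration/segregation, first/subsequent percept);
#' per-DF defaults are built in.
#'
#' @param df Frequency separation in semitones (3, 5 or 7) selecting the
#'   default target table; ignored when `t_against` is supplied.
#' @param t_against Named numeric vector `c(aI1=, aS1=, aI2=, aS2=)`.
#' @param t_for Target of the evidence-for accumulator.
#' @param sigma_against,sigma_for Noise standard deviations.
#' @param baseline Common accumulator value held during the latency period.
#' @param threshold Decision threshold.
#' @param latency_triplets Latency length in triplets (4 triplets = 2 s).
#' @param drift_dominated Set `TRUE` to permit supra-threshold targets
#'   (`t_against >= threshold`); otherwise they are rejected, since the
#'   saturating regime assumes all targets sub-threshold.
#' @return An object of class `accumulator_config`.
#' @export
accumulator_config <- function(df = 5,
                               t_against = NULL,
                               t_for = 0.6,
                               sigma_against = 0.085,
                               sigma_for = 0.03,
                               baseline = 0.7,
                               threshold = 1,
                               latency_triplets = 4,
                               drift_dominated = FALSE) {
  if (is.null(t_against)) {
    tab <- target_against_defaults()
    key <- as.character(df)
    if (!key %in% names(tab)) {
      abort(paste0("no default target table for df = ", df,
                   "; supply t_against explicitly"))
    }
    t_against <- tab[[key]]
  }
  stopifnot(all(c("aI1", "aS1", "aI2", "aS2") %in% names(t_against)))
  if (sigma_against <= sigma_for) {
    abort("sigma_against must exceed sigma_for")
  }
  if (!drift_dominated && any(t_against >= threshold)) {
    abort("t_against must be sub-threshold (set drift_dominated = TRUE to override)")
  }
  if (any(t_for >= t_against)) {
    abort("t_for must lie below every t_against")
  }
  structure(list(df = df, t_against = t_against, t_for = t_for,
                 sigma_against = sigma_against, sigma_for = sigma_for,
                 baseline = baseline, threshold = threshold,
                 latency_triplets = as.integer(latency_triplets),
                 drift_dominated = drift_dominated),
            class = "accumulator_config")
}

#' @export
print.accumulator_config <- function(x, ...) {
  cat("<accumulator_config> df =", x$df, "\n")
  cat("  t_against:", paste(names(x$t_against), sprintf("%.4f", x$t_against),
                            collapse = ", "), "\n")
  cat("  t_for =", x$t_for, " sigma_a =", x$sigma_against,
      " sigma_f =", x$sigma_for, "\n")
  cat("  baseline =", x$baseline, " threshold =", x$threshold,
      " latency =", x$latency_triplets, "triplets\n")
  invisible(x)
}

#' Initial accumulator state
#'
#' @param dominant First percept label, `"I"` or `"S"`.
#' @param config An [accumulator_config()].
#' @return A list with accumulator values `x_i`, `x_s`, the `dominant`
#'   percept, and `is_first` (whether the current percept is the trial's
#'   first).
#' @export
accumulator_state <- function(dominant = "I", config = accumulator_config()) {
  stopifnot(dominant %in% c("I", "S"))
  list(x_i = config$baseline, x_s = config$baseline,
       dominant = dominant, is_first = TRUE)
}

# target of the against-accumulator for the current state
current_t_against <- function(state, config) {
  key <- paste0("a", state$dominant, if (state$is_first) "1" else "2")
  unname(config$t_against[key])
}

#' One step of the two-accumulator dynamics
#'
#' Both accumulators are updated with state-dependent increments
#' \deqn{x(t+1) = x(t) + (T - x(t))\, p(t) + \sigma \xi(t)}
#' where during dominant integration the segregation accumulator plays the
#' "against" role (target `t_against`, noise `sigma_against`, increment rate
#' `p_s`) and the integration accumulator the "for" role (target `t_for`,
#' noise `sigma_for`, rate `p_i`); roles swap during dominant segregation.
#' Noise draws are independent between accumulators. The for-accumulator is
#' clamped just below threshold, since crossings by the evidence-for unit are
#' disregarded.
#'
#' @param state A state as from [accumulator_state()].
#' @param p_i,p_s Sampler-layer vote fractions (must sum to 1).
#' @param config An [accumulator_config()].
#' @param seed Optional seed.
#' @return The updated state (switch detection is separate; see
#'   [detect_switch()]).
#' @export
eva_step <- function(state, p_i, p_s, config = accumulator_config(),
                     seed = NULL) {
  if (abs(p_i + p_s - 1) > 1e-12) abort("p_i + p_s must equal 1")
  t_a <- current_t_against(state, config)
  with_seed(seed, {
    xi <- rnorm(2)
    if (state$dominant == "I") {
      x_s <- state$x_s + (t_a - state$x_s) * p_s + config$sigma_against * xi[1]
      x_i <- state$x_i + (config$t_for - state$x_i) * p_i +
        config$sigma_for * xi[2]
      if (x_i >= config$threshold) x_i <- config$threshold - 1e-9
    } else {
      x_i <- state$x_i + (t_a - state$x_i) * p_i + config$sigma_against * xi[1]
      x_s <- state$x_s + (config$t_for - state$x_s) * p_s +
        config$sigma_for * xi[2]
      if (x_s >= config$threshold) x_s <- config$threshold - 1e-9
    }
    state$x_i <- x_i
    state$x_s <- x_s
    state
  })
}

#' Detect a threshold crossing and reset
#'
#' If the against-accumulator has reached the decision threshold, the
#' dominant percept flips, both accumulators reset to the value the
#' evidence-for accumulator held just before the switch, and the current
#' percept stops being "first". Crossings by the for-accumulator never
#' trigger a switch (they are clamped in [eva_step()]).
#'
#' @param state A state as updated by [eva_step()].
#' @param config An [accumulator_config()].
#' @return A list with `switched` (logical) and the (possibly reset)
#'   `state`.
#' @export
detect_switch <- function(state, config = accumulator_config()) {
  against <- if (state$dominant == "I") state$x_s else state$x_i
  for_val <- if (state$dominant == "I") state$x_i else state$x_s
  if (against >= config$threshold) {
    state$x_i <- for_val
    state$x_s <- for_val
    state$dominant <- if (state$dominant == "I") "S" else "I"
    state$is_first <- FALSE
    list(switched = TRUE, state = state)
  } else {
    list(switched = FALSE, state = state)
  }
}

#' Closed-form AR(1) moments of an accumulator after a switch
#'
#' Under constant increment rate `p`, each accumulator follows a stationary
#' first-order autoregressive process with parameter `lambda = 1 - p`:
#' starting from `t_f` at the switch, after `n` triplets the state is normal
#' with mean `T - (T - t_f) lambda^n` and variance
#' `sigma^2 (1 - lambda^(2n)) / (1 - lambda^2)`.
#'
#' @param t_target Target of the accumulator (e.g. `t_against`).
#' @param t_f Reset/starting value (the for-target).
#' @param p Increment rate in (0, 1).
#' @param sigma Noise standard deviation.
#' @param n Triplets since the switch (vectorised, >= 0).
#' @return A tibble with columns `n`, `mean`, `var`, `lambda`.
#' @export
ar1_moments <- function(t_target, t_f, p, sigma, n) {
  if (p <= 0 || p >= 1) abort("increment rate p must lie in (0, 1)")
  if (any(n < 0)) abort("n must be >= 0")
  lam <- 1 - p
  tibble(n = n,
         mean = t_target - (t_target - t_f) * lam^n,
         var = sigma^2 * (1 - lam^(2 * n)) / (1 - lam^2),
         lambda = lam)
}

#' Lower bound on the switching noise level
#'
#' With the against-accumulator saturating at `t_a < 1` and stationary
#' standard deviation at most `sigma / sqrt(1 - p_m^2)`, requiring the
#' threshold to lie within three stationary standard deviations of the
#' target gives the necessary condition
#' \deqn{\sigma_{a,min} = (1 - T_a)\sqrt{1 - p_M^2}/3}
#' where `p_m` is the largest of `p_seg` and `1 - p_seg` across conditions.
#' Below this bound switches are vanishingly rare.
#'
#' @param t_a Target-against level (< 1).
#' @param p_m Maximal increment rate, in (0, 1).
#' @return The noise lower bound.
#' @examples
#' sigma_min(0.9, 0.75) # ~ 0.022
#' @export
sigma_min <- function(t_a, p_m) {
  stopifnot(all(t_a <= 1), all(p_m > 0 & p_m < 1))
  (1 - t_a) * sqrt(1 - p_m^2) / 3
}
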