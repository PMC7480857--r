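#' Behavioural reference statistics
#'
#' Group-mean percept durations from the behavioural task (15 subjects, 675
#' trials per condition), the gamma shapes of the normalized duration
#' distributions (about 2 for first percepts, 2.6 for subsequent ones), and
#' an approximate standard error reconstructed from the scaling
#' `SE = CV * mean / sqrt(15)` with CV 0.7 (first) / 0.6 (subsequent) —
#' subject-level SDs are not available, so `se_exp` is an approximation and
#' flagged as such.
#'
#' @return A tibble with `df`, `label`, `ordinal`, `mu_exp` (s),
#'   `alpha_exp`, `se_exp` (s), `se_approx` (always `TRUE`).
#' @export
reference_stats <- function() {
  out <- tibble(
    df = rep(c(3, 5, 7), times = 4),
    label = rep(c("I", "S", "I", "S"), each = 3),
    ordinal = rep(c("first", "subsequent"), each = 6),
    mu_exp = c(10.9, 5.3, 3.1,
               3.5, 6.6, 8.1,
               5.4, 3.4, 3.1,
               4.9, 5.2, 5.6)
  )
  out$alpha_exp <- ifelse(out$ordinal == "first", 2, 2.6)
  cv <- ifelse(out$ordinal == "first", 0.7, 0.6)
  out$se_exp <- cv * out$mu_exp / sqrt(15)
  out$se_approx <- TRUE
  out
}

#' Classify the shape of a duration distribution
#'
#' Region labels of the two-parameter response diagrams: `"G"` when the
#' fitted gamma shape is within a relative tolerance of the behavioural
#' shape (20%, relaxed to 30% for integration at DF = 7 where the
#' admissible band is very narrow), `"E"` (exponential-like) for shapes at
#' or below `e_max`, `"N"` (normal-like) at or above `n_min`, otherwise
#' `"other"`. The E and N cutoffs are quantitative stand-ins for "near 1"
#' and "much greater than 3".
#'
#' @param alpha Fitted gamma shape(s); vectorised.
#' @param alpha_exp Behavioural reference shape.
#' @param rel_tol Relative tolerance of the G band.
#' @param e_max,n_min Region cutoffs.
#' @return Character vector of labels.
#' @export
classify_region <- function(alpha, alpha_exp, rel_tol = 0.2,
                            e_max = 1.3, n_min = 6) {
  stopifnot(all(alpha > 0))
  dplyr::case_when(
    abs(alpha / alpha_exp - 1) <= rel_tol ~ "G",
    alpha <= e_max ~ "E",
    alpha >= n_min ~ "N",
    TRUE ~ "other"
  )
}

#' Two-parameter response diagram of the accumulation dynamics
#'
#' Sweeps the target-against level and its noise over a grid, running one
#' reduced experiment per cell and summarising the durations of a chosen
#' percept class: mean duration, fitted gamma shape, switch count, region
#' label, and the ratio of simulated to behavioural mean. In each cell the
#' whole `t_against` table is set to the cell's `t_a` (as when mapping the
#' response diagram) and `sigma_against` to the cell's `sigma_a`. Cells
#' with too few completed percepts are labelled `"na"`.
#'
#' @param df Frequency separation.
#' @param label,ordinal Percept class summarised (`"I"`/`"S"`,
#'   `"first"`/`"subsequent"`).
#' @param t_a_grid,sigma_a_grid Grids for target-against and its noise.
#' @param n_trials Trials per cell (reduced by default for speed).
#' @param refs Reference tibble as from [reference_stats()].
#' @param min_switches Completed-percept floor below which a cell is `"na"`.
#' @param rel_tol G-band tolerance passed to [classify_region()].
#' @param sampler,model Layer configurations.
#' @param seed Master seed; cell seeds are derived from it.
#' @return A tibble of class `eva_sweep` with one row per grid cell:
#'   `df`, `label`, `ordinal`, `t_a`, `sigma_a`, `mu`, `alpha`,
#'   `n_switches`, `region`, `mu_ratio`, `within_1se`.
#' @export
sweep_eva <- function(df, label = "I", ordinal = "subsequent",
                      t_a_grid, sigma_a_grid,
                      n_trials = 200,
                      refs = reference_stats(),
                      min_switches = 5,
                      rel_tol = 0.2,
                      sampler = sampler_config(),
                      model = spike_mean_model(),
                      seed = NULL) {
  if (length(t_a_grid) == 0 || length(sigma_a_grid) == 0) {
    abort("empty sweep grid")
  }
  ref <- refs %>%
    filter(.data$df == !!df, .data$label == !!label,
           .data$ordinal == !!ordinal)
  if (nrow(ref) != 1) abort("no unique reference row for this percept class")
  grid <- tidyr::expand_grid(t_a = t_a_grid, sigma_a = sigma_a_grid)
  seeds <- derive_seeds(seed, nrow(grid))
  cells <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    ta <- grid$t_a[i]
    sa <- grid$sigma_a[i]
    cfg <- accumulator_config(
      df = df,
      t_against = c(aI1 = ta, aS1 = ta, aI2 = ta, aS2 = ta),
      sigma_against = sa,
      # the for-noise must stay below the swept against-noise; it only
      # jitters the sub-threshold for-accumulator and is otherwise inert
      sigma_for = min(0.03, sa / 3),
      drift_dominated = ta >= 1
    )
    ex <- run_experiment(df, n_trials = n_trials, config = cfg,
                         sampler = sampler, model = model, seed = seeds[i])
    durs <- percept_durations(ex) %>%
      filter(.data$label == !!label, .data$ordinal == !!ordinal)
    n_sw <- nrow(durs)
    if (n_sw < min_switches) {
      return(tibble(t_a = ta, sigma_a = sa, mu = NA_real_, alpha = NA_real_,
                    n_switches = n_sw, region = "na", mu_ratio = NA_real_,
                    within_1se = NA))
    }
    mu <- mean(durs$duration_s)
    fit <- gamma_mle(normalize_durations(durs)$d_tilde)
    tibble(t_a = ta, sigma_a = sa, mu = mu, alpha = fit$alpha,
           n_switches = n_sw,
           region = classify_region(fit$alpha, ref$alpha_exp, rel_tol),
           mu_ratio = mu / ref$mu_exp,
           within_1se = abs(mu - ref$mu_exp) <= ref$se_exp)
  })
  out <- dplyr::bind_cols(tibble(df = df, label = label, ordinal = ordinal),
                          cells)
  class(out) <- c("eva_sweep", class(out))
  attr(out, "ref") <- ref
  out
}

#' Select a target-against level from a sweep
#'
#' The tuning rule for the target-against level: among sweep cells whose
#' mean duration is within 10% of one behavioural standard error of the
#' reference mean, pick the one whose fitted shape is closest to the
#' reference shape; ties break towards the smaller target. If no cell
#' qualifies, the nearest misses by `|mu - mu_exp|` are returned with
#' attribute `"matched"` set to `FALSE`.
#'
#' @param sweep An `eva_sweep` tibble.
#' @param refs Reference tibble as from [reference_stats()].
#' @param se_frac Fraction of the standard error admitted (0.1 = 10% SE).
#' @param n_nearest Nearest misses reported when no cell qualifies.
#' @return A one-row tibble (or `n_nearest` rows of diagnostics) with
#'   attribute `"matched"`.
#' @export
select_t_a <- function(sweep, refs = reference_stats(), se_frac = 0.1,
                       n_nearest = 3) {
  ref <- refs %>%
    filter(.data$df == sweep$df[1], .data$label == sweep$label[1],
           .data$ordinal == sweep$ordinal[1])
  if (nrow(ref) != 1) abort("no unique reference row for this sweep")
  ok <- sweep %>%
    filter(!is.na(.data$mu),
           abs(.data$mu - ref$mu_exp) <= se_frac * ref$se_exp)
  if (nrow(ok) > 0) {
    out <- ok %>%
      mutate(shape_err = abs(.data$alpha - ref$alpha_exp)) %>%
      arrange(.data$shape_err, .data$t_a) %>%
      slice(1)
    attr(out, "matched") <- TRUE
  } else {
    out <- sweep %>%
      filter(!is.na(.data$mu)) %>%
      mutate(mu_err = abs(.data$mu - ref$mu_exp)) %>%
      arrange(.data$mu_err) %>%
      slice(seq_len(min(n_nearest, dplyr::n())))
    attr(out, "matched") <- FALSE
  }
  out
}
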