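#' Full run configuration
#'
#' Bundles the layer configurations, experiment settings and master seed
#' into one serializable object. Every default is the value used for the
#' reference simulations (pool size 5, threshold 4.21 spikes/triplet, 20
#' samplers, baseline 0.7, for-target 0.6, noise 0.085/0.03, decision
#' threshold 1, per-DF target-against tables, 675 trials of 60 triplets).
#'
#' @param df Frequency separation in semitones.
#' @param model A [spike_mean_model()].
#' @param sampler A [sampler_config()].
#' @param accumulator An [accumulator_config()].
#' @param n_trials,n_mc,n_triplets Experiment dimensions.
#' @param p_first_seg Probability the first percept is S.
#' @param seed Master seed (optional).
#' @return An object of class `eva_config`.
#' @export
eva_config <- function(df = 5,
                       model = spike_mean_model(),
                       sampler = sampler_config(),
                       accumulator = accumulator_config(df),
                       n_trials = 675,
                       n_mc = 1,
                       n_triplets = model$n_triplets,
                       p_first_seg = first_seg_probability(df),
                       seed = NULL) {
  stopifnot(inherits(model, "spike_mean_model"),
            inherits(sampler, "sampler_config"),
            inherits(accumulator, "accumulator_config"))
  structure(list(df = df, model = model, sampler = sampler,
                 accumulator = accumulator, n_trials = n_trials,
                 n_mc = n_mc, n_triplets = n_triplets,
                 p_first_seg = p_first_seg, seed = seed),
            class = "eva_config")
}

#' @export
print.eva_config <- function(x, ...) {
  cat("<eva_config> df =", x$df, ";", x$n_trials, "trials x",
      x$n_triplets, "triplets;", x$n_mc, "replicate(s)\n")
  print(x$sampler)
  print(x$accumulator)
  invisible(x)
}

# known YAML keys per block, used for schema validation
config_schema <- function() {
  list(df = NULL, n_trials = NULL, n_mc = NULL, n_triplets = NULL,
       p_first_seg = NULL, seed = NULL,
       model = c("base_df", "m_first", "m_asym", "decay_rate", "n_triplets"),
       sampler = c("n_in", "c_th", "n_sl"),
       accumulator = c("t_against", "t_for", "sigma_against", "sigma_for",
                       "baseline", "threshold", "latency_triplets",
                       "drift_dominated"))
}

#' Read a run configuration from YAML
#'
#' Missing blocks or keys fall back to the defaults; unknown keys are
#' rejected with an error naming the offending key. `read_eva_config(NULL)`
#' returns the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for defaults.
#' @return An [eva_config()].
#' @export
read_eva_config <- function(path = NULL) {
  if (is.null(path)) return(eva_config())
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  bad <- setdiff(names(raw), names(schema))
  if (length(bad) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  for (block in c("model", "sampler", "accumulator")) {
    bad <- setdiff(names(raw[[block]]), schema[[block]])
    if (length(bad) > 0) {
      abort(paste0("unknown key(s) in '", block, "': ",
                   paste(bad, collapse = ", ")))
    }
  }
  df <- raw$df %||% 5
  model <- do.call(spike_mean_model, raw$model %||% list())
  sampler <- do.call(sampler_config, raw$sampler %||% list())
  acc_args <- raw$accumulator %||% list()
  if (!is.null(acc_args$t_against)) {
    acc_args$t_against <- unlist(acc_args$t_against)
  }
  accumulator <- do.call(accumulator_config, c(list(df = df), acc_args))
  eva_config(df = df, model = model, sampler = sampler,
             accumulator = accumulator,
             n_trials = raw$n_trials %||% 675,
             n_mc = raw$n_mc %||% 1,
             n_triplets = raw$n_triplets %||% model$n_triplets,
             p_first_seg = raw$p_first_seg %||% first_seg_probability(df),
             seed = raw$seed)
}

#' Write a run configuration to YAML
#'
#' @param config An [eva_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eva_config <- function(config, path) {
  stopifnot(inherits(config, "eva_config"))
  out <- list(
    df = config$df,
    n_trials = config$n_trials,
    n_mc = config$n_mc,
    n_triplets = config$n_triplets,
    p_first_seg = config$p_first_seg,
    seed = config$seed,
    model = unclass(config$model),
    sampler = unclass(config$sampler),
    accumulator = local({
      acc <- unclass(config$accumulator)
      acc$t_against <- as.list(acc$t_against)
      acc$df <- NULL
      acc
    })
  )
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run the configured experiment
#'
#' @param config An [eva_config()].
#' @param seed Overrides the configured seed if given.
#' @return An `eva_experiment` tibble (see [run_experiment()]).
#' @export
run_config <- function(config = eva_config(), seed = NULL) {
  run_experiment(config$df,
                 n_trials = config$n_trials,
                 n_mc = config$n_mc,
                 config = config$accumulator,
                 sampler = config$sampler,
                 model = config$model,
                 n_triplets = config$n_triplets,
                 p_first_seg = config$p_first_seg,
                 seed = seed %||% config$seed)
}

#' Write the standard result file set
#'
#' Serializes whatever result objects are supplied: percept durations
#' (CSV), gamma fits (JSON), buildup curves (TSV), sweep grids (CSV), plus
#' a run-metadata JSON with the master seed, a configuration hash and the
#' package version. Numbers are written at full double precision. Empty
#' result sets produce headers-only files.
#'
#' @param results Named list with any of `durations`, `fits` (named list of
#'   `gamma_fit` objects or a tibble), `buildup`, `sweep`.
#' @param dir Output directory (created if needed).
#' @param config Optional [eva_config()] recorded in the metadata.
#' @param seed Master seed recorded in the metadata.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(results, dir, config = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(obj, file, sep = ",") {
    path <- file.path(dir, file)
    utils::write.table(obj, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(results$durations)) {
    emit(results$durations, "durations.csv")
  }
  if (!is.null(results$buildup)) {
    emit(results$buildup, "buildup.tsv", sep = "\t")
  }
  if (!is.null(results$sweep)) {
    emit(results$sweep, "sweep.csv")
  }
  if (!is.null(results$fits)) {
    fits <- results$fits
    if (is.list(fits) && !is.data.frame(fits)) {
      fits <- purrr::map_dfr(fits, glance, .id = "cell")
    }
    path <- file.path(dir, "fits.json")
    jsonlite::write_json(fits, path, digits = NA, auto_unbox = TRUE)
    written <- c(written, path)
  }
  meta <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("evastream")),
    config_hash = if (!is.null(config)) rlang::hash(config) else NULL,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))], meta_path,
                       auto_unbox = TRUE)
  written <- c(written, meta_path)
  invisible(written)
}
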