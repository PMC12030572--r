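#' Configuration of the end-to-end pipeline run
#'
#' One object holding every stage parameter of [run_pipeline()], so a run is
#' fully described (and reproducible) by its configuration.
#'
#' @param seed Integer seed used for every source of randomness in the run.
#' @param synthetic Named list of overrides passed to [synthetic_config()]
#'   (the `seed` field is taken from `seed`).
#' @param window,iterations Baseline-correction parameters, see
#'   [baseline_params()].
#' @param normalize Normalization method, see [normalize_spectra()].
#' @param outlier_population Population for the box-plot outlier flags
#'   (`"all"` = pooled, the single-box-plot convention).
#' @param map_population Quartile population used for the heat maps and the
#'   region enrichment (`"per_leaf"` default, matching the cleansing step).
#' @param q Cleansing quantile, default 0.25 (lower quartile).
#' @param cleanse_population Population for the cleansing threshold.
#' @param cleansing Logical: run the cleansing + before/after comparison
#'   stages.
#' @param kfold,lv_max,tau Model-selection parameters, see [select_lvs()].
#' @param include_pooled Also model all durations pooled.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            synthetic = list(),
                            window = 31L, iterations = 5L,
                            normalize = "minmax",
                            outlier_population = "all",
                            map_population = "per_leaf",
                            q = 0.25,
                            cleanse_population = "per_leaf",
                            cleansing = TRUE,
                            kfold = 5L, lv_max = 15L, tau = 0.5,
                            include_pooled = FALSE) {
  cfg <- list(seed = as.integer(seed), synthetic = synthetic,
              window = as.integer(window), iterations = as.integer(iterations),
              normalize = normalize,
              outlier_population = outlier_population,
              map_population = map_population,
              q = q, cleanse_population = cleanse_population,
              cleansing = isTRUE(cleansing),
              kfold = as.integer(kfold), lv_max = as.integer(lv_max),
              tau = tau, include_pooled = isTRUE(include_pooled))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    stop("read_pipeline_config: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Run the full position-selection pipeline
#'
#' Orchestrates simulate, preprocess, validate, similarity, map, cleanse and
#' model stages on one synthetic dataset: generates the leaf scans, applies
#' the preprocessing chain, scores every position against its leaf mean,
#' flags box-plot outliers and below-quartile positions, maps them onto the
#' leaf grids with region enrichment, removes the per-leaf below-quartile
#' spectra, and evaluates the PLS-DA deficiency classifier before and after
#' that cleansing. Deterministic per seed.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: list with `config`, `validation`,
#'   `similarity_summary`, `outlier_tab`, `below_q1_tab`, `enrichment`,
#'   `cleansing` (rule + per-leaf counts; `NULL` when disabled) and
#'   `comparison` (model rows + deltas; `NULL` when disabled).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  syn_args <- config$synthetic
  syn_args$seed <- config$seed
  sim <- generate_dataset(do.call(synthetic_config, syn_args))

  params <- baseline_params(config$window, config$iterations)
  pre <- preprocess_spectra(sim$set, params, method = config$normalize)
  validation <- validate_dataset(pre, sim$grids)

  sims <- similarity_table(pre)
  pooled <- boxplot_outliers(sims, population = config$outlier_population)
  per_leaf <- boxplot_outliers(sims, population = config$map_population)

  maps <- lapply(sim$grids, function(g) build_similarity_map(per_leaf, g))
  enrichment <- region_enrichment(maps)

  cleansing <- NULL; comparison <- NULL
  if (config$cleansing) {
    cleansing <- cleanse(pre, sims, q = config$q,
                         population = config$cleanse_population)
    comparison <- before_after_comparison(
      pre, cleansing$kept, k = config$kfold, lv_max = config$lv_max,
      tau = config$tau, include_pooled = config$include_pooled)
  } else {
    comparison <- list(
      models = do.call(rbind, lapply(DURATION_LEVELS, function(d)
        duration_model_row(subset_spectra(pre, pre$meta$duration_h == d),
                           as.character(d), "raw", k = config$kfold,
                           lv_max = config$lv_max, tau = config$tau))),
      deltas = NULL)
    class(comparison) <- "comparison_report"
  }

  structure(list(config = config,
                 validation = validation,
                 similarity_summary = attr(pooled, "summary"),
                 outlier_tab = tabulate_flags(pooled, "is_outlier"),
                 below_q1_tab = tabulate_flags(pooled, "below_q1"),
                 enrichment = enrichment,
                 maps = maps,
                 cleansing = if (is.null(cleansing)) NULL else
                   list(rule = cleansing$rule,
                        per_leaf = cleansing$per_leaf,
                        n_excluded = length(cleansing$excluded_ids)),
                 comparison = comparison),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$config$seed, "\n", sep = "")
  cat("spectra: ", x$validation$n_spectra, " | similarity mean ",
      sprintf("%.5f", x$similarity_summary$mean[1]), " sd ",
      sprintf("%.5f", x$similarity_summary$sd[1]), " | outliers ",
      x$outlier_tab["Total", "Total"], " | below-Q1 ",
      x$below_q1_tab["Total", "Total"], "\n", sep = "")
  print(x$enrichment, digits = 3)
  if (!is.null(x$cleansing))
    cat("cleansing: ", x$cleansing$n_excluded, " spectra excluded (",
        x$cleansing$rule, ")\n", sep = "")
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' Writes every section of the report (maps reduced to their flagged-cell
#' counts) as JSON; contains no timestamps, so identical configurations
#' yield byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  payload <- list(
    config = unclass(report$config),
    n_spectra = report$validation$n_spectra,
    tabulation = as.data.frame(as.table(report$validation$tabulation)),
    similarity_summary = report$similarity_summary,
    outlier_tab = as.data.frame(as.table(report$outlier_tab)),
    below_q1_tab = as.data.frame(as.table(report$below_q1_tab)),
    enrichment = report$enrichment,
    flagged_cells = vapply(report$maps, function(m) sum(m$flagged), 1L),
    cleansing = report$cleansing,
    models = report$comparison$models,
    deltas = report$comparison$deltas)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
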