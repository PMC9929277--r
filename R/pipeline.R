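#' Derive stage seeds from a master seed
#'
#' @param master Master seed (integer).
#' @param n Number of seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
derive_seeds <- function(master, n) {
  set.seed(master)
  sample.int(2147483646L, n)
}

#' Study run configuration
#'
#' A single structured configuration for an end-to-end run: scenario
#' generator settings, labelling parameters, the resampling variants, the
#' model families, the cross-validation protocol, and explanation
#' settings, all driven by one master seed.
#'
#' @param seed Master seed.
#' @param weather A [weather_config()].
#' @param labeling A [labeling_config()].
#' @param mixing_days Days with mixing/stacking.
#' @param variants Dataset variants to evaluate, a subset of
#'   `c("original", "oversampled", "smote", "undersampled")`.
#' @param families Model families to evaluate.
#' @param n_trees Trees per ensemble (forest and boosting).
#' @param k Cross-validation folds.
#' @param leakage_mode Resampling placement (see [cross_validate()]).
#' @param positive Positive class for the metrics.
#' @param shap_method,shap_samples Explanation settings (see
#'   [shap_values()]).
#' @param out_dir Output directory for [run_study()] (`NULL` = no files).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, weather = weather_config(),
                       labeling = labeling_config(), mixing_days = 1:5,
                       variants = c("original", "oversampled", "smote",
                                    "undersampled"),
                       families = c("decision_tree", "random_forest",
                                    "gradient_boosting"),
                       n_trees = 100, k = 10,
                       leakage_mode = "resample_before_cv", positive = 1,
                       shap_method = "sampling", shap_samples = 200,
                       out_dir = NULL) {
  if (weather$n_days < 1) stop("scenario needs at least one day", call. = FALSE)
  variants <- match.arg(variants, several.ok = TRUE)
  families <- match.arg(families, several.ok = TRUE)
  structure(list(seed = seed, weather = weather, labeling = labeling,
                 mixing_days = mixing_days, variants = variants,
                 families = families, n_trees = n_trees, k = k,
                 leakage_mode = leakage_mode, positive = positive,
                 shap_method = shap_method, shap_samples = shap_samples,
                 out_dir = out_dir),
            class = "run_config")
}

resampler_for <- function(variant) {
  switch(variant,
         original = NULL,
         oversampled = function(tab, seed) random_oversample(tab, seed),
         smote = function(tab, seed) smote(tab, seed = seed),
         undersampled = function(tab, seed) random_undersample(tab, seed))
}

#' Reproduce the four-experiment comparison on a feature table
#'
#' Runs the study protocol — each model family under k-fold
#' cross-validation on the original table and on its oversampled, SMOTE
#' and under-sampled variants — and collects the aggregate metrics.
#'
#' @param table A feature table (e.g. `simulate_dataset(seed)$table`).
#' @param seed Master seed for fold assignment and model fits.
#' @param variants,families,n_trees,k,leakage_mode,positive As in
#'   [run_config()].
#' @return A list with `summary` (data frame of aggregate metrics per
#'   variant and family) and `reports` (nested list of
#'   [cross_validate()] reports, `reports[[variant]][[family]]`).
#' @export
reproduce_experiments <- function(table, seed = 1,
                                  variants = c("original", "oversampled",
                                               "smote", "undersampled"),
                                  families = c("decision_tree",
                                               "random_forest",
                                               "gradient_boosting"),
                                  n_trees = 100, k = 10,
                                  leakage_mode = "resample_before_cv",
                                  positive = 1) {
  seeds <- derive_seeds(seed, length(variants) * length(families))
  reports <- list()
  rows <- list()
  i <- 0L
  for (v in variants) {
    reports[[v]] <- list()
    for (fam in families) {
      i <- i + 1L
      spec <- model_spec(fam, n_trees = if (fam == "decision_tree") 1
                         else n_trees)
      rep <- cross_validate(spec, table, k = k,
                            resampler = resampler_for(v),
                            leakage_mode = leakage_mode, seed = seeds[i],
                            positive = positive, variant = v)
      reports[[v]][[fam]] <- rep
      rows[[i]] <- data.frame(variant = v, family = fam,
                              t(rep$aggregate))
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, reports = reports)
}

#' Explain the forest fitted to the under-sampled dataset
#'
#' The study's explanation protocol: under-sample the table, fit the
#' forest on the balanced result, and compute Shapley attributions with
#' the training table as both background and target set (so the base
#' value sits near 0.5 on a balanced set).
#'
#' @param table A feature table.
#' @param seed Master seed.
#' @param n_trees Forest size.
#' @param method,n_samples Passed to [shap_values()].
#' @return A list with `model`, `training` (the under-sampled table),
#'   `explanation`, `importance` ([global_importance()]).
#' @export
explain_undersampled_forest <- function(table, seed = 1, n_trees = 100,
                                        method = "sampling",
                                        n_samples = 200) {
  seeds <- derive_seeds(seed, 3)
  under <- random_undersample(table, seeds[1])$table
  fit <- train(model_spec("random_forest", n_trees = n_trees,
                          seed = seeds[2]), under)
  expl <- shap_values(fit, under, under, method = method,
                      n_samples = n_samples, seed = seeds[3])
  list(model = fit, training = under, explanation = expl,
       importance = global_importance(expl))
}

#' Run the full study from one configuration
#'
#' Executes simulate -> label -> assemble -> resample -> train ->
#' evaluate -> explain, optionally persisting every stage's output under
#' `config$out_dir`, and returns a manifest describing the run. A failure
#' in any stage leaves earlier outputs intact and marks the manifest
#' `partial`.
#'
#' @param config A [run_config()].
#' @return A list of class `run_manifest`: `config` fingerprint, per-stage
#'   `seeds`, `status` (`complete`/`partial`), `outputs` (file inventory),
#'   and the in-memory `results` (`scenario`, `experiments`,
#'   `field_stats`, `explanation`).
#' @export
run_study <- function(config = run_config()) {
  seeds <- derive_seeds(config$seed, 4)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  outputs <- character(0)
  results <- list()
  status <- "partial"
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
  }
  tryCatch({
    results$scenario <- simulate_dataset(
      seed = seeds[1], weather = config$weather,
      labeling = config$labeling, mixing_days = config$mixing_days)
    emit("feature_table.csv", function(p)
      write_feature_table(results$scenario$table, p))

    results$field_stats <- field_stats_report(results$scenario$series,
                                              config$labeling$threshold)
    emit("field_daily_summary.csv", function(p)
      utils::write.csv(results$field_stats$daily, p, row.names = FALSE))
    emit("field_stats.json", function(p) {
      fs <- results$field_stats
      jsonlite::write_json(list(
        time_above = list(levene = fs$time_above$levene,
                          F = fs$time_above$anova$F,
                          df = c(fs$time_above$anova$df_between,
                                 fs$time_above$anova$df_within),
                          p = fs$time_above$anova$p,
                          letters = fs$time_above$anova$means$letter),
        degree_minutes = list(levene = fs$degree_minutes$levene,
                              F = fs$degree_minutes$anova$F,
                              df = c(fs$degree_minutes$anova$df_between,
                                     fs$degree_minutes$anova$df_within),
                              p = fs$degree_minutes$anova$p,
                              letters = fs$degree_minutes$anova$means$letter)),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })

    results$experiments <- reproduce_experiments(
      results$scenario$table, seed = seeds[2], variants = config$variants,
      families = config$families, n_trees = config$n_trees, k = config$k,
      leakage_mode = config$leakage_mode, positive = config$positive)
    emit("experiment_metrics.csv", function(p)
      utils::write.csv(results$experiments$summary, p, row.names = FALSE))

    results$explanation <- explain_undersampled_forest(
      results$scenario$table, seed = seeds[3], n_trees = config$n_trees,
      method = config$shap_method, n_samples = config$shap_samples)
    emit("global_importance.csv", function(p)
      utils::write.csv(results$explanation$importance, p,
                       row.names = FALSE))
    emit("attributions.csv", function(p)
      write_attributions(results$explanation$explanation, p))
    status <- "complete"
  }, error = function(e) {
    warning("run stopped at stage ", length(results) + 1L, ": ",
            conditionMessage(e), call. = FALSE)
  })
  manifest <- structure(list(
    seed = config$seed, stage_seeds = seeds, status = status,
    prevalence = if (!is.null(results$scenario))
      results$scenario$prevalence else NA_real_,
    outputs = outputs, results = results),
    class = "run_manifest")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(seed = config$seed, stage_seeds = seeds, status = status,
           prevalence = manifest$prevalence, outputs = outputs),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  manifest
}

#' Load and validate a deposited 14-column observation table
#'
#' Validates the schema (exactly the 14 [feature_columns()]), the one-hot
#' treatment invariant, and the binary label, then reports the row count
#' and positive-class prevalence. The deposited benchmark file is an
#' optional input; every analysis in this package runs on synthetic data.
#'
#' @param path CSV path.
#' @return The validated feature table with attributes `n_rows` and
#'   `prevalence`.
#' @export
load_deposited <- function(path) {
  tab <- utils::read.csv(path)
  cols <- feature_columns()
  if (!setequal(names(tab), cols)) {
    stop("schema mismatch.\n  missing: ",
         paste(setdiff(cols, names(tab)), collapse = ", "),
         "\n  unexpected: ",
         paste(setdiff(names(tab), cols), collapse = ", "), call. = FALSE)
  }
  tab <- tab[cols]
  onehot <- tab$kg16_box + tab$kg21_box + tab$kg25_box + tab$kg21_no_box
  bad <- which(onehot != 1)
  if (length(bad))
    stop("one-hot treatment violation at row ", bad[1L], call. = FALSE)
  if (!all(tab$class_label %in% c(0, 1)))
    stop("`class_label` must be binary 0/1", call. = FALSE)
  message(sprintf("loaded %d observations, positive prevalence %.2f%%",
                  nrow(tab), 100 * mean(tab$class_label)))
  attr(tab, "n_rows") <- nrow(tab)
  attr(tab, "prevalence") <- mean(tab$class_label)
  tab
}
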