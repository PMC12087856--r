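# End-to-end orchestration: generate or load a dataset, impute, run the
# splitter x classifier selection grid, rank variable importance, fit the
# applicability domain, generate the in-silico population, run the route
# scenarios and the species comparison, writing every stage artifact as
# CSV plus a JSON run manifest with per-stage seeds and file checksums.
# A single master seed fans out to per-stage seeds by a stable string hash
# so any stage can be re-run in isolation.

stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Pipeline configuration
#'
#' @param dataset Path to a dataset CSV, or NULL to generate synthetically.
#' @param generator A `generator_config` used when `dataset` is NULL.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param splitters,classifiers Grid axes.
#' @param m Number of imputations.
#' @param insilico_n In-silico population size.
#' @param magnitudes Scenario magnitudes.
#' @param outdir Output directory for stage artifacts.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(dataset = NULL, generator = generator_config(),
                            seed = 1,
                            splitters = c("random", "kennard_stone",
                                          "kmeans", "som"),
                            classifiers = c("pls_da", "decision_tree",
                                            "ksvm", "random_forest"),
                            m = 8, insilico_n = 100000,
                            magnitudes = c(5, 10, 15, 20),
                            outdir = tempfile("npskin-run-")) {
  structure(list(dataset = dataset, generator = generator,
                 seed = as.integer(seed), splitters = splitters,
                 classifiers = classifiers, m = m,
                 insilico_n = insilico_n, magnitudes = magnitudes,
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: ingest/synth -> encode -> impute -> selection grid ->
#' importance -> applicability domain -> in-silico population + per-layer
#' ranges -> route scenarios -> species comparison. All stage outputs are
#' written under `config$outdir` and the returned manifest records seeds,
#' parameters and md5 checksums, so a re-run under the same config is
#' byte-identical.
#'
#' @param config A `pipeline_config`.
#' @return A `pipeline_manifest` (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  out_csv <- function(obj, name) {
    path <- file.path(config$outdir, name)
    utils::write.csv(as.data.frame(obj), path, row.names = FALSE, na = "")
    path
  }
  note <- function(stage, seed, files, params = list()) {
    manifest$stages[[stage]] <<- list(
      seed = seed, parameters = params,
      files = as.list(tools::md5sum(files)))
  }
  fail <- function(stage, e) {
    manifest$error <<- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    stop("run_pipeline: stage '", stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  }

  # -- data
  stage <- "data"
  records <- tryCatch({
    if (!is.null(config$dataset)) {
      if (!file.exists(config$dataset))
        stop("dataset file not found: ", config$dataset)
      read_dataset(config$dataset)
    } else {
      gc_ <- config$generator
      gc_$seed <- stage_seed(config$seed, stage)
      generate_dataset(gc_)
    }
  }, error = function(e) fail(stage, e))
  f <- out_csv(records, "dataset.csv")
  note(stage, stage_seed(config$seed, stage), f,
       list(n_records = nrow(records)))

  # -- encode + impute
  stage <- "impute"
  fm_complete <- tryCatch({
    fm <- encode_features(records)
    imp <- mice_impute(fm, m = config$m, n_iterations = 10,
                       seed = stage_seed(config$seed, stage))
    pool_completed(imp, "mean")
  }, error = function(e) fail(stage, e))
  f <- out_csv(fm_complete$values, "features_imputed.csv")
  note(stage, stage_seed(config$seed, stage), f, list(m = config$m))

  X <- fm_complete$values
  y <- fm_complete$depth

  # -- selection grid
  stage <- "grid"
  grid <- tryCatch(
    selection_grid(X, y, splitters = config$splitters,
                   classifiers = config$classifiers,
                   seed = stage_seed(config$seed, stage)),
    error = function(e) fail(stage, e))
  f1 <- out_csv(grid$accuracy, "selection_grid.csv")
  f2 <- out_csv(grid$kappa, "selection_kappa.csv")
  splits_df <- do.call(rbind, lapply(grid$splits, function(s)
    data.frame(id = c(s$train_ids, s$validation_ids, s$holdout_ids),
               partition = rep(c("train", "validation", "holdout"),
                               c(length(s$train_ids),
                                 length(s$validation_ids),
                                 length(s$holdout_ids))),
               method = s$method, seed = s$seed)))
  f3 <- out_csv(splits_df, "split_assignments.csv")
  note(stage, stage_seed(config$seed, stage), c(f1, f2, f3))

  # -- best model (highest hold-out accuracy cell) + importance
  stage <- "importance"
  inner <- grid$accuracy[setdiff(rownames(grid$accuracy), "Average"),
                         setdiff(colnames(grid$accuracy), "Average"),
                         drop = FALSE]
  best <- arrayInd(which.max(inner), dim(inner))
  best_classifier <- rownames(inner)[best[1]]
  best_splitter <- colnames(inner)[best[2]]
  spl <- grid$splits[[best_splitter]]
  model <- tryCatch(
    train_classifier(classifier_spec(best_classifier,
                                     seed = stage_seed(config$seed, stage)),
                     X[spl$train_ids, , drop = FALSE], y[spl$train_ids],
                     X[spl$validation_ids, , drop = FALSE],
                     y[spl$validation_ids]),
    error = function(e) fail(stage, e))
  imp_tab <- tryCatch(
    permutation_importance(model, X[spl$validation_ids, , drop = FALSE],
                           y[spl$validation_ids],
                           groups = fm_complete$encoding_map,
                           seed = stage_seed(config$seed, stage)),
    error = function(e) fail(stage, e))
  f <- out_csv(imp_tab, "importance.csv")
  note(stage, stage_seed(config$seed, stage), f,
       list(classifier = best_classifier, splitter = best_splitter))

  # -- applicability domain
  stage <- "applicability"
  ad <- tryCatch(
    fit_applicability_domain(X[spl$train_ids, , drop = FALSE], d = 3),
    error = function(e) fail(stage, e))

  # -- in-silico population + per-layer ranges
  stage <- "insilico"
  pop <- tryCatch(
    generate_insilico(records, n = config$insilico_n,
                      seed = stage_seed(config$seed, stage)),
    error = function(e) fail(stage, e))
  pop_fm <- encode_features(pop$records, reference = fm_complete)
  inside <- ad_contains(ad, pop_fm$values)
  lr <- tryCatch(layer_ranges(pop, model, fm_complete),
                 error = function(e) fail(stage, e))
  f1 <- out_csv(lr$kw, "layer_kw.csv")
  f2 <- out_csv(lr$dunn, "layer_dunn.csv")
  f3 <- out_csv(lr$ranges, "layer_ranges.csv")
  note(stage, stage_seed(config$seed, stage), c(f1, f2, f3),
       list(n = config$insilico_n,
            fraction_outside_ad = mean(!inside)))

  # -- route scenarios
  stage <- "routes"
  routes <- tryCatch(
    run_route_experiment(model, pop, fm_complete,
                         magnitudes = config$magnitudes),
    error = function(e) fail(stage, e))
  attribution <- route_attribution(routes)
  f1 <- out_csv(routes, "route_scenarios.csv")
  f2 <- out_csv(attribution, "route_attribution.csv")
  note(stage, NA, c(f1, f2))

  # -- species comparison
  stage <- "species"
  sim <- tryCatch(species_similarity(), error = function(e) fail(stage, e))
  f1 <- out_csv(sim$percent_differences, "species_percent_differences.csv")
  f2 <- out_csv(sim$distance, "species_distance.csv")
  note(stage, NA, c(f1, f2))

  manifest$best <- list(classifier = best_classifier,
                        splitter = best_splitter,
                        holdout_accuracy = inner[best[1], best[2]])
  manifest$outdir <- config$outdir
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  structure(manifest, class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, "), stages: ",
      paste(names(x$stages), collapse = ", "), "\n", sep = "")
  if (!is.null(x$best))
    cat("  best cell: ", x$best$classifier, " x ", x$best$splitter, " = ",
        round(x$best$holdout_accuracy, 1), "% hold-out accuracy\n",
        sep = "")
  invisible(x)
}

#' Replicate a single splitter x classifier hold-out cell
#'
#' Re-runs one cell of the selection grid over several random hold-out
#' seeds and returns the per-seed hold-out accuracies. Intended for
#' replicating a published cell from the compiled literature dataset once
#' that CSV is supplied.
#'
#' @param records A `penetration_records` dataset.
#' @param splitter,classifier The cell to replicate.
#' @param seeds Hold-out seeds (default 1:10).
#' @param m Imputations for the completion step.
#' @return Numeric vector of hold-out accuracies (percent), one per seed.
#' @export
replicate_holdout_cell <- function(records, splitter = "kennard_stone",
                                   classifier = "random_forest",
                                   seeds = 1:10, m = 8) {
  fm <- encode_features(records)
  fmc <- pool_completed(mice_impute(fm, m = m, seed = seeds[1]), "mean")
  vapply(seeds, function(s) {
    g <- selection_grid(fmc$values, fmc$depth, splitters = splitter,
                        classifiers = classifier, seed = s)
    g$accuracy[classifier, splitter]
  }, numeric(1))
}
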