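#' Ranking serialization
#'
#' Writes and reads a `ranking_result` as JSON (method, per-feature
#' scores, order, keep mask, sparse rate, threshold).
#'
#' @param ranking A `ranking_result`.
#' @param path JSON file path.
#' @return `write_ranking()` the path invisibly; `read_ranking()` a
#'   `ranking_result`.
#' @export
write_ranking <- function(ranking, path) {
  jsonlite::write_json(list(
    method = ranking$method,
    scores = as.list(ranking$scores),
    order = ranking$order,
    keep = as.list(ranking$keep),
    sparse_rate = ranking$sparse_rate,
    tau = ranking$tau
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  j <- jsonlite::read_json(path)
  scores <- unlist(j$scores)
  keep <- unlist(j$keep)
  new_ranking_result(j$method, scores, keep[names(scores)],
                     tau = j$tau)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters, with published defaults, into one
#' list that round-trips losslessly through YAML ([write_config()] /
#' [read_config()]). All randomness downstream is fanned out from the
#' single `seed`.
#'
#' @param seed Root seed.
#' @param n_healthy,n_diabetic Synthetic cohort sizes.
#' @param grid_height,grid_width Thermogram grid size in pixels.
#' @param smote Balance classes with SMOTE before pruning.
#' @param prune_r Correlation threshold for redundancy pruning.
#' @param n_folds Cross-validation folds.
#' @param methods Ranking methods to run.
#' @param epochs Selector training epochs.
#' @param window,max_rank Coincidence-ranking parameters.
#' @param top_k Number of top features fed to the evaluation SVM.
#' @param gamma,cost Fixed SVM hyperparameters.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 1L, n_healthy = 50L, n_diabetic = 50L,
                            grid_height = 60L, grid_width = 36L,
                            smote = TRUE, prune_r = 0.95, n_folds = 5L,
                            methods = c("variational", "concrete", "lasso", "rf"),
                            epochs = 500L, window = 30L, max_rank = 50L,
                            top_k = 10L, gamma = 0.1, cost = 1) {
  structure(list(seed = as.integer(seed), n_healthy = as.integer(n_healthy),
                 n_diabetic = as.integer(n_diabetic),
                 grid_height = as.integer(grid_height),
                 grid_width = as.integer(grid_width),
                 smote = smote, prune_r = prune_r,
                 n_folds = as.integer(n_folds), methods = methods,
                 epochs = as.integer(epochs), window = as.integer(window),
                 max_rank = as.integer(max_rank), top_k = as.integer(top_k),
                 gamma = gamma, cost = cost),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage_file <- function(run_dir, name) file.path(run_dir, name)

#' Run the full feature-ranking pipeline
#'
#' Executes generate -> extract -> preprocess -> rank (one per method) ->
#' coincide -> evaluate on a synthetic cohort, writing every intermediate
#' artifact (CSV/JSON) into `run_dir` together with a manifest recording
#' the seed, the config hash and the stages run.
#'
#' @param config A [pipeline_config()].
#' @param run_dir Output directory (created if needed).
#' @return Invisibly, a list with the run directory, the manifest and the
#'   evaluation reports.
#' @export
run_pipeline <- function(config = pipeline_config(), run_dir = tempfile("tsrun")) {
  if (!dir.exists(run_dir)) dir.create(run_dir, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  stages <- character(0)
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed in %s: %s", stage, run_dir,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # generate
  geom <- foot_geometry(config$grid_height, config$grid_width)
  subjects <- wrap("generate",
                   make_cohort(config$n_healthy, config$n_diabetic, geom,
                               seed = config$seed))
  stages <- c(stages, "generate")

  # extract
  ft <- wrap("extract", extract_feature_table(subjects))
  ft$source <- "synthetic"
  utils::write.csv(ft, stage_file(run_dir, "features.csv"), row.names = FALSE)
  stages <- c(stages, "extract")

  # preprocess
  ft2 <- wrap("preprocess", {
    tab <- ft
    if (isTRUE(config$smote)) {
      counts <- table(feature_labels(tab))
      if (max(counts) != min(counts)) {
        tab <- smote_balance(tab, seed = config$seed + 1L)
      }
    }
    pr <- suppressWarnings(prune_correlated(tab, r_threshold = config$prune_r))
    jsonlite::write_json(pr$report, stage_file(run_dir, "prune.json"),
                         auto_unbox = TRUE, digits = NA)
    pr$table
  })
  utils::write.csv(ft2, stage_file(run_dir, "pruned.csv"), row.names = FALSE)
  folds <- make_folds(feature_labels(ft2), config$n_folds,
                      seed = config$seed + 2L)
  jsonlite::write_json(folds, stage_file(run_dir, "folds.json"), digits = NA)
  stages <- c(stages, "preprocess")

  # rank
  rankings <- lapply(config$methods, function(m) {
    r <- wrap(paste0("rank:", m), {
      if (m %in% c("variational", "concrete")) {
        select_features(ft2, folds, method = m, seed = config$seed + 3L,
                        epochs = config$epochs)
      } else {
        select_features(ft2, folds, method = m, seed = config$seed + 3L)
      }
    })
    write_ranking(r, stage_file(run_dir, sprintf("ranking_%s.json", m)))
    r
  })
  names(rankings) <- config$methods
  stages <- c(stages, "rank")

  # coincide
  coin <- if (length(rankings) >= 2) {
    cc <- wrap("coincide", coincidence(rankings, config$window, config$max_rank))
    jsonlite::write_json(cc, stage_file(run_dir, "coincidence.json"),
                         auto_unbox = TRUE, digits = NA)
    cc
  } else NULL
  stages <- c(stages, "coincide")

  # evaluate
  counts <- table(feature_labels(ft2))
  if (max(counts) > 1.1 * min(counts)) {
    warning(sprintf("class imbalance at evaluation: %s",
                    paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  }
  reports <- wrap("evaluate", {
    reps <- lapply(rankings, function(r) {
      svm_evaluate(ft2, folds, features = utils::head(r$order, config$top_k),
                   gamma = config$gamma, cost = config$cost)
    })
    if (!is.null(coin) && nrow(coin) > 0) {
      reps$coincidence <- svm_evaluate(
        ft2, folds, features = utils::head(coin$feature, config$top_k),
        gamma = config$gamma, cost = config$cost)
    }
    reps
  })
  metrics <- lapply(reports, function(r) {
    list(mean = as.list(r$mean), sd = as.list(r$sd))
  })
  jsonlite::write_json(metrics, stage_file(run_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  stages <- c(stages, "evaluate")

  manifest <- list(seed = config$seed, config_hash = cfg_hash,
                   stages = stages, config = unclass(config))
  jsonlite::write_json(manifest, stage_file(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(run_dir = run_dir, manifest = manifest, reports = reports,
                 rankings = rankings, coincidence = coin))
}
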