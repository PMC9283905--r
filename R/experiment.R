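#' Experiment configuration
#'
#' Bundles every choice needed to run one decoding experiment end to end:
#' data source, epoch window, feature kind, metric learner, SVM kernel,
#' hyperparameter grid, seed, and output directory.
#'
#' @param data a [synth_config()] for generated data, or a file path to a
#'   MAT-dialect session file.
#' @param window `"pre"` or `"move"`.
#' @param feature `"F1A"`, `"F1B"`, or `"F2"`.
#' @param learner `"euclidean"`, `"ceml"`, `"egml"`, or `"nca"`.
#' @param svm `"linear"` or `"gaussian"`.
#' @param grid a [hyper_grid()] (default built from `feature`).
#' @param seed integer master seed.
#' @param out_dir output directory (created on demand); `NULL` disables file
#'   output.
#' @param ocfg [optimizer_config()] for the metric learners.
#' @param n_perm EGML permutation count.
#' @param outer_k,inner_k CV fold counts.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(data = synth_config(), window = "pre",
                              feature = "F1B", learner = "egml",
                              svm = "linear", grid = NULL, seed = 1,
                              out_dir = NULL, ocfg = optimizer_config(),
                              n_perm = 10, outer_k = 10, inner_k = 10) {
  window <- match.arg(window, c("pre", "move"))
  feature <- match.arg(feature, c("F1A", "F1B", "F2"))
  learner <- match.arg(learner, c("euclidean", "ceml", "egml", "nca"))
  svm <- match.arg(svm, c("linear", "gaussian"))
  if (!inherits(data, "synth_config") &&
      !(is.character(data) && length(data) == 1))
    stop("`data` must be a synth_config or a file path", call. = FALSE)
  if (is.null(grid)) grid <- hyper_grid(feature)
  structure(list(data = data, window = window, feature = feature,
                 learner = learner, svm = svm, grid = grid,
                 seed = as.integer(seed), out_dir = out_dir, ocfg = ocfg,
                 n_perm = n_perm, outer_k = outer_k, inner_k = inner_k),
            class = "experiment_config")
}

.load_recording <- function(data) {
  if (inherits(data, "synth_config")) generate_recording(data)
  else read_freeform_mat(data)
}

#' Run one decoding experiment end to end
#'
#' Pipeline: load or generate the recording, extract the epoch window, build
#' the feature matrix, run [nested_cv()] with the configured learner and SVM,
#' compute per-fold importance maps from the refit outer-fold pipelines, and
#' (when `out_dir` is set) write `cv.json`, `cv.csv`, the fold-averaged
#' importance CSV and topographic PNGs. Identical config and seed give
#' identical numerical outputs.
#'
#' @param cfg an [experiment_config()].
#' @param render render topomap PNGs (default TRUE when `out_dir` is set).
#' @return list with `cv` (a `cv_result`), `importance` (fold-averaged
#'   `importance_map`, NULL for learners without a composite map),
#'   `per_fold_importance`, and `paths` of files written.
#' @export
run_experiment <- function(cfg, render = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  rec <- .load_recording(cfg$data)
  ep <- extract_windows(rec, cfg$window)
  fm <- switch(cfg$feature,
               F1A = fourier_cartesian(ep, "full"),
               F1B = fourier_cartesian(ep, "0to5"),
               F2 = time_vectorize(ep))
  cv <- nested_cv(fm, ep$labels, cfg$learner, cfg$grid, cfg$svm,
                  seed = cfg$seed, outer_k = cfg$outer_k,
                  inner_k = cfg$inner_k, ocfg = cfg$ocfg,
                  n_perm = cfg$n_perm, return_models = TRUE)
  cim <- attr(fm, "channel_index_map")
  per_fold <- lapply(cv$models, function(pipe) {
    B <- compose_projection(pipe$pca, pipe$proj)
    channel_importance(sort_projection(B), cim)
  })
  overall <- rowMeans(vapply(per_fold, `[[`, numeric(21), "overall"))
  avg_per_dim <- Reduce(`+`, lapply(per_fold, `[[`, "per_dim")) /
    length(per_fold)
  imp <- structure(list(per_dim = avg_per_dim, overall = overall,
                        channels = per_fold[[1]]$channels,
                        degenerate_dims = integer()),
                   class = "importance_map")
  paths <- character()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    cvj <- file.path(cfg$out_dir, "cv.json")
    jsonlite::write_json(
      list(learner = cv$learner, svm = cv$svm_kind, seed = cv$seed,
           mean = cv$mean, sd = cv$sd, fold_accuracy = cv$fold_accuracy,
           chosen = cv$chosen),
      cvj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    cvc <- file.path(cfg$out_dir, "cv.csv")
    utils::write.csv(cbind(cv$chosen, accuracy = cv$fold_accuracy), cvc,
                     row.names = FALSE)
    paths <- c(cvj, cvc,
               topomap_export(imp, cfg$out_dir, render = render))
  }
  cv$models <- NULL
  list(cv = cv, importance = imp, per_fold_importance = per_fold,
       paths = paths)
}

#' Run a learner x feature x window experiment matrix
#'
#' Runs [run_experiment()] for every combination and collects a summary
#' table of mean +/- sd fold accuracy (one row per cell) plus a paired
#' t-test table comparing each learner against each other learner within
#' each feature x window cell. Failures in individual cells are recorded and
#' the remaining cells continue.
#'
#' @param base_cfg an [experiment_config()] providing data, SVM kind, grids,
#'   seed and output settings.
#' @param learners,features,windows the grid to span.
#' @return list with `summary` (data.frame), `paired_tests` (data.frame),
#'   `results` (nested list), `failures` (character).
#' @export
run_matrix <- function(base_cfg,
                       learners = c("euclidean", "ceml", "egml", "nca"),
                       features = c("F1A", "F1B", "F2"),
                       windows = c("pre", "move")) {
  stopifnot(inherits(base_cfg, "experiment_config"))
  summary_rows <- list()
  results <- list()
  failures <- character()
  for (w in windows) for (f in features) {
    cell <- list()
    for (l in learners) {
      cfg <- base_cfg
      cfg$window <- w; cfg$feature <- f; cfg$learner <- l
      cfg$grid <- if (is.null(base_cfg$grid)) hyper_grid(f) else base_cfg$grid
      cfg$out_dir <- if (!is.null(base_cfg$out_dir))
        file.path(base_cfg$out_dir, paste(w, f, l, sep = "_"))
      res <- tryCatch(run_experiment(cfg, render = FALSE),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures,
                      sprintf("%s/%s/%s: %s", w, f, l, conditionMessage(res)))
        next
      }
      cell[[l]] <- res
      summary_rows[[length(summary_rows) + 1]] <-
        data.frame(window = w, feature = f, learner = l,
                   mean_accuracy = res$cv$mean, sd_accuracy = res$cv$sd)
    }
    if (length(cell) > 1) {
      nm <- names(cell)
      for (i in seq_along(nm)) for (j in seq_along(nm)) {
        if (i >= j) next
        pt <- paired_fold_test(cell[[nm[i]]]$cv, cell[[nm[j]]]$cv)
        results[[paste(w, f, nm[i], nm[j], "ttest", sep = "_")]] <- pt
      }
    }
    results[[paste(w, f, sep = "_")]] <- cell
  }
  summary <- do.call(rbind, summary_rows)
  ptests <- do.call(rbind, lapply(
    names(results)[grepl("_ttest$", names(results))], function(key) {
      parts <- strsplit(key, "_")[[1]]
      pt <- results[[key]]
      data.frame(window = parts[1], feature = parts[2],
                 learner_a = parts[3], learner_b = parts[4],
                 t = pt$t, p_value = pt$p_value)
    }))
  if (!is.null(base_cfg$out_dir)) {
    dir.create(base_cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(base_cfg$out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(ptests))
      utils::write.csv(ptests, file.path(base_cfg$out_dir, "paired_tests.csv"),
                       row.names = FALSE)
  }
  list(summary = summary, paired_tests = ptests, results = results,
       failures = failures)
}
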