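#' Hyperparameter grid for nested cross-validation
#'
#' Defaults follow the study design: metric dimension p in \{3, 10, 100\},
#' nu in \{0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.8\}, Gaussian-SVM scales
#' \eqn{\{\sqrt{5p}, \sqrt{p}, \sqrt{p/2}, \sqrt{p/4}, \sqrt{p/20}\}}
#' (expressed as multipliers of \eqn{\sqrt{p}}), and PCA sizes per feature
#' kind: \{300, rank\} for F1A/F2, \{30, 189\} for F1B. `NA` in `d_pc` means
#' "all non-zero-variance components". Every slot can be overridden, which is
#' how small test grids are built.
#'
#' @param feature_kind `"F1A"`, `"F1B"`, or `"F2"` (sets the `d_pc` default).
#' @param d_pc integer vector of PCA sizes (`NA` = rank).
#' @param p integer vector of projection dimensions.
#' @param nu numeric vector of nu values.
#' @param sigma_svm_mult multipliers m such that `sigma_svm = m * sqrt(p)`.
#' @return a `hyper_grid` list.
#' @export
hyper_grid <- function(feature_kind = c("F1B", "F1A", "F2"),
                       d_pc = NULL,
                       p = c(3, 10, 100),
                       nu = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.8),
                       sigma_svm_mult = sqrt(c(5, 1, 1/2, 1/4, 1/20))) {
  feature_kind <- match.arg(feature_kind)
  if (is.null(d_pc))
    d_pc <- if (feature_kind == "F1B") c(30, NA) else c(300, NA)
  stopifnot(length(p) >= 1, length(nu) >= 1, length(sigma_svm_mult) >= 1)
  structure(list(d_pc = d_pc, p = p, nu = nu,
                 sigma_svm_mult = sigma_svm_mult,
                 feature_kind = feature_kind),
            class = "hyper_grid")
}

# Stratified k-fold assignment (1-based fold id per sample), seeded.
.stratified_folds <- function(labels, k, seed) {
  withr_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    fold
  })
}

# Fit PCA -> metric learner -> SVM on a training partition.
.fit_pipeline <- function(X_train, y_train, learner, d_pc, p, nu, sigma_svm,
                          svm_kind, seed, ocfg, n_perm, alpha) {
  pca <- pca_condition_fit(X_train, if (is.na(d_pc)) NULL else d_pc)
  Z <- pca_condition_apply(X_train, pca)
  proj <- switch(learner,
    euclidean = euclidean_baseline(ncol(Z)),
    ceml = ceml_fit(Z, y_train, p, ecfg = entropy_config(alpha),
                    ocfg = .reseed(ocfg, seed)),
    egml = egml_fit(Z, y_train, p, ecfg = entropy_config(alpha),
                    n_perm = n_perm, ocfg = .reseed(ocfg, seed)),
    nca = nca_fit(Z, y_train, p, ocfg = .reseed(ocfg, seed)),
    stop("unknown learner: ", learner, call. = FALSE)
  )
  Yp <- project(Z, proj)
  p_eff <- ncol(Yp)
  scfg <- if (svm_kind == "linear") svm_config(nu, "linear")
          else svm_config(nu, "gaussian", sigma_svm * sqrt(p_eff))
  model <- svm_train(Yp, y_train, scfg)
  list(pca = pca, proj = proj, svm = model)
}

.reseed <- function(ocfg, seed) { ocfg$seed <- seed; ocfg }

.predict_pipeline <- function(pipe, X) {
  Z <- pca_condition_apply(X, pipe$pca)
  svm_predict(pipe$svm, project(Z, pipe$proj))
}

#' Nested cross-validated evaluation of a decoding pipeline
#'
#' Outer stratified 10-fold CV over trials; within each outer training
#' partition, an inner stratified 10-fold CV ("hyperparameter folds") scores
#' every grid combination with PCA and the metric learner refit per inner
#' fold. The combination with the best mean inner accuracy (ties broken
#' toward the simplest model: smallest d_pc, then p, then nu, then largest
#' sigma_svm) is refit on the full outer-training partition and scored once
#' on the held-out outer fold. All transforms are fit strictly on training
#' data.
#'
#' @param features a `feature_matrix` (or plain matrix) of vectorized trials.
#' @param labels trial labels in \{1, 2\}.
#' @param learner `"euclidean"`, `"ceml"`, `"egml"`, or `"nca"`. For the
#'   Euclidean baseline `p` is not applicable and the grid collapses.
#' @param grid a [hyper_grid()].
#' @param svm_kind `"linear"` or `"gaussian"`.
#' @param seed integer; controls fold assignment and learner seeds.
#' @param outer_k,inner_k fold counts (default 10).
#' @param ocfg [optimizer_config()] for the metric learners.
#' @param n_perm EGML permutation count.
#' @param alpha entropy order.
#' @param return_models keep the refit outer-fold pipelines (for importance
#'   maps).
#' @return a `cv_result`: list with `fold_accuracy`, `chosen` (data.frame of
#'   per-fold hyperparameters), `mean`, `sd`, `seed`, `fold_assign`,
#'   `learner`, `svm_kind`, and optionally `models`.
#' @export
nested_cv <- function(features, labels, learner, grid = hyper_grid(),
                      svm_kind = c("linear", "gaussian"), seed = 1,
                      outer_k = 10, inner_k = 10,
                      ocfg = optimizer_config(), n_perm = 10, alpha = 1.01,
                      return_models = FALSE) {
  svm_kind <- match.arg(svm_kind)
  X <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(X)
  if (n < 20) stop("need at least 20 trials for nested CV", call. = FALSE)
  outer_fold <- .stratified_folds(labels, outer_k, seed)

  p_vals <- if (learner == "euclidean") NA_real_ else grid$p
  sig_vals <- if (svm_kind == "gaussian") grid$sigma_svm_mult else NA_real_
  combos <- expand.grid(d_pc = grid$d_pc, p = p_vals, nu = grid$nu,
                        sigma_svm = sig_vals, KEEP.OUT.ATTRS = FALSE)
  # tie-break order: simplest first (NA d_pc = rank sorts last)
  ord <- order(ifelse(is.na(combos$d_pc), Inf, combos$d_pc),
               ifelse(is.na(combos$p), 0, combos$p),
               combos$nu, -ifelse(is.na(combos$sigma_svm), 0, combos$sigma_svm))
  combos <- combos[ord, , drop = FALSE]

  fold_acc <- numeric(outer_k)
  chosen <- vector("list", outer_k)
  models <- if (return_models) vector("list", outer_k)

  for (of in seq_len(outer_k)) {
    tr <- which(outer_fold != of)
    te <- which(outer_fold == of)
    Xtr <- X[tr, , drop = FALSE]; ytr <- labels[tr]
    inner_fold <- .stratified_folds(ytr, inner_k, seed * 1000L + of)
    inner_mean <- numeric(nrow(combos))
    for (ci in seq_len(nrow(combos))) {
      cb <- combos[ci, ]
      accs <- rep(NA_real_, inner_k)
      for (inf in seq_len(inner_k)) {
        itr <- which(inner_fold != inf)
        ite <- which(inner_fold == inf)
        acc <- tryCatch({
          pipe <- .fit_pipeline(Xtr[itr, , drop = FALSE], ytr[itr], learner,
                                cb$d_pc, cb$p, cb$nu, cb$sigma_svm, svm_kind,
                                seed * 100000L + of * 100L + inf, ocfg,
                                n_perm, alpha)
          mean(.predict_pipeline(pipe, Xtr[ite, , drop = FALSE]) == ytr[ite])
        }, error = function(e) NA_real_)
        accs[inf] <- acc
      }
      inner_mean[ci] <- if (all(is.na(accs))) -Inf else mean(accs, na.rm = TRUE)
    }
    if (all(!is.finite(inner_mean)))
      stop(sprintf("outer fold %d: no grid combination was feasible", of),
           call. = FALSE)
    best <- which.max(inner_mean)   # first max = preferred tie-break
    cb <- combos[best, ]
    pipe <- .fit_pipeline(Xtr, ytr, learner, cb$d_pc, cb$p, cb$nu,
                          cb$sigma_svm, svm_kind, seed * 100000L + of * 100L,
                          ocfg, n_perm, alpha)
    fold_acc[of] <- mean(.predict_pipeline(pipe, X[te, , drop = FALSE]) ==
                           labels[te])
    chosen[[of]] <- data.frame(fold = of, d_pc = cb$d_pc, p = cb$p,
                               nu = cb$nu, sigma_svm = cb$sigma_svm,
                               inner_accuracy = inner_mean[best])
    if (return_models) models[[of]] <- pipe
  }
  res <- structure(list(fold_accuracy = fold_acc,
                        chosen = do.call(rbind, chosen),
                        mean = mean(fold_acc), sd = stats::sd(fold_acc),
                        seed = seed, fold_assign = outer_fold,
                        learner = learner, svm_kind = svm_kind),
                   class = "cv_result")
  if (return_models) res$models <- models
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s/%s: accuracy %.3f +/- %.3f over %d folds>\n",
              x$learner, x$svm_kind, x$mean, x$sd, length(x$fold_accuracy)))
  invisible(x)
}

#' Paired t-test over cross-validation folds
#'
#' Two-sided paired t-test across the matched outer-fold accuracies of two
#' [nested_cv()] results. Requires identical fold provenance (same seed and
#' fold assignment). When all fold differences are identical the t statistic
#' is degenerate: a zero difference yields t = 0, p = 1; a nonzero constant
#' difference yields t = +/-Inf, p = 0, flagged via `degenerate = TRUE`.
#'
#' @param resA,resB `cv_result` objects from the same fold split.
#' @return list with `t`, `p_value`, `mean_diff`, `degenerate`.
#' @export
paired_fold_test <- function(resA, resB) {
  if (!identical(resA$fold_assign, resB$fold_assign) ||
      !identical(resA$seed, resB$seed))
    stop("results come from different fold splits; paired test invalid",
         call. = FALSE)
  d <- resA$fold_accuracy - resB$fold_accuracy
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, p_value = 1, mean_diff = 0, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p_value = 0, mean_diff = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(resA$fold_accuracy, resB$fold_accuracy, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}
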