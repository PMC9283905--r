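#' nu-SVM configuration
#'
#' @param nu margin/support-vector fraction bound, in (0, 1].
#' @param kernel `"linear"` or `"gaussian"`.
#' @param sigma_svm Gaussian kernel scale (required for `kernel = "gaussian"`).
#' @return an `svm_config` list.
#' @export
svm_config <- function(nu, kernel = c("linear", "gaussian"), sigma_svm = NULL) {
  kernel <- match.arg(kernel)
  if (!is.numeric(nu) || nu <= 0 || nu > 1)
    stop("`nu` must be in (0, 1]", call. = FALSE)
  if (kernel == "gaussian") {
    if (is.null(sigma_svm) || sigma_svm <= 0)
      stop("`sigma_svm` must be > 0 for the gaussian kernel", call. = FALSE)
  }
  structure(list(nu = nu, kernel = kernel, sigma_svm = sigma_svm),
            class = "svm_config")
}

#' Train a nu-SVM classifier
#'
#' Thin wrapper over the LIBSVM nu-classification solver (via e1071). The
#' Gaussian kernel is \eqn{\exp(-\|x - x'\|^2 / (2\sigma_{SVM}^2))}, i.e.
#' LIBSVM `gamma = 1 / (2 sigma_svm^2)`. nu is feasible only up to twice the
#' minority-class fraction; infeasible values raise an error so callers can
#' skip and log the configuration.
#'
#' @param X_train n x d numeric matrix.
#' @param labels class labels in \{1, 2\}, both present.
#' @param cfg an [svm_config()].
#' @return an `svm_model` wrapping the fitted solver.
#' @export
svm_train <- function(X_train, labels, cfg) {
  X_train <- as.matrix(X_train)
  labels <- as.integer(labels)
  if (!all(labels %in% c(1L, 2L)))
    stop("labels must be in {1, 2}", call. = FALSE)
  tab <- table(factor(labels, levels = c(1, 2)))
  if (any(tab == 0)) stop("both classes must be present", call. = FALSE)
  nu_max <- 2 * min(tab) / length(labels)
  if (cfg$nu > nu_max + 1e-12)
    stop(sprintf("nu = %.3f infeasible for class balance (max %.3f)",
                 cfg$nu, nu_max), call. = FALSE)
  args <- list(x = X_train, y = factor(labels, levels = c(1, 2)),
               type = "nu-classification", nu = cfg$nu, scale = FALSE)
  if (cfg$kernel == "linear") {
    args$kernel <- "linear"
  } else {
    args$kernel <- "radial"
    args$gamma <- 1 / (2 * cfg$sigma_svm^2)
  }
  fit <- do.call(e1071::svm, args)
  structure(list(fit = fit, cfg = cfg, d = ncol(X_train)),
            class = "svm_model")
}

#' Predict classes with a trained nu-SVM
#'
#' Decision rule: class 1 when the decision value for the "1/2" comparison is
#' strictly positive, class 2 otherwise (so an exact tie goes to class 2).
#'
#' @param model an `svm_model` from [svm_train()].
#' @param X n x d matrix.
#' @return integer vector of predicted labels in \{1, 2\}.
#' @export
svm_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop(sprintf("X has %d columns, model expects %d", ncol(X), model$d),
         call. = FALSE)
  pr <- stats::predict(model$fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lev <- strsplit(colnames(dv)[1], "/")[[1]]
  unname(ifelse(dv[, 1] > 0, as.integer(lev[1]), as.integer(lev[2])))
}
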