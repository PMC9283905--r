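#' Optimizer configuration for the metric learners
#'
#' All three learners use full-batch first-order descent/ascent with a
#' backtracking (Armijo) line search by default.
#'
#' @param max_iter maximum number of iterations.
#' @param rel_tol stop when the relative objective change falls below this.
#' @param step_rule `"backtracking"` (Armijo, c = 1e-4, shrink 0.5) or
#'   `"fixed"`.
#' @param init `"pca_directions"` (leading right-singular directions of the
#'   centered data) or `"random_orthonormal"` (seeded).
#' @param seed integer seed controlling random initialization and, for EGML,
#'   the permutation draw.
#' @param step_size initial (or fixed) step size.
#' @return an `optimizer_config` list.
#' @export
optimizer_config <- function(max_iter = 500, rel_tol = 1e-6,
                             step_rule = c("backtracking", "fixed"),
                             init = c("pca_directions", "random_orthonormal"),
                             seed = 1, step_size = 1) {
  step_rule <- match.arg(step_rule)
  init <- match.arg(init)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  if (rel_tol <= 0) stop("`rel_tol` must be > 0", call. = FALSE)
  structure(list(max_iter = max_iter, rel_tol = rel_tol, step_rule = step_rule,
                 init = init, seed = seed, step_size = step_size),
            class = "optimizer_config")
}

#' Linear projection container
#'
#' The learned map `A` (d_in x p) together with its provenance. Projected
#' points are `Y = X %*% A`.
#'
#' @param A d_in x p numeric matrix.
#' @param learner one of `"euclidean"`, `"ceml"`, `"egml"`, `"nca"`.
#' @param sigma,alpha kernel scale and entropy order used during fitting
#'   (NULL where not applicable).
#' @param seed integer seed used by the fit.
#' @param converged logical.
#' @param objective_trace two-column matrix (iteration, objective).
#' @return a `linear_projection` object.
#' @export
linear_projection <- function(A, learner, sigma = NULL, alpha = NULL,
                              seed = NA_integer_, converged = NA,
                              objective_trace = NULL) {
  A <- as.matrix(A)
  dimnames(A) <- NULL
  structure(list(A = A, learner = learner, p = ncol(A), d_in = nrow(A),
                 sigma = sigma, alpha = alpha, seed = seed,
                 converged = converged, objective_trace = objective_trace),
            class = "linear_projection")
}

#' @export
print.linear_projection <- function(x, ...) {
  cat(sprintf("<linear_projection %s: %d -> %d%s%s>\n", x$learner, x$d_in, x$p,
              if (!is.null(x$sigma)) sprintf(", sigma=%.4g", x$sigma) else "",
              if (isTRUE(x$converged)) ", converged" else ""))
  invisible(x)
}

#' Project data through a learned map
#'
#' @param X n x d_in matrix.
#' @param proj a [linear_projection()].
#' @return n x p matrix `X %*% A`.
#' @export
project <- function(X, proj) {
  X <- as.matrix(X)
  if (ncol(X) != proj$d_in)
    stop(sprintf("X has %d columns but the projection expects %d",
                 ncol(X), proj$d_in), call. = FALSE)
  X %*% proj$A
}

#' Euclidean (identity) baseline
#'
#' No metric is learned: the identity map is returned so that distances in the
#' "projected" space equal input-space Euclidean distances.
#'
#' @param d input dimension (>= 1).
#' @return a [linear_projection()] with `A = I_d`.
#' @export
euclidean_baseline <- function(d) {
  if (d < 1) stop("`d` must be >= 1", call. = FALSE)
  linear_projection(diag(d), learner = "euclidean", converged = TRUE)
}

# ---- shared optimizer ------------------------------------------------------

# Minimizes fn; gr returns the gradient of fn. `retract` maps a candidate back
# onto the feasible set (identity when unconstrained).
.gd_minimize <- function(A0, fn, gr, retract = identity, ocfg) {
  A <- retract(A0)
  f <- fn(A)
  trace <- matrix(c(0, f), ncol = 2,
                  dimnames = list(NULL, c("iteration", "objective")))
  step <- ocfg$step_size
  converged <- FALSE
  for (it in seq_len(ocfg$max_iter)) {
    g <- gr(A)
    gnorm2 <- sum(g^2)
    if (!is.finite(gnorm2) || gnorm2 == 0) { converged <- TRUE; break }
    if (ocfg$step_rule == "fixed") {
      A_new <- retract(A - step * g)
      f_new <- fn(A_new)
    } else {
      accepted <- FALSE
      t_try <- step
      for (bt in 1:40) {
        A_new <- retract(A - t_try * g)
        f_new <- fn(A_new)
        if (is.finite(f_new) && f_new <= f - 1e-4 * t_try * gnorm2) {
          accepted <- TRUE
          break
        }
        t_try <- t_try / 2
      }
      if (!accepted) { converged <- TRUE; break }
      # reuse a slightly grown step next iteration
      step <- min(t_try * 2, 1e6)
    }
    rel <- abs(f - f_new) / max(abs(f), 1e-12)
    A <- A_new
    f <- f_new
    trace <- rbind(trace, c(it, f))
    if (rel < ocfg$rel_tol) { converged <- TRUE; break }
  }
  list(A = A, value = f, trace = trace, converged = converged)
}

.init_A <- function(X, p, ocfg) {
  d <- ncol(X)
  if (ocfg$init == "pca_directions") {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    sv <- svd(Xc, nu = 0, nv = p)
    A <- sv$v[, seq_len(p), drop = FALSE]
  } else {
    A <- withr_seed(ocfg$seed, {
      qr.Q(qr(matrix(stats::rnorm(d * p), d, p)))[, seq_len(p), drop = FALSE]
    })
  }
  A
}

.check_learner_input <- function(X, labels, p) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  if (length(labels) != nrow(X))
    stop("length(labels) must equal nrow(X)", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("at least 2 classes must be represented; with a single class the ",
         "supervised objectives are constant", call. = FALSE)
  if (p < 1 || p > ncol(X))
    stop(sprintf("`p` must be in [1, %d]", ncol(X)), call. = FALSE)
  X
}

# gradient of an entropy-type objective wrt A, given dS/dK (symmetric G).
# K is the Gaussian Gram of Y = X A with scale sigma.
.chain_to_A <- function(G, K, Y, X, sigma) {
  W <- G * unclass(K)
  GY <- (2 / sigma^2) * (W %*% Y - rowSums(W) * Y)
  crossprod(X, GY)
}

# ---- objective/gradient factories (internal; also exercised directly by the
# finite-difference tests) ---------------------------------------------------

# CEML: conditional entropy S(L | XA) as a function of A, with its gradient.
.ceml_objective <- function(X, labels, kcfg, ecfg) {
  KL <- label_gram(labels)
  KLm <- unclass(KL)
  sigma <- kcfg$sigma
  list(
    fn = function(A) {
      K <- gaussian_gram(X %*% A, kcfg)
      joint_entropy(KL, K, ecfg) - matrix_entropy(K, ecfg)
    },
    gr = function(A) {
      Y <- X %*% A
      K <- gaussian_gram(Y, kcfg)
      Km <- unclass(K)
      G_joint <- .entropy_grad_M(KLm * Km, ecfg) * KLm
      G_marg <- .entropy_grad_M(Km, ecfg)
      .chain_to_A(G_joint - G_marg, K, Y, X, sigma)
    }
  )
}

# EGML: NEGATIVE entropy gap (minimization sense) for a fixed permutation set.
.egml_objective <- function(X, labels, kcfg, ecfg, perms) {
  KLm <- unclass(label_gram(labels))
  KL_perm <- lapply(perms, function(pp) KLm[pp, pp, drop = FALSE])
  sigma <- kcfg$sigma
  n_perm <- length(perms)
  joint_of <- function(KLx, Km) {
    sp <- .gram_spectrum(KLx * Km, ecfg)
    log(sum(sp$values^ecfg$alpha)) / (1 - ecfg$alpha)
  }
  list(
    fn = function(A) {
      Km <- unclass(gaussian_gram(X %*% A, kcfg))
      perm_mean <- mean(vapply(KL_perm, joint_of, numeric(1), Km = Km))
      joint_of(KLm, Km) - perm_mean
    },
    gr = function(A) {
      Y <- X %*% A
      K <- gaussian_gram(Y, kcfg)
      Km <- unclass(K)
      G <- .entropy_grad_M(KLm * Km, ecfg) * KLm -
        Reduce(`+`, lapply(KL_perm, function(KLx) {
          .entropy_grad_M(KLx * Km, ecfg) * KLx
        })) / n_perm
      .chain_to_A(G, K, Y, X, sigma)
    }
  )
}

# NCA: NEGATIVE soft leave-one-out accuracy (minimization sense).
.nca_objective <- function(X, labels) {
  same <- outer(labels, labels, "==") * 1
  diag(same) <- 0
  list(
    fn = function(A) {
      P <- .nca_softmax(X %*% A)
      -sum(P * same)
    },
    gr = function(A) {
      Y <- X %*% A
      P <- .nca_softmax(Y)
      p_i <- rowSums(P * same)
      W <- P * (same - p_i)
      S <- W + t(W)
      GY <- 2 * (S %*% Y - rowSums(S) * Y)   # gradient of +sum(p_i)
      -crossprod(X, GY)
    }
  )
}

# ---- CEML ------------------------------------------------------------------

#' Conditional-entropy metric learning (CEML)
#'
#' Learns `A` minimizing the matrix-based conditional entropy
#' \eqn{S_\alpha(L \mid AX)} subject to the trace constraint
#' \eqn{\mathrm{tr}(A^\top A) = p}, enforced by rescaling onto the trace
#' sphere after every step. The Gaussian kernel scale defaults to
#' \eqn{\sqrt{p/2}}, matched to PCA-conditioned inputs with total variance
#' equal to the dimension.
#'
#' @param X n x d data matrix.
#' @param labels class labels, length n, at least two classes.
#' @param p projection dimension.
#' @param kcfg [kernel_config()]; default `kernel_config(sqrt(p/2))`.
#' @param ecfg [entropy_config()].
#' @param ocfg [optimizer_config()].
#' @return a [linear_projection()].
#' @export
ceml_fit <- function(X, labels, p, kcfg = NULL, ecfg = entropy_config(),
                     ocfg = optimizer_config()) {
  X <- .check_learner_input(X, labels, p)
  if (is.null(kcfg)) kcfg <- kernel_config(sqrt(p / 2))
  sigma <- kcfg$sigma
  obj <- .ceml_objective(X, labels, kcfg, ecfg)
  retract <- function(A) A * sqrt(p / sum(A^2))
  A0 <- .init_A(X, p, ocfg)
  res <- .gd_minimize(A0, obj$fn, obj$gr, retract, ocfg)
  linear_projection(res$A, "ceml", sigma = sigma, alpha = ecfg$alpha,
                    seed = ocfg$seed, converged = res$converged,
                    objective_trace = res$trace)
}

# ---- EGML ------------------------------------------------------------------

#' Entropy-gap metric learning (EGML)
#'
#' Learns `A` maximizing the entropy gap
#' \eqn{EG_\alpha(L; AX) = E_\Pi[S_\alpha(L, (AX)_\Pi)] - S_\alpha(L, AX)}.
#' The gap closes for projections much smaller or much larger than the kernel
#' scale, so no trace constraint is needed: the objective self-limits the
#' scale of `A`. The permutation set is drawn once per fit from the seed in
#' `ocfg` and held fixed across iterations, making the objective
#' deterministic.
#'
#' @inheritParams ceml_fit
#' @param n_perm number of permutations in the expectation (default 10).
#' @return a [linear_projection()].
#' @export
egml_fit <- function(X, labels, p, kcfg = NULL, ecfg = entropy_config(),
                     n_perm = 10, ocfg = optimizer_config()) {
  X <- .check_learner_input(X, labels, p)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (is.null(kcfg)) kcfg <- kernel_config(sqrt(p / 2))
  sigma <- kcfg$sigma
  n <- nrow(X)
  perms <- withr_seed(ocfg$seed,
                      replicate(n_perm, sample.int(n), simplify = FALSE))
  obj <- .egml_objective(X, labels, kcfg, ecfg, perms)
  A0 <- .init_A(X, p, ocfg)
  # start where the gap is informative: scale the initial map so the
  # projected total variance matches p * sigma^2 (the objective is flat far
  # from the kernel width, so an ill-scaled start stalls)
  tv <- sum(apply(X %*% A0, 2, stats::var))
  if (tv > 0) A0 <- A0 * sigma * sqrt(p / tv)
  res <- .gd_minimize(A0, obj$fn, obj$gr, identity, ocfg)
  pr <- linear_projection(res$A, "egml", sigma = sigma, alpha = ecfg$alpha,
                          seed = ocfg$seed, converged = res$converged,
                          objective_trace = res$trace)
  pr$objective_trace[, 2] <- -pr$objective_trace[, 2]  # report the gap itself
  pr$n_perm <- n_perm
  pr
}

# ---- NCA -------------------------------------------------------------------

# Soft-assignment matrix P (n x n, zero diagonal, rows sum to 1) for projected
# points Y.
.nca_softmax <- function(Y) {
  n <- nrow(Y)
  sq <- rowSums(Y^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(Y)
  d2[d2 < 0] <- 0
  Z <- -d2
  diag(Z) <- -Inf
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  diag(E) <- 0
  P <- E / rowSums(E)
  P
}

#' Neighborhood component analysis (NCA)
#'
#' Learns `A` maximizing the expected leave-one-out soft k-nn accuracy
#' \eqn{\sum_i p_i}, where \eqn{P_{ij}} is the softmax over negative squared
#' projected distances (a point is never its own neighbor) and
#' \eqn{p_i = \sum_{j \in \mathrm{class}(i)} P_{ij}}.
#'
#' @inheritParams ceml_fit
#' @return a [linear_projection()].
#' @export
nca_fit <- function(X, labels, p, ocfg = optimizer_config()) {
  X <- .check_learner_input(X, labels, p)
  obj <- .nca_objective(X, labels)
  A0 <- .init_A(X, p, ocfg)
  res <- .gd_minimize(A0, obj$fn, obj$gr, identity, ocfg)
  pr <- linear_projection(res$A, "nca", seed = ocfg$seed,
                          converged = res$converged,
                          objective_trace = res$trace)
  pr$objective_trace[, 2] <- -pr$objective_trace[, 2]
  pr
}

# ---- serialization ---------------------------------------------------------

#' Save / load a linear projection
#'
#' Writes `<prefix>.json` (learner metadata, dimensions) and `<prefix>.bin`
#' (the matrix `A`, column-major little-endian doubles).
#'
#' @param proj a [linear_projection()].
#' @param prefix file path prefix (no extension).
#' @return `write_projection` returns `prefix` invisibly; `read_projection`
#'   returns the reconstructed [linear_projection()].
#' @export
write_projection <- function(proj, prefix) {
  meta <- list(learner = proj$learner, d_in = proj$d_in, p = proj$p,
               sigma = proj$sigma, alpha = proj$alpha, seed = proj$seed,
               converged = proj$converged)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(proj$A), con, size = 8, endian = "little")
  invisible(prefix)
}

#' @rdname write_projection
#' @export
read_projection <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = meta$d_in * meta$p, size = 8,
                  endian = "little")
  A <- matrix(vals, meta$d_in, meta$p)
  linear_projection(A, meta$learner, sigma = meta$sigma, alpha = meta$alpha,
                    seed = meta$seed, converged = meta$converged)
}
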