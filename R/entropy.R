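#' Entropy estimator configuration
#'
#' Matrix-based alpha-order entropy behaves like Shannon entropy for alpha
#' close to 1; alpha = 1.01 is the default used throughout.
#'
#' @param alpha entropy order, must be > 1.
#' @param eig_clip eigenvalues of the normalized Gram matrix at or below this
#'   threshold are treated as exact zeros (dropped from the spectrum). Guards
#'   against round-off negatives.
#' @return an `entropy_config` list.
#' @export
entropy_config <- function(alpha = 1.01, eig_clip = 1e-12) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 1)
    stop("`alpha` must be a single number > 1", call. = FALSE)
  if (!is.numeric(eig_clip) || eig_clip < 0)
    stop("`eig_clip` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, eig_clip = eig_clip), class = "entropy_config")
}

# Trace-normalize, eigendecompose, validate PSD-ness. Returns clipped spectrum
# (values > eig_clip only) and, when vectors = TRUE, the full eigensystem of
# the normalized matrix.
.gram_spectrum <- function(M, cfg, vectors = FALSE) {
  tr <- sum(diag(M))
  if (!is.finite(tr) || tr <= 0)
    stop("Gram matrix trace must be positive", call. = FALSE)
  N <- M / tr
  e <- tryCatch(eigen(N, symmetric = TRUE, only.values = !vectors),
                error = function(err) NULL)
  if (is.null(e)) {
    # dsyevr occasionally fails on heavily structured sparse-like Gram
    # matrices; the SVD of a symmetric matrix gives |eigenvalues| with
    # u = sign(lambda) * v, so signs are recovered from u'v
    s <- svd(N)
    sgn <- sign(colSums(s$u * s$v))
    ord <- order(s$d * sgn, decreasing = TRUE)
    e <- list(values = (s$d * sgn)[ord], vectors = s$u[, ord, drop = FALSE])
  }
  lam <- e$values
  lmax <- max(lam, 0)
  if (min(lam) < -1e-10 * max(lmax, 1e-300))
    stop("Gram matrix has a negative eigenvalue beyond tolerance (",
         format(min(lam)), ")", call. = FALSE)
  keep <- lam > cfg$eig_clip
  list(values = lam[keep], all_values = lam, vectors = if (vectors) e$vectors,
       trace = tr, norm = N)
}

#' Matrix-based alpha-order entropy
#'
#' \eqn{S_\alpha(K) = \frac{1}{1-\alpha}\log\sum_i \lambda_i^\alpha}, where
#' \eqn{\lambda_i} are the eigenvalues of the unit-trace normalization
#' \eqn{K / \mathrm{tr}(K)}. The value is in nats and lies in
#' \eqn{[0, \log n]}.
#'
#' @param K a [gram_matrix()] or symmetric PSD numeric matrix.
#' @param cfg an [entropy_config()].
#' @return entropy in nats.
#' @export
matrix_entropy <- function(K, cfg = entropy_config()) {
  K <- .as_gram(K)
  sp <- .gram_spectrum(K, cfg)
  log(sum(sp$values^cfg$alpha)) / (1 - cfg$alpha)
}

.as_gram <- function(K) {
  if (inherits(K, "gram_matrix")) return(K)
  gram_matrix(as.matrix(K))
}

#' Joint matrix-based entropy
#'
#' Entropy of the Hadamard product \eqn{K_L \circ K_Y} (normalized to unit
#' trace); PSD by the Schur product theorem.
#'
#' @param K_L,K_Y [gram_matrix()] objects of identical size (conventionally the
#'   label kernel and the data kernel).
#' @param cfg an [entropy_config()].
#' @return joint entropy in nats.
#' @export
joint_entropy <- function(K_L, K_Y, cfg = entropy_config()) {
  K_L <- .as_gram(K_L); K_Y <- .as_gram(K_Y)
  if (!all(dim(K_L) == dim(K_Y)))
    stop("K_L and K_Y must have the same dimensions", call. = FALSE)
  M <- unclass(K_L) * unclass(K_Y)
  sp <- .gram_spectrum(M, cfg)
  log(sum(sp$values^cfg$alpha)) / (1 - cfg$alpha)
}

#' Conditional entropy S(L | Y)
#'
#' Difference between the joint entropy of (L, Y) and the marginal entropy of
#' Y. Non-negative up to numerical tolerance.
#'
#' @inheritParams joint_entropy
#' @return conditional entropy in nats.
#' @export
conditional_entropy <- function(K_L, K_Y, cfg = entropy_config()) {
  joint_entropy(K_L, K_Y, cfg) - matrix_entropy(K_Y, cfg)
}

#' Matrix-based mutual information
#'
#' \eqn{MI_\alpha(L; Y) = S_\alpha(L) + S_\alpha(Y) - S_\alpha(L, Y)}.
#'
#' @inheritParams joint_entropy
#' @return mutual information in nats (>= 0 up to round-off).
#' @export
mutual_information <- function(K_L, K_Y, cfg = entropy_config()) {
  matrix_entropy(K_L, cfg) + matrix_entropy(K_Y, cfg) -
    joint_entropy(K_L, K_Y, cfg)
}

#' Entropy gap
#'
#' Difference between the expected joint entropy under random permutation of
#' the sample/label correspondence and the observed joint entropy:
#' \eqn{EG_\alpha(L;Y) = E_\Pi[S_\alpha(L, Y_\Pi)] - S_\alpha(L, Y)}.
#' A permutation-calibrated mutual-information surrogate: unlike MI it does
#' not grow without bound as the scale of `Y` increases, so it can be
#' maximized over unconstrained linear maps.
#'
#' Permuting the rows/columns of \eqn{K_Y} is spectrally equivalent to
#' inversely permuting \eqn{K_L}; the latter is used internally.
#'
#' @param K_L label [gram_matrix()].
#' @param Y n x p matrix of points.
#' @param kcfg [kernel_config()] for the Gaussian kernel on `Y`.
#' @param cfg [entropy_config()].
#' @param n_perm number of random permutations averaged (>= 1).
#' @param rng_seed integer seed for the permutation stream; identical seeds
#'   give identical results.
#' @return the entropy gap in nats.
#' @export
entropy_gap <- function(K_L, Y, kcfg, cfg = entropy_config(),
                        n_perm = 10, rng_seed = 1) {
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  K_L <- .as_gram(K_L)
  Y <- as.matrix(Y)
  n <- nrow(K_L)
  if (nrow(Y) != n) stop("Y and K_L disagree on n", call. = FALSE)
  K_Y <- gaussian_gram(Y, kcfg)
  perms <- withr_seed(rng_seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  base <- joint_entropy(K_L, K_Y, cfg)
  permuted <- vapply(perms, function(p) {
    joint_entropy(gram_matrix(unclass(K_L)[p, p, drop = FALSE]), K_Y, cfg)
  }, numeric(1))
  mean(permuted) - base
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gradient of S_alpha(M / tr M) with respect to M (symmetric).
# dS = alpha/((1-alpha) t) * [ N^(alpha-1)/tr(N^alpha) - I ], N = M / t.
# Eigenvalues <= eig_clip contribute zero (for alpha > 1 the derivative of
# lambda^alpha vanishes at lambda = 0).
.entropy_grad_M <- function(M, cfg) {
  sp <- .gram_spectrum(M, cfg, vectors = TRUE)
  lam <- sp$all_values
  keep <- lam > cfg$eig_clip
  pow <- ifelse(keep, lam, 1)^(cfg$alpha - 1) * keep
  tral <- sum((lam[keep])^cfg$alpha)
  U <- sp$vectors
  Npow <- U %*% (pow * t(U))
  a <- cfg$alpha
  (a / ((1 - a) * sp$trace)) * (Npow / tral - diag(nrow(M)))
}
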