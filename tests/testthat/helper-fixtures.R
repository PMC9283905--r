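# Shared fixtures and small oracles, all generated in code.

# central finite-difference gradient, relative L2 error against analytic
fd_rel_error <- function(obj, A, h = 1e-5) {
  g <- obj$gr(A)
  gfd <- array(0, dim(A))
  for (i in seq_along(A)) {
    Ap <- A; Am <- A
    Ap[i] <- Ap[i] + h
    Am[i] <- Am[i] - h
    gfd[i] <- (obj$fn(Ap) - obj$fn(Am)) / (2 * h)
  }
  sqrt(sum((g - gfd)^2)) / (sqrt(sum(gfd^2)) + 1e-300)
}

# independent entropy oracle: direct dense-eigendecomposition evaluation of
# the closed form on the trace-normalized matrix
oracle_entropy <- function(M, alpha = 1.01) {
  lam <- eigen(M / sum(diag(M)), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12]
  log(sum(lam^alpha)) / (1 - alpha)
}

# two tight, well-separated 1-D clusters matched to labels (8 points)
clustered_8 <- function(gap = 10) {
  list(Y = matrix(c(0, 0.01, -0.01, 0.02, gap, gap + 0.01, gap - 0.01,
                    gap + 0.02), ncol = 1),
       labels = rep(1:2, each = 4))
}

# 2-D set where only coordinate 1 carries class information
informative_2d <- function(n = 200, seed = 0) {
  set.seed(seed)
  x1 <- rnorm(n)
  list(X = cbind(x1, rnorm(n)), labels = ifelse(x1 > 0, 1L, 2L))
}

# linearly separable Gaussian blobs in d dims, classes split on coordinate 1
blobs <- function(n = 60, d = 4, sep = 4, seed = 1) {
  set.seed(seed)
  lab <- rep(1:2, length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + ifelse(lab == 1, -sep / 2, sep / 2)
  list(X = X, labels = lab)
}

# small synthetic session shared by feature/pipeline tests
quick_recording <- function(n_trials = 40, seed = 1, ...) {
  generate_recording(synth_config(n_trials = n_trials, seed = seed, ...))
}

fast_ocfg <- function(max_iter = 30, seed = 1) {
  optimizer_config(max_iter = max_iter, seed = seed)
}
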