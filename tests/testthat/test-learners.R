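test_that("analytic gradients match central finite differences", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(10:25, 1)
    d <- sample(3:6, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * d), n, d)
    lab <- sample(rep(1:2, length.out = n))
    A <- matrix(rnorm(d * p), d, p) * 0.6
    kcfg <- kernel_config(0.9)
    ecfg <- entropy_config()
    perms <- replicate(3, sample.int(n), simplify = FALSE)
    expect_lt(fd_rel_error(egml:::.ceml_objective(X, lab, kcfg, ecfg), A),
              1e-5)
    expect_lt(fd_rel_error(egml:::.egml_objective(X, lab, kcfg, ecfg, perms),
                           A), 1e-5)
    expect_lt(fd_rel_error(egml:::.nca_objective(X, lab), A), 1e-5)
  }
})

test_that("all learners recover the informative coordinate in 2-D", {
  dat <- informative_2d(n = 200, seed = 0)
  oc <- fast_ocfg(max_iter = 150)
  # grid-search oracle: over unit directions, each objective prefers axis 1
  angles <- seq(0, pi - 0.01, length.out = 36)
  kcfg <- kernel_config(sqrt(1 / 2))
  ecfg <- entropy_config()
  perms <- egml:::withr_seed(1, replicate(5, sample.int(200), simplify = FALSE))
  objs <- list(ceml = egml:::.ceml_objective(dat$X, dat$labels, kcfg, ecfg),
               egml = egml:::.egml_objective(dat$X, dat$labels, kcfg, ecfg,
                                             perms),
               nca = egml:::.nca_objective(dat$X, dat$labels))
  for (nm in names(objs)) {
    vals <- vapply(angles, function(a) {
      objs[[nm]]$fn(matrix(c(cos(a), sin(a)), 2, 1))
    }, numeric(1))
    best <- angles[which.min(vals)]   # all three are minimization-sense
    axis_dist <- min(best, abs(pi - best))
    expect_lt(axis_dist, pi / 8)
  }
  # the fitted learners concentrate squared weight on coordinate 1
  fits <- list(ceml = ceml_fit(dat$X, dat$labels, 1, ocfg = oc),
               egml = egml_fit(dat$X, dat$labels, 1, ocfg = oc),
               nca = nca_fit(dat$X, dat$labels, 1, ocfg = oc))
  for (nm in names(fits)) {
    w <- fits[[nm]]$A[, 1]^2
    expect_gt(w[1] / sum(w), 0.9)
  }
})

test_that("CEML honors its contract", {
  dat <- informative_2d(60, seed = 2)
  expect_error(ceml_fit(dat$X, rep(1, 60), 1), "2 classes")
  expect_error(ceml_fit(dat$X, dat$labels, 5), "`p` must be in")
  pr <- ceml_fit(dat$X, dat$labels, 2, ocfg = fast_ocfg(40))
  expect_equal(sum(pr$A^2), 2, tolerance = 1e-6)
  # objective decreases monotonically (minimization)
  tr <- pr$objective_trace[, 2]
  expect_true(all(diff(tr) <= 1e-10))
})

test_that("EGML is scale-robust and needs no trace constraint", {
  dat <- informative_2d(80, seed = 4)
  oc <- fast_ocfg(max_iter = 80)
  pr1 <- egml_fit(dat$X, dat$labels, 1, n_perm = 5, ocfg = oc)
  pr2 <- egml_fit(dat$X * 100, dat$labels, 1, n_perm = 5, ocfg = oc)
  d1 <- as.vector(dist(project(dat$X, pr1)))
  d2 <- as.vector(dist(project(dat$X * 100, pr2)))
  expect_gt(cor(d1, d2), 0.99)
  # gap objective is reported increasing (maximization)
  tr <- pr1$objective_trace[, 2]
  expect_true(all(diff(tr) >= -1e-10))
  # zero projection has zero gap
  obj <- egml:::.egml_objective(dat$X, dat$labels, kernel_config(1),
                                entropy_config(),
                                list(sample.int(80)))
  expect_equal(obj$fn(matrix(0, 2, 1)), 0, tolerance = 1e-12)
})

test_that("NCA soft assignments are a proper leave-one-out distribution", {
  cl <- clustered_8()
  X <- cbind(cl$Y, 0.01 * seq_len(8))
  P <- egml:::.nca_softmax(X %*% diag(2))
  expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-10)
  expect_true(all(diag(P) == 0))
  # far-separated clusters matched to labels: soft LOO accuracy near 1
  same <- outer(cl$labels, cl$labels, "==") * 1
  diag(same) <- 0
  expect_gt(sum(P * same) / 8, 0.99)
})

test_that("fits are deterministic given the seed", {
  dat <- informative_2d(50, seed = 9)
  for (f in list(
    function(s) ceml_fit(dat$X, dat$labels, 1, ocfg = fast_ocfg(20, seed = s)),
    function(s) egml_fit(dat$X, dat$labels, 1, n_perm = 3,
                         ocfg = fast_ocfg(20, seed = s)),
    function(s) nca_fit(dat$X, dat$labels, 1, ocfg = fast_ocfg(20, seed = s))
  )) {
    expect_identical(f(7)$A, f(7)$A)
  }
})

test_that("euclidean baseline and projection algebra", {
  pr <- euclidean_baseline(3)
  expect_equal(pr$A, diag(3))
  set.seed(1)
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(project(X, pr), X)
  expect_equal(as.vector(dist(project(X, pr))), as.vector(dist(X)))
  # zero and hand-computed products
  A <- matrix(c(1, 2, 3, 4), 2, 2)
  X3 <- matrix(c(1, 0, 2, 1, 1, 1), 3, 2)
  expect_equal(project(X3, linear_projection(A, "ceml")), X3 %*% A)
  expect_equal(project(X3, linear_projection(matrix(0, 2, 2), "ceml")),
               matrix(0, 3, 2))
  expect_error(project(matrix(0, 2, 4), pr), "columns")
})

test_that("projections serialize and reload bit-exactly", {
  dat <- informative_2d(40, seed = 13)
  pr <- egml_fit(dat$X, dat$labels, 1, n_perm = 2, ocfg = fast_ocfg(10))
  prefix <- file.path(tempdir(), "proj_test")
  write_projection(pr, prefix)
  pr2 <- read_projection(prefix)
  expect_identical(pr2$A, pr$A)
  expect_identical(pr2$learner, "egml")
  expect_equal(pr2$sigma, pr$sigma)
})
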