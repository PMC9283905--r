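test_that("projection composition is the PCA-scaled matrix product", {
  set.seed(4)
  X <- matrix(rnorm(40 * 6), 40, 6)
  pca <- pca_condition_fit(X, 3)
  pr <- linear_projection(diag(3), "euclidean")
  expect_equal(compose_projection(pca, pr), pca$Q * pca$scale_factor)
  pr0 <- linear_projection(matrix(0, 3, 2), "ceml")
  expect_true(all(compose_projection(pca, pr0) == 0))
  # hand-multiplied fixed product
  pca_fake <- structure(list(Q = matrix(c(1, 0, 0, 1, 1, 1, 0, 0), 4, 2),
                             center = rep(0, 4), scale_factor = 2, d_pc = 2),
                        class = "pca_model")
  A <- matrix(c(3, -1), 2, 1)
  expect_equal(compose_projection(pca_fake, linear_projection(A, "nca")),
               (pca_fake$Q * 2) %*% A)
  expect_error(compose_projection(pca, linear_projection(diag(5), "nca")),
               "dims")
})

test_that("sort_projection orders singular values and reconstructs B", {
  B <- diag(c(3, 5))
  sp <- sort_projection(B)
  expect_equal(sp$singular_values, c(5, 3))
  expect_equal(abs(sp$B_tilde), rbind(c(0, 3), c(5, 0)), tolerance = 1e-12)
  # column norms equal singular values
  expect_equal(sqrt(colSums(sp$B_tilde^2)), sp$singular_values)
  # orthogonal-column B: B_tilde equals B up to column order and sign
  Bo <- cbind(c(2, 0, 0), c(0, 0, 7))
  spo <- sort_projection(Bo)
  expect_equal(abs(spo$B_tilde[, order(c(2, 7), decreasing = TRUE)]), abs(Bo))
  # random B reconstructs through U D V'
  set.seed(6)
  Br <- matrix(rnorm(18), 6, 3)
  spr <- sort_projection(Br)
  expect_lt(max(abs(spr$B_tilde %*% t(spr$V) - Br)), 1e-10)
  expect_error(sort_projection(matrix(0, 3, 2)), "zero")
})

test_that("channel importance is the per-column squared-norm fraction", {
  # column fully supported on one channel
  sp <- list(B_tilde = matrix(c(1, 2, 0, 0), 4, 1))
  imp <- channel_importance(sp, list(a = 1:2, b = 3:4))
  expect_equal(unname(imp$per_dim[, 1]), c(1, 0))
  # two channels, one row each, column (1, 1)
  sp2 <- list(B_tilde = matrix(c(1, 1), 2, 1))
  imp2 <- channel_importance(sp2, list(a = 1, b = 2))
  expect_equal(unname(imp2$per_dim[, 1]), c(0.5, 0.5))
  # hand example: column (1, 2, 2), I1 = {1, 2}, I2 = {3} -> (5/9, 4/9)
  sp3 <- list(B_tilde = matrix(c(1, 2, 2), 3, 1))
  imp3 <- channel_importance(sp3, list(ch1 = 1:2, ch2 = 3))
  expect_equal(unname(imp3$per_dim[, 1]), c(5 / 9, 4 / 9))
  expect_error(channel_importance(sp3, list(ch1 = 1:2, ch2 = 4)), "partition")
})

test_that("importance columns are stochastic and zero columns flagged", {
  set.seed(12)
  B <- matrix(rnorm(12 * 3), 12, 3)
  B[, 3] <- 0                       # degenerate direction
  sv <- svd(B)
  sp <- list(B_tilde = sv$u %*% diag(sv$d))
  cim <- split(1:12, rep(1:4, each = 3))
  names(cim) <- paste0("ch", 1:4)
  imp <- channel_importance(sp, cim)
  expect_equal(colSums(imp$per_dim), rep(1, 3), tolerance = 1e-10)
  expect_true(all(imp$per_dim >= 0 & imp$per_dim <= 1))
  expect_equal(sum(imp$overall), 1, tolerance = 1e-10)
  expect_equal(imp$degenerate_dims, 3L)
  expect_equal(unname(imp$per_dim[, 3]), rep(0.25, 4))
})

test_that("importance is invariant to orthogonal right-rotations of B", {
  set.seed(23)
  B <- matrix(rnorm(20 * 3), 20, 3)
  cim <- split(1:20, rep(1:5, each = 4))
  names(cim) <- paste0("ch", 1:5)
  base <- channel_importance(sort_projection(B), cim)
  for (i in 1:10) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    rot <- channel_importance(sort_projection(B %*% R), cim)
    expect_equal(rot$per_dim, base$per_dim, tolerance = 1e-8)
    expect_equal(rot$overall, base$overall, tolerance = 1e-8)
  }
})

test_that("topomap export writes exact CSV values and flat uniform fields", {
  imp <- structure(list(per_dim = matrix(1 / 21, 21, 2,
                                         dimnames = list(eeg_channels(), NULL)),
                        overall = setNames(rep(1 / 21, 21), eeg_channels()),
                        channels = eeg_channels(),
                        degenerate_dims = integer()),
                   class = "importance_map")
  out <- file.path(tempdir(), "topo_test")
  paths <- topomap_export(imp, out)
  csv <- read.csv(file.path(out, "importance.csv"))
  expect_equal(nrow(csv), 21 * 3)        # overall + 2 dims
  expect_equal(csv$importance, rep(1 / 21, 63))
  expect_true(all(file.exists(paths)))
  # uniform values interpolate to a flat field
  mont <- montage_1020()
  field <- egml:::.idw_field(mont, rep(0.3, 21),
                             seq(-1, 1, length.out = 20),
                             seq(-1, 1, length.out = 20))
  expect_lt(max(field) - min(field), 1e-6)
  # unknown channels are rejected with the resolvable list
  imp_bad <- imp
  imp_bad$channels[1] <- "XX"
  expect_error(topomap_export(imp_bad, out), "resolvable")
})

test_that("planted effect channels dominate importance for all learners", {
  hits <- c(ceml = 0, egml = 0, nca = 0)
  for (seed in 1:5) {
    rec <- generate_recording(synth_config(n_trials = 60, seed = seed))
    ep <- extract_windows(rec, "move")
    fm <- fourier_cartesian(ep, "0to5")
    pca <- pca_condition_fit(fm, 15)
    Z <- pca_condition_apply(fm, pca)
    oc <- fast_ocfg(20, seed = seed)
    fits <- list(ceml = ceml_fit(Z, ep$labels, 3, ocfg = oc),
                 egml = egml_fit(Z, ep$labels, 3, n_perm = 3, ocfg = oc),
                 nca = nca_fit(Z, ep$labels, 3, ocfg = oc))
    for (nm in names(fits)) {
      imp <- channel_importance(
        sort_projection(compose_projection(pca, fits[[nm]])),
        attr(fm, "channel_index_map"))
      ov <- sort(imp$overall, decreasing = TRUE)
      mass_planted <- sum(imp$overall[c("C3", "C4")])
      best_other_two <- sum(ov[setdiff(names(ov), c("C3", "C4"))][1:2])
      if (mass_planted > best_other_two) hits[nm] <- hits[nm] + 1
    }
  }
  expect_true(all(hits >= 4))   # at least 4 of 5 seeds per learner
})
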