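make_recording_with_onsets <- function(Tn, onsets, labels,
                                       signals = NULL) {
  if (is.null(signals)) signals <- matrix(0, 21, Tn)
  eeg_recording(signals, onsets = onsets, labels = labels)
}

test_that("window extraction uses the half-open onset convention", {
  Tn <- 2000
  sig <- matrix(0, 21, Tn)
  sig[1, ] <- seq_len(Tn)   # channel 1 encodes the sample index
  rec <- make_recording_with_onsets(Tn, onsets = 1000, labels = 1,
                                    signals = sig)
  pre <- extract_windows(rec, "pre")
  mv <- extract_windows(rec, "move")
  expect_equal(dim(pre$epochs), c(1, 21, 170))
  expect_equal(pre$epochs[1, 1, ], 830:999)
  expect_equal(mv$epochs[1, 1, ], 1000:1169)
})

test_that("trials whose windows leave the recording are dropped", {
  rec <- make_recording_with_onsets(400, onsets = c(100, 220), labels = c(1, 2))
  expect_message(pre <- extract_windows(rec, "pre"), "dropped 1/2")
  expect_equal(pre$kept, 2L)
  # onset 220 + 169 = 389 <= 400 so the move window keeps both
  mv <- suppressMessages(extract_windows(rec, "move"))
  expect_equal(length(mv$labels), 2)
  rec2 <- make_recording_with_onsets(300, onsets = 50, labels = 1)
  expect_error(suppressMessages(extract_windows(rec2, "pre")), "no trial")
})

test_that("feature dimensions match the vectorization design", {
  rec <- quick_recording(n_trials = 21, seed = 5)
  ep <- extract_windows(rec, "move")
  expect_equal(dim(ep$epochs)[3], 170)
  f1b <- fourier_cartesian(ep, "0to5")
  f1a <- fourier_cartesian(ep, "full")
  f2 <- time_vectorize(ep)
  expect_equal(ncol(f1b), 189)
  expect_equal(ncol(f1a), 3549)
  expect_equal(ncol(f2), 3570)
  for (fm in list(f1b, f1a, f2)) {
    cim <- attr(fm, "channel_index_map")
    expect_equal(length(cim), 21)
    expect_identical(sort(unlist(cim, use.names = FALSE)), seq_len(ncol(fm)))
  }
})

test_that("an on-bin cosine appears only in its own bin and channel", {
  Tn <- 400
  sig <- matrix(0, 21, Tn)
  fbin <- 2 * 200 / 170          # exactly DFT bin 2 of a 170-sample window
  tt <- (0:(Tn - 1)) / 200
  sig[8, ] <- cos(2 * pi * fbin * tt)   # channel C3
  # onset 171: the window starts a whole number of cycles in, so the bin-2
  # phase at the window start is zero and the imaginary part vanishes
  rec <- make_recording_with_onsets(Tn, onsets = 171, labels = 1,
                                    signals = sig)
  ep <- extract_windows(rec, "move")
  fm <- fourier_cartesian(ep, "0to5")
  v <- fm[1, ]
  cim <- attr(fm, "channel_index_map")
  # within C3's block (DC, Re1, Im1, Re2, Im2, ...) only Re2 is nonzero
  c3 <- v[cim[["C3"]]]
  expect_gt(abs(c3[4]), 50)     # Re of bin 2 = N/2 * amplitude-dependent
  expect_lt(max(abs(c3[-4])), 1e-9 * abs(c3[4]) + 1e-9)
  expect_lt(max(abs(v[-cim[["C3"]]])), 1e-9)
})

test_that("the 0-5 Hz band is self-consistent under inverse transform", {
  rec <- quick_recording(n_trials = 21, seed = 8)
  ep <- extract_windows(rec, "pre")
  fm <- fourier_cartesian(ep, "0to5")
  cim <- attr(fm, "channel_index_map")
  x <- ep$epochs[3, 5, ]
  # reconstruct the kept spectrum (bins 0..4 plus conjugates) and invert
  feats <- fm[3, cim[[5]]]
  spec <- complex(170)
  spec[1] <- feats[1]
  for (k in 1:4) {
    spec[k + 1] <- complex(real = feats[2 * k], imaginary = feats[2 * k + 1])
    spec[170 - k + 1] <- Conj(spec[k + 1])
  }
  lowpassed <- Re(fft(spec, inverse = TRUE)) / 170
  # oracle: zero out the same bins directly on the full spectrum
  full <- fft(x)
  full[6:166] <- 0
  expect_equal(lowpassed, Re(fft(full, inverse = TRUE)) / 170,
               tolerance = 1e-9)
})

test_that("time vectorization is an exact reshape round trip", {
  rec <- quick_recording(n_trials = 21, seed = 2)
  ep <- extract_windows(rec, "move")
  fm <- time_vectorize(ep)
  cim <- attr(fm, "channel_index_map")
  expect_equal(fm[4, cim[["Cz"]]], ep$epochs[4, 10, ])
  # zero epoch -> zero vector
  ep0 <- ep
  ep0$epochs[1, , ] <- 0
  expect_true(all(time_vectorize(ep0)[1, ] == 0))
})

test_that("PCA conditioning normalizes total variance to d_pc", {
  set.seed(31)
  X <- matrix(rnorm(200 * 12), 200, 12) %*% diag(sqrt(seq(0.1, 3, length.out = 12)))
  m <- pca_condition_fit(X, 5)
  Z <- pca_condition_apply(X, m)
  expect_equal(sum(apply(Z, 2, var)), 5, tolerance = 1e-6)
  expect_equal(crossprod(m$Q), diag(5), tolerance = 1e-10)
  # already-white data: scale factor 1
  n <- 5000
  W <- matrix(rnorm(n * 4), n, 4)
  W <- scale(W, scale = FALSE)
  W <- W %*% solve(chol(cov(W)))    # exactly unit covariance
  mw <- pca_condition_fit(W, 4)
  expect_equal(mw$scale_factor, 1, tolerance = 1e-6)
  # rank-1 data, d_pc = 1: transformed variance exactly 1
  r1 <- outer(rnorm(50), c(1, 2, 3))
  m1 <- pca_condition_fit(r1, 1)
  expect_equal(var(as.vector(pca_condition_apply(r1, m1))), 1,
               tolerance = 1e-8)
  expect_error(pca_condition_fit(r1, 2), "rank \\(1\\)")
})

test_that("PCA application reproduces the fit-time transform", {
  set.seed(5)
  X <- matrix(rnorm(30 * 6), 30, 6)
  m <- pca_condition_fit(X, 3)
  Z <- pca_condition_apply(X, m)
  expect_equal(sum(apply(Z, 2, var)), 3, tolerance = 1e-8)
  # the mean vector maps to zero
  expect_equal(as.vector(pca_condition_apply(rbind(m$center), m)),
               rep(0, 3), tolerance = 1e-10)
  # hand-computed 1-component projection of a fixed 3 x 2 matrix
  Xt <- matrix(c(0, 1, 2, 0, 2, 4), 3, 2)   # second column = 2 * first
  mt <- pca_condition_fit(Xt, 1)
  ctr <- c(1, 2)
  dirv <- c(1, 2) / sqrt(5)
  raw_scores <- as.vector((Xt - rep(ctr, each = 3)) %*% dirv)
  expected <- raw_scores * sqrt(1 / var(raw_scores))
  got <- as.vector(pca_condition_apply(Xt, mt))
  # sign of the principal direction is arbitrary
  expect_equal(abs(got), abs(expected), tolerance = 1e-8)
  expect_error(pca_condition_apply(matrix(0, 2, 5), mt), "columns")
})
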