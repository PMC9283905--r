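#' Fixed 10/20 channel order
#'
#' The 19 scalp electrodes of the international 10/20 montage plus the two ear
#' electrodes A1/A2, in the canonical order used throughout the package.
#'
#' @return character vector of 21 channel names.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "C3", "C4", "Cz",
    "T3", "T4", "T5", "T6", "P3", "P4", "Pz", "O1", "O2", "A1", "A2")
}

#' Continuous EEG recording container
#'
#' @param signals 21 x T numeric matrix (microvolts), rows in [eeg_channels()]
#'   order.
#' @param fs sampling rate in Hz; must be 200.
#' @param onsets strictly increasing 1-based sample indices of keypress
#'   (movement) onsets.
#' @param labels class per onset: 1 ("d" key) or 2 ("l" key).
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(signals, fs = 200, onsets = integer(),
                          labels = integer()) {
  signals <- as.matrix(signals)
  if (nrow(signals) != 21)
    stop("`signals` must have 21 rows (one per channel)", call. = FALSE)
  if (fs != 200) stop("sampling rate must be 200 Hz", call. = FALSE)
  if (length(onsets) != length(labels))
    stop("onsets and labels must have equal length", call. = FALSE)
  if (length(onsets) > 1 && any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing", call. = FALSE)
  if (length(labels) && !all(labels %in% c(1, 2)))
    stop("labels must be 1 or 2", call. = FALSE)
  structure(list(signals = signals, fs = fs, onsets = as.integer(onsets),
                 labels = as.integer(labels), channels = eeg_channels()),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: 21 ch x %d samples (%.1f s at %d Hz), %d onsets>\n",
              ncol(x$signals), ncol(x$signals) / x$fs, x$fs, length(x$onsets)))
  invisible(x)
}

#' Extract per-trial windows around movement onsets
#'
#' The pre-movement window covers the 0.85 s (170 samples) immediately before
#' each onset; the movement window covers the 170 samples starting at the
#' onset sample (half-open convention: the onset sample belongs to the
#' movement window, so the two windows are disjoint). Trials whose window
#' exits the recording are dropped with a message.
#'
#' @param rec an [eeg_recording()].
#' @param window `"pre"` or `"move"`.
#' @return an `epoch_set`: list with `epochs` (n x 21 x 170 array), `labels`,
#'   `window`, and `kept` (indices of retained trials).
#' @export
extract_windows <- function(rec, window = c("pre", "move")) {
  window <- match.arg(window)
  stopifnot(inherits(rec, "eeg_recording"))
  Tn <- ncol(rec$signals)
  w <- 170L
  if (window == "pre") {
    starts <- rec$onsets - w
    ends <- rec$onsets - 1L
  } else {
    starts <- rec$onsets
    ends <- rec$onsets + w - 1L
  }
  keep <- which(starts >= 1L & ends <= Tn)
  if (length(keep) < length(rec$onsets))
    message(sprintf("extract_windows: dropped %d/%d trials whose %s window leaves the recording",
                    length(rec$onsets) - length(keep), length(rec$onsets), window))
  if (length(keep) == 0)
    stop("no trial window fits inside the recording", call. = FALSE)
  ep <- array(0, dim = c(length(keep), 21L, w))
  for (i in seq_along(keep)) {
    k <- keep[i]
    ep[i, , ] <- rec$signals[, starts[k]:ends[k]]
  }
  structure(list(epochs = ep, labels = rec$labels[keep], window = window,
                 kept = keep, fs = rec$fs, channels = rec$channels),
            class = "epoch_set")
}

.new_feature_matrix <- function(X, feature_kind, per_channel, channels) {
  idx <- split(seq_len(ncol(X)),
               rep(seq_along(channels), each = per_channel))
  names(idx) <- channels
  structure(X, class = c("feature_matrix", "matrix"),
            feature_kind = feature_kind, channel_index_map = idx,
            channels = channels)
}

#' Cartesian Fourier features (Feature1)
#'
#' Per channel, the 170-point DFT of the epoch is taken; the retained complex
#' bins are split into (real, imaginary) pairs and concatenated channel by
#' channel. Bin k sits at frequency `k * 200/170` Hz. The DC bin contributes
#' its real part only; the Nyquist bin is excluded.
#'
#' * `band = "0to5"`: bins k = 0..4 (up to 4.71 Hz), 9 features/channel,
#'   d = 189 (Feature1-B).
#' * `band = "full"`: bins k = 0..84, 169 features/channel, d = 3549
#'   (Feature1-A).
#'
#' @param ep an `epoch_set` from [extract_windows()].
#' @param band `"0to5"` or `"full"`.
#' @return a `feature_matrix` (n x d) with attributes `feature_kind` and
#'   `channel_index_map`.
#' @export
fourier_cartesian <- function(ep, band = c("0to5", "full")) {
  band <- match.arg(band)
  stopifnot(inherits(ep, "epoch_set"))
  n <- dim(ep$epochs)[1]
  kmax <- if (band == "0to5") 4L else 84L
  per_ch <- 1L + 2L * kmax
  X <- matrix(0, n, 21L * per_ch)
  for (i in seq_len(n)) {
    # 170 x 21: one column per channel
    S <- t(ep$epochs[i, , ])
    Fc <- stats::mvfft(S)[seq_len(kmax + 1L), , drop = FALSE]
    feats <- apply(Fc, 2, function(col) {
      c(Re(col[1]), as.vector(rbind(Re(col[-1]), Im(col[-1]))))
    })
    X[i, ] <- as.vector(feats)
  }
  kind <- if (band == "0to5") "F1B" else "F1A"
  .new_feature_matrix(X, kind, per_ch, ep$channels)
}

#' Time-domain feature vectorization (Feature2)
#'
#' Flattens each n x 21 x 170 epoch into a 3570-dimensional vector in
#' channel-major order (channel 1's 170 samples first).
#'
#' @param ep an `epoch_set`.
#' @return a `feature_matrix` (n x 3570).
#' @export
time_vectorize <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  n <- dim(ep$epochs)[1]
  X <- matrix(0, n, 21L * 170L)
  for (i in seq_len(n)) X[i, ] <- as.vector(t(ep$epochs[i, , ]))
  .new_feature_matrix(X, "F2", 170L, ep$channels)
}

#' Fit PCA conditioning with total-variance normalization
#'
#' Mean-centers, projects onto the leading `d_pc` principal directions, and
#' applies one global scale `s` so that the total variance (trace of the
#' covariance) of the transformed training data equals `d_pc`. This gives the
#' downstream kernel scales (`sigma`, `sigma_SVM`) a predictable data range.
#'
#' @param X_train n x d training feature matrix.
#' @param d_pc number of components, or `NULL` for all non-zero-variance
#'   components (the rank).
#' @return a `pca_model`: list with `Q` (d x d_pc orthonormal loadings),
#'   `center`, `scale_factor`, `d_pc`.
#' @export
pca_condition_fit <- function(X_train, d_pc = NULL) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n < 2) stop("need at least 2 training samples", call. = FALSE)
  ctr <- colMeans(X_train)
  Xc <- sweep(X_train, 2, ctr)
  sv <- svd(Xc, nu = 0)
  tol <- max(dim(Xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > max(tol, 0))
  if (is.null(d_pc)) d_pc <- rank
  if (d_pc < 1) stop("`d_pc` must be >= 1", call. = FALSE)
  if (d_pc > rank)
    stop(sprintf("`d_pc` = %d exceeds the data rank (%d)", d_pc, rank),
         call. = FALSE)
  if (d_pc > n - 1)
    stop(sprintf("`d_pc` = %d exceeds n_train - 1 = %d", d_pc, n - 1),
         call. = FALSE)
  Q <- sv$v[, seq_len(d_pc), drop = FALSE]
  vars <- sv$d[seq_len(d_pc)]^2 / (n - 1)
  s <- sqrt(d_pc / sum(vars))
  structure(list(Q = Q, center = ctr, scale_factor = s, d_pc = d_pc),
            class = "pca_model")
}

#' Apply a fitted PCA conditioning model
#'
#' @param X n x d matrix in the original feature space.
#' @param model a `pca_model` from [pca_condition_fit()].
#' @return n x d_pc matrix `(X - center) %*% Q * s`.
#' @export
pca_condition_apply <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center))
    stop(sprintf("X has %d columns, model expects %d", ncol(X),
                 length(model$center)), call. = FALSE)
  sweep(X, 2, model$center) %*% model$Q * model$scale_factor
}
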