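#' Configuration for the synthetic EEG generator
#'
#' Emulates a self-paced binary keypress session: a continuous 21-channel
#' recording at 200 Hz with ~700 freely-timed onsets, balanced classes, a
#' readiness-potential-like slow negative drift on frontal channels before
#' each onset, a lateralized motor deflection on C3/C4 after it, and
#' white + 1/f background noise.
#'
#' @param n_trials number of keypress events (default 700, >= 20).
#' @param fs sampling rate (must be 200 Hz).
#' @param iti_mean,iti_jitter inter-trial interval mean and half-width of the
#'   uniform jitter, seconds (default 2.5 +/- 0.5).
#' @param effect_channels_pre channels carrying the pre-onset drift.
#' @param effect_channels_move channels carrying the post-onset deflection.
#' @param effect_band frequency band (Hz) the effect templates live in; the
#'   templates are half-period raised cosines over the 0.85 s window, whose
#'   fundamental falls inside the default 0.5-4 Hz band.
#' @param effect_amplitude peak effect amplitude in microvolts.
#' @param lateralization signed fraction by which class 1 vs class 2 flips
#'   the left/right weighting of the effect channels (0 = no class
#'   difference, 1 = fully lateralized).
#' @param noise_white,noise_pink standard-deviation-scale amplitudes of the
#'   white and 1/f background components (microvolts).
#' @param seed integer seed; the recording is fully reproducible from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_trials = 700, fs = 200, iti_mean = 2.5,
                         iti_jitter = 0.5,
                         effect_channels_pre = c("F3", "F4", "Fz"),
                         effect_channels_move = c("C3", "C4"),
                         effect_band = c(0.5, 4), effect_amplitude = 3,
                         lateralization = 0.5,
                         noise_white = 1, noise_pink = 1, seed = 1) {
  if (n_trials < 20) stop("`n_trials` must be >= 20", call. = FALSE)
  if (fs != 200) stop("`fs` must be 200", call. = FALSE)
  chans <- eeg_channels()
  bad <- setdiff(c(effect_channels_pre, effect_channels_move), chans)
  if (length(bad))
    stop("unresolvable channel name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (effect_amplitude < 0 || noise_white < 0 || noise_pink < 0)
    stop("amplitudes must be >= 0", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), fs = fs,
                 iti_mean = iti_mean, iti_jitter = iti_jitter,
                 effect_channels_pre = effect_channels_pre,
                 effect_channels_move = effect_channels_move,
                 effect_band = effect_band,
                 effect_amplitude = effect_amplitude,
                 lateralization = lateralization,
                 noise_white = noise_white, noise_pink = noise_pink,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f ("pink") noise of length n via spectral shaping: amplitude ~ f^(-1/2),
# so power ~ 1/f. Unit-variance before scaling. Computed at a 2-3-5-smooth
# padded length so the FFT stays O(n log n) for any requested n, then
# truncated.
.pink_noise <- function(n) {
  m <- stats::nextn(n)
  white <- stats::rnorm(m)
  spec <- stats::fft(white)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)          # symmetric frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)] / m
  as.vector(scale(x))
}

# Class weighting of a channel set: left-hemisphere channels (x < 0 in the
# montage) get weight (1 + s*lat), right-hemisphere (1 - s*lat); midline
# channels get the same amplitude modulation as the left side (the slow
# pre-movement potential differs by intended hand at the vertex as well);
# s = +1 for class 1, -1 for class 2. Every effect channel therefore carries
# class information of comparable strength.
.lateral_weights <- function(channels, class, lateralization) {
  mont <- montage_1020()
  x <- mont$x[match(channels, mont$channel)]
  s <- if (class == 1) 1 else -1
  ifelse(x > 0, 1 - s * lateralization, 1 + s * lateralization)
}

# Channel weights of the class-signed slow wave: +1 laterally, -1 on the
# midline. Orthogonal (over the channel set) to the lateralized drift
# contrast, so the two class directions spread evenly over the channels.
.wave_weights <- function(channels) {
  mont <- montage_1020()
  x <- mont$x[match(channels, mont$channel)]
  ifelse(x == 0, -1, 1)
}

#' Generate a synthetic continuous EEG recording
#'
#' Onsets are placed sequentially with jittered inter-trial intervals; class
#' labels are drawn balanced (counts differ by at most 1). Per trial, a
#' negative raised-cosine drift over the 170 pre-onset samples is added on
#' the pre-effect channels and a raised-cosine bump over the 170 post-onset
#' samples on the move-effect channels, both weighted by a class-dependent
#' left/right lateralization. Background noise (white + 1/f) is added to all
#' channels. A marker channel is not stored explicitly; the onsets/labels
#' fields carry the events, and [write_freeform_mat()] materializes the
#' marker on export.
#'
#' @param cfg a [synth_config()].
#' @return an [eeg_recording()].
#' @export
generate_recording <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr_seed(cfg$seed, {
    fs <- cfg$fs
    w <- 170L
    itis <- stats::runif(cfg$n_trials, cfg$iti_mean - cfg$iti_jitter,
                         cfg$iti_mean + cfg$iti_jitter)
    onsets <- as.integer(round(cumsum(itis) * fs)) + fs  # 1 s lead-in
    Tn <- max(onsets) + 2L * fs
    if (onsets[1] <= w)
      stop("recording too short for the first trial's pre-window",
           call. = FALSE)
    labels <- sample(rep_len(c(1L, 2L), cfg$n_trials))
    chans <- eeg_channels()
    sig <- matrix(0, 21L, Tn)
    if (cfg$noise_white > 0)
      sig <- sig + cfg$noise_white * matrix(stats::rnorm(21L * Tn), 21L, Tn)
    if (cfg$noise_pink > 0)
      for (ch in 1:21) sig[ch, ] <- sig[ch, ] + cfg$noise_pink * .pink_noise(Tn)

    t01 <- (seq_len(w) - 1) / (w - 1)
    # two-component effect per window: a shared template whose left/right
    # weighting flips with the class, plus a class-signed slow wave at half
    # amplitude on the same channels. Both are additive mean shifts, so for
    # binary labels they combine into a single discriminative direction
    # (mu1 - mu2) supported entirely on the effect channels.
    tpl_pre <- -cfg$effect_amplitude * 0.5 * (1 - cos(pi * t01))  # ramp to -A
    tpl_move <- cfg$effect_amplitude * 0.5 * (1 - cos(2 * pi * t01)) # bump
    tpl_sign <- cfg$effect_amplitude * 0.5 * sin(2 * pi * t01)    # 1.18 Hz
    i_pre <- match(cfg$effect_channels_pre, chans)
    i_move <- match(cfg$effect_channels_move, chans)
    wv_pre <- .wave_weights(cfg$effect_channels_pre)
    wv_move <- .wave_weights(cfg$effect_channels_move)
    for (k in seq_len(cfg$n_trials)) {
      on <- onsets[k]
      s <- if (labels[k] == 1) 1 else -1
      wpre <- .lateral_weights(cfg$effect_channels_pre, labels[k],
                               cfg$lateralization)
      wmove <- .lateral_weights(cfg$effect_channels_move, labels[k],
                                cfg$lateralization)
      pre_idx <- (on - w):(on - 1L)
      move_idx <- on:(on + w - 1L)
      for (j in seq_along(i_pre))
        sig[i_pre[j], pre_idx] <- sig[i_pre[j], pre_idx] +
          wpre[j] * tpl_pre + s * wv_pre[j] * tpl_sign
      for (j in seq_along(i_move))
        sig[i_move[j], move_idx] <- sig[i_move[j], move_idx] +
          wmove[j] * tpl_move + s * wv_move[j] * tpl_sign
    }
    eeg_recording(sig, fs = fs, onsets = onsets, labels = labels)
  })
}
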