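# Seeded synthetic EEG with class-dependent band power and a paired
# eye-closure stream, so the full pipeline is testable without external
# recordings.

#' Configuration of the synthetic EEG generator
#'
#' The generator emulates a 17-channel, 200 Hz vigilance recording: every
#' 8-s window belongs to a class (awake / fatigue), and its signal is a sum
#' of five band-limited oscillations whose RMS amplitudes depend on the
#' class, plus pink (1/f) background noise and a white floor. Oscillations
#' are narrowband-filtered noise rather than pure sinusoids, so short
#' frames never degenerate to zero variance. The default class profiles
#' encode the conventional drowsiness signature: fatigue elevates alpha
#' (3x the awake amplitude) and theta (2x) and attenuates beta and gamma;
#' alpha receives a posterior spatial boost. A per-window eye-closure
#' fraction is drawn from a class-dependent Beta distribution straddling
#' the 0.35 PERCLOS threshold (awake Beta(2, 18), fatigue Beta(9, 3.5));
#' both tails put about 0.3% of windows on the wrong side of the
#' threshold, so embedded PERCLOS labels agree with the requested classes
#' in over 99% of windows.
#'
#' @param n_channels Number of channels (default 17, the vigilance montage).
#' @param rate Sampling rate in Hz (default 200).
#' @param class_profiles Tibble `class x band` of RMS amplitudes in
#'   microvolts.
#' @param alpha_posterior_gain Extra alpha gain on PO/O channels.
#' @param pink_sd,white_sd Background noise RMS amplitudes in microvolts.
#' @param perclos_shapes Named list of `c(shape1, shape2)` Beta parameters
#'   per class.
#' @param seed Integer seed; every draw of the generator derives from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 17,
                         rate = 200,
                         class_profiles = NULL,
                         alpha_posterior_gain = 1.5,
                         pink_sd = 4,
                         white_sd = 2,
                         perclos_shapes = list(awake = c(2, 18),
                                               fatigue = c(9, 3.5)),
                         seed = 1L) {
  if (is.null(class_profiles)) {
    class_profiles <- tibble::tribble(
      ~class,     ~delta, ~theta, ~alpha, ~beta, ~gamma,
      "awake",         8,      5,      6,     9,      4,
      "fatigue",       9,     10,     18,   4.5,      2
    )
  }
  stopifnot(n_channels >= 1, rate > 2 * max(band_specs()$high))
  amps <- as.matrix(class_profiles[, band_specs()$band])
  if (any(amps < 0)) stop("band amplitudes must be non-negative",
                          call. = FALSE)
  structure(list(n_channels = n_channels, rate = rate,
                 class_profiles = class_profiles,
                 alpha_posterior_gain = alpha_posterior_gain,
                 pink_sd = pink_sd, white_sd = white_sd,
                 perclos_shapes = perclos_shapes, seed = as.integer(seed)),
            class = "synth_config")
}

# channels x bands gain matrix; posterior channels get the alpha boost
.spatial_gain <- function(cfg, channel_names) {
  g <- matrix(1, cfg$n_channels, 5,
              dimnames = list(channel_names, band_specs()$band))
  posterior <- grepl("^(PO|O)", channel_names)
  g[posterior, "alpha"] <- cfg$alpha_posterior_gain
  g
}

# band-limited unit-RMS noise, one column per channel, shaped in the
# frequency domain with raised-cosine edges
.band_noise <- function(n, n_ch, low, high, rate) {
  x <- matrix(stats::rnorm(n * n_ch), n, n_ch)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)                       # two-sided frequency axis
  edge <- max(0.5, 0.1 * (high - low))
  gain <- rep(0, n)
  inside <- f >= low & f <= high
  gain[inside] <- 1
  lo_r <- f >= low - edge & f < low
  gain[lo_r] <- 0.5 * (1 + cos(pi * (low - f[lo_r]) / edge))
  hi_r <- f > high & f <= high + edge
  gain[hi_r] <- 0.5 * (1 + cos(pi * (f[hi_r] - high) / edge))
  y <- Re(stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE)) / n
  sweep(y, 2, pmax(apply(y, 2, stats::sd), 1e-12), "/")
}

# 1/f background: white noise with 1/sqrt(f) amplitude shaping
.pink_noise <- function(n, n_ch, rate) {
  x <- matrix(stats::rnorm(n * n_ch), n, n_ch)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)
  gain <- ifelse(f < 0.5, 0, 1 / sqrt(f))
  y <- Re(stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE)) / n
  sweep(y, 2, pmax(apply(y, 2, stats::sd), 1e-12), "/")
}

#' Generate a synthetic labelled EEG recording
#'
#' Produces one 8-s window per entry of `class_sequence`, each with the
#' band-power profile of its class, plus a paired eye-closure stream whose
#' PERCLOS values are consistent with the class. Fully determined by
#' `cfg$seed` (plus `seed_offset`).
#'
#' @param cfg A [synth_config()].
#' @param class_sequence Character vector of window classes, e.g.
#'   `c("awake", "fatigue", ...)`.
#' @param seed_offset Added to `cfg$seed`, letting several independent
#'   recordings derive from one configuration.
#' @return A list with `recording` (an [eeg_recording()]) and `labels`, a
#'   tibble with one row per window: `window`, `window_start_s`, `class`,
#'   `eye_closure_s`, `perclos`.
#' @export
generate_recording <- function(cfg, class_sequence, seed_offset = 0L) {
  if (length(class_sequence) == 0) {
    stop("class_sequence must be non-empty", call. = FALSE)
  }
  known <- cfg$class_profiles$class
  if (!all(class_sequence %in% known)) {
    stop("unknown class in sequence; configured classes: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  bands <- band_specs()
  win_s <- 8
  n_win <- length(class_sequence)
  n <- win_s * cfg$rate
  channel_names <- if (cfg$n_channels == 17) vigilance_channels() else
    paste0("CH", seq_len(cfg$n_channels))
  spat <- .spatial_gain(cfg, channel_names)
  amps <- as.matrix(cfg$class_profiles[, bands$band])
  rownames(amps) <- cfg$class_profiles$class

  data <- matrix(0, cfg$n_channels, n_win * n)
  closure <- numeric(n_win)
  withr::with_seed(cfg$seed + seed_offset, {
    for (wdx in seq_len(n_win)) {
      cls <- class_sequence[wdx]
      win <- matrix(0, n, cfg$n_channels)
      for (b in seq_len(nrow(bands))) {
        osc <- .band_noise(n, cfg$n_channels, bands$low[b], bands$high[b],
                           cfg$rate)
        win <- win + osc * rep(amps[cls, b] * spat[, b], each = n)
      }
      win <- win + cfg$pink_sd * .pink_noise(n, cfg$n_channels, cfg$rate)
      win <- win + cfg$white_sd * matrix(stats::rnorm(n * cfg$n_channels),
                                         n, cfg$n_channels)
      data[, (wdx - 1) * n + seq_len(n)] <- t(win)
      sh <- cfg$perclos_shapes[[cls]]
      closure[wdx] <- win_s * stats::rbeta(1, sh[1], sh[2])
    }
  })

  labels <- tibble::tibble(
    window = seq_len(n_win),
    window_start_s = (seq_len(n_win) - 1) * win_s,
    class = class_sequence,
    eye_closure_s = closure,
    perclos = closure / win_s
  )
  list(recording = eeg_recording(data, cfg$rate, channel_names),
       labels = labels)
}

#' Generate a ready-to-train 4D feature dataset
#'
#' Composes [generate_recording()], segmentation and [build_features()]:
#' draws a shuffled class sequence with the requested per-class counts,
#' synthesises the EEG, and converts every 8-s window into an
#' `h x w x d x 2T` entropy tensor.
#'
#' @param cfg A [synth_config()].
#' @param n_per_class Named integer vector of window counts per class,
#'   e.g. `c(awake = 100, fatigue = 100)`; unequal counts give an
#'   imbalanced dataset with exactly the requested ratio.
#' @param grid Electrode grid (default dense 6 x 9).
#' @param scale If `TRUE` (default), z-score mapped cells and store the
#'   scaler on the dataset.
#' @param seed_offset Passed to [generate_recording()].
#' @return A [feature_dataset()] with `labels` set to the requested
#'   classes and `perclos` holding the embedded eye-closure fractions.
#' @export
generate_feature_dataset <- function(cfg, n_per_class,
                                     grid = electrode_grid(),
                                     scale = TRUE, seed_offset = 0L) {
  stopifnot(!is.null(names(n_per_class)), all(n_per_class >= 0))
  seq_cls <- rep(names(n_per_class), times = n_per_class)
  seq_cls <- withr::with_seed(cfg$seed + seed_offset + 1L,
                              sample(seq_cls))
  gen <- generate_recording(cfg, seq_cls, seed_offset = seed_offset)
  segs <- segment_recording(gen$recording)
  feats <- lapply(segs, build_features, rate = cfg$rate,
                  channel_names = gen$recording$channel_names, grid = grid)
  ds <- feature_dataset(feats, factor(seq_cls, levels = names(n_per_class)),
                        grid = grid, perclos = gen$labels$perclos)
  if (scale) ds <- scale_features(ds)
  ds
}
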