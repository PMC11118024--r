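# Raw-recording handling: trimming, resampling, segmentation, framing,
# and PERCLOS-based labelling.

#' Construct a raw EEG recording
#'
#' A recording is a channels x samples matrix (microvolts) plus its sampling
#' rate and 10-20 channel names.
#'
#' @param data Numeric matrix, channels in rows.
#' @param rate Sampling rate in Hz.
#' @param channel_names Character vector, one unique name per row.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_names) {
  data <- as.matrix(data)
  if (nrow(data) < 1) stop("recording needs at least one channel",
                           call. = FALSE)
  if (rate <= 0) stop("sampling rate must be positive", call. = FALSE)
  if (length(channel_names) != nrow(data)) {
    stop("need one channel name per row", call. = FALSE)
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique",
                                         call. = FALSE)
  structure(list(data = data, rate = rate,
                 channel_names = as.character(channel_names)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$rate

#' Trim seconds from both ends of a recording
#'
#' Discards a stretch at the start and end of the session, where electrode
#' settling and task onset/offset make the signal unreliable.
#'
#' @param rec An `eeg_recording`.
#' @param head_s,tail_s Seconds to remove from the start and the end.
#' @return The trimmed `eeg_recording`; channel order is unchanged.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 100), 2), 10, c("A", "B"))
#' recording_duration(trim_recording(rec, 2, 3))   # 5 s
#' @export
trim_recording <- function(rec, head_s, tail_s = head_s) {
  stopifnot(head_s >= 0, tail_s >= 0)
  n <- ncol(rec$data)
  drop_head <- round(head_s * rec$rate)
  drop_tail <- round(tail_s * rec$rate)
  if (drop_head + drop_tail >= n) {
    stop("recording shorter than the requested trim (",
         head_s + tail_s, " s)", call. = FALSE)
  }
  rec$data <- rec$data[, (drop_head + 1):(n - drop_tail), drop = FALSE]
  rec
}

#' Downsample a recording
#'
#' Anti-aliased resampling of every channel to `target_rate`, performed in
#' the frequency domain: the spectrum is truncated at the new Nyquist
#' frequency (an ideal low-pass guard) and inverted at the new length.
#' This is exact for band-limited content away from the segment edges and
#' handles integer and rational rate ratios alike.
#'
#' @param rec An `eeg_recording`.
#' @param target_rate Target sampling rate in Hz; must not exceed the
#'   recording rate.
#' @return The resampled `eeg_recording` at `target_rate`; duration is
#'   preserved to within one sample.
#' @export
downsample_recording <- function(rec, target_rate) {
  if (target_rate > rec$rate) {
    stop("target rate (", target_rate, " Hz) exceeds recording rate (",
         rec$rate, " Hz)", call. = FALSE)
  }
  if (target_rate == rec$rate) return(rec)
  n <- ncol(rec$data)
  m <- floor(n * target_rate / rec$rate)
  X <- stats::mvfft(t(rec$data))
  keep <- min(floor(m / 2), floor(n / 2))       # bins below new Nyquist
  Y <- matrix(0i, m, nrow(rec$data))
  Y[1, ] <- X[1, ]
  if (keep >= 1) {
    Y[2:(keep + 1), ] <- X[2:(keep + 1), ]
    Y[m - (1:keep) + 1, ] <- X[n - (1:keep) + 1, ]
  }
  out <- t(Re(stats::mvfft(Y, inverse = TRUE)) / n)
  rec$data <- out
  rec$rate <- target_rate
  rec
}

#' Cut a recording into non-overlapping fixed-length segments
#'
#' Vigilance labels arrive one per 8-second window, so the default segment
#' length is 8 s; the trailing remainder shorter than one segment is
#' discarded.
#'
#' @param rec An `eeg_recording`.
#' @param seg_s Segment length in seconds (default 8).
#' @return A list of channels x (seg_s * rate) matrices, chronological,
#'   each carrying a `start_s` attribute. Empty list if the recording is
#'   shorter than one segment.
#' @export
segment_recording <- function(rec, seg_s = 8) {
  len <- round(seg_s * rec$rate)
  n_seg <- ncol(rec$data) %/% len
  if (n_seg == 0) return(list())
  lapply(seq_len(n_seg), function(i) {
    seg <- rec$data[, ((i - 1) * len + 1):(i * len), drop = FALSE]
    attr(seg, "start_s") <- (i - 1) * seg_s
    seg
  })
}

#' Split a segment into non-overlapping frames
#'
#' An 8-s segment at 200 Hz with the default half-second frame yields
#' 2T = 16 frames of 100 samples; concatenating the frames in order
#' reproduces the segment exactly.
#'
#' @param seg A channels x samples matrix (one segment).
#' @param rate Sampling rate in Hz.
#' @param frame_s Frame length in seconds; must divide the segment duration
#'   exactly.
#' @return A 3D array `channels x n_frames x samples_per_frame`.
#' @export
frame_segment <- function(seg, rate, frame_s = 0.5) {
  m <- nrow(seg)
  n <- ncol(seg)
  spf <- frame_s * rate
  if (abs(spf - round(spf)) > 1e-9) {
    stop("frame length must be a whole number of samples", call. = FALSE)
  }
  spf <- round(spf)
  if (n %% spf != 0) {
    stop("frame length (", frame_s, " s) does not divide the segment",
         call. = FALSE)
  }
  nf <- n %/% spf
  out <- array(0, dim = c(m, nf, spf))
  for (f in seq_len(nf)) {
    out[, f, ] <- seg[, ((f - 1) * spf + 1):(f * spf), drop = FALSE]
  }
  out
}

#' PERCLOS: percentage of eye closure over an observation window
#'
#' The ratio of eye-closure time to the total observed time, the standard
#' vigilance ground truth. The observation window defaults to the 8-s
#' labelling window.
#'
#' @param closure_s Seconds the eyes were closed (vectorised).
#' @param window_s Total observed time in seconds (> 0).
#' @return A tibble with columns `eye_closure_s`, `window_s`, `perclos`.
#' @examples
#' perclos(4, 8)$perclos   # 0.5
#' @export
perclos <- function(closure_s, window_s = 8) {
  if (any(window_s <= 0)) stop("window must be positive", call. = FALSE)
  if (any(closure_s < 0 | closure_s > window_s)) {
    stop("closure time must lie in [0, window]", call. = FALSE)
  }
  tibble::tibble(eye_closure_s = closure_s, window_s = window_s,
                 perclos = closure_s / window_s)
}

#' Vigilance class from PERCLOS
#'
#' Binary labelling splits awake from fatigue at PERCLOS 0.35; the ternary
#' scheme adds a drowsy class at 0.7. Values falling exactly on a threshold
#' are assigned to the more fatigued class by default (`strict = FALSE`);
#' `strict = TRUE` uses strict inequality instead, since label conventions
#' at the boundary differ between datasets.
#'
#' @param p Numeric PERCLOS values in `[0, 1]`, or a tibble from
#'   [perclos()].
#' @param scheme `"binary"` or `"ternary"`.
#' @param strict Boundary handling, see above.
#' @return A factor with levels `awake`, `fatigue` (and `drowsy` for the
#'   ternary scheme); monotone non-decreasing in `p`.
#' @examples
#' label_from_perclos(c(0.34, 0.5, 0.7))
#' @export
label_from_perclos <- function(p, scheme = c("binary", "ternary"),
                               strict = FALSE) {
  scheme <- match.arg(scheme)
  if (is.data.frame(p)) p <- p$perclos
  stopifnot(all(p >= 0 & p <= 1))
  at_least <- function(x, thr) if (strict) x > thr else x >= thr
  if (scheme == "binary") {
    factor(ifelse(at_least(p, 0.35), "fatigue", "awake"),
           levels = c("awake", "fatigue"))
  } else {
    factor(ifelse(at_least(p, 0.7), "drowsy",
                  ifelse(at_least(p, 0.35), "fatigue", "awake")),
           levels = c("awake", "fatigue", "drowsy"))
  }
}

# ---- plain-text recording container ---------------------------------------

#' Read or write a recording as a plain-text container
#'
#' A recording directory holds `data.csv` (channels x samples, no header)
#' and `meta.yaml` with fields `rate` and `channel_names`. Label streams
#' travel as `labels.csv` with columns `window_start_s` and either
#' `eye_closure_s` or `perclos`.
#'
#' @param dir Directory path.
#' @param rec An `eeg_recording`.
#' @return `read_recording()` returns an `eeg_recording`.
#' @export
read_recording <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  dat <- as.matrix(utils::read.csv(file.path(dir, "data.csv"),
                                   header = FALSE))
  dimnames(dat) <- NULL
  eeg_recording(dat, meta$rate, meta$channel_names)
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(rate = rec$rate,
                        channel_names = rec$channel_names),
                   file.path(dir, "meta.yaml"))
  utils::write.table(rec$data, file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a label stream CSV
#'
#' @param path CSV with columns `window_start_s` and `eye_closure_s` or
#'   `perclos`.
#' @param window_s Observation window used to convert closure times.
#' @return A tibble with `window_start_s` and `perclos`.
#' @export
read_label_stream <- function(path, window_s = 8) {
  d <- tibble::as_tibble(utils::read.csv(path))
  if (!"perclos" %in% names(d)) {
    if (!"eye_closure_s" %in% names(d)) {
      stop("label stream needs `perclos` or `eye_closure_s`", call. = FALSE)
    }
    d$perclos <- perclos(d$eye_closure_s, window_s)$perclos
  }
  d[, c("window_start_s", "perclos")]
}
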