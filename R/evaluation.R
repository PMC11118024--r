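# Classification metrics and wavelet-coherence similarity between signal
# sets.

#' Classification metrics from truth and prediction
#'
#' Accuracy, precision, recall, F1 and Cohen's kappa from the contingency
#' table. For two classes, precision/recall/F1 refer to the positive class
#' (by default the last factor level, i.e. `fatigue` under the package's
#' labelling); with more classes they are macro-averaged. Kappa is
#' `(p_o - p_e) / (1 - p_e)` with `p_e` the chance agreement implied by the
#' marginals; if the truth contains a single class, kappa is undefined and
#' returned as `NaN` with a warning.
#'
#' @param truth,pred Vectors or factors of equal length.
#' @param positive Positive class for binary precision/recall (default:
#'   last level of `truth`).
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `kappa`.
#' @examples
#' classification_metrics(c(1, 0, 0, 0), c(1, 1, 0, 0), positive = "1")
#' @export
classification_metrics <- function(truth, pred, positive = NULL) {
  stopifnot(length(truth) == length(pred))
  lev <- if (is.factor(truth)) levels(truth) else
    sort(unique(as.character(c(truth, pred))))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  tab <- table(truth, pred)
  n <- sum(tab)
  acc <- sum(diag(tab)) / n

  prf <- function(cls) {
    tp <- tab[cls, cls]
    p <- if (sum(tab[, cls]) == 0) 0 else tp / sum(tab[, cls])
    r <- if (sum(tab[cls, ]) == 0) 0 else tp / sum(tab[cls, ])
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }
  if (length(lev) == 2) {
    if (is.null(positive)) positive <- lev[length(lev)]
    m <- prf(positive)
  } else {
    present <- lev[rowSums(tab) > 0]
    m <- rowMeans(vapply(present, prf, numeric(3)))
  }

  if (length(unique(as.character(truth))) < 2) {
    warning("single-class truth: kappa undefined", call. = FALSE)
    kappa <- NaN
  } else {
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    kappa <- if (pe == 1) NaN else (acc - pe) / (1 - pe)
  }
  tibble::tibble(accuracy = acc, precision = m[1], recall = m[2],
                 f1 = m[3], kappa = kappa)
}

# ---- wavelet coherence -----------------------------------------------------

# Analytic Morlet CWT (omega0 = 6) computed in the frequency domain on a
# logarithmic scale grid. Returns a scales x time complex matrix.
.morlet_cwt <- function(x, scales, omega0 = 6) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  omega <- 2 * pi * (seq_len(n) - 1) / n
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  W <- matrix(0i, length(scales), n)
  norm0 <- pi^(-0.25)
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi <- numeric(n)
    pos <- omega > 0
    psi[pos] <- norm0 * sqrt(2 * pi * s) * exp(-0.5 * (s * omega[pos] - omega0)^2)
    W[i, ] <- stats::fft(X * psi, inverse = TRUE) / n
  }
  W
}

# boxcar smoothing along time (width ~ scale) and a 3-voice boxcar across
# scales; without smoothing the coherence of Eq-style normalisation is
# identically 1
.wc_smooth <- function(M, scales) {
  n <- ncol(M)
  for (i in seq_along(scales)) {
    w <- max(5L, 2L * floor(scales[i] / 2) + 1L)
    w <- min(w, 2L * floor((n - 1) / 2) + 1L)
    k <- rep(1 / w, w)
    row <- stats::filter(M[i, ], k, sides = 2, circular = TRUE)
    M[i, ] <- as.numeric(row)
  }
  if (nrow(M) >= 3) {
    sm <- M
    for (i in seq_len(nrow(M))) {
      lo <- max(1, i - 1); hi <- min(nrow(M), i + 1)
      sm[i, ] <- colMeans(M[lo:hi, , drop = FALSE])
    }
    M <- sm
  }
  M
}

#' Wavelet coherence between two time series
#'
#' Computes the smoothed, normalised cross-wavelet measure
#' `|S(conj(Cx) * Cy)|^2 / (S(|Cx|^2) * S(|Cy|^2))` on an analytic Morlet
#' (omega0 = 6) scale grid of `n_scales` logarithmic voices spanning
#' periods from 4 samples to n/4. The smoothing operator `S` is a boxcar
#' in time with width proportional to scale and a 3-voice boxcar across
#' scales. Every cell lies in `[0, 1]`; the measure is symmetric in its
#' arguments, and identical series give coherence 1 everywhere.
#'
#' @param x,y Numeric vectors of equal length (at least 32 samples).
#' @param n_scales Number of logarithmic scale voices (default 32).
#' @return A `wc_report`: list with `matrix` (scales x time), `periods`
#'   (in samples) and `scalar` (the collapsed score, see [wc_scalar()]).
#' @export
wavelet_coherence <- function(x, y, n_scales = 32) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 32) stop("need at least 32 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant series: coherence undefined", call. = FALSE)
  }
  periods <- exp(seq(log(4), log(n / 4), length.out = n_scales))
  fourier <- (4 * pi) / (6 + sqrt(2 + 36))     # period per unit scale
  scales <- periods / fourier
  Cx <- .morlet_cwt(x, scales)
  Cy <- .morlet_cwt(y, scales)
  Sxy <- .wc_smooth(Re(Conj(Cx) * Cy), scales)
  Qxy <- .wc_smooth(Im(Conj(Cx) * Cy), scales)
  Sxx <- .wc_smooth(Mod(Cx)^2, scales)
  Syy <- .wc_smooth(Mod(Cy)^2, scales)
  wc <- (Sxy^2 + Qxy^2) / pmax(Sxx * Syy, 1e-300)
  wc <- pmin(pmax(wc, 0), 1)
  out <- list(matrix = wc, periods = periods)
  out$scalar <- wc_scalar(out)
  structure(out, class = "wc_report")
}

#' Collapse a coherence matrix to a scalar score
#'
#' Averages along the time axis first, then across scales, so the score
#' stays in `[0, 1]` regardless of signal length and can be read as a
#' percentage.
#'
#' @param report A `wc_report` or a plain scales x time matrix.
#' @return A scalar in `[0, 1]`.
#' @export
wc_scalar <- function(report) {
  M <- if (is.list(report)) report$matrix else report
  mean(rowMeans(M))
}

#' Wavelet-coherence score between multi-channel signals
#'
#' @param x,y Channels x time matrices with matching shapes; coherence is
#'   computed channel by channel and averaged.
#' @param n_scales Scale voices per channel comparison.
#' @return A scalar in `[0, 1]`.
#' @export
wc_multidim <- function(x, y, n_scales = 32) {
  stopifnot(all(dim(x) == dim(y)))
  mean(vapply(seq_len(nrow(x)), function(i) {
    wavelet_coherence(x[i, ], y[i, ], n_scales)$scalar
  }, numeric(1)))
}

#' Average wavelet coherence between two groups of signals
#'
#' Scores every cross pair (a in A, b in B) with [wc_multidim()] and
#' averages, giving a similarity measure between, e.g., a set of real and
#' a set of generated signals.
#'
#' @param A,B Non-empty lists of channels x time matrices.
#' @param n_scales Scale voices.
#' @return A scalar in `[0, 1]`.
#' @export
wc_groups <- function(A, B, n_scales = 32) {
  stopifnot(length(A) > 0, length(B) > 0)
  scores <- vapply(A, function(a) {
    vapply(B, function(b) wc_multidim(a, b, n_scales), numeric(1))
  }, numeric(length(B)))
  mean(scores)
}

#' Band-frame profile of a 4D feature tensor
#'
#' The dimensionality reduction used when scoring generated against real
#' feature tensors with wavelet coherence: each mapped electrode cell
#' yields one row tracing its five band entropies frame by frame
#' (d * 2T = 80 samples under the defaults), long enough for the wavelet
#' scale grid while retaining the band-time structure of the tensor.
#'
#' @param x An `h x w x d x 2T` array.
#' @param grid The electrode grid that built the tensor.
#' @return A channels x (d * 2T) matrix, one row per mapped cell.
#' @export
feature_profile <- function(x, grid = electrode_grid()) {
  t(vapply(seq_len(nrow(grid)), function(i) {
    as.vector(x[grid$row[i], grid$col[i], , ])
  }, numeric(dim(x)[3] * dim(x)[4])))
}
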