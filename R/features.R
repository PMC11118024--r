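# Band decomposition, differential entropy, and the 4D feature tensor:
# grid height x grid width x frequency band x time frame.

#' The five canonical EEG frequency bands
#'
#' delta (1-4 Hz), theta (4-8 Hz), alpha (8-14 Hz), beta (14-31 Hz) and
#' gamma (31-51 Hz); band edges are half-power (-3 dB) corners of the
#' band-pass filters.
#'
#' @return A tibble with columns `band`, `low`, `high` in the fixed
#'   delta-to-gamma order.
#' @export
band_specs <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 8, 14, 31),
    high = c(4, 8, 14, 31, 51)
  )
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (zero phase, squared magnitude response). The two-pass transfer function
#' is evaluated on the FFT grid and applied spectrally, which is exact for
#' the periodic extension of the signal and lets a whole multi-channel
#' segment be filtered with two FFTs per channel; a direct
#' `signal::filtfilt()` pass gives the same response away from the segment
#' edges and is used as the reference in the test-suite.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param low,high Band edges in Hz, `0 < low < high < rate / 2`.
#' @param rate Sampling rate in Hz.
#' @param order Butterworth order of each pass (default 4).
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, low, high, rate, order = 4) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (low <= 0 || high <= low) stop("need 0 < low < high", call. = FALSE)
  if (high >= rate / 2) {
    stop("band edge ", high, " Hz at or above Nyquist (", rate / 2, " Hz)",
         call. = FALSE)
  }
  n <- ncol(x)
  H2 <- .butter_mag2(n, low, high, rate, order)
  X <- stats::mvfft(t(x))
  y <- t(Re(stats::mvfft(X * H2, inverse = TRUE)) / n)
  if (vec) drop(y) else y
}

# squared magnitude of the digital Butterworth band-pass on the fft grid,
# memoised since the same (n, band, rate) combination recurs per segment
.butter_cache <- new.env(parent = emptyenv())

.butter_mag2 <- function(n, low, high, rate, order) {
  key <- paste(n, low, high, rate, order, sep = "|")
  hit <- .butter_cache[[key]]
  if (!is.null(hit)) return(hit)
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1) / n
  z <- exp(-1i * outer(w, 0:(length(bf$b) - 1)))
  H <- as.vector(z %*% bf$b) / as.vector(z %*% bf$a)
  out <- Mod(H)^2
  .butter_cache[[key]] <- out
  out
}

#' Differential entropy of a signal frame
#'
#' The differential entropy of a continuous random variable is
#' `-integral f(x) log f(x) dx`. For a band-limited EEG frame modelled as
#' Gaussian this has the closed form `0.5 * log(2 * pi * e * sigma^2)`,
#' estimated here from the frame sample variance. Degenerate
#' (near-constant) frames are floored at `var_floor` inside the logarithm,
#' with a warning.
#'
#' @param x Numeric vector (one frame), or a matrix/array whose last
#'   dimension indexes samples, in which case entropy is computed along it.
#' @param var_floor Variance floor guarding against `-Inf` (default 1e-12).
#' @return Differential entropy in nats (scalar, or array with the last
#'   dimension dropped).
#' @examples
#' differential_entropy(rnorm(1e4))          # about 0.5 * log(2 * pi * e)
#' @export
differential_entropy <- function(x, var_floor = 1e-12) {
  if (is.null(dim(x))) {
    if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
    v <- stats::var(x)
    if (v < var_floor) {
      warning("near-constant frame: variance floored at ", var_floor,
              call. = FALSE)
      v <- var_floor
    }
    return(0.5 * log(2 * pi * exp(1) * v))
  }
  d <- dim(x)
  nd <- length(d)
  n <- d[nd]
  m <- matrix(aperm(x, c(nd, seq_len(nd - 1))), nrow = n)
  mu <- colMeans(m)
  v <- colSums(m^2) / n - mu^2
  v <- v * n / (n - 1)
  if (any(v < var_floor)) {
    warning("near-constant frame(s): variance floored at ", var_floor,
            call. = FALSE)
    v <- pmax(v, var_floor)
  }
  out <- 0.5 * log(2 * pi * exp(1) * v)
  if (nd == 2) out else array(out, dim = d[-nd])
}

#' Map per-channel entropies onto the electrode grid
#'
#' Fills an `h x w x d x 2T` tensor: the cell mapped to each channel holds
#' that channel's entropy for each band and frame; unmapped cells are
#' exactly zero.
#'
#' @param de A channels x bands x frames array of differential entropies.
#' @param grid Grid tibble from [electrode_grid()].
#' @param channel_names Channel name for each row of `de`.
#' @return An `h x w x d x 2T` numeric array.
#' @export
map_to_grid <- function(de, grid, channel_names) {
  validate_grid(grid)
  h <- attr(grid, "h"); w <- attr(grid, "w")
  miss <- setdiff(channel_names, grid$channel)
  if (length(miss) > 0) {
    stop("channels missing from grid mapping: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- dim(de)[2]; nf <- dim(de)[3]
  out <- array(0, dim = c(h, w, d, nf))
  idx <- match(channel_names, grid$channel)
  for (i in seq_along(channel_names)) {
    out[grid$row[idx[i]], grid$col[idx[i]], , ] <- de[i, , ]
  }
  out
}

#' Build the 4D feature tensor for one segment
#'
#' Pipeline: band-pass the segment into the five canonical bands, cut each
#' band-limited signal into half-second frames, compute the Gaussian
#' differential entropy of every (channel, band, frame), and place the
#' entropies on the 2D electrode grid. Filtering precedes framing so the
#' short frames carry no filter transients.
#'
#' @param seg A channels x samples matrix (one 8-s segment).
#' @param rate Sampling rate in Hz.
#' @param channel_names Channel name per row of `seg`.
#' @param grid Grid tibble (default dense 6 x 9).
#' @param bands Band table (default [band_specs()]).
#' @param frame_s Frame length in seconds (default 0.5, giving 2T = 16).
#' @return An `h x w x d x 2T` array; `(6, 9, 5, 16)` under the defaults.
#' @export
build_features <- function(seg, rate, channel_names,
                           grid = electrode_grid(), bands = band_specs(),
                           frame_s = 0.5) {
  m <- nrow(seg)
  spf <- round(frame_s * rate)
  nf <- ncol(seg) %/% spf
  if (nf * spf != ncol(seg)) {
    stop("frame length must divide the segment", call. = FALSE)
  }
  de <- array(0, dim = c(m, nrow(bands), nf))
  for (b in seq_len(nrow(bands))) {
    filt <- bandpass_filter(seg, bands$low[b], bands$high[b], rate)
    framed <- frame_segment(filt, rate, frame_s)   # m x nf x spf
    de[, b, ] <- differential_entropy(framed)
  }
  map_to_grid(de, grid, channel_names)
}

#' Stack per-segment features into a dataset
#'
#' @param features List of `h x w x d x 2T` arrays.
#' @param labels Factor or vector of class labels, one per feature tensor.
#' @param grid The grid the features were built on.
#' @param perclos Optional per-segment PERCLOS values.
#' @return A `feature_dataset`: list with `x` (h x w x d x 2T x N array),
#'   `labels`, `grid`, `perclos`, and an optional `scaler`.
#' @export
feature_dataset <- function(features, labels, grid = electrode_grid(),
                            perclos = NULL) {
  stopifnot(length(features) == length(labels))
  d1 <- dim(features[[1]])
  x <- array(0, dim = c(d1, length(features)))
  for (i in seq_along(features)) x[, , , , i] <- features[[i]]
  structure(list(x = x, labels = factor(labels), grid = grid,
                 perclos = perclos, scaler = NULL),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<feature_dataset> %d samples of %d x %d x %d x %d features\n",
              d[5], d[1], d[2], d[3], d[4]))
  print(table(x$labels))
  invisible(x)
}

#' Number of samples in a feature dataset
#' @param ds A `feature_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) dim(ds$x)[5]

#' Standardise mapped grid cells of a feature dataset
#'
#' Entropies at mapped electrode cells are z-scored with a single mean and
#' standard deviation estimated over the whole dataset; unmapped cells stay
#' exactly zero, preserving the grid's zero-padding invariant. The fitted
#' scaler is stored on the dataset so generated samples can be mapped back
#' with [unscale_features()].
#'
#' @param ds A `feature_dataset`.
#' @param scaler Optional precomputed `list(mean, sd)` to apply (e.g. the
#'   training-set scaler applied to a test set).
#' @return The dataset with scaled `x` and a `scaler` element.
#' @export
scale_features <- function(ds, scaler = NULL) {
  mask <- grid_mask(ds$grid)
  d <- dim(ds$x)
  mask5 <- array(mask, dim = d)   # recycles over d, 2T, N
  vals <- ds$x[mask5]
  if (is.null(scaler)) {
    scaler <- list(mean = mean(vals), sd = stats::sd(vals))
    if (scaler$sd == 0) scaler$sd <- 1
  }
  ds$x[mask5] <- (vals - scaler$mean) / scaler$sd
  ds$scaler <- scaler
  ds
}

#' @rdname scale_features
#' @param x An `h x w x d x 2T (x N)` array in scaled units.
#' @export
unscale_features <- function(x, scaler) {
  x * scaler$sd + scaler$mean
}

#' Logical mask of mapped grid cells
#' @param grid Grid tibble.
#' @return An `h x w` logical matrix, `TRUE` where an electrode is mapped.
#' @export
grid_mask <- function(grid) {
  h <- attr(grid, "h"); w <- attr(grid, "w")
  m <- matrix(FALSE, h, w)
  m[cbind(grid$row, grid$col)] <- TRUE
  m
}

#' Subset a feature dataset by sample index
#' @param ds A `feature_dataset`.
#' @param idx Integer sample indices.
#' @return A `feature_dataset` with the selected samples.
#' @export
subset_dataset <- function(ds, idx) {
  ds$x <- ds$x[, , , , idx, drop = FALSE]
  ds$labels <- ds$labels[idx]
  if (!is.null(ds$perclos)) ds$perclos <- ds$perclos[idx]
  ds
}

#' Concatenate feature datasets
#' @param ... `feature_dataset` objects on the same grid.
#' @return A single combined `feature_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  x <- array(0, dim = c(dim(parts[[1]]$x)[1:4],
                        sum(vapply(parts, n_samples, 0L))))
  at <- 0L
  for (p in parts) {
    n <- n_samples(p)
    if (n > 0) x[, , , , at + seq_len(n)] <- p$x
    at <- at + n
  }
  out <- parts[[1]]
  out$x <- x
  out$labels <- factor(unlist(lapply(parts, function(p)
    as.character(p$labels))), levels = levels(parts[[1]]$labels))
  out$perclos <- NULL
  out
}
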