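#' Remove baseline drift by least-squares polynomial fit
#'
#' Fits a polynomial trend (degree 1 by default) by ordinary least squares
#' and subtracts it, removing slow baseline drift from a single-channel
#' series. With `degree = 1` the returned series has (numerically) zero mean
#' and zero linear slope.
#'
#' @param x numeric vector (single-channel series), length at least 2.
#' @param degree polynomial degree of the trend model (default 1, linear).
#' @return the detrended series, same length as `x`.
#' @examples
#' detrend_baseline(c(5, 5, 5, 5))        # all zeros
#' detrend_baseline(2 * (1:100))          # ramp removed
#' @export
detrend_baseline <- function(x, degree = 1L) {
  if (length(x) < 2L) stop("invalid input: series length must be >= 2")
  t <- seq_along(x)
  B <- stats::poly(t, degree = degree, raw = FALSE)
  fit <- stats::lm.fit(cbind(1, B), x)
  as.numeric(fit$residuals)
}

# Column-wise linear detrend of a matrix via a precomputed orthonormal basis.
detrend_mat <- function(X, degree = 1L) {
  n <- nrow(X)
  t <- seq_len(n)
  B <- cbind(1 / sqrt(n), stats::poly(t, degree = degree, raw = FALSE))
  # columns of B orthonormal: residual = X - B (B'X)
  X - B %*% crossprod(B, X)
}

#' Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass filter (`signal::butter`) and applies it
#' either zero-phase (forward-backward, default) or causally in a single
#' pass. Zero-phase application squares the magnitude response and removes
#' group delay; the single-pass mode is the online-capable variant.
#'
#' @param x numeric vector, or a matrix filtered column-wise.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order (default 4).
#' @param zero_phase logical; forward-backward filtering (default `TRUE`).
#' @return filtered series, same shape as `x`.
#' @export
bandpass <- function(x, fs, low, high, order = 4L, zero_phase = TRUE) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid parameter: band edges must satisfy 0 < low < high < fs/2")
  if (order < 1L) stop("invalid parameter: order must be >= 1")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x), ncol = 1) else x
  Y <- if (zero_phase) cpp_filtfilt_mat(bf$b, bf$a, X)
       else apply(X, 2, function(col) cpp_iir_filter(bf$b, bf$a, col))
  if (vec) as.numeric(Y) else Y
}

#' Downsample a band-limited signal
#'
#' Reduces the sampling rate of a signal that prior band-pass filtering has
#' already limited below `fs_out / 2`. The default polyphase method
#' interpolates with a Kaiser-windowed sinc kernel whose cutoff sits at the
#' output Nyquist rate; `"fft"` resamples in the Fourier domain instead
#' (exact for band-limited periodic segments).
#'
#' @param x numeric vector or matrix (columns = channels).
#' @param fs_in,fs_out input and output sampling rates, `fs_out < fs_in`.
#' @param method `"polyphase"` (default) or `"fft"`.
#' @return the resampled signal with `round(n * fs_out / fs_in)` samples.
#' @export
downsample <- function(x, fs_in, fs_out, method = c("polyphase", "fft")) {
  method <- match.arg(method)
  if (fs_out >= fs_in) stop("invalid parameter: fs_out must be < fs_in")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(as.numeric(x), ncol = 1) else x
  n <- nrow(X)
  m <- round(n * fs_out / fs_in)
  if (method == "polyphase") {
    Y <- cpp_resample(X, fs_in, fs_out, 12L)
  } else {
    F <- stats::mvfft(X)
    G <- matrix(0 + 0i, nrow = m, ncol = ncol(X))
    keep <- min(floor(m / 2), floor(n / 2))  # one-sided bins to retain
    G[1, ] <- F[1, ]
    if (keep >= 1) {
      G[2:(keep + 1), ] <- F[2:(keep + 1), ]
      G[(m - keep + 1):m, ] <- F[(n - keep + 1):n, ]
    }
    Y <- Re(stats::mvfft(G, inverse = TRUE)) / n
  }
  if (vec) as.numeric(Y) else Y
}

#' Sliding-window sampling of a recording
#'
#' Cuts `n_windows` fixed-duration windows that uniformly tile the
#' recording: stride = `floor((L - W) / (n_windows - 1))` samples, so the
#' first window starts at the beginning and the last ends at (or just
#' before) the end of the recording.
#'
#' @param rec a `psa_recording`.
#' @param window_ms window duration in milliseconds (default 2000).
#' @param n_windows number of windows (default 50).
#' @return a `psa_windows` batch: array `[window_samples, n_windows,
#'   n_channels]` plus window/stride metadata.
#' @examples
#' rec <- new_recording(matrix(rnorm(60 * 256), ncol = 1), 256, "Cz", "EEG")
#' wb <- slide_windows(rec, 2000, 50)
#' dim(wb$windows)  # 512 x 50 x 1
#' @export
slide_windows <- function(rec, window_ms = 2000, n_windows = 50L) {
  if (n_windows < 1L) stop("invalid parameter: n_windows must be >= 1")
  W <- round(window_ms * rec$fs / 1000)
  L <- n_samples(rec)
  if (L < W)
    stop(sprintf("insufficient data: recording (%d samples) shorter than window (%d samples)",
                 L, W))
  stride <- if (n_windows > 1L) floor((L - W) / (n_windows - 1L)) else 0L
  if (n_windows > 1L && stride < 1L)
    stop("insufficient data: recording too short for the requested window count")
  starts <- 1L + (seq_len(n_windows) - 1L) * stride
  A <- array(0, dim = c(W, n_windows, ncol(rec$samples)),
             dimnames = list(NULL, NULL, rec$channel_labels))
  for (w in seq_len(n_windows))
    A[, w, ] <- rec$samples[starts[w]:(starts[w] + W - 1L), ]
  structure(list(windows = A, window_ms = window_ms,
                 stride_ms = stride / rec$fs * 1000, source_fs = rec$fs,
                 starts = starts, channel_labels = rec$channel_labels,
                 modality = rec$modality),
            class = "psa_windows")
}

#' Full preprocessing chain for one round's recording
#'
#' Applies the three preprocessing steps and windowed sampling to a raw
#' multichannel recording: least-squares baseline removal, 4th-order
#' Butterworth band-pass (EEG 0.5-45 Hz, EOG 0.1-30 Hz), downsampling
#' (EEG to 256 Hz, EOG to 128 Hz), then sliding-window sampling
#' (2000 ms windows, 50 per round by default).
#'
#' @param rec a raw `psa_recording` containing EEG and EOG channels.
#' @param config a [psa_config()] list (preprocessing section used).
#' @return list with `eeg` and `eog` `psa_windows` batches.
#' @export
preprocess_recording <- function(rec, config = psa_config()) {
  pp <- config$preprocess
  out <- list()
  for (mod in c("EEG", "EOG")) {
    if (!any(rec$modality == mod)) next
    sub <- recording_modality(rec, mod)
    band <- if (mod == "EEG") pp$eeg_band else pp$eog_band
    fs_out <- if (mod == "EEG") pp$fs_eeg else pp$fs_eog
    X <- detrend_mat(sub$samples, pp$detrend_degree)
    X <- bandpass(X, sub$fs, band[1], band[2], pp$filter_order, pp$zero_phase)
    X <- downsample(X, sub$fs, fs_out, pp$resample_method)
    ds <- new_recording(X, fs_out, sub$channel_labels, sub$modality)
    out[[tolower(mod)]] <- slide_windows(ds, pp$window_ms, pp$n_windows)
  }
  out
}
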