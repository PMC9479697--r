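# Daubechies-5 orthonormal scaling filter (10 taps, analysis convention).
db5_filters <- function() {
  lo <- c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
          0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
          0.16010239797419293)
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi)
}

#' Decompose a window into EEG rhythm bands by wavelet reconstruction
#'
#' Runs a 5-level periodized discrete wavelet transform with the Daubechies
#' basis of fifth vanishing order (db5) and reconstructs the contribution of
#' each level separately. At a 256 Hz sampling rate the dyadic levels map
#' onto the canonical rhythm bands: A5 -> delta (0-4 Hz), D5 -> theta
#' (4-8 Hz), D4 -> alpha (8-16 Hz), D3 -> beta (16-32 Hz) and D1+D2 ->
#' gamma (> 32 Hz, the band being open-ended above). The five band series
#' sum back to the input window exactly (orthogonal perfect reconstruction).
#'
#' @param x numeric window (single channel, nominally at 256 Hz), length at
#'   least `2^levels`.
#' @param levels decomposition depth (default 5).
#' @return named list of band series (`delta`, `theta`, `alpha`, `beta`,
#'   `gamma`), each the length of `x`.
#' @examples
#' x <- sin(2 * pi * 10 * (0:511) / 256)
#' b <- wavelet_rhythms(x)
#' sum(b$alpha^2) / sum(x^2)  # 10 Hz energy lands in the alpha band
#' @export
wavelet_rhythms <- function(x, levels = 5L) {
  out <- wavelet_rhythms_mat(matrix(as.numeric(x), ncol = 1), levels)
  lapply(out, as.numeric)
}

# Matrix version: each column of X is one window; returns band matrices.
wavelet_rhythms_mat <- function(X, levels = 5L) {
  n <- nrow(X)
  if (n < 2^levels)
    stop(sprintf("invalid input: window length %d too short for %d-level decomposition",
                 n, levels))
  block <- 2^levels
  n_pad <- ceiling(n / block) * block
  if (n_pad != n) X <- rbind(X, matrix(0, n_pad - n, ncol(X)))
  f <- db5_filters()
  bands <- cpp_dwt_band_reconstruct(X, f$lo, f$hi, levels)
  # bands: D1, D2, ..., DL, AL
  trim <- function(M) M[seq_len(n), , drop = FALSE]
  list(delta = trim(bands[[levels + 1]]),
       theta = trim(bands[[levels]]),
       alpha = trim(bands[[levels - 1]]),
       beta  = trim(bands[[levels - 2]]),
       gamma = trim(bands[[levels - 3]] + bands[[levels - 4]]))
}

#' @rdname wavelet_rhythms
#' @export
rhythm_band_names <- function() c("delta", "theta", "alpha", "beta", "gamma")
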