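# Network input preparation: band-limited resampling to the architecture's
# input frequency and forcing a uniform input length. Deliberately nothing
# else: no filtering, baseline-wander removal or amplitude normalization.

#' Band-limited (Fourier) resampling
#'
#' Resamples a signal from `from_fs` to `to_fs` in the frequency domain:
#' the DFT is truncated or zero-extended to the target length (with the
#' usual Nyquist-bin split), so the result is the band-limited
#' interpolation of the input. Output length is `round(n * to_fs /
#' from_fs)`, which preserves total duration to within one sample period.
#'
#' @param x Numeric vector.
#' @param from_fs,to_fs Source and target sampling frequencies in Hz.
#' @return Numeric vector of length `round(length(x) * to_fs / from_fs)`.
#' @export
resample_signal <- function(x, from_fs, to_fs) {
  if (!length(x)) stop("cannot resample an empty signal")
  if (from_fs <= 0 || to_fs <= 0) stop("sampling frequencies must be positive")
  if (from_fs == to_fs) return(x)
  n <- length(x)
  m <- round(n * to_fs / from_fs)
  if (m < 1) stop("target length rounds to zero")
  X <- stats::fft(x)
  Z <- complex(m)
  k <- min(n, m)
  h <- k %/% 2
  Z[1:(h + 1)] <- X[1:(h + 1)]
  negmax <- if (k %% 2 == 0) h - 1L else h
  if (negmax >= 1) {
    f <- seq_len(negmax)
    Z[m - f + 1] <- X[n - f + 1]
  }
  if (k %% 2 == 0 && h >= 1) {
    if (m < n) {
      # fold the symmetric component into the new Nyquist bin
      Z[h + 1] <- X[h + 1] + X[n - h + 1]
    } else {
      # split the old Nyquist bin across the two new symmetric bins
      Z[h + 1] <- X[h + 1] / 2
      Z[m - h + 1] <- X[h + 1] / 2
    }
  }
  Re(stats::fft(Z, inverse = TRUE)) / n
}

#' Force a signal to an exact length
#'
#' Longer signals are cropped at the tail (the head of the signal is
#' kept); shorter signals are zero-padded at the tail. Idempotent.
#'
#' @param x Numeric vector.
#' @param target_len Desired length (>= 1).
#' @return Numeric vector of length exactly `target_len`.
#' @export
fit_length <- function(x, target_len) {
  if (target_len < 1) stop("target_len must be >= 1")
  n <- length(x)
  if (n == target_len) return(x)
  if (n > target_len) return(x[seq_len(target_len)])
  c(x, numeric(target_len - n))
}

#' Prepare segments as network inputs
#'
#' Resamples every segment of a [segment_set] to the network input
#' frequency and crops/zero-pads to an exact sample count, returning a
#' numeric matrix with one row per segment.
#'
#' @param segs A `segment_set`.
#' @param input_fs Network input frequency in Hz.
#' @param input_len Network input length in samples.
#' @return List with `x` (matrix `n x input_len`), `y` (integer labels)
#'   and `meta` (the segment metadata).
#' @export
prepare_inputs <- function(segs, input_fs, input_len) {
  stopifnot(inherits(segs, "segment_set"))
  n <- length(segs$signals)
  x <- matrix(0, n, input_len)
  for (i in seq_len(n)) {
    s <- segs$signals[[i]]
    if (segs$fs != input_fs) s <- resample_signal(s, segs$fs, input_fs)
    x[i, ] <- fit_length(s, input_len)
  }
  list(x = x, y = segs$meta$label, meta = segs$meta)
}
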