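# Signal conditioning ahead of correlation: band-pass filtering, noise-floor
# estimation, envelope-based amplitude masking, band-limited axial
# interpolation. All operations act per A-line (per column).

.fir_taps <- function(cfg, fs, n_taps = 301L) {
  ny <- fs / 2
  if (cfg$passband[2] >= ny)
    stop("bandpass: passband_high must be below fs/2")
  signal::fir1(n_taps - 1L, cfg$passband / ny, type = "pass",
               window = signal::hamming(n_taps))
}

# Centered FFT convolution of every column with `h` (odd length); output has
# the input length, i.e. the group delay of the linear-phase filter is
# compensated. Edges are zero-padded.
.conv_same <- function(x, h) {
  n <- nrow(x); lh <- length(h)
  nfft <- 2^ceiling(log2(n + lh - 1L))
  H <- stats::fft(c(h, rep(0, nfft - lh)))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  d <- (lh - 1L) / 2L
  y[(d + 1L):(d + n), , drop = FALSE]
}

#' Band-pass filter a frame of A-lines
#'
#' Linear-phase windowed-sinc FIR filter (301 Hamming taps by default — enough
#' to reach >= 40 dB attenuation at half the lower passband edge with a
#' 180 MHz sampling rate) applied per A-line with the group delay compensated,
#' so the output is aligned with the input.
#'
#' @param frame Numeric matrix `[n_samples x n_lines]`.
#' @param params [acquisition_params()] (supplies `fs`).
#' @param cfg [doppler_config()] (supplies the passband).
#' @param n_taps Number of FIR taps (odd).
#' @return Filtered matrix, same shape as `frame`.
#' @export
bandpass <- function(frame, params = acquisition_params(),
                     cfg = doppler_config(), n_taps = 301L) {
  if (!is.matrix(frame)) frame <- matrix(frame, ncol = 1L)
  if (n_taps %% 2L == 0L) stop("bandpass: n_taps must be odd")
  if (nrow(frame) < n_taps)
    stop("bandpass: frame shorter than filter length (", n_taps, " taps)")
  .conv_same(frame, .fir_taps(cfg, params$fs, n_taps))
}

#' Estimate the noise floor of a frame
#'
#' Mean absolute amplitude over a signal-free region, pooled across all
#' A-lines. `noise_region = NULL` selects the region automatically: all
#' samples earlier than the shallowest valid surface arrival minus one pulse
#' length when a `profile` is supplied, else the first 200 samples. An empty
#' auto-selection falls back to the first 200 samples with a warning.
#'
#' @param frame Numeric matrix `[n_samples x n_lines]`.
#' @param noise_region Integer vector of sample indices, or `NULL` for auto.
#' @param profile Optional `surface_profile` used by the auto selection.
#' @param pulse_len Pulse length in samples subtracted from the shallowest
#'   arrival during auto selection.
#' @return Scalar mean absolute amplitude.
#' @export
noise_floor <- function(frame, noise_region = NULL, profile = NULL,
                        pulse_len = 33L) {
  if (!is.matrix(frame)) frame <- matrix(frame, ncol = 1L)
  n <- nrow(frame)
  if (is.null(noise_region)) {
    if (!is.null(profile)) {
      top <- floor(min(profile$arrival[profile$valid])) - pulse_len
      if (!is.finite(top) || top < 1) {
        warning("noise_floor: empty auto region; falling back to first 200 samples")
        noise_region <- seq_len(min(200L, n))
      } else noise_region <- seq_len(min(top, n))
    } else noise_region <- seq_len(min(200L, n))
  }
  if (!length(noise_region)) {
    warning("noise_floor: empty region; falling back to first 200 samples")
    noise_region <- seq_len(min(200L, n))
  }
  mean(abs(frame[noise_region, ]))
}

#' Analytic-signal envelope of a frame
#'
#' Magnitude of the analytic representation of each A-line (Hilbert envelope),
#' computed in the frequency domain.
#'
#' @param frame Numeric matrix `[n_samples x n_lines]`.
#' @return Matrix of envelope amplitudes, same shape.
#' @export
envelope <- function(frame) {
  if (!is.matrix(frame)) frame <- matrix(frame, ncol = 1L)
  n <- nrow(frame)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  z <- stats::mvfft(stats::mvfft(frame) * h, inverse = TRUE) / n
  Mod(z)
}

#' Amplitude mask against the noise floor
#'
#' `TRUE` where the envelope of the A-line is at least `noise_factor` times
#' the noise floor; used to keep noise-only samples out of the correlation.
#'
#' @param frame Numeric matrix `[n_samples x n_lines]` (band-passed RF).
#' @param floor Noise floor amplitude from [noise_floor()] (must be >= 0).
#' @param noise_factor Threshold multiple of the floor (0 masks nothing).
#' @return Logical matrix, same shape as `frame`.
#' @export
amplitude_mask <- function(frame, floor, noise_factor = 3.0) {
  if (floor < 0) stop("amplitude_mask: floor must be >= 0")
  envelope(frame) >= noise_factor * floor
}

#' Band-limited axial interpolation
#'
#' Fourier-domain (zero-padded spectrum) resampling of each A-line to
#' `nres` times its length. Original samples are preserved at stride `nres`;
#' the band-limited pulse shape is preserved, which integer-lag correlation
#' depends on (linear interpolation would bias sub-sample shifts).
#'
#' @param frame Numeric matrix `[n_samples x n_lines]`.
#' @param nres Integer upsampling factor (>= 1; 1 is the identity).
#' @return Matrix `[n_samples * nres x n_lines]`.
#' @export
upsample_axial <- function(frame, nres) {
  if (!is.matrix(frame)) frame <- matrix(frame, ncol = 1L)
  nres <- as.integer(nres)
  if (is.na(nres) || nres < 1L) stop("upsample_axial: nres must be >= 1")
  if (nres == 1L) return(frame)
  n <- nrow(frame); m <- n * nres
  X <- stats::mvfft(frame)
  Y <- matrix(0 + 0i, m, ncol(frame))
  if (n %% 2L == 0L) {
    hn <- n / 2L
    Y[1:hn, ] <- X[1:hn, ]
    Y[hn + 1L, ] <- X[hn + 1L, ] / 2
    Y[m - hn + 1L, ] <- X[hn + 1L, ] / 2
    if (hn >= 2L) Y[(m - hn + 2L):m, ] <- X[(hn + 2L):n, ]
  } else {
    hn <- (n + 1L) / 2L
    Y[1:hn, ] <- X[1:hn, ]
    Y[(m - (n - hn) + 1L):m, ] <- X[(hn + 1L):n, ]
  }
  Re(stats::mvfft(Y, inverse = TRUE)) / n
}

# Expand an original-grid mask to the interpolated grid (each original sample
# covers its nres interpolated successors).
upsample_mask <- function(mask, nres) {
  if (nres == 1L) return(mask)
  mask[rep(seq_len(nrow(mask)), each = nres), , drop = FALSE]
}
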