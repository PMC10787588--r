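# The correlational velocity estimator: velocity resolution, the
# sliding-window lag search between adjacent A-lines, correlation gating,
# shift-to-velocity conversion, and ROI averaging.

#' Doppler velocity resolution
#'
#' The axial speed corresponding to a one-interpolated-sample correlation
#' shift per PRF interval:
#' `Vres = c/2 * fprf / (fs * nres)`.
#' With the defaults (c = 1540 m/s, PRF = 1 kHz, fs = 180 MHz, nres = 3) this
#' is 1.4259e-3 m/s, i.e. about 1.42 mm/s.
#'
#' @param params [acquisition_params()].
#' @param nres Interpolation factor (>= 1).
#' @return Speed in m/s.
#' @export
velocity_resolution <- function(params = acquisition_params(), nres = 3L) {
  if (length(nres) != 1L || !is.finite(nres) || nres < 1)
    stop("velocity_resolution: nres must be >= 1")
  params$c / 2 * params$fprf / (params$fs * nres)
}

new_velocity_map <- function(pshift, rho, valid, window_centers, nres,
                             window_len = NA_integer_, window_hop = NA_integer_,
                             vc = NULL, v = NULL, vres = NULL,
                             theta = NULL, shifts = NULL,
                             window_centers_orig = NULL, roi_lines = NULL) {
  m <- list(pshift = pshift, rho = rho, valid = valid,
            window_centers = window_centers, nres = nres,
            window_len = window_len, window_hop = window_hop,
            vc = vc, v = v,
            vres = vres, theta = theta, shifts = shifts,
            window_centers_orig = window_centers_orig, roi_lines = roi_lines)
  class(m) <- "velocity_map"
  m
}

#' @export
print.velocity_map <- function(x, ...) {
  cat(sprintf("<velocity_map> %d windows x %d line pairs; %.1f%% valid\n",
              nrow(x$pshift), ncol(x$pshift), 100 * mean(x$valid)))
  if (!is.null(x$vc)) cat(sprintf("  mean |vc| = %.3g mm/s\n",
                                  1e3 * mean(abs(x$vc[x$valid]), na.rm = TRUE)))
  if (!is.null(x$v)) cat(sprintf("  mean |v|  = %.3g mm/s (compensated)\n",
                                 1e3 * mean(abs(x$v[x$valid]), na.rm = TRUE)))
  invisible(x)
}

#' Sliding-window correlation lag search between adjacent A-lines
#'
#' For each adjacent A-line pair (i, i+1) and each window of `window_len`
#' interpolated samples (centers spaced `window_hop` apart), finds the integer
#' lag in `[-max_lag, max_lag]` maximizing the normalized (zero-mean,
#' unit-norm) cross-correlation of the window of line i+1 against line i, and
#' records the lag (`pshift`) and the correlation value there (`rho`). A
#' window is valid only when the amplitude mask is true across the whole
#' window on both lines. Sign convention: `pshift > 0` means the echo arrives
#' earlier in line i+1, i.e. motion toward the transducer, i.e. positive
#' velocity. Ties go to the smaller `|lag|`, then to the non-negative lag.
#' With `cfg$subsample_refine`, a parabolic fit through the peak and its two
#' neighbours refines `pshift` to a real value clamped to the search range.
#'
#' @param frame_interp Matrix `[n_samples*nres x n_lines]`: band-passed,
#'   upsampled RF (see [bandpass()], [upsample_axial()]).
#' @param mask Logical matrix of the same shape (interpolated grid; see
#'   [amplitude_mask()] and the internal mask upsampling in [process_scan()]),
#'   or `NULL` for no masking.
#' @param cfg [doppler_config()].
#' @return A `velocity_map` with `pshift`, `rho`, `valid`
#'   (`[n_windows x n_pairs]`) and `window_centers` (1-based interpolated-grid
#'   indices).
#' @export
correlate_adjacent <- function(frame_interp, mask = NULL,
                               cfg = doppler_config()) {
  if (!is.matrix(frame_interp)) stop("correlate_adjacent: frame must be a matrix")
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(frame_interp), ncol(frame_interp))
  }
  if (!identical(dim(mask), dim(frame_interp)))
    stop("correlate_adjacent: mask shape differs from frame")
  r <- corr_lag_search_cpp(frame_interp, mask, cfg$window_len, cfg$max_lag,
                           cfg$window_hop, cfg$subsample_refine)
  new_velocity_map(r$pshift, r$rho, r$valid, r$window_centers, cfg$nres,
                   window_len = cfg$window_len, window_hop = cfg$window_hop)
}

#' Gate a velocity map on correlation amplitude
#'
#' Marks windows invalid where the correlation coefficient falls below
#' `rho_min`; all other fields are untouched. This is the
#' correlation-amplitude filter that rejects residual noise correlations.
#'
#' @param vmap A `velocity_map` from [correlate_adjacent()].
#' @param rho_min Threshold in `[0, 1]` (or slightly above 1 to reject all).
#' @return The gated `velocity_map`.
#' @export
gate <- function(vmap, rho_min = 0.7) {
  stopifnot(inherits(vmap, "velocity_map"))
  vmap$valid <- vmap$valid & !is.na(vmap$rho) & (vmap$rho >= rho_min)
  vmap
}

#' Convert correlation shifts to axial velocities
#'
#' `vc = pshift * vres` on valid windows, `NA` elsewhere.
#'
#' @param vmap A `velocity_map`.
#' @param vres Velocity resolution from [velocity_resolution()], m/s.
#' @return The map with `vc` (m/s) filled.
#' @export
to_velocity <- function(vmap, vres) {
  stopifnot(inherits(vmap, "velocity_map"))
  if (!is.finite(vres) || vres <= 0) stop("to_velocity: vres must be > 0")
  vc <- vmap$pshift * vres
  vc[!vmap$valid] <- NA_real_
  vmap$vc <- vc
  vmap$vres <- vres
  vmap
}

#' ROI averaging over blocks of consecutive A-line pairs
#'
#' Replaces, per window row, the velocities by their mean over disjoint blocks
#' of `roi_lines` consecutive line pairs (the last partial block is kept when
#' it holds at least `roi_lines/2` pairs). A block cell is valid when at least
#' 10% of its member windows were valid; `rho` becomes the block mean over
#' member windows. Suppresses estimation noise from limited per-pair
#' correlation windows and from integer-sample alignment jitter (whose
#' per-pair errors telescope to near zero over a block).
#'
#' @param vmap A `velocity_map` with `vc` (and optionally `v`) present.
#' @param roi_lines Pairs per block (>= 1; larger than the number of pairs
#'   collapses to a single block).
#' @return A `velocity_map` with one column per block.
#' @export
roi_average <- function(vmap, roi_lines = 100L) {
  stopifnot(inherits(vmap, "velocity_map"))
  if (roi_lines < 1L) stop("roi_average: roi_lines must be >= 1")
  np <- ncol(vmap$pshift)
  roi_lines <- min(as.integer(roi_lines), np)
  nb_full <- np %/% roi_lines
  rem <- np %% roi_lines
  keep_partial <- rem >= roi_lines / 2
  nb <- nb_full + as.integer(keep_partial && rem > 0L)
  if (nb == 0L) { nb <- 1L; nb_full <- 0L; keep_partial <- TRUE }
  nw <- nrow(vmap$pshift)
  blocks <- lapply(seq_len(nb), function(b) {
    lo <- (b - 1L) * roi_lines + 1L
    hi <- if (b <= nb_full) b * roi_lines else np
    lo:hi
  })
  avg_field <- function(M) {
    if (is.null(M)) return(NULL)
    out <- matrix(NA_real_, nw, nb)
    for (b in seq_len(nb)) {
      cols <- blocks[[b]]
      V <- M[, cols, drop = FALSE]
      V[!vmap$valid[, cols, drop = FALSE]] <- NA_real_
      out[, b] <- rowMeans(V, na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
    out
  }
  valid_out <- matrix(FALSE, nw, nb)
  rho_out <- matrix(NA_real_, nw, nb)
  for (b in seq_len(nb)) {
    cols <- blocks[[b]]
    valid_out[, b] <- rowMeans(vmap$valid[, cols, drop = FALSE]) >= 0.10
    rho_out[, b] <- rowMeans(vmap$rho[, cols, drop = FALSE], na.rm = TRUE)
  }
  rho_out[is.nan(rho_out)] <- NA_real_
  out <- vmap
  out$pshift <- avg_field(vmap$pshift)
  out$vc <- avg_field(vmap$vc)
  out$v <- avg_field(vmap$v)
  out$rho <- rho_out
  out$valid <- valid_out & !is.na(out$pshift)
  out$roi_lines <- roi_lines
  out$window_centers_orig <- NULL
  out
}
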