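# Surface time-of-arrival detection, A-line alignment, per-line beam-to-flow
# angle estimation from the surface geometry, capped cosine compensation, and
# polar display warping.

new_surface_profile <- function(arrival, valid, n_samples,
                                interpolated = NULL, shifts = NULL,
                                theta = NULL, theta_raw = NULL) {
  p <- list(arrival = arrival, valid = valid, n_samples = n_samples,
            interpolated = interpolated %||% rep(FALSE, length(arrival)),
            shifts = shifts, theta = theta, theta_raw = theta_raw)
  class(p) <- "surface_profile"
  p
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf("<surface_profile> %d lines, %.1f%% valid\n",
              length(x$arrival), 100 * mean(x$valid)))
  if (!is.null(x$theta))
    cat(sprintf("  theta: %.1f-%.1f deg\n", min(x$theta, na.rm = TRUE),
                max(x$theta, na.rm = TRUE)))
  invisible(x)
}

#' Rising-edge surface time-of-arrival detection
#'
#' Per US A-line, the arrival index `Li` is the first sample whose envelope
#' reaches `toa_threshold_db` dB above the noise floor (the water-tissue
#' interface generates a dominant echo). The floor is measured on the same
#' scale as the quantity thresholded — the mean envelope over the noise
#' region — so the detection margin is not eroded by the envelope/RF
#' amplitude ratio. Lines with no crossing are flagged invalid; if more than
#' half the lines are invalid a warning is attached. Occasional early
#' triggers on noise tails are expected and removed by [reject_outliers()].
#'
#' @param us_frame US RF matrix `[n_samples x n_lines]` (band-passed).
#' @param params [acquisition_params()].
#' @param cfg [doppler_config()] (supplies `toa_threshold_db`).
#' @param floor Noise floor on the envelope scale; `NULL` computes the mean
#'   envelope over the automatic noise region (see [noise_floor()]).
#' @return A `surface_profile` with 1-based `arrival` indices.
#' @export
detect_surface <- function(us_frame, params = acquisition_params(),
                           cfg = doppler_config(), floor = NULL) {
  env <- envelope(us_frame)
  if (is.null(floor)) floor <- noise_floor(env)
  thr <- floor * 10^(cfg$toa_threshold_db / 20)
  arrival <- apply(env >= thr, 2, function(hit) {
    i <- which(hit)
    if (length(i)) i[1] else NA_real_
  })
  valid <- !is.na(arrival)
  prof <- new_surface_profile(arrival, valid, nrow(us_frame))
  if (mean(valid) < 0.5)
    warning("detect_surface: more than 50% of lines have no threshold crossing")
  prof
}

# Running median; circular wrap for rotational scans.
.run_median <- function(x, k, circular) {
  n <- length(x)
  if (n < k) k <- max(1L, n - (1 - n %% 2L))
  h <- k %/% 2L
  if (circular) {
    xp <- c(x[(n - h + 1):n], x, x[1:h])
    vapply(seq_len(n), function(i) stats::median(xp[i:(i + 2 * h)], na.rm = TRUE),
           numeric(1))
  } else {
    vapply(seq_len(n), function(i)
      stats::median(x[max(1, i - h):min(n, i + h)], na.rm = TRUE), numeric(1))
  }
}

#' Reject outliers in a surface profile
#'
#' Sliding median (window 15 lines; circular for rotational scans, linear for
#' stationary ones): arrivals further than `5 * MAD` from the local median —
#' and invalid lines — are replaced by it and marked interpolated.
#'
#' @param profile A `surface_profile` from [detect_surface()].
#' @param params [acquisition_params()] (scan mode selects circular wrap).
#' @param window Median window length in lines.
#' @param k_mad Rejection threshold in MADs.
#' @return The cleaned `surface_profile` (all lines valid).
#' @export
reject_outliers <- function(profile, params = acquisition_params(),
                            window = 15L, k_mad = 5) {
  stopifnot(inherits(profile, "surface_profile"))
  if (!any(profile$valid))
    stop("reject_outliers: no surface (all lines invalid)")
  x <- profile$arrival
  med <- .run_median(x, window, circular = params$scan_mode == "rotational")
  resid <- x - med
  # MAD floored at one sample: arrivals are sample-quantized, and a profile
  # that is smooth apart from that quantization must pass unchanged.
  mad <- max(stats::mad(resid[profile$valid], na.rm = TRUE), 1)
  bad <- !profile$valid | is.na(resid) | abs(resid) > k_mad * mad
  x[bad] <- med[bad]
  new_surface_profile(x, rep(TRUE, length(x)), profile$n_samples,
                      interpolated = bad, shifts = profile$shifts,
                      theta = profile$theta)
}

#' Smooth a surface profile
#'
#' Sliding circular median followed by a circular running mean over the
#' arrival indices. Threshold-crossing time-of-arrival detection carries
#' multi-sample jitter at realistic US noise levels (the 10 dB threshold sits
#' in the foot of the interface echo); since the physical surface is smooth
#' at the A-line pitch, the alignment and angle-estimation stages use the
#' smoothed profile, which suppresses spurious inter-line shifts that would
#' otherwise leak into the correlation lags.
#'
#' @param profile A cleaned `surface_profile` (see [reject_outliers()]).
#' @param params [acquisition_params()] (scan mode selects circular wrap).
#' @param median_window,mean_window Window lengths in lines.
#' @return The smoothed `surface_profile` (arrivals may be fractional).
#' @export
smooth_surface <- function(profile, params = acquisition_params(),
                           median_window = 15L, mean_window = 9L) {
  stopifnot(inherits(profile, "surface_profile"))
  circ <- params$scan_mode == "rotational"
  x <- .run_median(profile$arrival, median_window, circular = circ)
  n <- length(x)
  if (mean_window > 1L && n >= mean_window) {
    h <- mean_window %/% 2L
    xp <- if (circ) c(x[(n - h + 1):n], x, x[1:h])
          else c(rep(x[1], h), x, rep(x[n], h))
    x <- stats::filter(xp, rep(1 / (2 * h + 1), 2 * h + 1), sides = 2)[(h + 1):(h + n)]
  }
  profile$arrival <- as.numeric(x)
  profile
}

#' Align A-lines to a common surface arrival
#'
#' Shifts each A-line by an integer number of original samples so that every
#' arrival sits at the reference (the rounded median arrival); vacated samples
#' are zero-filled. The recorded shifts (`reference - arrival`, positive =
#' shifted deeper) are later undone by [backshift()] for co-registration with
#' the unshifted US image.
#'
#' @param pa_frame PA RF matrix `[n_samples x n_lines]`.
#' @param profile A cleaned `surface_profile` (see [reject_outliers()]).
#' @return List with `frame` (aligned matrix), `shifts` (integer per line)
#'   and `reference` (the common arrival index).
#' @export
align_to_surface <- function(pa_frame, profile) {
  stopifnot(inherits(profile, "surface_profile"))
  if (!all(profile$valid))
    stop("align_to_surface: profile has invalid lines; run reject_outliers() first")
  n <- nrow(pa_frame)
  ref <- round(stats::median(profile$arrival))
  shifts <- as.integer(round(ref - profile$arrival))
  if (any(abs(shifts) > n / 2))
    stop("align_to_surface: shift magnitude exceeds n_samples/2")
  out <- matrix(0, n, ncol(pa_frame))
  for (i in seq_len(ncol(pa_frame))) {
    s <- shifts[i]
    if (s == 0L) out[, i] <- pa_frame[, i]
    else if (s > 0L) out[(s + 1L):n, i] <- pa_frame[1:(n - s), i]
    else out[1:(n + s), i] <- pa_frame[(1L - s):n, i]
  }
  list(frame = out, shifts = shifts, reference = ref)
}

#' Undo surface alignment on a velocity map
#'
#' Translates the window centers back to the original (pre-alignment) sample
#' grid for co-registration with the US image: the center of window row w in
#' line pair i moves by `-shifts[i] * nres` interpolated samples (the inverse
#' of the alignment shift of the pair's first line).
#'
#' @param vmap A `velocity_map`.
#' @param shifts Integer per-line shifts from [align_to_surface()].
#' @return The map with `window_centers_orig` (`[n_windows x n_pairs]`,
#'   interpolated-grid units) filled.
#' @export
backshift <- function(vmap, shifts) {
  stopifnot(inherits(vmap, "velocity_map"))
  np <- ncol(vmap$pshift)
  if (length(shifts) < np)
    stop("backshift: need one shift per line")
  vmap$shifts <- shifts
  vmap$window_centers_orig <-
    outer(vmap$window_centers, shifts[seq_len(np)] * vmap$nres, `-`)
  vmap
}

#' Estimate per-line beam-to-flow angles from the surface profile
#'
#' Converts arrivals to radii from the rotation axis
#' (`r = probe_offset + depth(L)` under the active propagation convention)
#' and, in the default `"exact"` mode, computes at each surface vertex the
#' angle between the outward radial (A-line) direction and the chord joining
#' the previous surface point — the closed-form triangle solution whose
#' law-of-sines identity is the per-line arrival recursion without the
#' small-angle approximation. The `"recursive"` mode implements that
#' approximate recursion, `sin(theta_i) = r_i * sin(dphi + theta_{i-1}) /
#' r_{i-1}`, seeded with the exact angle. Flow is assumed parallel to the
#' surface. All angles are folded to `[0, 90]` and then capped at
#' `cfg$angle_cap`; the uncapped values are kept in `theta_raw`.
#'
#' @param profile A cleaned `surface_profile`.
#' @param params [acquisition_params()] (rotational scan).
#' @param cfg [doppler_config()] (supplies `angle_cap`).
#' @param mode `"exact"` or `"recursive"`.
#' @return The profile with `theta` (capped, degrees) and `theta_raw` filled.
#' @export
estimate_angles <- function(profile, params = acquisition_params(scan_mode = "rotational"),
                            cfg = doppler_config(), mode = c("exact", "recursive")) {
  stopifnot(inherits(profile, "surface_profile"))
  mode <- match.arg(mode)
  if (params$scan_mode != "rotational")
    stop("estimate_angles: angle estimation requires a rotational scan")
  L <- length(profile$arrival)
  r <- radius_of_sample(profile$arrival, params)
  dphi <- params$line_angle_step * pi / 180
  prev <- c(L, seq_len(L - 1L))
  # Interior chord angle at the current vertex B (previous point A at
  # azimuth 0, B at azimuth dphi): angle between the chord B-A and the
  # outward radial direction at B, unfolded in (0, 180). This is the exact
  # triangle solution satisfying r_prev/sin(theta) = r/sin(180 - dphi - theta).
  chord_angle <- function(rp, ri) {
    cx <- ri * cos(dphi) - rp
    cy <- ri * sin(dphi)
    clen <- sqrt(cx^2 + cy^2)
    ct <- (cx * cos(dphi) + cy * sin(dphi)) / clen
    ifelse(clen == 0, NA_real_,
           acos(pmin(1, pmax(-1, ct))) * 180 / pi)
  }
  if (mode == "exact") {
    theta <- chord_angle(r[prev], r)
  } else {
    theta <- numeric(L)
    theta[1] <- chord_angle(r[L], r[1])
    for (i in 2:L) {
      s <- r[i] * sin(dphi + theta[i - 1] * pi / 180) / r[i - 1]
      theta[i] <- asin(pmin(1, pmax(-1, s))) * 180 / pi
    }
  }
  profile$theta_raw <- theta
  folded <- pmin(abs(theta), 180 - abs(theta))
  profile$theta <- pmin(folded, cfg$angle_cap)
  profile
}

#' Angle-compensate axial velocities
#'
#' `v = vc / cos(min(theta, angle_cap))` on valid windows. `theta` is either
#' one fixed angle in degrees (linear-phantom and constant-angle spiral
#' modes) or a `surface_profile` carrying per-line angles from
#' [estimate_angles()] (the angle of a pair's first line is used). The cap
#' prevents over-compensation where the cosine approaches zero.
#'
#' @param vmap A `velocity_map` with `vc` present.
#' @param theta Fixed angle (degrees, in `[0, 90)`) or a `surface_profile`.
#' @param cfg [doppler_config()] (supplies `angle_cap`).
#' @return The map with `v` (m/s) and `theta` (per pair, degrees) filled.
#' @export
compensate <- function(vmap, theta, cfg = doppler_config()) {
  stopifnot(inherits(vmap, "velocity_map"))
  if (is.null(vmap$vc)) stop("compensate: run to_velocity() first")
  np <- ncol(vmap$vc)
  th <- if (inherits(theta, "surface_profile")) {
    if (is.null(theta$theta)) stop("compensate: profile lacks angles; run estimate_angles()")
    theta$theta[seq_len(np)]
  } else {
    if (!is.numeric(theta) || any(!is.finite(theta)))
      stop("compensate: theta must be numeric degrees or a surface_profile")
    rep_len(theta, np)
  }
  if (any(th < 0) || any(th >= 90))
    stop("compensate: theta must lie in [0, 90) degrees")
  thc <- pmin(th, cfg$angle_cap)
  fac <- 1 / cos(thc * pi / 180)
  vmap$v <- sweep(vmap$vc, 2, fac, `*`)
  vmap$v[!vmap$valid] <- NA_real_
  vmap$theta <- thc
  vmap
}

#' Warp a (sample x line) image to polar display
#'
#' Maps a rotational B-scan image to a square raster: each A-line sample sits
#' at radius `probe_offset + depth(sample)` (per the propagation convention)
#' and azimuth `(line - 1) * line_angle_step`. Pixels are filled by bilinear
#' sampling (with azimuthal wrap-around); pixels outside the scanned annulus
#' are `NA`.
#'
#' @param image Numeric matrix `[n_samples x n_lines]` (`NA`s allowed).
#' @param params [acquisition_params()].
#' @param out_px Output raster side length in pixels.
#' @return `out_px x out_px` matrix (`NA` outside the annulus).
#' @export
to_polar <- function(image, params = acquisition_params(scan_mode = "rotational"),
                     out_px = 512L) {
  n <- nrow(image); L <- ncol(image)
  rmax <- radius_of_sample(n, params)
  px <- seq(-rmax, rmax, length.out = out_px)
  X <- matrix(px, out_px, out_px)            # column coordinate
  Y <- matrix(px, out_px, out_px, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  az <- (atan2(Y, X) * 180 / pi) %% 360
  ks <- sample_of_radius(r, params)          # fractional sample index
  li <- az / params$line_angle_step + 1      # fractional line index (wraps)
  inside <- ks >= 1 & ks <= n
  out <- matrix(NA_real_, out_px, out_px)
  if (!any(inside)) return(out)
  k0 <- pmin(floor(ks[inside]), n - 1); fk <- ks[inside] - k0
  l0 <- floor(li[inside]); fl <- li[inside] - l0
  l0w <- ((l0 - 1) %% L) + 1
  l1w <- (l0 %% L) + 1
  idx <- function(k, l) image[cbind(k, l)]
  out[inside] <-
    (1 - fk) * (1 - fl) * idx(k0, l0w) + fk * (1 - fl) * idx(k0 + 1, l0w) +
    (1 - fk) * fl * idx(k0, l1w) + fk * fl * idx(k0 + 1, l1w)
  out
}
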