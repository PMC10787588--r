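#' Phantom specification for the scan simulator
#'
#' Describes the geometry, flow, pulse and noise of a synthetic phantom scan.
#' Three kinds are supported, standing in for the physical validation
#' phantoms:
#' \describe{
#'   \item{`linear_tube`}{a straight thin-walled tube (580 um inner diameter
#'     by default) crossing a stationary beam at `beam_to_flow_angle`;}
#'   \item{`spiral`}{a tube turn wrapped around a cylindrical phantom, imaged
#'     by a rotational scan at a constant, known beam-to-flow angle;}
#'   \item{`lumen`}{a rotational scan of a lumen-like surface (radius per
#'     azimuth via `lumen_radius_fn`) with an optional superficial flow layer
#'     whose direction follows the surface tangent.}
#' }
#'
#' Absorbers are ideal points convolved with the transducer pulse; the beam is
#' a line (no diffraction or attenuation), so the RF is kinematically exact:
#' per PRF interval every flow scatterer advances along the beam by
#' `flow_speed * cos(theta) / fprf` meters. Noise is white Gaussian added
#' after pulse synthesis, scaled so that the RMS ratio to the signal inside
#' the flow region equals `snr_db`.
#'
#' @param kind `"linear_tube"`, `"spiral"` or `"lumen"`.
#' @param tube_inner_diameter Tube inner diameter, m.
#' @param flow_speed Flow speed along the tube/surface, m/s.
#' @param flow_profile `"plug"` (uniform across the bore) or `"parabolic"`.
#' @param beam_to_flow_angle Angle between beam and flow direction, degrees
#'   (linear tube; also the spiral angle when `probe_tilt` is `NULL`).
#' @param flow_direction `+1` for motion toward the transducer (positive
#'   Doppler), `-1` away.
#' @param spiral_pitch Helix pitch, m per turn (spiral).
#' @param probe_tilt Probe-axis tilt, degrees; when given, the spiral
#'   beam-to-flow angle is derived via [helix_beam_angle()] at the
#'   tube-crossing azimuth.
#' @param lumen_radius_fn Function of azimuth (degrees) returning the surface
#'   radius in m (lumen); `NULL` means a constant `surface_radius`.
#' @param surface_radius Mean surface radius from the rotation axis, m
#'   (rotational kinds).
#' @param surface_ecc Amplitude of the one-cycle sinusoidal surface-radius
#'   variation, m (spiral; emulates an eccentric probe position).
#' @param tube_depth Depth of the tube/flow-layer center below the surface, m
#'   (rotational kinds).
#' @param arc_fraction Fraction of the revolution over which the beam
#'   intersects the tube (spiral), starting at line 1.
#' @param scatterer_density Point absorbers per mm of beam-intersected tube.
#' @param pulse_center_freq Transducer center frequency, Hz.
#' @param pulse_frac_bandwidth Fractional -6 dB bandwidth of the pulse.
#' @param snr_db Signal-to-noise ratio, dB (RMS, inside the flow region);
#'   `Inf` for noiseless.
#' @param n_samples Samples per A-line.
#' @param n_lines Number of A-lines (rotational default: lines per revolution
#'   times `arc_fraction` rounded to a full revolution scan).
#' @param tube_center_depth Depth of the tube center below the transducer
#'   surface, m (linear tube; default mid-window).
#' @param seed Integer seed; mandatory (all generation is reproducible).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("linear_tube", "spiral", "lumen"),
                         tube_inner_diameter = 580e-6,
                         flow_speed = 3.15e-3,
                         flow_profile = c("plug", "parabolic"),
                         beam_to_flow_angle = 60,
                         flow_direction = 1,
                         spiral_pitch = 8e-3,
                         probe_tilt = NULL,
                         lumen_radius_fn = NULL,
                         surface_radius = 7e-3,
                         surface_ecc = 0.15e-3,
                         tube_depth = 0.8e-3,
                         arc_fraction = 1,
                         scatterer_density = 40,
                         pulse_center_freq = 15e6,
                         pulse_frac_bandwidth = 1.15,
                         snr_db = 20,
                         n_samples = 3000L,
                         n_lines = NULL,
                         tube_center_depth = NULL,
                         seed) {
  if (missing(seed) || is.null(seed))
    stop("phantom_spec: 'seed' is mandatory for stochastic generation")
  kind <- match.arg(kind)
  flow_profile <- match.arg(flow_profile)
  spec <- list(kind = kind, tube_inner_diameter = tube_inner_diameter,
               flow_speed = flow_speed, flow_profile = flow_profile,
               beam_to_flow_angle = beam_to_flow_angle,
               flow_direction = sign(flow_direction),
               spiral_pitch = spiral_pitch, probe_tilt = probe_tilt,
               lumen_radius_fn = lumen_radius_fn,
               surface_radius = surface_radius, surface_ecc = surface_ecc,
               tube_depth = tube_depth, arc_fraction = arc_fraction,
               scatterer_density = scatterer_density,
               pulse_center_freq = pulse_center_freq,
               pulse_frac_bandwidth = pulse_frac_bandwidth,
               snr_db = snr_db, n_samples = as.integer(n_samples),
               n_lines = if (is.null(n_lines)) NULL else as.integer(n_lines),
               tube_center_depth = tube_center_depth,
               seed = as.integer(seed))
  if (any(spec$flow_speed < 0)) stop("phantom_spec: flow_speed must be >= 0")
  if (spec$beam_to_flow_angle <= 0 || spec$beam_to_flow_angle >= 90)
    stop("phantom_spec: beam_to_flow_angle must lie in (0, 90) degrees")
  if (!is.finite(spec$snr_db) && spec$snr_db != Inf)
    stop("phantom_spec: snr_db must be finite or Inf")
  class(spec) <- "phantom_spec"
  spec
}

# Gaussian pulse envelope standard deviation (seconds) from the fractional
# -6 dB bandwidth: the spectral magnitude is Gaussian with sd sigma_f and
# full -6 dB (half-amplitude) width 2*sigma_f*sqrt(2*log(2)).
pulse_sigma_t <- function(fc, frac_bw) {
  sigma_f <- fc * frac_bw / (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigma_f)
}

#' Synthesize the transducer pulse
#'
#' Gaussian-enveloped cosine with unit peak amplitude whose -6 dB spectral
#' full width divided by `fc` equals `frac_bw`. The returned waveform has odd
#' length and is centered on its peak.
#'
#' @param fc Center frequency, Hz (must be below `fs/2`).
#' @param frac_bw Fractional -6 dB bandwidth.
#' @param fs Sampling frequency, Hz.
#' @return Numeric vector (odd length, peak value 1 at the center sample).
#' @export
make_pulse <- function(fc = 15e6, frac_bw = 1.15, fs = 180e6) {
  if (fc <= 0 || frac_bw <= 0 || fs <= 0)
    stop("make_pulse: fc, frac_bw, fs must be > 0")
  if (fc >= fs / 2)
    stop("make_pulse: aliasing - fc must be below fs/2")
  sigma_t <- pulse_sigma_t(fc, frac_bw)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * fc * t)
}

# Evaluate the continuous pulse at arbitrary sample offsets (fractional
# delays are exact; no resampling involved).
pulse_at <- function(dk, fc, fs, sigma_t)
  exp(-(dk / fs)^2 / (2 * sigma_t^2)) * cos(2 * pi * fc * dk / fs)

# One A-line: sum of `amps[j] * pulse(k - pos[j])` over scatterers.
pulse_line <- function(n, pos, amps, fc, fs, sigma_t, half) {
  col <- numeric(n)
  for (j in seq_along(pos)) {
    lo <- max(1L, ceiling(pos[j] - half))
    hi <- min(n, floor(pos[j] + half))
    if (lo > hi) next
    k <- lo:hi
    col[k] <- col[k] + amps[j] * pulse_at(k - pos[j], fc, fs, sigma_t)
  }
  col
}

#' Beam-to-flow angle of a helical tube under a tilted rotational probe
#'
#' Analytic helix-tangent geometry: a tube of pitch `pitch` (m/turn) wraps a
#' cylinder of radius `radius`; the probe axis is tilted by `probe_tilt`
#' degrees (in the plane of the beam at azimuth 0) relative to the cylinder
#' axis, and the side-viewing beam at azimuth `psi` (degrees, measured from
#' the tilt plane) is perpendicular to the probe axis. Returns the angle in
#' degrees between the beam direction and the helix tangent at that azimuth,
#' folded to `[0, 90]`.
#'
#' @param pitch Helix pitch, m per turn.
#' @param radius Helix radius, m.
#' @param probe_tilt Probe-axis tilt, degrees.
#' @param psi Beam azimuth, degrees.
#' @return Beam-to-flow angle, degrees.
#' @export
helix_beam_angle <- function(pitch, radius, probe_tilt, psi = 0) {
  lam <- atan2(pitch, 2 * pi * radius)            # helix pitch angle
  tau <- probe_tilt * pi / 180
  ps <- psi * pi / 180
  b <- c(cos(ps) * cos(tau), sin(ps), -cos(ps) * sin(tau))
  tg <- c(-sin(ps) * cos(lam), cos(ps) * cos(lam), sin(lam))
  acos(pmin(1, abs(sum(b * tg)))) * 180 / pi
}

#' Simulate a stationary-beam linear-tube scan sequence
#'
#' The imaging head is held fixed while a tube crosses the beam at
#' `beam_to_flow_angle`; `n_lines` A-lines are acquired at `1/fprf` intervals.
#' Point absorbers seeded along the beam-intersected tube chord advect along
#' the tube each PRF interval, so the axial displacement between adjacent
#' A-lines is exactly `flow_speed * cos(angle) / fprf` (scatterers leaving the
#' chord re-enter at the far end, keeping density stationary). The US channel
#' carries strong tube-wall echoes at the chord boundaries.
#'
#' @param spec A [phantom_spec()] with `kind = "linear_tube"`.
#' @param params [acquisition_params()] with `scan_mode = "stationary"`.
#' @return A [scan_set()] with ground truth and realized signal/noise RMS
#'   recorded in `meta`.
#' @export
simulate_stationary_sequence <- function(spec, params = acquisition_params()) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind == "linear_tube")
  if (params$scan_mode != "stationary")
    stop("simulate_stationary_sequence: params$scan_mode must be 'stationary'")
  set.seed(spec$seed)
  n <- spec$n_samples
  L <- spec$n_lines %||% 201L
  spm <- samples_per_meter(params)
  theta <- spec$beam_to_flow_angle * pi / 180
  chord_m <- spec$tube_inner_diameter / sin(theta)
  chord_k <- chord_m * spm
  kc <- if (is.null(spec$tube_center_depth)) (n + 1) / 2 else
    sample_of_radius(params$probe_offset + spec$tube_center_depth, params)
  k0 <- kc - chord_k / 2
  k1 <- kc + chord_k / 2
  sigma_t <- pulse_sigma_t(spec$pulse_center_freq, spec$pulse_frac_bandwidth)
  half <- ceiling(4 * sigma_t * params$fs)
  if (k0 - half < 1 || k1 + half > n)
    stop("simulate_stationary_sequence: geometry error - tube (plus pulse support) outside the sampled depth window")

  nsc <- max(8L, round(spec$scatterer_density * chord_m * 1e3))
  x0 <- runif(nsc, k0, k1)
  amps <- rnorm(nsc)
  vfac <- if (spec$flow_profile == "parabolic") 1 - runif(nsc)^2 else rep(1, nsc)
  delta <- spec$flow_direction * spec$flow_speed * vfac * cos(theta) * spm / params$fprf
  W <- k1 - k0

  pa <- matrix(0, n, L)
  for (i in seq_len(L)) {
    pos <- k0 + ((x0 - k0 - delta * (i - 1)) %% W)
    pa[, i] <- pulse_line(n, pos, amps, spec$pulse_center_freq,
                          params$fs, sigma_t, half)
  }
  band <- ceiling(k0):floor(k1)
  sig_rms <- sqrt(mean(pa[band, ]^2))
  wall_amp <- max(sig_rms, 1e-12) * 10^(30 / 20)
  us <- matrix(pulse_line(n, c(k0, k1), c(wall_amp, wall_amp),
                          spec$pulse_center_freq, params$fs, sigma_t, half),
               n, L)

  sigma_n <- if (is.finite(spec$snr_db)) sig_rms * 10^(-spec$snr_db / 20) else 0
  noise_rms <- 0
  if (sigma_n > 0) {
    noise <- matrix(rnorm(n * L, 0, sigma_n), n, L)
    noise_rms <- sqrt(mean(noise[band, ]^2))
    pa <- pa + noise
    us <- us + matrix(rnorm(n * L, 0, sigma_n), n, L)
  }

  vax <- matrix(0, n, L)
  spd <- matrix(0, n, L)
  vax[band, ] <- spec$flow_direction * spec$flow_speed * cos(theta)
  spd[band, ] <- spec$flow_speed
  gt <- list(true_axial_velocity = vax, true_speed = spd,
             flow_angle = rep(spec$beam_to_flow_angle, L),
             surface_arrival = rep(k0, L))
  meta <- list(seed = spec$seed, generator = "corrdop-sim-1",
               signal_rms = sig_rms, noise_sigma = sigma_n,
               snr_db_realized = if (noise_rms > 0)
                 20 * log10(sig_rms / noise_rms) else Inf,
               tube_band_first = band[1], tube_band_last = band[length(band)])
  scan_set(pa, us, params, meta = meta, ground_truth = gt)
}

#' Simulate a rotational (endoscopic) B-scan
#'
#' Per line the beam rotates by the angular step. For `kind = "spiral"` a tube
#' turn sits at a fixed depth below a slowly varying (eccentric) surface and
#' its speckle advects axially at `flow_speed * cos(theta)` per PRF interval,
#' with `theta` either given (`beam_to_flow_angle`) or derived from
#' `probe_tilt` via [helix_beam_angle()]. For `kind = "lumen"` the surface
#' radius follows `lumen_radius_fn` and an optional superficial flow layer
#' (when `flow_speed > 0`) runs parallel to the surface, so its beam-to-flow
#' angle per line comes from the local surface slope. The US channel carries a
#' dominant water-surface interface echo (>= 30 dB above its noise); the
#' whole A-line content rides on the surface profile, which the
#' time-of-arrival alignment stage must remove.
#'
#' @param spec A [phantom_spec()] with `kind` `"spiral"` or `"lumen"`.
#' @param params [acquisition_params()] with `scan_mode = "rotational"`.
#' @return A [scan_set()] with ground truth (including `surface_arrival` and
#'   per-line `flow_angle`).
#' @export
simulate_rotational_scan <- function(spec,
                                     params = acquisition_params(scan_mode = "rotational")) {
  stopifnot(inherits(spec, "phantom_spec"), spec$kind %in% c("spiral", "lumen"))
  if (params$scan_mode != "rotational")
    stop("simulate_rotational_scan: params$scan_mode must be 'rotational'")
  set.seed(spec$seed)
  n <- spec$n_samples
  L <- spec$n_lines %||% params$lines_per_rev
  spm <- samples_per_meter(params)
  phi <- (seq_len(L) - 1) * params$line_angle_step   # degrees

  r_surf <- if (spec$kind == "lumen" && !is.null(spec$lumen_radius_fn))
    vapply(phi, spec$lumen_radius_fn, numeric(1))
  else if (spec$kind == "spiral")
    spec$surface_radius + spec$surface_ecc * sin(2 * pi * (seq_len(L) - 1) / params$lines_per_rev)
  else rep(spec$surface_radius, L)
  Ls <- sample_of_radius(r_surf, params)             # continuous, 1-based

  sigma_t <- pulse_sigma_t(spec$pulse_center_freq, spec$pulse_frac_bandwidth)
  half <- ceiling(4 * sigma_t * params$fs)
  if (any(Ls - half < 1))
    stop("simulate_rotational_scan: geometry error - surface above the sampled window")

  # per-line beam-to-flow angle of the flow region
  if (spec$kind == "spiral") {
    theta_deg <- rep(if (!is.null(spec$probe_tilt))
      helix_beam_angle(spec$spiral_pitch,
                       mean(r_surf) + spec$tube_depth, spec$probe_tilt)
      else spec$beam_to_flow_angle, L)
  } else {
    # flow parallel to the surface: angle from the local radial slope
    ip <- c(2:L, 1L); im <- c(L, 1:(L - 1))
    dphi_rad <- params$line_angle_step * pi / 180
    drdphi <- (r_surf[ip] - r_surf[im]) / (2 * dphi_rad)
    theta_deg <- 90 - atan2(abs(drdphi), r_surf) * 180 / pi
  }

  has_flow <- spec$flow_speed > 0 || spec$kind == "spiral"
  in_arc <- seq_len(L) <= max(1, round(spec$arc_fraction * L))
  theta <- theta_deg * pi / 180
  chord_k <- spec$tube_inner_diameter /
    pmax(sin(mean(theta)), sin(20 * pi / 180)) * spm
  b0 <- spec$tube_depth * spm - chord_k / 2
  b1 <- spec$tube_depth * spm + chord_k / 2
  if (any(Ls + b1 + half > n))
    stop("simulate_rotational_scan: geometry error - flow region below the sampled window")
  if (has_flow && mean(theta_deg[in_arc] >= 70) > 0.5)
    warning("simulate_rotational_scan: ground-truth flow angle >= 70 deg for >50% of tube-intersecting lines (uncorrectable geometry)")

  pa <- matrix(0, n, L)
  vax <- matrix(0, n, L)
  spd <- matrix(0, n, L)

  if (has_flow) {
    chord_m <- (b1 - b0) / spm
    nsc <- max(8L, round(spec$scatterer_density * chord_m * 1e3))
    x0 <- runif(nsc, b0, b1)
    amps <- rnorm(nsc)
    W <- b1 - b0
    # cumulative axial advection (theta may vary per line for lumen flow)
    dk <- spec$flow_direction * spec$flow_speed * cos(theta) * spm / params$fprf
    shift <- c(0, cumsum(dk))[seq_len(L)]
    for (i in seq_len(L)) {
      if (!in_arc[i]) next
      pos <- Ls[i] + b0 + ((x0 - b0 - shift[i]) %% W)
      pa[, i] <- pulse_line(n, pos, amps, spec$pulse_center_freq,
                            params$fs, sigma_t, half)
      rows <- max(1, ceiling(Ls[i] + b0)):min(n, floor(Ls[i] + b1))
      vax[rows, i] <- spec$flow_direction * spec$flow_speed * cos(theta[i])
      spd[rows, i] <- spec$flow_speed
    }
  }

  sig_rms <- if (has_flow) {
    v <- unlist(lapply(which(in_arc), function(i) {
      rows <- max(1, ceiling(Ls[i] + b0)):min(n, floor(Ls[i] + b1))
      pa[rows, i]
    }))
    sqrt(mean(v^2))
  } else 0

  sigma_n <- if (!is.finite(spec$snr_db)) 0
  else if (sig_rms > 0) sig_rms * 10^(-spec$snr_db / 20) else 1
  if (sigma_n > 0) pa <- pa + matrix(rnorm(n * L, 0, sigma_n), n, L)

  wall_amp <- 1
  sigma_us <- if (is.finite(spec$snr_db)) wall_amp * 10^(-35 / 20) else 0
  us <- matrix(0, n, L)
  for (i in seq_len(L))
    us[, i] <- pulse_line(n, Ls[i], wall_amp, spec$pulse_center_freq,
                          params$fs, sigma_t, half)
  if (sigma_us > 0) us <- us + matrix(rnorm(n * L, 0, sigma_us), n, L)

  gt <- list(true_axial_velocity = vax, true_speed = spd,
             flow_angle = theta_deg, surface_arrival = Ls)
  meta <- list(seed = spec$seed, generator = "corrdop-sim-1",
               signal_rms = sig_rms, noise_sigma = sigma_n,
               flow_angle_used = if (has_flow) mean(theta_deg[in_arc]) else NA_real_)
  scan_set(pa, us, params, meta = meta, ground_truth = gt)
}
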