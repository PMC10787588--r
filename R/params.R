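#' Acquisition parameters of a PA/US scan
#'
#' Bundles the physical constants of one acquisition: speed of sound, laser
#' pulse repetition frequency (PRF, the A-line rate), RF sampling rate, the
#' rotational scan geometry (lines per revolution and the angular step between
#' adjacent A-lines), the transducer-surface-to-rotation-axis offset, and the
#' PA-to-US firing delay. All values are SI (m, s, Hz); display helpers convert
#' to mm/s.
#'
#' Defaults correspond to a 1 kHz Nd:YAG AR-PAM/US endoscope digitized at
#' 180 MHz with 1000 A-lines per revolution and a 5.57 mm probe offset.
#'
#' @param c Speed of sound in the coupling medium, m/s.
#' @param fprf Pulse repetition frequency, Hz (A-line acquisition rate).
#' @param fs RF sampling frequency, Hz.
#' @param lines_per_rev A-lines acquired in one full probe revolution.
#' @param line_angle_step Angular step between adjacent A-lines, degrees.
#'   Must satisfy `line_angle_step * lines_per_rev == 360`.
#' @param probe_offset Distance from the transducer surface to the rotation
#'   axis, meters.
#' @param pa_us_delay Delay between the PA and US firings of a pulse pair,
#'   seconds.
#' @param scan_mode `"stationary"` (fixed beam, e.g. linear-tube phantom) or
#'   `"rotational"` (endoscopic B-scan).
#' @param propagation_convention `"round_trip"` (depth of sample k is
#'   `c/2 * k/fs`, pulse-echo) or `"one_way"` (`c * k/fs`).
#' @return An object of class `acq_params`.
#' @examples
#' p <- acquisition_params()
#' p$fs    # 1.8e8
#' @export
acquisition_params <- function(c = 1540, fprf = 1000, fs = 180e6,
                               lines_per_rev = 1000,
                               line_angle_step = 360 / lines_per_rev,
                               probe_offset = 5.57e-3,
                               pa_us_delay = 16.3e-6,
                               scan_mode = c("stationary", "rotational"),
                               propagation_convention = c("round_trip", "one_way")) {
  scan_mode <- match.arg(scan_mode)
  propagation_convention <- match.arg(propagation_convention)
  p <- list(c = c, fprf = fprf, fs = fs,
            lines_per_rev = as.integer(lines_per_rev),
            line_angle_step = line_angle_step,
            probe_offset = probe_offset, pa_us_delay = pa_us_delay,
            scan_mode = scan_mode,
            propagation_convention = propagation_convention)
  class(p) <- "acq_params"
  validate_acq_params(p)
}

validate_acq_params <- function(p) {
  for (f in c("c", "fprf", "fs", "lines_per_rev", "line_angle_step",
              "probe_offset", "pa_us_delay")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("acquisition_params: field '%s' must be a single finite value > 0", f))
  }
  if (abs(p$line_angle_step * p$lines_per_rev - 360) > 1e-9)
    stop("acquisition_params: field 'line_angle_step' violates line_angle_step * lines_per_rev == 360 (within 1e-9)")
  p
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params>\n")
  cat(sprintf("  c = %g m/s, fprf = %g Hz, fs = %g Hz\n", x$c, x$fprf, x$fs))
  cat(sprintf("  %d lines/rev, step %.4g deg, probe offset %.3g mm\n",
              x$lines_per_rev, x$line_angle_step, 1e3 * x$probe_offset))
  cat(sprintf("  scan_mode = %s, propagation = %s\n", x$scan_mode,
              x$propagation_convention))
  invisible(x)
}

#' Doppler processing configuration
#'
#' Every tunable constant of the correlational Doppler chain in one validated
#' record. Defaults are the processing constants of the AR-PAM flowmetry
#' pipeline: 3--30 MHz FIR passband, x3 axial interpolation, 25-point
#' correlation window, correlation-coefficient gate, 70 deg compensation cap,
#' 10 dB rising-edge threshold, 100-line ROI averaging and 20 report regions.
#'
#' @param passband Length-2 numeric, FIR passband in Hz (low, high).
#' @param nres Integer axial interpolation factor applied before correlation.
#' @param window_len Correlation window length in interpolated samples (odd).
#' @param max_lag Lag search half-range in interpolated samples.
#' @param rho_min Correlation-coefficient gate threshold in \[0, 1\].
#' @param noise_factor Amplitude mask threshold as a multiple of the noise
#'   floor (mean absolute noise amplitude).
#' @param angle_cap Maximum beam-to-flow angle used in cosine compensation,
#'   degrees; larger estimated angles are clamped to this value.
#' @param subsample_refine Logical; refine the integer correlation lag by a
#'   parabolic fit through the peak and its neighbours.
#' @param toa_threshold_db Rising-edge surface detection threshold in dB above
#'   the noise floor.
#' @param roi_lines A-line pairs per ROI-averaging block.
#' @param n_regions Number of equal sectors for region statistics.
#' @param window_hop Hop between window centers, interpolated samples.
#' @return An object of class `doppler_config`.
#' @examples
#' cfg <- doppler_config(subsample_refine = TRUE)
#' cfg$window_len   # 25
#' @export
doppler_config <- function(passband = c(3e6, 30e6), nres = 3L,
                           window_len = 25L, max_lag = 15L, rho_min = 0.7,
                           noise_factor = 3.0, angle_cap = 70,
                           subsample_refine = FALSE, toa_threshold_db = 10,
                           roi_lines = 100L, n_regions = 20L,
                           window_hop = 12L) {
  cfg <- list(passband = as.numeric(passband), nres = as.integer(nres),
              window_len = as.integer(window_len),
              max_lag = as.integer(max_lag), rho_min = rho_min,
              noise_factor = noise_factor, angle_cap = angle_cap,
              subsample_refine = isTRUE(subsample_refine),
              toa_threshold_db = toa_threshold_db,
              roi_lines = as.integer(roi_lines),
              n_regions = as.integer(n_regions),
              window_hop = as.integer(window_hop))
  class(cfg) <- "doppler_config"
  validate_doppler_config(cfg)
}

validate_doppler_config <- function(cfg) {
  fail <- function(field, bound)
    stop(sprintf("doppler_config: field '%s' out of range (%s)", field, bound))
  pb <- cfg$passband
  if (length(pb) != 2L || !all(is.finite(pb)) || pb[1] <= 0 || pb[1] >= pb[2])
    fail("passband", "0 < low < high required")
  if (cfg$nres < 1L) fail("nres", "must be >= 1")
  if (cfg$window_len < 3L || cfg$window_len %% 2L == 0L)
    fail("window_len", "must be odd and >= 3")
  if (cfg$max_lag < 1L || cfg$max_lag >= cfg$window_len)
    fail("max_lag", "0 < max_lag < window_len required")
  if (!is.finite(cfg$rho_min) || cfg$rho_min < 0 || cfg$rho_min > 1)
    fail("rho_min", "must lie in [0, 1]")
  if (!is.finite(cfg$noise_factor) || cfg$noise_factor < 0)
    fail("noise_factor", "must be >= 0")
  if (!is.finite(cfg$angle_cap) || cfg$angle_cap <= 0 || cfg$angle_cap >= 90)
    fail("angle_cap", "must lie in (0, 90) degrees")
  if (!is.finite(cfg$toa_threshold_db) || cfg$toa_threshold_db < 0)
    fail("toa_threshold_db", "must be >= 0")
  if (cfg$roi_lines < 1L) fail("roi_lines", "must be >= 1")
  if (cfg$n_regions < 1L) fail("n_regions", "must be >= 1")
  if (cfg$window_hop < 1L) fail("window_hop", "must be >= 1")
  cfg
}

#' @export
print.doppler_config <- function(x, ...) {
  cat("<doppler_config>\n")
  cat(sprintf("  passband %g-%g MHz, nres %d, window %d, max_lag %d, hop %d\n",
              x$passband[1] / 1e6, x$passband[2] / 1e6, x$nres, x$window_len,
              x$max_lag, x$window_hop))
  cat(sprintf("  rho_min %.2f, noise_factor %.1f, angle_cap %g deg, refine %s\n",
              x$rho_min, x$noise_factor, x$angle_cap, x$subsample_refine))
  cat(sprintf("  toa threshold %g dB, roi %d lines, %d regions\n",
              x$toa_threshold_db, x$roi_lines, x$n_regions))
  invisible(x)
}

#' Load acquisition and Doppler configuration from a YAML file
#'
#' The file may contain two top-level maps, `acquisition` and `doppler`, whose
#' keys are the arguments of [acquisition_params()] and [doppler_config()].
#' Missing keys (or a `NULL` path) fall back to the defaults; every value is
#' validated, and an out-of-range value fails naming the field and bound.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A list with elements `params` ([acquisition_params()]) and
#'   `config` ([doppler_config()]).
#' @export
load_config <- function(path = NULL) {
  acq <- list(); dop <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_config: file not found: ", path)
    y <- yaml::read_yaml(path)
    acq <- y$acquisition %||% list()
    dop <- y$doppler %||% list()
    unknown <- setdiff(names(acq), names(formals(acquisition_params)))
    if (length(unknown))
      stop("load_config: unknown acquisition key(s): ",
           paste(unknown, collapse = ", "))
    unknown <- setdiff(names(dop), names(formals(doppler_config)))
    if (length(unknown))
      stop("load_config: unknown doppler key(s): ",
           paste(unknown, collapse = ", "))
  }
  list(params = do.call(acquisition_params, acq),
       config = do.call(doppler_config, dop))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Depth/radius mapping. `k` is a 1-based sample index (possibly fractional);
# sample 1 is at the transducer surface (t = 0).
samples_per_meter <- function(params) {
  if (params$propagation_convention == "round_trip") 2 * params$fs / params$c
  else params$fs / params$c
}

depth_of_sample <- function(k, params) (k - 1) / samples_per_meter(params)

radius_of_sample <- function(k, params) params$probe_offset + depth_of_sample(k, params)

sample_of_radius <- function(r, params)
  1 + (r - params$probe_offset) * samples_per_meter(params)
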