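#' Run the full correlational Doppler chain on a ScanSet
#'
#' Band-pass filtering, noise-floor estimation, (for rotational scans)
#' US surface detection / outlier rejection / PA A-line alignment, amplitude
#' masking, axial interpolation, sliding-window correlation with gating,
#' conversion to axial velocity, angle compensation (fixed angle or
#' surface-derived per-line angles), optional ROI averaging, and back-shifting
#' of window centers to the original grid.
#'
#' @param scan A [scan_set()].
#' @param cfg [doppler_config()].
#' @param fixed_angle Fixed beam-to-flow angle in degrees (linear-tube and
#'   constant-angle spiral processing); `NULL` derives per-line angles from
#'   the detected surface via [estimate_angles()].
#' @param align Apply US time-of-arrival detection and PA alignment
#'   (default: rotational scans only).
#' @param roi Apply [roi_average()] with `cfg$roi_lines` blocks.
#' @param angle_mode Angle estimation mode, see [estimate_angles()].
#' @return List with `vmap` (the `velocity_map`), `profile` (the
#'   `surface_profile`, or `NULL`), `floor` (PA noise floor) and `vres`.
#' @export
process_scan <- function(scan, cfg = doppler_config(), fixed_angle = NULL,
                         align = scan$params$scan_mode == "rotational",
                         roi = FALSE, angle_mode = "exact") {
  params <- scan$params
  pa_f <- bandpass(scan$pa, params, cfg)
  profile <- NULL
  shifts <- NULL
  if (align) {
    us_f <- bandpass(scan$us, params, cfg)
    profile <- detect_surface(us_f, params, cfg)
    if (!any(profile$valid)) stop("process_scan: no surface detected")
    profile <- reject_outliers(profile, params)
    profile <- smooth_surface(profile, params)
    al <- align_to_surface(pa_f, profile)
    pa_f <- al$frame
    shifts <- al$shifts
  }
  floor_pa <- noise_floor(pa_f, profile = profile)
  mask <- amplitude_mask(pa_f, floor_pa, cfg$noise_factor)
  up <- upsample_axial(pa_f, cfg$nres)
  vmap <- correlate_adjacent(up, upsample_mask(mask, cfg$nres), cfg)
  vmap <- gate(vmap, cfg$rho_min)
  vres <- velocity_resolution(params, cfg$nres)
  vmap <- to_velocity(vmap, vres)
  if (!is.null(fixed_angle)) {
    vmap <- compensate(vmap, fixed_angle, cfg)
  } else if (!is.null(profile)) {
    profile <- estimate_angles(profile, params, cfg, mode = angle_mode)
    vmap <- compensate(vmap, profile, cfg)
  }
  if (roi) vmap <- roi_average(vmap, cfg$roi_lines)
  if (!is.null(shifts) && !roi) vmap <- backshift(vmap, shifts)
  list(vmap = vmap, profile = profile, floor = floor_pa, vres = vres)
}

#' Mean estimated flow speed of a velocity map
#'
#' Signed mean of the compensated velocity over valid windows (the sign
#' carries the flow direction; its magnitude is the speed estimate).
#'
#' @param vmap A `velocity_map` with `v` filled.
#' @return Mean velocity, m/s.
#' @export
mean_flow_speed <- function(vmap) {
  stopifnot(inherits(vmap, "velocity_map"))
  vals <- vmap$v[vmap$valid]
  mean(vals[is.finite(vals)])
}
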