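# In-silico reproductions of the three phantom validation experiments:
# linear-tube linearity sweep, angle-dependence sweep, and the rotational
# spiral sweep with ROI averaging.

# Derived per-run seeds; kept inside the 32-bit integer range.
.run_seed <- function(seed, run, offset = 0L)
  as.integer((as.numeric(seed) * 1000 + offset + run) %% .Machine$integer.max)

.fit_r2 <- function(truth, est) {
  fit <- stats::lm(est ~ truth)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

#' Linear-tube flow linearity experiment
#'
#' For each true speed, simulates the stationary linear-tube phantom
#' (60 deg beam-to-flow angle by default) `reps` times with distinct seeds,
#' runs the full pipeline with sub-sample refinement and fixed-angle
#' compensation, and reports the per-speed mean and sd of the estimated
#' speed, an ordinary least-squares fit of estimate versus truth (with R^2),
#' and the maximum relative error over speeds.
#'
#' @param speeds True flow speeds, m/s (default: the ten-speed sweep
#'   0.63-6.3 mm/s in 0.63 mm/s increments).
#' @param reps Replicate scans per speed (distinct derived seeds).
#' @param seed Base seed; run k uses `seed * 1000 + k`.
#' @param angle Beam-to-flow angle, degrees.
#' @param snr_db Simulated SNR, dB.
#' @param n_lines A-lines per scan.
#' @param params [acquisition_params()] (stationary).
#' @param cfg [doppler_config()]; sub-sample refinement is switched on.
#' @return A `flow_report` list: `table` (per-speed truth, mean, sd in m/s),
#'   `fit` (slope/intercept/R^2), `max_rel_err`, `settings`.
#' @export
experiment_linearity <- function(speeds = seq(0.63e-3, 6.3e-3, by = 0.63e-3),
                                 reps = 3L, seed = 1L, angle = 60,
                                 snr_db = 20, n_lines = 201L,
                                 params = acquisition_params(scan_mode = "stationary"),
                                 cfg = doppler_config(subsample_refine = TRUE)) {
  if (any(speeds <= 0)) stop("experiment_linearity: speeds must be > 0")
  vres <- velocity_resolution(params, cfg$nres)
  if (max(speeds) * cos(angle * pi / 180) / vres > cfg$max_lag)
    stop("experiment_linearity: projected shift exceeds max_lag")
  run <- 0L
  rows <- lapply(speeds, function(v) {
    ests <- vapply(seq_len(reps), function(r) {
      run <<- run + 1L
      spec <- phantom_spec("linear_tube", flow_speed = v,
                           beam_to_flow_angle = angle, snr_db = snr_db,
                           n_lines = n_lines, seed = .run_seed(seed, run))
      scan <- simulate_stationary_sequence(spec, params)
      res <- process_scan(scan, cfg, fixed_angle = angle)
      abs(mean_flow_speed(res$vmap))
    }, numeric(1))
    data.frame(truth = v, mean_est = mean(ests),
               sd_est = stats::sd(ests))
  })
  tab <- do.call(rbind, rows)
  fit <- .fit_r2(tab$truth, tab$mean_est)
  rel_err <- abs(tab$mean_est - tab$truth) / tab$truth
  structure(list(table = tab, fit = fit,
                 max_rel_err = max(rel_err),
                 settings = list(kind = "linearity", angle = angle,
                                 snr_db = snr_db, n_lines = n_lines,
                                 reps = reps, seed = seed,
                                 subsample_refine = cfg$subsample_refine)),
            class = "flow_report")
}

#' Angle-dependence experiment
#'
#' Holds the flow speed fixed and varies the beam-to-flow angle, reporting
#' per angle the uncompensated mean axial velocity (which follows
#' `v * cos(theta)`) and the compensated estimate (which recovers `v` up to
#' the `angle_cap`; above the cap the capped factor under-recovers by
#' `cos(theta)/cos(cap)`).
#'
#' @param angles Beam-to-flow angles, degrees.
#' @param speed True flow speed, m/s.
#' @param seed Base seed.
#' @param reps Replicates per angle.
#' @param snr_db,n_lines,params,cfg As in [experiment_linearity()].
#' @return A `flow_report` with per-angle `truth`, `uncompensated`,
#'   `compensated` columns (m/s).
#' @export
experiment_angle_sweep <- function(angles = c(70, 60, 50), speed = 6.3e-3,
                                   seed = 1L, reps = 3L, snr_db = 20,
                                   n_lines = 201L,
                                   params = acquisition_params(scan_mode = "stationary"),
                                   cfg = doppler_config(subsample_refine = TRUE)) {
  if (any(angles <= 0 | angles >= 90))
    stop("experiment_angle_sweep: angles must lie in (0, 90)")
  run <- 0L
  rows <- lapply(angles, function(th) {
    est <- vapply(seq_len(reps), function(r) {
      run <<- run + 1L
      spec <- phantom_spec("linear_tube", flow_speed = speed,
                           beam_to_flow_angle = th, snr_db = snr_db,
                           n_lines = n_lines, seed = .run_seed(seed, run))
      scan <- simulate_stationary_sequence(spec, params)
      res <- process_scan(scan, cfg, fixed_angle = th)
      c(vc = abs(mean(res$vmap$vc[res$vmap$valid], na.rm = TRUE)),
        v = abs(mean_flow_speed(res$vmap)))
    }, c(vc = 0, v = 0))
    data.frame(angle = th, truth = speed,
               uncompensated = mean(est["vc", ]),
               compensated = mean(est["v", ]))
  })
  structure(list(table = do.call(rbind, rows),
                 settings = list(kind = "angle_sweep", speed = speed,
                                 snr_db = snr_db, reps = reps, seed = seed)),
            class = "flow_report")
}

#' Rotational spiral-phantom experiment
#'
#' For each speed, simulates the rotational spiral phantom (full revolution,
#' constant known beam-to-flow angle, eccentric surface), runs the full
#' pipeline including US time-of-arrival alignment, constant-angle
#' compensation and ROI averaging over `cfg$roi_lines` A-line pairs, and fits
#' estimate versus truth.
#'
#' @param speeds True flow speeds, m/s.
#' @param reps Replicates per speed.
#' @param seed Base seed; run k uses `seed * 1000 + 500 + k`.
#' @param angle Constant beam-to-flow angle, degrees.
#' @param snr_db Simulated SNR, dB.
#' @param params [acquisition_params()] (rotational).
#' @param cfg [doppler_config()]; sub-sample refinement is switched on.
#' @return A `flow_report` (same shape as [experiment_linearity()]).
#' @export
experiment_spiral <- function(speeds = seq(1e-3, 6e-3, by = 1e-3),
                              reps = 3L, seed = 1L, angle = 60, snr_db = 20,
                              params = acquisition_params(scan_mode = "rotational"),
                              cfg = doppler_config(subsample_refine = TRUE)) {
  if (any(speeds <= 0)) stop("experiment_spiral: speeds must be > 0")
  run <- 0L
  rows <- lapply(speeds, function(v) {
    ests <- vapply(seq_len(reps), function(r) {
      run <<- run + 1L
      spec <- phantom_spec("spiral", flow_speed = v,
                           beam_to_flow_angle = angle, snr_db = snr_db,
                           seed = .run_seed(seed, run, offset = 500L))
      scan <- simulate_rotational_scan(spec, params)
      res <- process_scan(scan, cfg, fixed_angle = angle, align = TRUE,
                          roi = TRUE)
      abs(mean_flow_speed(res$vmap))
    }, numeric(1))
    data.frame(truth = v, mean_est = mean(ests), sd_est = stats::sd(ests))
  })
  tab <- do.call(rbind, rows)
  fit <- .fit_r2(tab$truth, tab$mean_est)
  rel_err <- abs(tab$mean_est - tab$truth) / tab$truth
  structure(list(table = tab, fit = fit, max_rel_err = max(rel_err),
                 settings = list(kind = "spiral", angle = angle,
                                 snr_db = snr_db, reps = reps, seed = seed,
                                 roi_lines = cfg$roi_lines)),
            class = "flow_report")
}

#' @export
print.flow_report <- function(x, ...) {
  cat(sprintf("<flow_report: %s>\n", x$settings$kind))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v * 1e3, 4))  # mm/s
  names(tab)[num] <- paste0(names(tab)[num], "_mm_s")
  if ("angle" %in% names(x$table)) {
    tab$angle_mm_s <- NULL
    tab$angle <- x$table$angle
  }
  print(tab, row.names = FALSE)
  if (!is.null(x$fit))
    cat(sprintf("fit: slope %.3f, intercept %.3g mm/s, R^2 = %.4f; max rel err = %.1f%%\n",
                x$fit$slope, 1e3 * x$fit$intercept, x$fit$r_squared,
                100 * x$max_rel_err))
  invisible(x)
}

#' Write a flow report to CSV and JSON
#'
#' @param report A `flow_report`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the two files.
#' @return Character vector of the written paths, invisibly.
#' @export
write_flow_report <- function(report, dir, name = report$settings$kind) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  js <- file.path(dir, paste0(name, ".json"))
  utils::write.csv(report$table, csv, row.names = FALSE)
  jsonlite::write_json(report[c("fit", "max_rel_err", "settings")][
    !vapply(report[c("fit", "max_rel_err", "settings")], is.null, logical(1))],
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
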