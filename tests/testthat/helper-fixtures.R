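# Shared fixtures, all generated in code.

default_params <- function(...) acquisition_params(...)

# A small stationary linear-tube scan (short lines keep the suite fast; the
# line must still exceed the 301-tap filter).
tiny_linear_scan <- function(flow_speed = 3.15e-3, n_lines = 24L,
                             n_samples = 900L, snr_db = 20, seed = 7L,
                             angle = 60, ...) {
  spec <- phantom_spec("linear_tube", flow_speed = flow_speed,
                       beam_to_flow_angle = angle, snr_db = snr_db,
                       n_samples = n_samples, n_lines = n_lines,
                       tube_center_depth = 1.9e-3, seed = seed, ...)
  simulate_stationary_sequence(spec, acquisition_params(scan_mode = "stationary"))
}

# Band-limited random test signal: white noise through the pipeline passband.
bandlimited_noise <- function(n, n_lines = 1L, seed = 1L,
                              params = acquisition_params(),
                              cfg = doppler_config()) {
  set.seed(seed)
  bandpass(matrix(rnorm(n * n_lines), n, n_lines), params, cfg)
}

# Brute-force NCC lag-search oracle for a single window (independent of the
# C++ kernel): plain cor() over every lag, same tie rule.
oracle_lag <- function(line_prev, line_next, center, wlen, maxlag) {
  half <- wlen %/% 2
  a <- line_next[(center - half):(center + half)]
  lags <- -maxlag:maxlag
  cc <- vapply(lags, function(l) {
    b <- line_prev[(center - half + l):(center + half + l)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (all(is.na(cc))) return(NA_real_)
  best <- max(cc, na.rm = TRUE)
  cand <- lags[!is.na(cc) & cc == best]
  cand <- cand[order(abs(cand), -sign(cand))]
  cand[1]
}
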