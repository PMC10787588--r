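test_that("synthesized pulse has the specified fractional bandwidth", {
  pl <- make_pulse(15e6, 1.15, 180e6)
  expect_true(length(pl) %% 2 == 1)
  expect_equal(pl[(length(pl) + 1) / 2], 1)   # unit peak, centered
  expect_equal(max(abs(pl)), 1)

  # FFT oracle for the -6 dB fractional width
  n <- 2^15
  S <- Mod(stats::fft(c(pl, rep(0, n - length(pl)))))[1:(n / 2)]
  f <- (0:(n / 2 - 1)) * 180e6 / n
  idx <- which(S >= max(S) / 2)
  frac_bw <- (f[max(idx)] - f[min(idx)]) / 15e6
  expect_gt(frac_bw, 1.09)
  expect_lt(frac_bw, 1.21)

  # near-monochromatic limit: spectral peak at fc within one bin
  pl2 <- make_pulse(15e6, 0.02, 180e6)
  n2 <- 2^17
  S2 <- Mod(stats::fft(c(pl2, rep(0, n2 - length(pl2)))))[1:(n2 / 2)]
  f2 <- (0:(n2 / 2 - 1)) * 180e6 / n2
  expect_lt(abs(f2[which.max(S2)] - 15e6), 2 * 180e6 / n2)

  expect_error(make_pulse(fc = 100e6, fs = 180e6), "alias")
})

test_that("zero flow gives identical noiseless A-lines and zero ground truth", {
  scan <- tiny_linear_scan(flow_speed = 0, snr_db = Inf, n_lines = 5L)
  for (i in 2:5) expect_identical(scan$pa[, i], scan$pa[, 1])
  expect_true(all(scan$ground_truth$true_axial_velocity == 0))
})

test_that("one-original-sample displacement per interval shifts A-lines by one sample", {
  p <- acquisition_params(scan_mode = "stationary")
  # v cos(60) / fprf = c / (2 fs)  =>  exactly one sample per PRF interval
  v <- p$c * p$fprf / (2 * p$fs * cos(pi / 3))
  scan <- tiny_linear_scan(flow_speed = v, snr_db = Inf, n_lines = 4L)
  band <- which(scan$ground_truth$true_speed[, 1] > 0)
  interior <- (min(band) + 40):(max(band) - 40)
  for (i in 1:3)
    expect_equal(scan$pa[interior, i + 1], scan$pa[interior + 1, i],
                 tolerance = 1e-12)
})

test_that("realized SNR matches the requested level within 1 dB", {
  scan <- tiny_linear_scan(snr_db = 20, n_lines = 30L, n_samples = 1200L)
  expect_lt(abs(scan$meta$snr_db_realized - 20), 1)
  snr_direct <- 20 * log10(scan$meta$signal_rms / scan$meta$noise_sigma)
  expect_lt(abs(snr_direct - 20), 1)
})

test_that("simulation is deterministic in the seed", {
  a <- tiny_linear_scan(seed = 11L, n_lines = 4L, n_samples = 600L)
  b <- tiny_linear_scan(seed = 11L, n_lines = 4L, n_samples = 600L)
  expect_identical(a$pa, b$pa)
  expect_identical(a$us, b$us)
  pr <- acquisition_params(scan_mode = "rotational")
  s1 <- simulate_rotational_scan(
    phantom_spec("spiral", seed = 3L, n_lines = 40L, n_samples = 900L), pr)
  s2 <- simulate_rotational_scan(
    phantom_spec("spiral", seed = 3L, n_lines = 40L, n_samples = 900L), pr)
  expect_identical(s1$pa, s2$pa)
})

test_that("rotational default spans a full revolution of 1000 A-lines", {
  pr <- acquisition_params(scan_mode = "rotational")
  spec <- phantom_spec("lumen", flow_speed = 0, snr_db = Inf,
                       n_samples = 700L, seed = 2L)
  scan <- simulate_rotational_scan(spec, pr)
  expect_identical(ncol(scan$pa), 1000L)
})

test_that("constant-radius lumen has constant surface arrival; interface echo sits at the geometric depth", {
  pr <- acquisition_params(scan_mode = "rotational")
  spec <- phantom_spec("lumen", flow_speed = 0, snr_db = Inf,
                       n_samples = 700L, n_lines = 30L, seed = 2L)
  scan <- simulate_rotational_scan(spec, pr)
  arr <- scan$ground_truth$surface_arrival
  expect_equal(max(arr) - min(arr), 0)
  # echo peak within half a pulse length of the mapped radius
  k_geom <- 1 + (7e-3 - pr$probe_offset) * 2 * pr$fs / pr$c
  expect_lt(abs(which.max(abs(scan$us[, 1])) - k_geom), 17)
})

test_that("helix-tangent geometry yields the designed spiral flow angle", {
  # pitch angle 60 deg, tilt solving sin(tilt)*sin(60) = cos(60) -> 60 deg
  r <- 7.8e-3
  pitch <- 2 * pi * r * tan(pi / 3)
  tilt <- asin(0.5 / sin(pi / 3)) * 180 / pi
  expect_equal(helix_beam_angle(pitch, r, tilt), 60, tolerance = 1e-6)

  pr <- acquisition_params(scan_mode = "rotational")
  spec <- phantom_spec("spiral", flow_speed = 2e-3, spiral_pitch = pitch,
                       probe_tilt = tilt, snr_db = Inf, surface_radius = 7e-3,
                       n_samples = 900L, n_lines = 30L, seed = 5L)
  scan <- simulate_rotational_scan(spec, pr)
  expect_true(all(abs(scan$ground_truth$flow_angle - 60) < 0.5))
})

test_that("noiseless plug flow advances by v*cos(theta)/Vres interpolated samples", {
  p <- acquisition_params(scan_mode = "stationary")
  cfg <- doppler_config(subsample_refine = TRUE)
  v <- 4.2e-3
  scan <- tiny_linear_scan(flow_speed = v, snr_db = Inf, n_lines = 6L)
  up <- upsample_axial(bandpass(scan$pa, p, cfg), cfg$nres)
  vm <- correlate_adjacent(up, NULL, cfg)
  band <- which(scan$ground_truth$true_speed[, 1] > 0)
  wc_orig <- (vm$window_centers - 1) / cfg$nres + 1
  sel <- wc_orig > min(band) + 15 & wc_orig < max(band) - 15
  true_shift <- v * cos(pi / 3) / velocity_resolution(p, cfg$nres)
  expect_equal(median(vm$pshift[sel, ], na.rm = TRUE), true_shift,
               tolerance = 0.05)
})

test_that("near-perpendicular flow geometry warns as uncorrectable", {
  pr <- acquisition_params(scan_mode = "rotational")
  spec <- phantom_spec("spiral", flow_speed = 2e-3, beam_to_flow_angle = 80,
                       snr_db = Inf, n_samples = 900L, n_lines = 20L,
                       seed = 4L)
  expect_warning(simulate_rotational_scan(spec, pr), "70 deg")
})
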