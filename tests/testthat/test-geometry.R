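pr <- acquisition_params(scan_mode = "rotational")
cfg0 <- doppler_config()

test_that("rising-edge detection finds a strong echo at its onset", {
  set.seed(9)
  n <- 1500
  noise_sd <- 0.01
  fr <- matrix(rnorm(3 * n, 0, noise_sd), n, 3)
  pl <- make_pulse()
  amp <- noise_sd * 10^(40 / 20)                  # 40 dB above the floor
  onset <- 500
  rows <- onset:(onset + length(pl) - 1)
  fr[rows, 1:2] <- fr[rows, 1:2] + amp * pl       # line 3 stays pure noise
  prof <- suppressWarnings(detect_surface(fr, pr, cfg0))
  expect_true(all(prof$valid[1:2]))
  expect_false(prof$valid[3])                     # all-noise line invalid
  # threshold-crossing oracle on the same waveform
  env <- envelope(fr)
  thr <- noise_floor(env) * 10^(cfg0$toa_threshold_db / 20)
  for (i in 1:2) {
    expect_identical(prof$arrival[i], as.numeric(which(env[, i] >= thr)[1]))
    expect_gte(prof$arrival[i], onset - 5)
    expect_lte(prof$arrival[i], onset + 17)       # within the rise
  }
})

test_that("outlier rejection replaces spikes and is circularly equivariant", {
  n <- 120
  smooth <- 400 + 20 * sin(2 * pi * (0:(n - 1)) / n)
  prof <- corrdop:::new_surface_profile(smooth, rep(TRUE, n), 2000L)
  expect_equal(reject_outliers(prof, pr)$arrival, smooth)

  spiked <- rep(350, n); spiked[40] <- 550
  profs <- corrdop:::new_surface_profile(spiked, rep(TRUE, n), 2000L)
  out <- reject_outliers(profs, pr)
  expect_equal(out$arrival, rep(350, n))
  expect_true(out$interpolated[40])

  # rotating the lines rotates the output identically
  k <- 17
  rot <- c(smooth[-(1:k)], smooth[1:k]) + rep(c(0, 3), length.out = n)
  profr <- corrdop:::new_surface_profile(rot, rep(TRUE, n), 2000L)
  unrot <- corrdop:::new_surface_profile(
    c(rot[(n - k + 1):n], rot[1:(n - k)]), rep(TRUE, n), 2000L)
  a <- reject_outliers(profr, pr)$arrival
  b <- reject_outliers(unrot, pr)$arrival
  expect_equal(a, c(b[(k + 1):n], b[1:k]))

  allbad <- corrdop:::new_surface_profile(rep(NA_real_, n), rep(FALSE, n), 2000L)
  expect_error(reject_outliers(allbad, pr), "no surface")
})

test_that("alignment shifts lines to a common arrival and back-shift inverts it", {
  fr <- matrix(0, 300, 2)
  fr[100, 1] <- 1; fr[110, 2] <- 1
  prof <- corrdop:::new_surface_profile(c(100, 110), c(TRUE, TRUE), 300L)
  al <- align_to_surface(fr, prof)
  expect_identical(al$shifts, c(5L, -5L))
  expect_equal(which(al$frame[, 1] == 1), 105)
  expect_equal(which(al$frame[, 2] == 1), 105)

  # constant profile: no-op
  profc <- corrdop:::new_surface_profile(c(80, 80), c(TRUE, TRUE), 300L)
  alc <- align_to_surface(fr, profc)
  expect_identical(alc$frame, fr)
  expect_identical(alc$shifts, c(0L, 0L))

  # window centers return to original coordinates
  vm <- corrdop:::new_velocity_map(
    pshift = matrix(0, 3, 1), rho = matrix(1, 3, 1),
    valid = matrix(TRUE, 3, 1), window_centers = c(90L, 150L, 210L), nres = 3L)
  bs <- backshift(vm, al$shifts)
  expect_equal(bs$window_centers_orig[, 1], c(90, 150, 210) - 3 * 5)
  bs0 <- backshift(vm, c(0L, 0L))
  expect_equal(bs0$window_centers_orig[, 1], c(90, 150, 210))

  fr4 <- matrix(0, 300, 4)
  prof_far <- corrdop:::new_surface_profile(c(10, 10, 10, 290), rep(TRUE, 4), 300L)
  expect_error(align_to_surface(fr4, prof_far), "n_samples/2")
})

test_that("chord angles reproduce the planar-trig solutions and the cap", {
  # constant radius: isosceles chord angle (180 - dphi)/2 = 89.82 -> capped at 70
  n <- 50
  arr <- rep(500, n)
  prof <- corrdop:::new_surface_profile(arr, rep(TRUE, n), 3000L)
  prof <- estimate_angles(prof, pr, cfg0)
  expect_equal(prof$theta_raw[2], (180 - 0.36) / 2, tolerance = 1e-6)
  expect_true(all(prof$theta == 70))

  # r 10 -> 10.1 mm over one 0.36 deg step: theta ~ 32.08 deg
  r1 <- 10e-3; r2 <- 10.1e-3
  k1 <- 1 + (r1 - pr$probe_offset) * 2 * pr$fs / pr$c
  k2 <- 1 + (r2 - pr$probe_offset) * 2 * pr$fs / pr$c
  prof2 <- corrdop:::new_surface_profile(c(k1, k2, k2), rep(TRUE, 3), 6000L)
  prof2 <- estimate_angles(prof2, pr, cfg0)
  expect_equal(prof2$theta[2], 32.08, tolerance = 0.05)

  # law-of-sines identity of the exact solution, 1e-9 relative
  set.seed(10)
  arr3 <- 900 + cumsum(rnorm(40, 0, 15))
  prof3 <- corrdop:::new_surface_profile(arr3, rep(TRUE, 40), 6000L)
  prof3 <- estimate_angles(prof3, pr, cfg0)
  r <- corrdop:::radius_of_sample(prof3$arrival, pr)
  dphi <- pr$line_angle_step
  for (i in 2:40) {
    th <- prof3$theta_raw[i]
    lhs <- r[i - 1] / sin(th * pi / 180)
    rhs <- r[i] / sin((180 - dphi - th) * pi / 180)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-9)
  }

  # recursive mode tracks the exact mode on smooth profiles
  arr4 <- 900 + 40 * sin(2 * pi * (0:99) / 100)
  prof4 <- corrdop:::new_surface_profile(arr4, rep(TRUE, 100), 6000L)
  ex <- estimate_angles(prof4, pr, cfg0, mode = "exact")$theta
  rec <- estimate_angles(prof4, pr, cfg0, mode = "recursive")$theta
  expect_lt(max(abs(ex - rec)), 2)
})

test_that("surface slope recovers a designed 45 degree flow angle", {
  # exponential arc r = r0 exp(phi): dr/(r dphi) = 1 -> theta = 45 deg
  spec <- phantom_spec("lumen", flow_speed = 0, snr_db = Inf,
                       lumen_radius_fn = function(phi_deg)
                         6e-3 * exp(phi_deg * pi / 180),
                       n_samples = 3000L, n_lines = 100L, seed = 3L)
  scan <- simulate_rotational_scan(spec, pr)
  expect_equal(mean(scan$ground_truth$flow_angle[5:95]), 45, tolerance = 0.5)
  us_f <- bandpass(scan$us, pr, cfg0)
  prof <- suppressWarnings(detect_surface(us_f, pr, cfg0))
  prof <- estimate_angles(prof, pr, cfg0)
  expect_equal(median(prof$theta[10:90]), 45, tolerance = 2)
})

test_that("compensation applies the capped cosine factor", {
  vm <- corrdop:::new_velocity_map(
    pshift = matrix(1, 2, 3), rho = matrix(1, 2, 3),
    valid = matrix(TRUE, 2, 3), window_centers = c(30L, 60L), nres = 3L,
    vc = matrix(1e-3, 2, 3))
  expect_equal(compensate(vm, 60, cfg0)$v[1, 1], 2e-3)
  expect_equal(compensate(vm, 0, cfg0)$v, vm$vc)
  v80 <- compensate(vm, 80, cfg0)
  expect_equal(v80$v[1, 1], 1e-3 / cos(70 * pi / 180), tolerance = 1e-9)
  expect_equal(v80$v[1, 1], 2.9238044e-3, tolerance = 1e-6)
  expect_error(compensate(vm, 95, cfg0), "theta")
  expect_error(compensate(vm, -5, cfg0), "theta")

  # factor bounded in [1, 1/cos(cap)] and monotone below the cap
  angles <- seq(0, 89, by = 1)
  facs <- vapply(angles, function(a) compensate(vm, a, cfg0)$v[1, 1] / 1e-3,
                 numeric(1))
  expect_true(all(facs >= 1 - 1e-12 & facs <= 1 / cos(70 * pi / 180) + 1e-12))
  expect_true(all(diff(facs[angles <= 70]) > 0))
})

test_that("polar warping preserves values and annulus geometry", {
  n <- 400; L <- 1000
  img <- matrix(3.5, n, L)
  pol <- to_polar(img, pr, out_px = 201L)
  expect_true(all(abs(pol[!is.na(pol)] - 3.5) < 1e-9))

  # finite pixel count ~ annulus area fraction of the bounding square
  rmax <- corrdop:::radius_of_sample(n, pr)
  r0 <- pr$probe_offset
  expected <- pi * (rmax^2 - r0^2) / (2 * rmax)^2 * 201^2
  expect_lt(abs(sum(!is.na(pol)) - expected) / expected, 0.02)

  # a bright blob at line ~1 maps to azimuth ~0 at its radius (the raster
  # pixel pitch is coarser than the axial sample pitch, so the blob spans a
  # few samples/lines to guarantee a pixel lands on it)
  img2 <- matrix(0, n, L)
  img2[190:210, c(999:1000, 1:3)] <- 100
  pol2 <- to_polar(img2, pr, out_px = 401L)
  pk <- which(pol2 == max(pol2, na.rm = TRUE), arr.ind = TRUE)[1, ]
  ctr <- (401 + 1) / 2
  px_m <- 2 * rmax / 400
  r_pk <- sqrt((pk[1] - ctr)^2 + (pk[2] - ctr)^2) * px_m
  expect_lt(abs(r_pk - corrdop:::radius_of_sample(200, pr)), 3 * px_m)
  az <- atan2(pk[2] - ctr, pk[1] - ctr) * 180 / pi
  expect_lt(abs(az), 3)
})

test_that("rotational lumen with superficial flow recovers the compensated speed end-to-end", {
  cfg <- doppler_config(subsample_refine = TRUE)
  # arc with dr/(r dphi) = tan(30 deg): surface-tangent flow at 60 deg to beam
  rfn <- function(phi_deg) 5.8e-3 * exp(tan(30 * pi / 180) * phi_deg * pi / 180)
  spec <- phantom_spec("lumen", flow_speed = 2e-3, lumen_radius_fn = rfn,
                       snr_db = 20, n_samples = 3000L, n_lines = 200L,
                       seed = 5L)
  scan <- simulate_rotational_scan(spec, pr)
  expect_equal(mean(scan$ground_truth$flow_angle[20:180]), 60, tolerance = 0.1)
  res <- process_scan(scan, cfg, fixed_angle = NULL, align = TRUE)
  interior <- 20:180                       # away from the arc's wrap seam
  expect_equal(median(res$profile$theta[interior]), 60, tolerance = 2)
  vals <- res$vmap$v[, interior][res$vmap$valid[, interior]]
  expect_equal(mean(vals, na.rm = TRUE), 2e-3, tolerance = 0.2)
})
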