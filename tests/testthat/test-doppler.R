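p0 <- acquisition_params()

test_that("velocity resolution follows the closed form", {
  expect_identical(velocity_resolution(p0, 3), 1540 / 2 * 1000 / (180e6 * 3))
  expect_equal(1e3 * velocity_resolution(p0, 3), 1.425926, tolerance = 1e-6)
  expect_equal(velocity_resolution(p0, 1), 4.277778e-3, tolerance = 1e-6)
  p2 <- acquisition_params(fs = 360e6)
  expect_equal(velocity_resolution(p2, 3), velocity_resolution(p0, 3) / 2)
  expect_error(velocity_resolution(p0, 0), "nres")
})

test_that("identical adjacent lines give zero shift and unit correlation", {
  x <- bandlimited_noise(900, 1, seed = 4)
  fr <- cbind(x, x, x)
  vm <- correlate_adjacent(fr, NULL, doppler_config())
  expect_true(all(vm$valid))
  expect_true(all(vm$pshift == 0))
  expect_true(all(vm$rho > 1 - 1e-9))
})

test_that("a known integer shift is recovered exactly with high correlation", {
  x <- bandlimited_noise(1200, 1, seed = 5)
  adv <- c(x[-(1:2)], x[1:2])          # content arrives 2 samples earlier
  vm <- correlate_adjacent(cbind(x, adv), NULL, doppler_config())
  interior <- 3:(nrow(vm$pshift) - 3)
  expect_true(all(vm$pshift[interior, 1] == 2))
  expect_true(all(vm$rho[interior, 1] >= 0.999))

  # antisymmetry: swapping the lines negates the shift
  vm2 <- correlate_adjacent(cbind(adv, x), NULL, doppler_config())
  expect_true(all(vm2$pshift[interior, 1] == -2))
})

test_that("lag search matches the brute-force oracle on random windows", {
  cfg <- doppler_config(window_hop = 10L)
  checked <- 0L
  for (s in 1:4) {
    fr <- bandlimited_noise(1500, 2, seed = 100 + s)
    fr[, 2] <- fr[, 2] + 0.3 * c(fr[-(1:3), 1], fr[1:3, 1])  # partial coherence
    vm <- correlate_adjacent(fr, NULL, cfg)
    for (w in seq_along(vm$window_centers)) {
      exp_lag <- oracle_lag(fr[, 1], fr[, 2], vm$window_centers[w],
                            cfg$window_len, cfg$max_lag)
      expect_identical(vm$pshift[w, 1], as.numeric(exp_lag))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 100L)
})

test_that("tied correlation maxima resolve to the smallest then non-negative lag", {
  pat <- rep(c(1, 5, 2, 8, 3, 7), length.out = 600)   # period 6, exact sums
  vm <- correlate_adjacent(cbind(pat, pat), NULL, doppler_config())
  expect_true(all(vm$pshift == 0))                    # ties at 0, ±6, ±12

  rot3 <- c(pat[-(1:3)], pat[1:3])                    # true lag 3; tie with -3
  vm3 <- correlate_adjacent(cbind(pat, rot3), NULL, doppler_config())
  interior <- 5:(nrow(vm3$pshift) - 5)
  expect_true(all(vm3$pshift[interior, 1] == 3))
})

test_that("mask contract: windows touching masked samples are invalid", {
  x <- bandlimited_noise(900, 3, seed = 6)
  mask <- matrix(TRUE, 900, 3)
  mask[450, 2] <- FALSE
  vm <- correlate_adjacent(x, mask, doppler_config())
  touching <- abs(vm$window_centers - 450) <= 12
  expect_true(all(!vm$valid[touching, ]))
  expect_true(all(vm$valid[!touching, ]))
  all_off <- correlate_adjacent(x, matrix(FALSE, 900, 3), doppler_config())
  expect_identical(sum(all_off$valid), 0L)
})

test_that("correlation gating keeps high-rho windows only", {
  x <- bandlimited_noise(900, 2, seed = 8)
  vm <- correlate_adjacent(x, NULL, doppler_config())
  expect_identical(gate(vm, 0)$valid, vm$valid)
  expect_identical(sum(gate(vm, 1 + 1e-9)$valid), 0L)
})

test_that("shift-to-velocity conversion multiplies by the resolution", {
  vm <- corrdop:::new_velocity_map(
    pshift = matrix(c(3, 0, 1), 3, 1), rho = matrix(0.9, 3, 1),
    valid = matrix(c(TRUE, TRUE, FALSE), 3, 1),
    window_centers = c(10L, 20L, 30L), nres = 3L)
  vres <- 1.425926e-3
  out <- to_velocity(vm, vres)
  expect_equal(out$vc[1, 1], 4.277778e-3, tolerance = 1e-6)
  expect_identical(out$vc[2, 1], 0)
  expect_true(is.na(out$vc[3, 1]))
  expect_error(to_velocity(vm, -1), "vres")
})

test_that("ROI averaging pools valid windows over line-pair blocks", {
  nw <- 4L; np <- 10L
  v0 <- 2e-3
  vc <- matrix(v0, nw, np)
  vc[, seq(2, np, by = 2)] <- 0                     # alternating 0 / 2 v
  vm <- corrdop:::new_velocity_map(
    pshift = vc / 1e-3, rho = matrix(0.9, nw, np),
    valid = matrix(TRUE, nw, np), window_centers = 1:nw * 10L, nres = 3L,
    vc = vc)
  out <- roi_average(vm, 10L)
  expect_identical(ncol(out$vc), 1L)
  expect_equal(out$vc[, 1], rep(v0 / 2, nw))        # block mean = v

  # roi_lines = 1 is the identity on valid entries
  out1 <- roi_average(vm, 1L)
  expect_equal(out1$vc, vc)

  # constant field: every block mean equals the constant
  vmc <- vm; vmc$vc <- matrix(v0, nw, np)
  expect_true(all(roi_average(vmc, 4L)$vc == v0))

  # partial-block rule: 10 pairs, roi 4 -> blocks 4, 4 and remainder 2 = roi/2 kept
  expect_identical(ncol(roi_average(vm, 4L)$vc), 3L)
  # 10 pairs, roi 7 -> one full block plus remainder 3 >= 3.5? no -> dropped
  expect_identical(ncol(roi_average(vm, 7L)$vc), 1L)
  # 10 pairs, roi 6 -> remainder 4 >= 3 kept
  expect_identical(ncol(roi_average(vm, 6L)$vc), 2L)

  # validity rule: a block with <10% valid members is invalid
  vmi <- vm
  vmi$valid[1, ] <- FALSE
  vmi$vc[1, ] <- NA_real_
  out_i <- roi_average(vmi, 10L)
  expect_false(out_i$valid[1, 1])
})

test_that("noise-only frames pass almost no windows through default gating", {
  p <- acquisition_params(scan_mode = "stationary")
  cfg <- doppler_config()
  fracs <- vapply(1:5, function(s) {
    set.seed(s)
    raw <- matrix(rnorm(1600 * 12), 1600, 12)
    fil <- bandpass(raw, p, cfg)
    fl <- noise_floor(fil)
    mask <- amplitude_mask(fil, fl, cfg$noise_factor)
    up <- upsample_axial(fil, cfg$nres)
    vm <- gate(correlate_adjacent(up, corrdop:::upsample_mask(mask, cfg$nres),
                                  cfg), cfg$rho_min)
    mean(vm$valid)
  }, numeric(1))
  expect_true(all(fracs <= 0.01))
})
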