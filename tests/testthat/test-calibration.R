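test_that("camera background subtraction scales with exposure", {
  counts <- array(100, c(4, 4, 3))
  st <- flim_stack(counts, 1:3 * 1000, integration_ms = 500,
                   n_accumulations = 2)
  bg <- camera_background(matrix(25, 4, 4), integration_ms = 250,
                          n_accumulations = 1)
  # data at 4x the exposure of the background: subtract 4x the offset
  out <- subtract_camera_background(st, bg)
  expect_true(all(out$counts == 0))
  # matched settings: plain subtraction; zero background is the identity
  st2 <- flim_stack(counts, 1:3 * 1000)
  expect_true(all(subtract_camera_background(
    st2, camera_background(matrix(100, 4, 4)))$counts == 0))
  expect_identical(subtract_camera_background(
    st2, camera_background(matrix(0, 4, 4)))$counts, st2$counts)
  expect_error(subtract_camera_background(
    st2, camera_background(matrix(1, 2, 2))), "shape")
})

test_that("TVB model captures the medium decay and spatial intensity", {
  d <- 1:5 * 1000
  # spatially uniform medium: intensity map is exactly 1
  uni <- flim_stack(array(rep(c(10, 6, 4, 2, 1), each = 36), c(6, 6, 5)), d)
  tvb <- create_tvb(uni)
  expect_true(all(abs(tvb$intensity_map - 1) < 1e-12))
  expect_equal(tvb$profile$counts, c(10, 6, 4, 2, 1))
  # doubled counts in the left half: map is 4/3 left, 2/3 right
  counts <- array(rep(c(10, 6, 4, 2, 1), each = 36), c(6, 6, 5))
  counts[, 1:3, ] <- counts[, 1:3, ] * 2
  tvb2 <- create_tvb(flim_stack(counts, d))
  expect_true(all(abs(tvb2$intensity_map[, 1:3] - 4 / 3) < 1e-9))
  expect_true(all(abs(tvb2$intensity_map[, 4:6] - 2 / 3) < 1e-9))
  # photon conservation: profile sums to total medium photons / n_pixels
  expect_equal(sum(tvb2$profile$counts), sum(counts) / 36)
  expect_error(create_tvb(flim_stack(array(0, c(4, 4, 5)), d)), "degenerate")
})

test_that("IRF profile construction normalizes on the fine grid", {
  cfg <- test_config()
  set.seed(21)
  irf_stack <- simulate_irf_stack(cfg)
  bg <- camera_background(matrix(cfg$camera_offset, 16, 16))
  prof <- create_irf_profile(irf_stack, bg)
  expect_equal(sum(prof$amplitudes), 1, tolerance = 1e-9)
  expect_equal(prof$dt, 25)
  # support spans ~ the 4 ns gate width
  nz <- range(which(prof$amplitudes > 0.2 * max(prof$amplitudes)))
  expect_equal(diff(prof$delays[nz]), 4000, tolerance = 0.05 * 4000)
  # delta-like input: all weight lands in the single lit bin
  one <- array(0, c(4, 4, 41))
  one[, , 17] <- 50
  prof1 <- create_irf_profile(flim_stack(one, seq(0, 1000, 25)))
  expect_equal(prof1$amplitudes[17], 1)
  # optional sharpening subdivides bins but preserves each bin mass
  prof5 <- create_irf_profile(flim_stack(one, seq(0, 1000, 25)), refine = 5)
  expect_equal(prof5$dt, 5)
  expect_equal(sum(prof5$amplitudes[81:85]), 1)
  # non-uniform delay grid is rejected
  expect_error(create_irf_profile(flim_stack(array(1, c(4, 4, 3)),
                                             c(0, 25, 80))), "uniform")
})

test_that("shift map recovers spatial timing offsets and stays mean-zero", {
  # scattered excitation light is photon-rich; centroid noise scales as
  # gate_width / sqrt(12 N)
  cfg <- test_config(shift_gradient_ps = 50, photons_irf = 2e5)
  set.seed(22)
  irf_stack <- simulate_irf_stack(cfg)
  bg <- camera_background(matrix(cfg$camera_offset, 16, 16))
  sm <- create_irf_shift_map(irf_stack, bg)
  expect_lt(abs(mean(sm)), 1)
  truth <- sim_shift_cols(cfg)[round(seq(1, cfg$n_col, length.out = 16))]
  truth <- truth - mean(truth)
  expect_lt(sqrt(mean((colMeans(sm) - truth)^2)), 2)
  # spatially uniform IRF: map is ~0 everywhere
  cfg0 <- test_config(shift_gradient_ps = 0, photons_irf = 5e6)
  set.seed(23)
  sm0 <- create_irf_shift_map(simulate_irf_stack(cfg0), bg)
  expect_lt(max(abs(sm0)), 1)
  # adding a constant delay to every pixel leaves the map unchanged
  shifted <- irf_stack
  shifted$gates$delay_ps <- shifted$gates$delay_ps + 100
  sm_shift <- create_irf_shift_map(shifted, bg)
  expect_lt(max(abs(sm_shift - sm)), 1e-6)
})

test_that("t0 estimation recovers known global shifts within 5 ps", {
  for (true_t0 in c(0, 100, -60)) {
    cfg <- test_config(t0_ps = true_t0, shift_gradient_ps = 20)
    set.seed(100 + true_t0)
    irf <- create_irf_profile(simulate_irf_stack(cfg),
                              camera_background(matrix(cfg$camera_offset, 16, 16)))
    dye <- simulate_reference_dye(cfg)
    t0 <- estimate_t0(dye, irf, cfg$reference_lifetime_ps,
                      background = camera_background(
                        matrix(cfg$camera_offset, 16, 16)))
    expect_lt(abs(as.numeric(t0) - true_t0), 5)
  }
})

test_that("t0 estimation is equivariant under data shifts", {
  cfg <- test_config(t0_ps = 0, shift_gradient_ps = 0)
  set.seed(31)
  irf <- create_irf_profile(simulate_irf_stack(cfg),
                            camera_background(matrix(cfg$camera_offset, 16, 16)))
  bg <- camera_background(matrix(cfg$camera_offset, 16, 16))
  base <- estimate_t0(simulate_reference_dye(cfg), irf,
                      cfg$reference_lifetime_ps, background = bg)
  for (delta in c(-200, -50, 50, 200)) {
    cfgd <- test_config(t0_ps = delta, shift_gradient_ps = 0)
    set.seed(31)
    t0d <- estimate_t0(simulate_reference_dye(cfgd), irf,
                       cfg$reference_lifetime_ps, background = bg)
    expect_lt(abs((as.numeric(t0d) - as.numeric(base)) - delta), 5)
  }
})

test_that("peak-delay search is an exhaustive argmax with early tie-break", {
  expect_equal(find_peak_delay(c(3, 3, 3), delays = c(100, 200, 300)), 100)
  set.seed(41)
  y <- rpois(60, 40 * exp(-abs(seq(-3, 3, length.out = 60))))
  d <- seq(0, 5900, 100)
  expect_equal(find_peak_delay(y, delays = d), d[which.max(y)])
  st <- flim_stack(array(rep(c(1, 9, 2), each = 16), c(4, 4, 3)), 1:3 * 1000)
  expect_equal(find_peak_delay(st), 2000)
})

test_that("AutoGate delays are pre-pulse + peak + log-spaced tail", {
  d7 <- autogate_delays(4300, 16000, 7)
  expect_length(d7, 7)
  expect_true(all(diff(d7) > 0))
  expect_lt(d7[1], 4300)
  expect_equal(d7[2], 4300)
  expect_equal(d7[7], 16000)
  d4 <- autogate_delays(4300, 16000, 4)
  expect_length(d4, 4)
  expect_equal(d4[2], 4300)
  # geometric progression of (delay - peak + eps) in the tail
  eps <- (16000 - 4300) / 20
  ratios <- diff(log(d7[-1] - 4300 + eps))
  expect_lt(diff(range(ratios)), 1e-9)
  expect_error(autogate_delays(4300, 4300, 7), "exceed")
  expect_error(autogate_delays(4300, 16000, 3), "4 gates")
})
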