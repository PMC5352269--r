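test_that("zero photon budget produces a pure background field", {
  cfg <- test_config(tvb_photons = 0)
  set.seed(141)
  sim <- simulate_fov(cfg, list(name = "empty", tau1_ps = 1000, photons = 0))
  expect_true(all(sim$stack$counts == cfg$camera_offset))
  expect_true(all(sim$truth$labels == 0))
})

test_that("pre-noise expectations equal the shared forward model exactly", {
  cfg <- test_config()
  d <- cfg$sample_delays
  m <- sim_unit_decay(cfg, d, 3964, 3022, 0.3, shift = 12)
  p <- decay_params(3964, 3022, beta = 0.3, shift_ps = 12)
  conv <- convolve_with_irf(p, sim_true_irf(cfg), d)
  expect_equal(m, conv / sum(conv), tolerance = 1e-12)
})

test_that("quadrature forward model agrees with but is independent of the fitter's", {
  cfg_q <- test_config(independent_forward = TRUE)
  cfg_s <- test_config(independent_forward = FALSE)
  d <- cfg_q$sample_delays
  mq <- sim_unit_decay(cfg_q, d, 2430)
  ms <- sim_unit_decay(cfg_s, d, 2430)
  expect_lt(max(abs(mq - ms)), 2e-4)   # same physics
  expect_false(isTRUE(all.equal(mq, ms, tolerance = 1e-12)))  # distinct path
})

test_that("Poisson law: the mean of repeated fields approaches the expectation", {
  cfg <- test_config(n_row = 8, n_col = 8, tvb_photons = 0, n_cells = 2,
                     shift_gradient_ps = 0)
  d <- cfg$sample_delays
  m <- sim_unit_decay(cfg, d, 3000, shift = cfg$t0_ps)
  expected <- 800 * m
  set.seed(142)
  draws <- replicate(200, rpois(length(d), expected))
  avg <- rowMeans(draws)
  expect_true(all(abs(avg - expected) <= 3 * sqrt(pmax(expected, 0.5) / 200)))
})

test_that("simulated plates are byte-identical under a fixed seed", {
  cfg <- test_config(seed = 7)
  p1 <- simulate_construct_plate(cfg, truths = c(mTq5A = 4008),
                                 n_wells_per_condition = 1, n_fov = 2)
  p2 <- simulate_construct_plate(cfg, truths = c(mTq5A = 4008),
                                 n_wells_per_condition = 1, n_fov = 2)
  expect_identical(p1$fovs$stack[[1]]$counts, p2$fovs$stack[[1]]$counts)
  expect_identical(p1$irf_stack$counts, p2$irf_stack$counts)
  expect_identical(p1$dye_stack$counts, p2$dye_stack$counts)
})

test_that("the construct-plate preset carries the four per-well truths", {
  cfg <- test_config(seed = 8)
  plate <- simulate_construct_plate(cfg, n_wells_per_condition = 1, n_fov = 1)
  tr <- dplyr::arrange(plate$truth, condition)
  expect_equal(setNames(tr$tau1_ps, tr$condition),
               c(mTq17V = 3004, mTq32V = 3133, mTq5A = 4008, mTq5V = 2717))
  expect_true(all(c("empty", "medium_only", "unlabeled_cells") %in%
                    plate$fovs$role))
  expect_s3_class(plate$background, "camera_background")
})

test_that("the dose-plate preset lifetimes follow the one-site logistic", {
  cfg <- test_config(seed = 9, n_row = 8, n_col = 8, n_cells = 2)
  plate <- simulate_dose_plate(cfg, ic50_M = 38e-9, n_fov = 1)
  doses <- 10^seq(-9, -5, length.out = 9)
  tr <- plate$truth[grepl("_d", plate$truth$condition), ]
  tr <- tr[order(tr$condition), ]
  expect_equal(tr$tau1_ps, 2600 + 300 * doses / (doses + 38e-9))
  expect_equal(plate$truth$tau1_ps[plate$truth$condition == "positive"], 2900)
  expect_equal(plate$truth$tau1_ps[plate$truth$condition == "negative"], 2600)
})

test_that("simulated IRF stacks have the configured gate-width support", {
  cfg <- test_config(shift_gradient_ps = 0)
  set.seed(151)
  irf_stack <- simulate_irf_stack(cfg)
  prof <- create_irf_profile(irf_stack,
                             camera_background(matrix(cfg$camera_offset,
                                                      16, 16)))
  nz <- range(which(prof$amplitudes > 0.2 * max(prof$amplitudes)))
  expect_lt(abs(diff(prof$delays[nz]) - cfg$gate_width_ps), 250)
})

test_that("the reference-dye loop closes through calibration", {
  for (t0_true in c(0, 100)) {
    cfg <- test_config(t0_ps = t0_true)
    set.seed(160 + t0_true)
    bg <- camera_background(matrix(cfg$camera_offset, 16, 16))
    prof <- create_irf_profile(simulate_irf_stack(cfg), bg)
    t0 <- estimate_t0(simulate_reference_dye(cfg), prof,
                      cfg$reference_lifetime_ps, background = bg)
    expect_lt(abs(as.numeric(t0) - t0_true), 5)
  }
})
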