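# shared-lifetime (global) fitting via variable projection

test_that("a single-pixel image reduces the global fit to a pixel-wise fit", {
  cfg <- test_config(n_row = 1, n_col = 1, shift_gradient_ps = 0,
                     tvb_photons = 0, camera_offset = 0)
  cal <- true_cal(cfg)
  d <- cfg$sample_delays
  set.seed(101)
  y <- rpois(length(d), 4000 * sim_unit_decay(cfg, d, 3200))
  st <- flim_stack(array(y, c(1, 1, length(d))), d, well = "A1", fov = 1L)
  opts <- fit_options(weighting = "none", threshold = 0,
                      bias_correction = FALSE)
  g <- fit_global(st, cal, "mono", opts)
  p <- fit_pixelwise(st, cal, opts)
  expect_lt(abs(g$params$estimate[1] - p$pixels$tau_ps[1]), 1)
})

test_that("noiseless global fits recover the shared lifetimes exactly", {
  cfg <- test_config(n_row = 8, n_col = 8, shift_gradient_ps = 0,
                     tvb_photons = 0, camera_offset = 0)
  cal <- true_cal(cfg)
  d <- cfg$sample_delays
  betas <- seq(0.1, 0.9, length.out = 8)
  mu <- array(0, c(8, 8, length(d)))
  for (cc in 1:8)
    mu[, cc, ] <- rep(5000 * sim_unit_decay(cfg, d, 3964, 3022, betas[cc]),
                      each = 8)
  st <- flim_stack(mu, d, well = "A1", fov = 1L)
  g <- fit_global(st, cal, "biexp",
                  fit_options(weighting = "none", threshold = 0,
                              bias_correction = FALSE),
                  fit_offset = FALSE)
  expect_lt(abs(g$params$estimate[1] - 3964), 2)
  expect_lt(abs(g$params$estimate[2] - 3022), 2)
  truth <- betas[g$pixels$col]
  expect_lt(max(abs(g$pixels$beta - truth)), 0.01)
})

test_that("global fit optimum matches joint brute-force NLLS on small instances", {
  skip_if_not_installed("minpack.lm")
  cfg <- test_config(n_row = 8, n_col = 8, shift_gradient_ps = 0,
                     tvb_photons = 0, camera_offset = 0)
  cal <- true_cal(cfg)
  d <- cfg$sample_delays
  irf <- cal$irf
  set.seed(111)
  stacks <- lapply(1:2, function(k) {
    betas <- runif(8, 0.1, 0.8)
    mu <- array(0, c(8, 8, length(d)))
    for (cc in 1:8)
      mu[, cc, ] <- rep(3000 * sim_unit_decay(cfg, d, 3964, 3022, betas[cc]),
                        each = 8)
    flim_stack(array(rpois(length(mu), mu), dim(mu)), d,
               well = "A1", fov = k)
  })
  opts <- fit_options(weighting = "none", threshold = 0,
                      bias_correction = FALSE)
  g <- fit_global(stacks, cal, "biexp", opts, fit_offset = FALSE)

  # joint NLLS over (log tau1, log tau2, all per-pixel amplitudes)
  ymat <- do.call(cbind, lapply(stacks, function(st)
    t(matrix(st$counts, ncol = length(d)))))
  npx <- ncol(ymat)
  resid_fn <- function(p) {
    taus <- exp(p[1:2])
    b1 <- convolve_with_irf(decay_params(taus[1]), irf, d)
    b2 <- convolve_with_irf(decay_params(taus[2]), irf, d)
    A1 <- p[2 + seq_len(npx)]
    A2 <- p[2 + npx + seq_len(npx)]
    as.vector(ymat - outer(b1, A1) - outer(b2, A2))
  }
  start_amp <- colSums(ymat) / 2 / sum(convolve_with_irf(
    decay_params(3500), irf, d))
  jf <- minpack.lm::nls.lm(
    par = c(log(c(4200, 2800)), rep(start_amp, 2)),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 400, ptol = 1e-12,
                                         ftol = 1e-12))
  chisq_joint <- sum(jf$fvec^2)
  expect_lt(abs(g$objective - chisq_joint) / chisq_joint, 1e-6)
})

test_that("global fits are deterministic across repeated runs", {
  cfg <- test_config(n_row = 6, n_col = 6, shift_gradient_ps = 0,
                     tvb_photons = 0, camera_offset = 0)
  cal <- true_cal(cfg)
  d <- cfg$sample_delays
  set.seed(121)
  mu <- array(rep(2000 * sim_unit_decay(cfg, d, 3964, 3022, 0.4), each = 36),
              c(6, 6, length(d)))
  st <- flim_stack(array(rpois(length(mu), mu), dim(mu)), d,
                   well = "A1", fov = 1L)
  opts <- fit_options(threshold = 0, bias_correction = FALSE)
  g1 <- fit_global(st, cal, "biexp", opts, fit_offset = FALSE)
  g2 <- fit_global(st, cal, "biexp", opts, fit_offset = FALSE)
  expect_identical(g1$params, g2$params)
  expect_identical(g1$pixels, g2$pixels)
})
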