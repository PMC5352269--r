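fake_pixels <- function(df) {
  structure(list(type = "pixel", model = list(n_exp = 1), pixels = df),
            class = "flim_fit")
}

test_that("well aggregation pools pixels and uses the FOV as replicate unit", {
  # single uniform FOV: mean = value, no spread
  one <- fake_pixels(tibble::tibble(well = "A1", fov = 1L,
                                    tau_ps = rep(4008, 20)))
  a1 <- aggregate_plate(one, level = "well")
  expect_equal(a1$mean_tau_ps, 4008)
  expect_equal(a1$n_fov, 1)
  # two FOVs with means 4000 and 4016: between-FOV STD = 8 * sqrt(2)
  two <- fake_pixels(tibble::tibble(
    well = "A1", fov = rep(1:2, each = 10),
    tau_ps = rep(c(4000, 4016), each = 10)))
  a2 <- aggregate_plate(two, level = "well")
  expect_equal(a2$std, 8 * sqrt(2))
  expect_equal(a2$err, 8)
  expect_equal(a2$mean_tau_ps, 4008)
  # hand-computed pooled mean with unequal FOV sizes (pixel-pooled, exact)
  mix <- fake_pixels(tibble::tibble(
    well = "B2", fov = c(1L, 1L, 1L, 2L),
    tau_ps = c(3000, 3100, 3200, 2700)))
  expect_equal(aggregate_plate(mix, level = "well")$mean_tau_ps, 3000)
})

test_that("aggregation is invariant under FOV relabeling and supports levels", {
  set.seed(131)
  px <- tibble::tibble(well = rep(c("A1", "B1"), each = 40),
                       fov = rep(rep(1:2, each = 20), 2),
                       tau_ps = rnorm(80, 4000, 30))
  base <- aggregate_plate(fake_pixels(px), level = "well")
  perm <- px[sample(nrow(px)), ]
  perm$fov <- ifelse(perm$fov == 1L, 2L, 1L)  # relabel FOVs
  again <- aggregate_plate(fake_pixels(perm), level = "well")
  expect_equal(dplyr::arrange(again, well)$mean_tau_ps,
               dplyr::arrange(base, well)$mean_tau_ps)
  expect_equal(dplyr::arrange(again, well)$std,
               dplyr::arrange(base, well)$std)
  # column and condition levels
  ly <- plate_layout(c("A1", "B1"), c("sample", "sample"),
                     condition = c("x", "x"))
  colagg <- aggregate_plate(fake_pixels(px), ly, level = "column")
  expect_equal(nrow(colagg), 1)  # both wells sit in plate column 1
  expect_equal(colagg$n_fov, 4)
  cond <- aggregate_plate(fake_pixels(px), ly, level = "condition")
  expect_equal(cond$mean_tau_ps, mean(px$tau_ps))
})

test_that("Z-prime follows the control-moment formula and its monotonicities", {
  # perfect assay: zero spreads give Z' = 1
  expect_equal(z_prime_moments(3100, 0, 2200, 0)$z_prime, 1)
  # worked arithmetic case
  expect_equal(z_prime_moments(3100, 50, 2200, 100)$z_prime, 0.5)
  # from replicate vectors
  pos <- c(3090, 3110); neg <- c(2150, 2250)
  expect_equal(z_prime(pos, neg)$z_prime,
               1 - 3 * (sd(pos) + sd(neg)) / abs(mean(pos) - mean(neg)))
  # widening spreads strictly decreases Z'; widening separation increases it
  zs <- sapply(c(10, 50, 100), function(s)
    z_prime_moments(3100, s, 2200, s)$z_prime)
  expect_true(all(diff(zs) < 0))
  zsep <- sapply(c(300, 600, 900), function(dmu)
    z_prime_moments(2200 + dmu, 50, 2200, 50)$z_prime)
  expect_true(all(diff(zsep) > 0))
  expect_error(z_prime_moments(3000, 10, 3000, 10), "undefined")
})

test_that("FRET efficiency is the standard lifetime ratio", {
  expect_equal(fret_efficiency(4008, 4008), 0)
  expect_equal(fret_efficiency(2004, 4008), 0.5)
  expect_equal(fret_efficiency(3022, 3964), 1 - 3022 / 3964)
  expect_error(fret_efficiency(4000, 3000), "negative")
})

test_that("dose-response fits recover IC50 with fixed asymptotes and Hill 1", {
  doses <- 10^seq(-9, -5, length.out = 9)
  truth <- 38e-9
  y <- 2600 + 300 * doses / (doses + truth)
  # noiseless recovery < 1%
  dr <- fit_dose_response(tibble::tibble(concentration = doses, response = y),
                          y0 = 2600, yinf = 2900)
  expect_lt(abs(ic50(dr) / truth - 1), 0.01)
  # response at c = IC50 is the asymptote midpoint (closed form)
  mid <- 2600 + 300 * ic50(dr) / (ic50(dr) + ic50(dr))
  expect_equal(mid, (2600 + 2900) / 2)
  # the full 4PL parameter vector is reported with fixed flags
  expect_equal(dr$term, c("ic50_M", "y0", "yinf", "hill"))
  expect_equal(dr$fixed, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(dr$estimate[dr$term == "hill"], 1)
  expect_error(fit_dose_response(
    tibble::tibble(concentration = doses[1:3], response = y[1:3]),
    2600, 2900), "4 distinct")
  expect_error(fit_dose_response(
    tibble::tibble(concentration = doses, response = y), 2600, 2600),
    "distinct")
})

test_that("dose-response recovery holds under plate-level noise (many seeds)", {
  # Fig.-7-style design: 9 doses x 2 replicate wells x 8 FOVs per well,
  # between-FOV noise matched to the construct-plate STDs (~30 ps)
  doses <- 10^seq(-9, -5, length.out = 9)
  truth <- 38e-9
  rel_err <- sapply(1:100, function(seed) {
    set.seed(seed)
    resp <- sapply(doses, function(cc) {
      mu <- 2600 + 300 * cc / (cc + truth)
      mean(rnorm(2 * 8, mu, 30))  # 16 FOV means per dose
    })
    dr <- fit_dose_response(tibble::tibble(concentration = doses,
                                           response = resp),
                            y0 = 2600, yinf = 2900)
    abs(ic50(dr) / truth - 1)
  })
  expect_lt(median(rel_err), 0.10)
  expect_lt(mean(rel_err > 0.20), 0.1)
})

test_that("time courses with constant fraction stay flat and self-consistent", {
  cfg <- test_config(photons_per_pixel = 5e4, shift_gradient_ps = 0,
                     tvb_photons = 0, camera_offset = 0, n_cells = 6,
                     sample_delays = c(1300, 4300, 4919, 6656, 8035,
                                       10391, 16000))
  tc <- simulate_timecourse(cfg, times_s = seq(0, 50, 10),
                            beta_before = 0.35, beta_after = 0.35,
                            step_s = 1e9)
  cal <- true_cal(cfg)
  out <- time_course(tc$stacks, tc$times_s, cal, tc$mask,
                     options = fit_options(threshold = 300))
  expect_equal(nrow(out), 6)
  expect_lt(diff(range(out$mean_beta)), 0.1)
  # internal consistency: tau_mean = (1 - beta) tau1 + beta tau2
  t1 <- attr(out, "tau1_ps"); t2 <- attr(out, "tau2_ps")
  expect_equal(out$mean_tau_ps, (1 - out$mean_beta) * t1 + out$mean_beta * t2,
               tolerance = 1e-6)
  # excluded time points are dropped from the output
  out2 <- time_course(tc$stacks, tc$times_s, cal, tc$mask,
                      exclude_times_s = c(20, 30),
                      options = fit_options(threshold = 300))
  expect_false(any(out2$time_s %in% c(20, 30)))
  expect_equal(nrow(out2), 4)
})
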