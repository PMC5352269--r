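#' Fitting options
#'
#' @param weighting `"mle"` (Poisson maximum likelihood — the deviance is
#'   minimized with the TVB as a known additive baseline; the default, and
#'   essentially bias-free down to hundreds of photons), `"poisson"`
#'   (least squares with model-based `1/max(mu, floor)` weights updated over
#'   `n_reweight` passes) or `"none"` (unweighted least squares, useful for
#'   oracle comparisons).
#' @param threshold pixels whose background-corrected total intensity is at or
#'   below this count are excluded from maps (lifetime accuracy needs
#'   hundreds of photons).
#' @param tau_range search bounds for lifetimes (ps).
#' @param grid_n number of log-spaced grid points bracketing the pixel-wise
#'   variable-projection search (golden-section refinement between the
#'   bracketing neighbours supplies the final precision).
#' @param n_reweight Poisson reweighting passes.
#' @param w_floor weight floor (counts) preventing division blow-ups.
#' @param max_iter outer optimizer iteration cap (binned/global fits).
#' @param bias_correction correct the small-sample curvature bias of
#'   pixel-wise lifetime estimates (about +0.4% at 500 photons for any
#'   least-squares or likelihood estimator) by a per-FOV parametric
#'   bootstrap: synthetic pixels are drawn from the fitted model at the
#'   empirical brightness distribution, refit with the same estimator, and
#'   the measured bias subtracted. Deterministic given `boot_seed`.
#' @param boot_n bootstrap pixels per FOV.
#' @param boot_seed internal RNG seed for the bootstrap (ambient RNG state
#'   is preserved).
#' @return a list of class `fit_options`.
#' @export
fit_options <- function(weighting = c("mle", "poisson", "none"), threshold = 100,
                        tau_range = c(300, 8000), grid_n = 60,
                        n_reweight = 2, w_floor = 1, max_iter = 200,
                        bias_correction = TRUE, boot_n = 3000,
                        boot_seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(threshold >= 0, length(tau_range) == 2, tau_range[1] > 0,
            tau_range[2] > tau_range[1], grid_n >= 10, boot_n >= 100)
  structure(list(weighting = weighting, threshold = threshold,
                 tau_range = tau_range, grid_n = grid_n,
                 n_reweight = n_reweight, w_floor = w_floor,
                 max_iter = max_iter, bias_correction = bias_correction,
                 boot_n = boot_n, boot_seed = boot_seed),
            class = "fit_options")
}

tau_grid_of <- function(options) {
  exp(seq(log(options$tau_range[1]), log(options$tau_range[2]),
          length.out = options$grid_n))
}

fit_mode_of <- function(options) {
  switch(options$weighting, none = 0L, poisson = 1L, mle = 2L)
}

# apply calibration: camera background subtracted from the counts; the TVB
# becomes a known additive baseline (per pixel, per gate) so Poisson
# likelihood fitting can keep the data on the raw count scale. A free offset
# is only fitted when no TVB model is available.
calibrate_stack <- function(stack, calibration) {
  stopifnot(is_flim_stack(stack), inherits(calibration, "flim_calibration"))
  if (!is.null(calibration$background))
    stack <- subtract_camera_background(stack, calibration$background)
  baseline <- array(0, dim(stack$counts))
  fit_offset <- TRUE
  if (!is.null(calibration$tvb)) {
    tvb <- calibration$tvb
    if (!isTRUE(all.equal(tvb$profile$delay_ps, stack$gates$delay_ps)))
      stop("TVB gate set does not match the stack")
    for (g in seq_len(nrow(stack$gates)))
      baseline[, , g] <- tvb$profile$counts[g] * tvb$intensity_map
    fit_offset <- FALSE
  }
  dims <- dim(stack$counts)[1:2]
  shifts <- matrix(calibration$t0, dims[1], dims[2])
  if (!is.null(calibration$shift_map)) {
    if (!identical(dim(calibration$shift_map), dims))
      stop("shift map shape does not match the stack")
    shifts <- shifts + calibration$shift_map
  }
  list(stack = stack, baseline = baseline, fit_offset = fit_offset,
       shifts = shifts)
}

new_flim_fit <- function(type, model, options, ...) {
  structure(c(list(type = type, model = model, options = options), list(...)),
            class = "flim_fit")
}

#' Pixel-wise monoexponential decay fitting
#'
#' Fits every pixel above the intensity threshold independently with the
#' IRF-convolved monoexponential model, using that pixel's IRF time shift
#' (t0 plus the shift-map value). The amplitude (and, when no TVB model was
#' supplied, a constant offset) is solved linearly for each candidate
#' lifetime — a variable-projection search over a log-spaced lifetime grid
#' with golden-section refinement — under the Poisson likelihood (or the
#' selected weighting scheme).
#'
#' @param stacks a [flim_stack()] or list of them.
#' @param calibration a [flim_calibration()].
#' @param options a [fit_options()].
#' @return A `flim_fit` object; `$pixels` is a tibble with one row per fitted
#'   pixel (`well`, `fov`, `row`, `col`, `intensity`, `tau_ps`, `amplitude`,
#'   `offset`, `chisq`, `converged`). Unconverged pixels are flagged, not
#'   dropped.
#' @export
fit_pixelwise <- function(stacks, calibration, options = fit_options()) {
  if (is_flim_stack(stacks)) stacks <- list(stacks)
  grid <- tau_grid_of(options)
  px <- purrr::map_dfr(stacks, function(st) {
    cal <- calibrate_stack(st, calibration)
    tot <- rowSums(cal$stack$counts, dims = 2L)
    sel <- which(tot > options$threshold)
    if (length(sel) == 0) return(tibble::tibble())
    ng <- nrow(st$gates)
    mode <- fit_mode_of(options)
    ymat <- t(matrix(cal$stack$counts, ncol = ng)[sel, , drop = FALSE])
    if (mode == 2L) ymat <- pmax(ymat, 0)
    bmat <- t(matrix(cal$baseline, ncol = ng)[sel, , drop = FALSE])
    irf <- calibration$irf
    res <- cpp_fit_mono_px(ymat, bmat, st$gates$delay_ps,
                           irf_lower_edge(irf), irf$dt, irf$amplitudes,
                           cal$shifts[sel], grid, cal$fit_offset, mode,
                           options$n_reweight, options$w_floor)
    idx <- arrayInd(sel, dim(tot))
    dof <- ng - (2L + cal$fit_offset)
    bias <- 0
    if (isTRUE(options$bias_correction) && sum(res$flag != 1L) >= 50) {
      # decorrelate bootstrap draws between FOVs
      fov_seed <- (options$boot_seed +
                     sum(utf8ToInt(paste0(st$well, "_", st$fov)))) %% .Machine$integer.max
      bias <- boot_tau_bias(res, ymat, bmat, st$gates$delay_ps, irf,
                            cal$shifts[sel], cal$fit_offset, grid, mode,
                            options, fov_seed)
    }
    tibble::tibble(well = st$well, fov = st$fov,
                   row = idx[, 1], col = idx[, 2], intensity = tot[sel],
                   tau_ps = res$tau - bias, amplitude = res$amplitude,
                   offset = res$offset, bias_ps = bias,
                   chisq = res$objective / max(dof, 1),
                   converged = res$flag != 1L, flag = res$flag)
  })
  new_flim_fit("pixel", list(n_exp = 1), options, pixels = px,
               calibration = calibration)
}

# per-FOV parametric-bootstrap estimate of the pixel-wise lifetime bias:
# synthetic pixels at the FOV-mean lifetime with the empirical amplitude /
# offset / baseline / shift distribution, pushed through the same estimator
boot_tau_bias <- function(res, ymat, bmat, delays, irf, shifts, fit_offset,
                          grid, mode, options, seed) {
  ok <- which(res$flag != 1L)
  tau_bar <- mean(res$tau[ok])
  rng <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv()))
  set.seed(seed)
  pick <- sample(ok, options$boot_n, replace = TRUE)
  mu <- matrix(0, nrow(ymat), options$boot_n)
  for (s in unique(shifts[pick])) {
    b <- cpp_conv_basis(tau_bar, delays, irf_lower_edge(irf), irf$dt,
                        irf$amplitudes, s)[, 1]
    j <- which(shifts[pick] == s)
    mu[, j] <- outer(b, res$amplitude[pick[j]]) +
      rep(res$offset[pick[j]], each = length(b)) + bmat[, pick[j]]
  }
  yb <- matrix(rpois(length(mu), pmax(mu, 0)), nrow(mu))
  rb <- cpp_fit_mono_px(yb, bmat[, pick, drop = FALSE], delays,
                        irf_lower_edge(irf), irf$dt, irf$amplitudes,
                        shifts[pick], grid, fit_offset, mode,
                        options$n_reweight, options$w_floor)
  mean(rb$tau[rb$flag != 1L]) - tau_bar
}

#' Globally binned decay fitting
#'
#' Pools the photons of an ROI into a single decay (global binning) and fits
#' the IRF-convolved mono- or double-exponential model. The nonlinear
#' parameters (lifetimes) are optimized with the linear amplitudes and offset
#' profiled out; Poisson weights are refreshed from the model over a few
#' outer passes. Bi-exponential fits start from the monoexponential solution
#' split +/-30% and are relabeled so `tau1 >= tau2` after convergence.
#' Asymptotic standard errors come from the weighted Gauss-Newton
#' approximation at the optimum.
#'
#' @param x a [flim_stack()], or a decay: tibble with `delay_ps`, `counts`
#'   (e.g. from [bin_pixels()]).
#' @param calibration a [flim_calibration()]. When `x` is a pre-binned decay
#'   only the IRF and t0 are used (background/TVB cannot be re-applied).
#' @param model `"mono"` or `"biexp"`.
#' @param mask optional ROI mask; default pools the whole frame.
#' @param options a [fit_options()].
#' @param n_pixels number of pixels pooled (for the degrees-of-freedom and
#'   offset bookkeeping) when `x` is a pre-binned decay.
#' @param fit_offset for a pre-binned decay: whether a free constant offset
#'   is included (set `FALSE` when the background was already removed, e.g.
#'   via a TVB model — with few gates a free offset badly degrades the
#'   conditioning of double-exponential fits).
#' @return A `flim_fit`; `$params` holds estimates and standard errors,
#'   `$fitted` the observed/fitted decay, `$degenerate` flags an
#'   under-determined bi-exponential (lifetimes collapsed or beta at bound).
#' @export
fit_global_binned <- function(x, calibration, model = c("mono", "biexp"),
                              mask = NULL, options = fit_options(),
                              n_pixels = 1, fit_offset = TRUE) {
  model <- match.arg(model)
  shifts <- calibration$t0
  shift_wts <- 1
  if (is_flim_stack(x) || (is.list(x) && is_flim_stack(x[[1]]))) {
    stacks <- if (is_flim_stack(x)) list(x) else x
    if (is.null(mask))
      mask <- matrix(1L, dim(stacks[[1]]$counts)[1],
                     dim(stacks[[1]]$counts)[2])
    n_pixels <- sum(mask > 0)
    ng <- nrow(stacks[[1]]$gates)
    y_pool <- 0
    tot_pool <- 0
    for (st in stacks) {
      cal <- calibrate_stack(st, calibration)
      fit_offset <- cal$fit_offset
      y_pool <- y_pool + bin_pixels(cal$stack, mask)$counts -
        colSums(matrix(cal$baseline, ncol = ng)[mask > 0, , drop = FALSE])
      tot_pool <- tot_pool + rowSums(cal$stack$counts, dims = 2L)[mask > 0]
    }
    dec <- tibble::tibble(delay_ps = stacks[[1]]$gates$delay_ps,
                          counts = y_pool)
    # the binned model averages the convolved basis over the pooled pixels'
    # IRF shifts (intensity-weighted): a single-shift model leaves a
    # systematic residual that can derail close double-exponential fits
    shifts <- calibrate_stack(stacks[[1]], calibration)$shifts[mask > 0]
    shift_wts <- pmax(tot_pool, 0)
    if (sum(shift_wts) <= 0) shift_wts <- rep(1, length(shifts))
    sw <- round(shifts, 1)
    shift_wts <- vapply(split(shift_wts, sw), sum, 0)
    shifts <- as.numeric(names(shift_wts))
    shift_wts <- shift_wts / sum(shift_wts)
  } else dec <- x
  y <- dec$counts
  d <- dec$delay_ps
  if (sum(pmax(y, 0)) < 10 * n_pixels)
    warning("pooled photon count is low; fit may be under-determined")
  irf <- calibration$irf

  basis <- function(tau) {
    b <- 0
    for (i in seq_along(shifts))
      b <- b + shift_wts[i] *
        cpp_conv_basis(tau, d, irf_lower_edge(irf), irf$dt,
                       irf$amplitudes, shifts[i])[, 1]
    b
  }
  design <- function(taus) {
    X <- vapply(taus, basis, numeric(length(d)))
    if (fit_offset) cbind(X, 1) else X
  }
  wls <- function(X, w) stats::lm.wfit(X, y, w)
  rss_of <- function(taus, w) {
    f <- wls(design(taus), w)
    sum(w * f$residuals^2)
  }
  weights_for <- function(mu) {
    if (options$weighting == "none") rep(1, length(y))
    else 1 / pmax(mu, options$w_floor * max(n_pixels, 1))
  }

  # --- mono fit (also the biexp start) ---
  w <- weights_for(y)
  for (pass in seq_len(options$n_reweight + 1)) {
    opt1 <- optimize(function(tt) rss_of(tt, w), options$tau_range, tol = 0.01)
    f1 <- wls(design(opt1$minimum), w)
    if (pass <= options$n_reweight && options$weighting == "poisson")
      w <- weights_for(drop(design(opt1$minimum) %*% f1$coefficients))
  }
  tau_mono <- opt1$minimum

  if (model == "mono") {
    X <- design(tau_mono)
    f <- wls(X, w)
    se <- param_se(function(th) {
      drop(design(th[1]) %*% th[-1])
    }, c(tau_mono, f$coefficients), w)
    est <- c(tau_ps = tau_mono, amplitude = f$coefficients[1],
             offset = if (fit_offset) f$coefficients[2] else 0)
    params <- tibble::tibble(
      term = c("tau_ps", "amplitude", if (fit_offset) "offset"),
      estimate = unname(est[seq_len(2 + fit_offset)]),
      std_error = se[seq_len(2 + fit_offset)])
    fitted <- drop(X %*% f$coefficients)
    dof <- max(length(y) - ncol(X) - 1, 1)
    return(new_flim_fit("binned", list(n_exp = 1), options,
                        params = params,
                        fitted = tibble::tibble(delay_ps = d, observed = y,
                                                fitted = fitted,
                                                residual = y - fitted),
                        chisq = sum(w * (y - fitted)^2) / dof, dof = dof,
                        n_pixels = n_pixels, degenerate = FALSE))
  }

  # --- biexp: outer optimization over log-lifetimes ---
  # the profiled surface can hold shallow spurious basins, so a coarse
  # 2-D grid (centred on the mono fit) picks the start before polishing
  obj <- function(p, w) rss_of(exp(p), w)
  grid_start <- function(w) {
    cand <- exp(seq(log(max(tau_mono * 0.45, options$tau_range[1])),
                    log(min(tau_mono * 2.2, options$tau_range[2])),
                    length.out = 14))
    best <- c(tau_mono * 1.3, tau_mono * 0.7); bestv <- Inf
    for (i in seq_along(cand)) for (j in seq_len(i - 1)) {
      v <- rss_of(c(cand[i], cand[j]), w)
      if (v < bestv) { bestv <- v; best <- c(cand[i], cand[j]) }
    }
    log(best)
  }
  lb <- rep(log(options$tau_range[1]), 2)
  ub <- rep(log(options$tau_range[2]), 2)
  w <- weights_for(y)
  for (pass in seq_len(options$n_reweight + 1)) {
    opt <- nlminb(grid_start(w), obj, w = w, lower = lb, upper = ub,
                  control = list(iter.max = options$max_iter))
    if (pass <= options$n_reweight && options$weighting == "poisson") {
      taus <- exp(opt$par)
      f <- wls(design(taus), w)
      w <- weights_for(drop(design(taus) %*% f$coefficients))
    }
  }
  taus <- exp(opt$par)
  X <- design(taus)
  f <- wls(X, w)
  amps <- f$coefficients[1:2]
  off <- if (fit_offset) f$coefficients[3] else 0
  # relabel so tau1 is the longer component
  if (taus[2] > taus[1]) { taus <- taus[2:1]; amps <- amps[2:1] }
  I0 <- sum(amps)
  beta <- if (I0 != 0) amps[2] / I0 else NA_real_
  degenerate <- abs(taus[1] - taus[2]) < 0.01 * taus[1] ||
    any(amps < 0) || !is.na(beta) && (beta <= 0 || beta >= 1)

  se <- param_se(function(th) {
    Xt <- design(th[1:2])
    drop(Xt %*% th[-(1:2)])
  }, c(taus, amps, if (fit_offset) off), w)
  fitted <- drop(design(taus) %*% c(amps, if (fit_offset) off))
  dof <- max(length(y) - (4 + fit_offset) - 1, 1)
  params <- tibble::tibble(
    term = c("tau1_ps", "tau2_ps", "amplitude1", "amplitude2",
             if (fit_offset) "offset", "beta"),
    estimate = c(taus, amps, if (fit_offset) off, beta),
    std_error = c(se, beta_se(taus, amps, if (fit_offset) off, se)))
  new_flim_fit("binned", list(n_exp = 2), options, params = params,
               fitted = tibble::tibble(delay_ps = d, observed = y,
                                       fitted = fitted, residual = y - fitted),
               chisq = sum(w * (y - fitted)^2) / dof, dof = dof,
               n_pixels = n_pixels, degenerate = degenerate)
}

# asymptotic SEs from the weighted Gauss-Newton approximation
param_se <- function(mu_fn, theta, w) {
  J <- vapply(seq_along(theta), function(i) {
    h <- pmax(abs(theta[i]) * 1e-5, 1e-8)
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (mu_fn(tp) - mu_fn(tm)) / (2 * h)
  }, numeric(length(w)))
  H <- crossprod(J, w * J)
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_,
                                                       nrow(H), ncol(H)))
  sqrt(pmax(diag(cov), 0))
}

# delta-method SE for beta = A2/(A1+A2)
beta_se <- function(taus, amps, off, se) {
  I0 <- sum(amps)
  if (I0 == 0 || anyNA(se)) return(NA_real_)
  g <- c(0, 0, -amps[2] / I0^2, amps[1] / I0^2, if (!is.null(off)) 0)
  sqrt(sum((g * se)^2))
}

#' Pixel-wise FRET population-fraction refit with fixed lifetimes
#'
#' The second stage of the standard FRET workflow: with the two component
#' lifetimes fixed (from a globally binned fit, or user-supplied), each pixel
#' reduces to a linear problem in the two basis decays plus offset. Returns
#' the per-pixel FRETing donor fraction `beta`, clipped to `[0, 1]` with an
#' at-bound flag when an amplitude went negative.
#'
#' @param stacks a [flim_stack()] or list of them.
#' @param calibration a [flim_calibration()].
#' @param tau1,tau2 fixed lifetimes (ps), `tau1 > tau2`.
#' @param mask optional label mask; when given, only labelled pixels are fit
#'   and the label is carried in the output.
#' @param options a [fit_options()].
#' @return A `flim_fit`; `$pixels` has `beta`, `amplitude` (total I0),
#'   `offset`, `chisq`, `at_bound` per pixel.
#' @export
refit_pixelwise_fixed_tau <- function(stacks, calibration, tau1, tau2,
                                      mask = NULL, options = fit_options()) {
  if (is_flim_stack(stacks)) stacks <- list(stacks)
  if (tau2 >= tau1)
    stop("degenerate design: fixed lifetimes must satisfy tau1 > tau2")
  px <- purrr::map_dfr(stacks, function(st) {
    cal <- calibrate_stack(st, calibration)
    tot <- rowSums(cal$stack$counts, dims = 2L)
    keep <- tot > options$threshold
    if (!is.null(mask)) keep <- keep & mask > 0
    sel <- which(keep)
    if (length(sel) == 0) return(tibble::tibble())
    ng <- nrow(st$gates)
    mode <- fit_mode_of(options)
    ymat <- t(matrix(cal$stack$counts, ncol = ng)[sel, , drop = FALSE])
    if (mode == 2L) ymat <- pmax(ymat, 0)
    bmat <- t(matrix(cal$baseline, ncol = ng)[sel, , drop = FALSE])
    irf <- calibration$irf
    res <- cpp_fit_fraction_px(ymat, bmat, st$gates$delay_ps,
                               irf_lower_edge(irf), irf$dt, irf$amplitudes,
                               cal$shifts[sel], tau1, tau2, cal$fit_offset,
                               mode, options$n_reweight, options$w_floor)
    idx <- arrayInd(sel, dim(tot))
    dof <- ng - (2L + cal$fit_offset)
    beta <- pmin(pmax(res$beta, 0), 1)
    tibble::tibble(well = st$well, fov = st$fov,
                   row = idx[, 1], col = idx[, 2], intensity = tot[sel],
                   label = if (!is.null(mask)) mask[sel] else NA_integer_,
                   beta = beta,
                   amplitude = res$a1 + res$a2, offset = res$offset,
                   tau_mean_ps = (1 - beta) * tau1 + beta * tau2,
                   chisq = res$objective / max(dof, 1),
                   at_bound = res$at_bound != 0L)
  })
  new_flim_fit("fraction", list(n_exp = 2, tau1 = tau1, tau2 = tau2), options,
               pixels = px, calibration = calibration)
}

#' Global fitting via separable nonlinear least squares
#'
#' Fits lifetime components shared across all pixels of one or more fields of
#' view simultaneously with per-pixel linear parameters (component amplitudes
#' and offset), by variable projection: the outer optimizer walks the global
#' lifetimes and, for every candidate, the per-pixel linear problems are
#' solved in closed form and their weighted residuals summed. Exploits the
#' spatial variation of the FRETing fraction to constrain the component
#' lifetimes more strongly than global binning.
#'
#' Weights are held fixed during the outer optimization (Poisson weights from
#' the observed counts) so the objective is a fixed quadratic form in the
#' linear parameters and the optimum matches a joint nonlinear least-squares
#' fit with the same weights.
#'
#' @param stacks a [flim_stack()] or list of them.
#' @param calibration a [flim_calibration()].
#' @param model `"biexp"` (global `tau1`, `tau2`; per-pixel `beta`) or
#'   `"mono"` (one global lifetime, per-pixel amplitude).
#' @param options a [fit_options()]; `weighting = "none"` gives plain least
#'   squares.
#' @param fit_offset override the per-pixel free-offset choice (default:
#'   offset fitted only when no TVB model is in the calibration). A free
#'   offset per pixel weakens lifetime identifiability considerably; prefer
#'   a TVB model or background-free data.
#' @return A `flim_fit` with `$params` (global lifetimes), `$pixels`
#'   (per-pixel fractions/amplitudes at the optimum) and `$objective`.
#' @export
fit_global <- function(stacks, calibration, model = c("biexp", "mono"),
                       options = fit_options(), fit_offset = NULL) {
  model <- match.arg(model)
  if (is_flim_stack(stacks)) stacks <- list(stacks)
  mode <- fit_mode_of(options)
  prep <- purrr::map(stacks, function(st) {
    cal <- calibrate_stack(st, calibration)
    if (!is.null(fit_offset)) cal$fit_offset <- fit_offset
    tot <- rowSums(cal$stack$counts, dims = 2L)
    sel <- which(tot > options$threshold)
    ng <- nrow(st$gates)
    y <- t(matrix(cal$stack$counts, ncol = ng)[sel, , drop = FALSE])
    if (mode == 2L) y <- pmax(y, 0)
    list(st = st, y = y,
         base = t(matrix(cal$baseline, ncol = ng)[sel, , drop = FALSE]),
         shifts = cal$shifts[sel], sel = sel, dim = dim(tot),
         fit_offset = cal$fit_offset, delays = st$gates$delay_ps,
         intensity = tot[sel])
  })
  irf <- calibration$irf

  # unconstrained linear solve inside the profiled objective: clamping
  # amplitudes at zero would bias the shared lifetimes toward wider spacing
  frac_obj <- function(p, taus) {
    r <- cpp_fit_fraction_px(p$y, p$base, p$delays, irf_lower_edge(irf),
                             irf$dt, irf$amplitudes, p$shifts,
                             taus[1], taus[2], p$fit_offset, mode, 0L,
                             options$w_floor, constrain = FALSE)
    sum(r$objective)
  }
  mono_obj <- function(p, tau) {
    rss <- 0
    for (j in seq_along(p$shifts)) {
      b <- cpp_conv_basis(tau, p$delays, irf_lower_edge(irf), irf$dt,
                          irf$amplitudes, p$shifts[j])[, 1]
      y <- p$y[, j] - p$base[, j]
      w <- if (mode == 0L) rep(1, length(y))
      else 1 / pmax(p$y[, j], options$w_floor)
      X <- if (p$fit_offset) cbind(b, 1) else cbind(b)
      f <- stats::lm.wfit(X, y, w)
      rss <- rss + sum(w * f$residuals^2)
    }
    rss
  }

  # start from a binned fit of the pooled decay
  pooled <- list(delay_ps = prep[[1]]$delays,
                 counts = Reduce(`+`, purrr::map(prep, ~ rowSums(.x$y - .x$base))))
  start_fit <- fit_global_binned(tibble::as_tibble(pooled), calibration,
                                 model = "mono", options = options,
                                 n_pixels = sum(purrr::map_int(prep, ~ ncol(.x$y))))
  if (model == "mono") {
    obj <- function(lt) sum(purrr::map_dbl(prep, mono_obj, tau = exp(lt)))
    opt <- optimize(function(t) obj(log(t)), options$tau_range, tol = 0.01)
    taus <- opt$minimum
    params <- tibble::tibble(term = "tau_ps", estimate = taus,
                             std_error = NA_real_)
    objective <- opt$objective
    pixels <- tibble::tibble()
  } else {
    gobj <- function(taus) sum(purrr::map_dbl(prep, frac_obj, taus = taus))
    # coarse grid start around the pooled mono lifetime: the profiled
    # surface is shallow and can trap a descent from a poor start
    tau_mono <- start_fit$params$estimate[start_fit$params$term == "tau_ps"]
    if (length(tau_mono) == 0)
      tau_mono <- mean(start_fit$params$estimate[1:2])
    cand <- exp(seq(log(max(tau_mono * 0.45, options$tau_range[1])),
                    log(min(tau_mono * 2.2, options$tau_range[2])),
                    length.out = 12))
    st0 <- log(c(tau_mono * 1.3, tau_mono * 0.7)); bestv <- Inf
    for (i in seq_along(cand)) for (j in seq_len(i - 1)) {
      v <- gobj(c(cand[i], cand[j]))
      if (v < bestv) { bestv <- v; st0 <- log(c(cand[i], cand[j])) }
    }
    opt <- nlminb(st0, function(p) gobj(exp(p)),
                  lower = log(options$tau_range[1]),
                  upper = log(options$tau_range[2]),
                  control = list(iter.max = options$max_iter))
    taus <- sort(exp(opt$par), decreasing = TRUE)
    objective <- opt$objective
    pixels <- purrr::map_dfr(prep, function(p) {
      r <- cpp_fit_fraction_px(p$y, p$base, p$delays,
                               irf_lower_edge(irf), irf$dt, irf$amplitudes,
                               p$shifts, taus[1], taus[2], p$fit_offset,
                               mode, 0L, options$w_floor)
      idx <- arrayInd(p$sel, p$dim)
      tibble::tibble(well = p$st$well, fov = p$st$fov,
                     row = idx[, 1], col = idx[, 2],
                     intensity = p$intensity,
                     beta = pmin(pmax(r$beta, 0), 1),
                     amplitude = r$a1 + r$a2, offset = r$offset,
                     at_bound = r$at_bound != 0L)
    })
    params <- tibble::tibble(term = c("tau1_ps", "tau2_ps"), estimate = taus,
                             std_error = NA_real_)
  }
  new_flim_fit("global", list(n_exp = if (model == "biexp") 2 else 1),
               options, params = params, pixels = pixels,
               objective = objective, converged = opt$convergence %in% c(0, NULL) ||
                 !is.null(opt$objective))
}

#' Goodness-of-fit summary
#'
#' Reduced chi-square statistics with their degrees of freedom: per-ROI for
#' binned fits, distributional summaries over pixels for map fits.
#'
#' @param fit a `flim_fit`.
#' @return a tibble.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "flim_fit"))
  if (!is.null(fit$chisq))
    return(tibble::tibble(chisq_reduced = fit$chisq, dof = fit$dof))
  tibble::tibble(chisq_reduced_median = median(fit$pixels$chisq),
                 chisq_reduced_mean = mean(fit$pixels$chisq),
                 n_pixels = nrow(fit$pixels),
                 n_unconverged = sum(!fit$pixels$converged %||% FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.flim_fit <- function(x, ...) {
  cat("<flim_fit> type:", x$type,
      if (!is.null(x$model$n_exp)) paste0("(", x$model$n_exp, "-exp)"), "\n")
  if (!is.null(x$params)) print(x$params)
  if (!is.null(x$pixels) && nrow(x$pixels) > 0)
    cat(nrow(x$pixels), "fitted pixels\n")
  invisible(x)
}
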