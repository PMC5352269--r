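# internal: swap counts without re-validation (calibrated data may be negative)
replace_counts <- function(stack, counts) {
  stack$counts <- counts
  stack
}

#' Camera background frame
#'
#' The CCD/intensifier offset image acquired with the excitation blocked,
#' together with the settings under which it was recorded. Background scales
#' linearly with `integration_ms * n_accumulations`, so it can be re-scaled
#' to match data acquired at different exposure settings.
#'
#' @param image non-negative background image (counts), or a scalar.
#' @param integration_ms,n_accumulations settings used for the background
#'   acquisition.
#' @return An object of class `camera_background`.
#' @export
camera_background <- function(image, integration_ms = 250, n_accumulations = 1) {
  stopifnot(all(image >= 0), integration_ms > 0, n_accumulations >= 1)
  structure(list(image = image, integration_ms = integration_ms,
                 n_accumulations = n_accumulations),
            class = "camera_background")
}

#' @rdname camera_background
#' @param stack a single- or multi-gate [flim_stack()] acquired with the
#'   laser blocked; planes are averaged.
#' @export
camera_background_from_stack <- function(stack) {
  stopifnot(is_flim_stack(stack))
  camera_background(rowMeans(stack$counts, dims = 2L),
                    integration_ms = stack$gates$integration_ms[1],
                    n_accumulations = stack$gates$n_accumulations[1])
}

#' Subtract the camera background from a stack
#'
#' Per-pixel, per-gate subtraction of the background image scaled by the
#' exposure ratio `(integration_ms * n_accumulations)_data / (...)_background`.
#' Results are floating point; negative values are permitted.
#'
#' @param stack a [flim_stack()].
#' @param background a [camera_background()].
#' @return The corrected stack.
#' @export
subtract_camera_background <- function(stack, background) {
  stopifnot(is_flim_stack(stack), inherits(background, "camera_background"))
  img <- background$image
  if (length(img) > 1 && !identical(dim(img), dim(stack$counts)[1:2]))
    stop("background image shape does not match stack frames")
  out <- stack$counts
  for (g in seq_len(nrow(stack$gates))) {
    scale <- (stack$gates$integration_ms[g] * stack$gates$n_accumulations[g]) /
      (background$integration_ms * background$n_accumulations)
    out[, , g] <- out[, , g] - img * scale
  }
  replace_counts(stack, out)
}

#' Time-varying background (TVB) model
#'
#' Built from a medium-only control well: `profile` is the spatially averaged
#' background decay (counts per gate per pixel) and `intensity_map` a
#' dimensionless per-pixel scale factor with spatial mean 1, so the expected
#' background at pixel p, gate g is `profile[g] * intensity_map[p]`.
#'
#' @param medium_stack a [flim_stack()] of the medium-only well (or a list
#'   of its fields of view, which are averaged — the background is dim, so
#'   pooling all available medium acquisitions matters), same gate set as
#'   the data it will correct.
#' @param background a [camera_background()] subtracted first (optional).
#' @return An object of class `tvb_model` with `profile` (tibble
#'   `delay_ps`, `counts`) and `intensity_map`.
#' @export
create_tvb <- function(medium_stack, background = NULL) {
  if (is.list(medium_stack) && !is_flim_stack(medium_stack)) {
    pooled <- Reduce(`+`, lapply(medium_stack, function(s) s$counts)) /
      length(medium_stack)
    medium_stack <- replace_counts(medium_stack[[1]], pooled)
  }
  stopifnot(is_flim_stack(medium_stack))
  if (!is.null(background))
    medium_stack <- subtract_camera_background(medium_stack, background)
  profile <- apply(medium_stack$counts, 3, mean)
  tot <- rowSums(medium_stack$counts, dims = 2L)
  mtot <- mean(tot)
  if (mtot <= 0 || all(abs(profile) < 1e-12))
    stop("degenerate TVB: medium stack carries no signal")
  structure(list(profile = tibble::tibble(delay_ps = medium_stack$gates$delay_ps,
                                          counts = profile),
                 intensity_map = pmax(tot / mtot, 0)),
            class = "tvb_model")
}

#' Subtract a TVB model from a stack
#' @param stack a [flim_stack()] (camera background already removed).
#' @param tvb a [create_tvb()] model with the same gate set.
#' @return The corrected stack (floating point).
#' @export
subtract_tvb <- function(stack, tvb) {
  stopifnot(is_flim_stack(stack), inherits(tvb, "tvb_model"))
  if (!isTRUE(all.equal(tvb$profile$delay_ps, stack$gates$delay_ps)))
    stop("TVB gate set does not match the stack")
  out <- stack$counts
  for (g in seq_len(nrow(stack$gates)))
    out[, , g] <- out[, , g] - tvb$profile$counts[g] * tvb$intensity_map
  replace_counts(stack, out)
}

#' Build the IRF temporal profile from a scattered-light stack
#'
#' Pools the background-subtracted scattered-light measurement over all
#' pixels, clips negative bins to zero (amplitudes are physically
#' non-negative) and normalizes to unit sum on the fine uniform delay grid
#' (25 ps steps in the standard acquisition). The scan integrates the
#' response over each delay step, so the piecewise-constant density on the
#' scan grid is the faithful reconstruction for responses smooth at the
#' 25 ps scale (any physical intensifier gate: optical switching blurs the
#' edges over ~100 ps or more). An optional `refine`-fold mass-preserving
#' linear subdivision is available for profiles with genuine sub-sample
#' structure; it is off by default because its edge-bin renormalization
#' skews smooth profiles slightly.
#'
#' @param irf_stack a [flim_stack()] sampled at fine uniform delay steps.
#' @param background a [camera_background()] (optional).
#' @param refine odd sub-bin factor for the sharpening reconstruction
#'   (1, the default, disables it).
#' @return An [irf_profile()].
#' @export
create_irf_profile <- function(irf_stack, background = NULL, refine = 1L) {
  stopifnot(is_flim_stack(irf_stack), refine >= 1)
  if (!is.null(background))
    irf_stack <- subtract_camera_background(irf_stack, background)
  d <- irf_stack$gates$delay_ps
  if (length(d) < 2) stop("IRF stack needs a fine delay scan")
  steps <- diff(d)
  if (any(abs(steps - steps[1]) > 1e-6 * steps[1]))
    stop("IRF stack delay grid is not uniform")
  amp <- pmax(apply(irf_stack$counts, 3, sum), 0)
  if (refine <= 1) return(irf_profile(d, amp))
  dt <- steps[1]
  n <- length(d)
  # per-bin linear density: slope from central differences of bin masses
  slope <- (c(amp[-1], 0) - c(0, amp[-n])) / (2 * dt)
  sub_off <- (seq_len(refine) - (refine + 1) / 2) * dt / refine
  sub_d <- as.vector(outer(sub_off, d, `+`))
  sub_m <- as.vector(vapply(seq_len(n), function(j) {
    m <- amp[j] / refine + slope[j] * sub_off * (dt / refine)
    m <- pmax(m, 0)
    if (sum(m) > 0) m * (amp[j] / sum(m)) else m  # bin mass preserved
  }, numeric(refine)))
  irf_profile(sub_d, sub_m)
}

# 2-D median filter with NA-ignoring window, reflecting edges by truncation
median_filter2 <- function(m, size = 5) {
  half <- (size - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  shifts <- expand.grid(dr = -half:half, dc = -half:half)
  stackarr <- array(NA_real_, c(nr, nc, nrow(shifts)))
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    rs <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    stackarr[, , k] <- m[rs, cs]
  }
  apply(stackarr, c(1, 2), median, na.rm = TRUE)
}

#' Per-pixel IRF shift map
#'
#' Estimates, for every pixel, the temporal offset of its IRF relative to the
#' global profile as the difference of temporal centroids, then smooths with a
#' 2-D median filter and re-centres to zero spatial mean. Pixels whose total
#' IRF counts fall below `min_counts` (where the centroid variance explodes)
#' are inpainted from the smoothed neighbourhood.
#'
#' @param irf_stack a [flim_stack()] of the scattered-light IRF scan.
#' @param background a [camera_background()] (optional).
#' @param min_counts low-count floor below which pixels are inpainted.
#' @param filter_size median filter window (odd integer).
#' @return numeric matrix of per-pixel offsets (ps), spatial mean ~ 0.
#' @export
create_irf_shift_map <- function(irf_stack, background = NULL,
                                 min_counts = 100, filter_size = 5) {
  stopifnot(is_flim_stack(irf_stack))
  if (!is.null(background))
    irf_stack <- subtract_camera_background(irf_stack, background)
  cts <- pmax(irf_stack$counts, 0)
  d <- irf_stack$gates$delay_ps
  tot <- rowSums(cts, dims = 2L)
  num <- matrix(0, dim(cts)[1], dim(cts)[2])
  for (g in seq_along(d)) num <- num + cts[, , g] * d[g]
  cent <- num / ifelse(tot > 0, tot, NA_real_)
  global_cent <- sum(num) / sum(tot)
  shift <- cent - global_cent
  shift[tot < min_counts] <- NA_real_
  sm <- median_filter2(shift, filter_size)
  sm[is.na(sm)] <- 0
  sm - mean(sm)
}

#' Global IRF timing correction t0 from a reference dye
#'
#' The scattered-light IRF can be globally offset in time from the true
#' fluorescence IRF (different optical path, excitation-wavelength timing).
#' This fits a monoexponential decay with the lifetime *fixed* to the
#' reference dye's literature value (e.g. Coumarin 6, ~2430 ps) to the
#' spatially pooled dye decay, with the IRF shift as the only nonlinear free
#' parameter (amplitude and offset solved linearly). The returned `t0` is the
#' shift to apply to the IRF time axis before convolution; analysis of sample
#' data consumes its negative.
#'
#' @param dye_stack a [flim_stack()] of the reference-dye well, fine delay
#'   sampling.
#' @param irf an [irf_profile()].
#' @param reference_lifetime_ps literature lifetime of the dye (ps).
#' @param shift_map optional per-pixel IRF offsets for the dye field; when
#'   given, the model basis is averaged over the pixel shifts so the pooled
#'   decay (a mixture of slightly shifted responses) is matched without
#'   bias. The map's spatial mean is zero, so omitting it leaves t0
#'   unbiased to first order but slightly less accurate.
#' @param background a [camera_background()] (optional).
#' @param search_ps search half-range for the shift (ps).
#' @return scalar t0 (ps) with attributes `chisq_reduced` and `converged`.
#' @export
estimate_t0 <- function(dye_stack, irf, reference_lifetime_ps,
                        shift_map = NULL, background = NULL,
                        search_ps = 2000) {
  stopifnot(is_flim_stack(dye_stack), inherits(irf, "irf_profile"),
            reference_lifetime_ps > 0)
  if (!is.null(background))
    dye_stack <- subtract_camera_background(dye_stack, background)
  y <- apply(dye_stack$counts, 3, sum)
  d <- dye_stack$gates$delay_ps
  w <- 1 / pmax(y, 1)
  px_shifts <- 0
  if (!is.null(shift_map)) {
    if (!identical(dim(shift_map), dim(dye_stack$counts)[1:2]))
      stop("shift map shape does not match the dye stack")
    px_shifts <- round(as.vector(shift_map), 1)
  }
  shift_tab <- table(px_shifts)
  shift_vals <- as.numeric(names(shift_tab))
  shift_wts <- as.numeric(shift_tab) / sum(shift_tab)
  obj <- function(s) {
    b <- 0
    for (i in seq_along(shift_vals))
      b <- b + shift_wts[i] *
        cpp_conv_basis(reference_lifetime_ps, d, irf_lower_edge(irf),
                       irf$dt, irf$amplitudes, s + shift_vals[i])[, 1]
    fit <- stats::lm.wfit(cbind(b, 1), y, w)
    sum(w * fit$residuals^2)
  }
  opt <- optimize(obj, c(-search_ps, search_ps), tol = 0.01)
  t0 <- opt$minimum
  chisq <- opt$objective / max(length(y) - 3, 1)
  conv <- abs(t0) < search_ps * 0.999
  if (!conv) warning("t0 search hit the boundary; dye data may be unsuitable")
  if (chisq > 5)
    warning("poor monoexponential fit to reference dye (reduced chi-square ",
            signif(chisq, 3), "); check reference data")
  structure(t0, chisq_reduced = chisq, converged = conv)
}

#' Delay of maximum intensity in a decay
#'
#' @param decay a numeric vector of per-delay counts with delays supplied via
#'   `delays`, a tibble with `delay_ps`/`counts`, or a [flim_stack()] (frames
#'   summed spatially). Ties break to the earliest delay.
#' @param delays delays (ps) when `decay` is a bare numeric vector.
#' @return the peak delay (ps).
#' @export
find_peak_delay <- function(decay, delays = NULL) {
  if (is_flim_stack(decay)) {
    delays <- decay$gates$delay_ps
    decay <- apply(decay$counts, 3, sum)
  } else if (is.data.frame(decay)) {
    delays <- decay$delay_ps
    decay <- decay$counts
  }
  stopifnot(length(decay) >= 1, length(delays) == length(decay))
  delays[which.max(decay)]
}

#' Logarithmically spaced gate delays ("AutoGate")
#'
#' Chooses `n_gates` delays for sampling a decay: one gate before the
#' excitation pulse (measuring background only), one at the intensity peak,
#' and the remaining `n_gates - 2` log-spaced between the peak and
#' `last_delay` — successive values of `delay - peak + eps` form a geometric
#' progression. Four gates suffice for monoexponential fitting; seven or more
#' are used for more complex decay models.
#'
#' @param peak_delay delay of maximum intensity (ps), e.g. from
#'   [find_peak_delay()].
#' @param last_delay latest delay to sample (ps), `> peak_delay`.
#' @param n_gates total number of gates (>= 4).
#' @param pre_pulse_offset how far before the peak the background gate sits
#'   (ps); clipped at 0.
#' @param eps log-spacing regularizer (ps); default `(last - peak)/20`.
#' @return strictly increasing numeric vector of `n_gates` delays (ps).
#' @export
autogate_delays <- function(peak_delay, last_delay, n_gates = 7,
                            pre_pulse_offset = 3000, eps = NULL) {
  if (last_delay <= peak_delay) stop("last_delay must exceed peak_delay")
  if (n_gates < 4) stop("at least 4 gates are required")
  if (is.null(eps)) eps <- (last_delay - peak_delay) / 20
  k <- n_gates - 2
  ratio <- ((last_delay - peak_delay + eps) / eps)^(1 / k)
  tail_d <- peak_delay + eps * ratio^seq_len(k) - eps
  out <- c(max(0, peak_delay - pre_pulse_offset), peak_delay, tail_d)
  stopifnot(all(diff(out) > 0))
  out
}

#' Calibration bundle
#'
#' Collects everything the fit needs: IRF profile, global t0, per-pixel IRF
#' shift map, camera background and TVB model. Any element except the IRF may
#' be omitted.
#'
#' @param irf an [irf_profile()].
#' @param t0 global IRF shift (ps), from [estimate_t0()].
#' @param shift_map matrix from [create_irf_shift_map()], or `NULL`.
#' @param background a [camera_background()], or `NULL`.
#' @param tvb a [create_tvb()] model, or `NULL`.
#' @return An object of class `flim_calibration`.
#' @export
flim_calibration <- function(irf, t0 = 0, shift_map = NULL, background = NULL,
                             tvb = NULL) {
  stopifnot(inherits(irf, "irf_profile"), is.finite(t0))
  structure(list(irf = irf, t0 = as.numeric(t0), shift_map = shift_map,
                 background = background, tvb = tvb),
            class = "flim_calibration")
}

#' Serialize a calibration bundle to a JSON + TIFF directory
#'
#' Scalars and profiles go to `calibration.json`; the shift map, background
#' image and TVB intensity map are written as 32-bit float TIFFs.
#'
#' @param cal a [flim_calibration()].
#' @param dir output directory.
#' @return `read_calibration` returns the [flim_calibration()].
#' @export
write_calibration <- function(cal, dir) {
  stopifnot(inherits(cal, "flim_calibration"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(t0 = cal$t0,
             irf = list(delays = cal$irf$delays, amplitudes = cal$irf$amplitudes))
  if (!is.null(cal$background))
    js$background <- list(integration_ms = cal$background$integration_ms,
                          n_accumulations = cal$background$n_accumulations)
  if (!is.null(cal$tvb))
    js$tvb_profile <- list(delay_ps = cal$tvb$profile$delay_ps,
                           counts = cal$tvb$profile$counts)
  jsonlite::write_json(js, file.path(dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cal$shift_map))
    write_map_tiff(cal$shift_map, file.path(dir, "shift_map.tif"))
  if (!is.null(cal$background))
    write_map_tiff(as.matrix(cal$background$image),
                   file.path(dir, "camera_background.tif"))
  if (!is.null(cal$tvb))
    write_map_tiff(cal$tvb$intensity_map, file.path(dir, "tvb_intensity.tif"))
  invisible(dir)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "calibration.json"),
                            simplifyVector = TRUE)
  irf <- irf_profile(js$irf$delays, js$irf$amplitudes)
  shift_map <- if (file.exists(file.path(dir, "shift_map.tif")))
    read_map_tiff(file.path(dir, "shift_map.tif"))
  bg <- if (file.exists(file.path(dir, "camera_background.tif")))
    camera_background(read_map_tiff(file.path(dir, "camera_background.tif")),
                      js$background$integration_ms, js$background$n_accumulations)
  tvb <- if (!is.null(js$tvb_profile)) {
    structure(list(profile = tibble::tibble(delay_ps = js$tvb_profile$delay_ps,
                                            counts = js$tvb_profile$counts),
                   intensity_map = read_map_tiff(file.path(dir, "tvb_intensity.tif"))),
              class = "tvb_model")
  }
  flim_calibration(irf, js$t0, shift_map, bg, tvb)
}

#' Background level diagnostic
#'
#' Ratio of mean total intensity in a control stack to that of a donor-only
#' sample stack — the acceptance check that plate/medium/autofluorescence
#' backgrounds stay below a stated fraction (typically 1%) of the signal.
#' Reported over mean intensities.
#'
#' @param control_stack,signal_stack [flim_stack()]s (camera background
#'   removed for a meaningful ratio).
#' @return the scalar intensity ratio.
#' @export
background_ratio <- function(control_stack, signal_stack) {
  mean(total_intensity_image(control_stack)) /
    mean(total_intensity_image(signal_stack))
}
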