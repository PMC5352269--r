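#' Aggregate fitted maps to well, column or condition summaries
#'
#' Pools thresholded pixels into summary rows: the mean lifetime over all
#' pixels of the unit, the standard deviation *between field-of-view means*
#' (pixels within a FOV are not independent, so the FOV is the replicate
#' unit), and the standard error of the unit mean over FOVs.
#'
#' @param fit a `flim_fit` with per-pixel results (`tau_ps` or `tau_mean_ps`),
#'   or a tibble with columns `well`, `fov` and a value column.
#' @param layout a [plate_layout()] joined onto the summaries.
#' @param level `"well"`, `"column"` (plate column across wells) or
#'   `"condition"`.
#' @param value name of the pixel value column; default picks `tau_ps` then
#'   `tau_mean_ps` then `beta`.
#' @return tibble with `mean`, `std` (between-FOV), `err`, `n_fov`,
#'   `n_pixels` per unit, named after the value (e.g. `mean_tau_ps`).
#' @export
aggregate_plate <- function(fit, layout = NULL,
                            level = c("well", "column", "condition"),
                            value = NULL) {
  level <- match.arg(level)
  px <- if (inherits(fit, "flim_fit")) fit$pixels else fit
  stopifnot(is.data.frame(px), nrow(px) > 0)
  if (is.null(value))
    value <- intersect(c("tau_ps", "tau_mean_ps", "beta"), names(px))[1]
  px$.value <- px[[value]]
  if (!is.null(layout)) {
    px <- dplyr::left_join(px, layout, by = "well")
    if (level == "condition" && any(is.na(px$condition[px$role == "sample"])))
      warning("sample pixels without a condition were dropped")
  }
  unit <- switch(level,
                 well = "well",
                 column = "plate_col",
                 condition = "condition")
  if (level == "column")
    px$plate_col <- well_position(px$well)$col
  if (level == "condition" && is.null(layout))
    stop("condition-level aggregation needs a plate layout")
  fovs <- px |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(unit, "well", "fov")))) |>
    dplyr::summarise(fov_mean = mean(.data$.value),
                     n_pixels = dplyr::n(), .groups = "drop")
  out <- px |>
    dplyr::group_by(dplyr::across(dplyr::all_of(unit))) |>
    dplyr::summarise(mean = mean(.data$.value),
                     n_pixels = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      fovs |>
        dplyr::group_by(dplyr::across(dplyr::all_of(unit))) |>
        dplyr::summarise(std = sd(.data$fov_mean),
                         n_fov = dplyr::n(),
                         err = sd(.data$fov_mean) / sqrt(dplyr::n()),
                         .groups = "drop"),
      by = unit)
  names(out)[names(out) == "mean"] <- paste0("mean_", value)
  if (!is.null(layout) && level == "well")
    out <- dplyr::left_join(out, layout, by = "well")
  out
}

#' Z-prime screening-assay quality factor
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|` over the replicate
#' units of the positive and negative control arms (FOV means by default).
#' `Z' > 0.5` is considered excellent for a pharmaceutical assay.
#'
#' @param positive,negative numeric vectors of replicate-unit values (e.g.
#'   FOV mean lifetimes) for each control arm; at least 2 each.
#' @return tibble with `z_prime`, the control means and SDs.
#' @export
z_prime <- function(positive, negative) {
  stopifnot(length(positive) >= 2, length(negative) >= 2)
  z_prime_moments(mean(positive), sd(positive), mean(negative), sd(negative))
}

#' @rdname z_prime
#' @param mu_pos,sigma_pos,mu_neg,sigma_neg control-arm moments.
#' @export
z_prime_moments <- function(mu_pos, sigma_pos, mu_neg, sigma_neg) {
  if (mu_pos == mu_neg)
    stop("Z' undefined: control means are equal")
  tibble::tibble(z_prime = 1 - 3 * (sigma_pos + sigma_neg) /
                   abs(mu_pos - mu_neg),
                 mu_pos = mu_pos, sigma_pos = sigma_pos,
                 mu_neg = mu_neg, sigma_neg = sigma_neg)
}

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_fret / tau_donor`: the fractional shortening of the donor
#' lifetime in the FRETing state relative to the unquenched donor.
#'
#' @param tau_fret lifetime of the FRETing donor (ps).
#' @param tau_donor unquenched donor lifetime (ps), `>= tau_fret`.
#' @return E in `[0, 1)`.
#' @export
fret_efficiency <- function(tau_fret, tau_donor) {
  stopifnot(all(tau_fret > 0), all(tau_donor > 0))
  if (any(tau_fret > tau_donor))
    stop("tau_fret exceeds tau_donor: FRET efficiency would be negative")
  1 - tau_fret / tau_donor
}

#' Logistic dose-response fit with fixed asymptotes (IC50 only)
#'
#' Fits the four-parameter logistic model with the Hill coefficient fixed to
#' 1 and both asymptotes fixed to the control-well values, leaving IC50 as
#' the single free parameter:
#' \deqn{y(c) = y_0 + (y_\infty - y_0)\, c / (c + IC_{50})}
#' where `y0` is the zero-dose (negative control) response and `yinf` the
#' saturating (positive control) response. At `c = IC50` the response is the
#' midpoint of the asymptotes. The full 4PL parameter vector is reported for
#' interoperability even though only IC50 was fitted.
#'
#' @param data tibble with `concentration` (molar, > 0) and `response`.
#' @param y0,yinf fixed asymptotes from the negative / positive controls.
#' @param hill Hill coefficient; only 1 is supported (fixed by design).
#' @param weights optional per-point weights.
#' @return an object of class `dose_response`: tibble of parameters plus
#'   attributes `fitted` (curve table), `flag_residual`.
#' @export
fit_dose_response <- function(data, y0, yinf, hill = 1, weights = NULL) {
  stopifnot(all(c("concentration", "response") %in% names(data)),
            all(data$concentration > 0), hill == 1)
  if (length(unique(data$concentration)) < 4)
    stop("at least 4 distinct concentrations are required")
  if (y0 == yinf) stop("asymptotes must be distinct")
  w <- weights %||% rep(1, nrow(data))
  cvec <- data$concentration
  model <- function(lic50) y0 + (yinf - y0) * cvec / (cvec + 10^lic50)
  ssr <- function(lic50) sum(w * (data$response - model(lic50))^2)
  rng <- log10(range(cvec)) + c(-3, 3)
  opt <- optimize(ssr, rng, tol = 1e-6)
  lic50 <- opt$minimum
  ic50 <- 10^lic50
  # curvature-based asymptotic CI on log10(IC50)
  h <- 0.01
  d2 <- (ssr(lic50 + h) - 2 * opt$objective + ssr(lic50 - h)) / h^2
  dof <- max(nrow(data) - 1, 1)
  sigma2 <- opt$objective / dof
  se_l <- if (d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  ci <- 10^(lic50 + c(-1, 1) * qnorm(0.975) * se_l)
  # non-monotone / lack-of-fit flag: residual spread vs replicate spread
  resid <- data$response - model(lic50)
  flag <- sqrt(mean(resid^2)) > 0.25 * abs(yinf - y0)
  out <- tibble::tibble(
    term = c("ic50_M", "y0", "yinf", "hill"),
    estimate = c(ic50, y0, yinf, 1),
    fixed = c(FALSE, TRUE, TRUE, TRUE))
  attr(out, "ci95_M") <- ci
  attr(out, "se_log10") <- se_l
  attr(out, "data") <- data
  attr(out, "flag_residual") <- flag
  cgrid <- 10^seq(log10(min(cvec)) - 1, log10(max(cvec)) + 1, length.out = 120)
  attr(out, "curve") <- tibble::tibble(
    concentration = cgrid,
    response = y0 + (yinf - y0) * cgrid / (cgrid + ic50))
  class(out) <- c("dose_response", class(out))
  out
}

#' IC50 of a dose-response fit (molar)
#' @param fit a [fit_dose_response()] result.
#' @export
ic50 <- function(fit) fit$estimate[fit$term == "ic50_M"]

#' FRET biosensor time-course analysis
#'
#' The two-stage workflow for live-cell biosensor series: (1) a globally
#' binned double-exponential fit over the baseline window (default: the
#' first `baseline_n` retained time points) estimates the two component
#' lifetimes; (2) those lifetimes are fixed and every time point is refit
#' pixel-wise for the FRETing fraction, summarized per segmented cell.
#' Time points disturbed by, e.g., stimulus-induced focus shifts can be
#' excluded.
#'
#' @param stacks list of [flim_stack()], one per time point.
#' @param times_s acquisition times (s).
#' @param calibration a [flim_calibration()].
#' @param mask per-cell segmentation label matrix (static across the series).
#' @param baseline_n number of leading retained time points pooled for the
#'   lifetime fit.
#' @param exclude_times_s time points to drop before any fitting.
#' @param options a [fit_options()].
#' @return tibble with `time_s`, `mean_tau_ps`, `mean_beta`, `se_beta`
#'   (per-cell standard error), `n_cells`, plus attributes `tau1_ps`,
#'   `tau2_ps`, `baseline_fit`.
#' @export
time_course <- function(stacks, times_s, calibration, mask,
                        baseline_n = 3, exclude_times_s = NULL,
                        options = fit_options()) {
  stopifnot(length(stacks) == length(times_s))
  keep <- !(times_s %in% (exclude_times_s %||% numeric(0)))
  stacks <- stacks[keep]; times_s <- times_s[keep]
  base_idx <- seq_len(min(baseline_n, length(stacks)))
  base_fit <- fit_global_binned(stacks[base_idx], calibration,
                                model = "biexp", mask = (mask > 0) * 1L,
                                options = options)
  if (isTRUE(base_fit$degenerate))
    stop("baseline double-exponential fit is degenerate; cannot fix lifetimes")
  tau1 <- base_fit$params$estimate[base_fit$params$term == "tau1_ps"]
  tau2 <- base_fit$params$estimate[base_fit$params$term == "tau2_ps"]

  out <- purrr::map_dfr(seq_along(stacks), function(i) {
    fr <- refit_pixelwise_fixed_tau(stacks[[i]], calibration, tau1, tau2,
                                    mask = mask, options = options)
    cells <- fr$pixels |>
      dplyr::filter(!is.na(.data$label), .data$label > 0) |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(beta = mean(.data$beta),
                       tau_mean_ps = mean(.data$tau_mean_ps),
                       .groups = "drop")
    tibble::tibble(time_s = times_s[i],
                   mean_tau_ps = mean(cells$tau_mean_ps),
                   mean_beta = mean(cells$beta),
                   se_beta = sd(cells$beta) / sqrt(nrow(cells)),
                   se_tau_ps = sd(cells$tau_mean_ps) / sqrt(nrow(cells)),
                   n_cells = nrow(cells))
  })
  attr(out, "tau1_ps") <- tau1
  attr(out, "tau2_ps") <- tau2
  attr(out, "baseline_fit") <- base_fit
  out
}
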