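#' Simulation configuration
#'
#' Describes the emulated time-gated FLIM instrument and sample: a square
#' gate-width-dominated IRF, Poisson photon statistics, a constant camera
#' offset, a weak time-varying background from the culture medium, and a
#' column-wise linear gradient of IRF arrival times across the field of view.
#' Delay conventions: the excitation pulse arrives so that fluorescence
#' intensity peaks at `pulse_ps`; the measured scattered-light IRF occupies
#' `[pulse_ps - gate_width_ps, pulse_ps]` on the delay axis.
#'
#' @param n_row,n_col field-of-view size in pixels.
#' @param gate_width_ps intensifier gate width (ps); 4 ns standard.
#' @param edge_blur_ps Gaussian blur of the gate edges (ps, standard
#'   deviation); gated optical intensifiers switch over ~100-300 ps, so the
#'   response is a square smoothed at its edges, not an ideal step.
#' @param pulse_ps delay of peak intensity (ps).
#' @param sample_delays gate delays used for sample FLIM acquisitions (ps);
#'   default is the 7-gate log-spaced AutoGate scheme.
#' @param irf_scan,dye_scan fine 25 ps delay grids for the IRF and
#'   reference-dye acquisitions.
#' @param photons_per_pixel expected detected photons per in-cell pixel,
#'   summed over the sample gates (hundreds give ~10% single-exponential
#'   lifetime accuracy).
#' @param photons_irf,photons_dye per-pixel photon budgets of the
#'   calibration acquisitions (totals over the fine delay scan). Scattered
#'   excitation light and a concentrated dye solution are bright; the
#'   acquisition protocol fills ~75% of the camera's dynamic range, so
#'   hundreds of counts per 25 ps sample — not single counts — is the
#'   realistic regime.
#' @param camera_offset CCD offset (counts per gate frame) at the reference
#'   settings `integration_ms` x `n_accumulations`.
#' @param integration_ms,n_accumulations reference acquisition settings.
#' @param tvb_photons,tvb_tau_ps medium-background photon budget per pixel
#'   (summed over gates) and its decay time.
#' @param autofluor_photons photon budget of unlabeled-cell autofluorescence.
#' @param shift_gradient_ps peak-to-peak IRF arrival-time gradient across
#'   columns (ps), mean zero.
#' @param t0_ps true global shift of the fluorescence IRF relative to the
#'   scattered-light IRF (ps).
#' @param reference_lifetime_ps reference dye lifetime (Coumarin 6: 2430 ps).
#' @param n_cells,cell_radius_px,cell_sdlog,brightness_sdlog cell-shape model:
#'   random ellipses with lognormal semi-axes and per-cell lognormal
#'   brightness.
#' @param independent_forward if `TRUE`, expected counts are computed by
#'   numerical quadrature of the continuous square-gate IRF instead of the
#'   analysis code's discretized convolution — a guard ensuring parameter
#'   recovery is not an artifact of sharing one forward model.
#' @param dye_dim spatial size of calibration acquisitions.
#' @param seed RNG seed recorded in the output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_row = 64, n_col = 64,
                       gate_width_ps = 4000, edge_blur_ps = 100,
                       pulse_ps = 4300,
                       sample_delays = autogate_delays(4300, 16000, 7),
                       irf_scan = seq(0, 6000, by = 25),
                       dye_scan = seq(0, 16000, by = 25),
                       photons_per_pixel = 500,
                       photons_irf = 1e5, photons_dye = 1e5,
                       camera_offset = 50,
                       integration_ms = 250, n_accumulations = 1,
                       tvb_photons = 10, tvb_tau_ps = 600,
                       autofluor_photons = 3,
                       shift_gradient_ps = 50, t0_ps = 0,
                       reference_lifetime_ps = 2430,
                       n_cells = 12, cell_radius_px = 6, cell_sdlog = 0.25,
                       brightness_sdlog = 0.3,
                       independent_forward = FALSE,
                       dye_dim = 32, seed = 1) {
  stopifnot(photons_per_pixel > 0, photons_irf > 0, photons_dye > 0,
            gate_width_ps > 0, pulse_ps > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Column-wise IRF arrival-time offsets of the simulated field (ps, mean 0)
#' @param config a [sim_config()].
#' @export
sim_shift_cols <- function(config) {
  if (config$n_col == 1) return(0)
  config$shift_gradient_ps * (seq_len(config$n_col) - 1) / (config$n_col - 1) -
    config$shift_gradient_ps / 2
}

# density of the gate response: a square [lo, hi] with Gaussian edge blur
sim_irf_density <- function(u, lo, hi, blur) {
  w <- hi - lo
  if (blur <= 0) return(as.numeric(u >= lo & u <= hi) / w)
  (pnorm((u - lo) / blur) - pnorm((u - hi) / blur)) / w
}

# exact integral of the density over [a, b] via the closed-form
# antiderivative of the normal CDF: int Phi(x) dx = x Phi(x) + phi(x)
sim_irf_mass <- function(a, b, lo, hi, blur) {
  if (blur <= 0)
    return(pmax(pmin(b, hi) - pmax(a, lo), 0) / (hi - lo))
  iphi <- function(x, edge) {
    z <- (x - edge) / blur
    blur * (z * pnorm(z) + dnorm(z))
  }
  ((iphi(b, lo) - iphi(a, lo)) - (iphi(b, hi) - iphi(a, hi))) / (hi - lo)
}

#' The simulator's ground-truth IRF profile
#'
#' The gate-width-dominated instrument response — a square with Gaussian
#' edge blur — integrated over the 25 ps scan bins, optionally time-shifted:
#' the profile an ideal scattered-light measurement would recover.
#'
#' @param config a [sim_config()].
#' @param shift temporal shift (ps).
#' @return an [irf_profile()].
#' @export
sim_true_irf <- function(config, shift = 0) {
  grid <- config$irf_scan
  dt <- grid[2] - grid[1]
  lo <- config$pulse_ps - config$gate_width_ps + shift
  hi <- config$pulse_ps + shift
  mass <- sim_irf_mass(grid - dt / 2, grid + dt / 2, lo, hi,
                       config$edge_blur_ps)
  irf_profile(grid, pmax(mass, 0))
}

#' Expected per-gate fractions of the simulated decay
#'
#' Expected detected counts per gate for one total detected photon: the
#' exponential mixture convolved with the true square-gate IRF shifted by
#' `shift`. With `config$independent_forward = TRUE` the expectation is
#' computed by trapezoid quadrature of the continuous square IRF instead of
#' the analysis code's discretized convolution (the inverse-crime guard).
#'
#' @param config a [sim_config()].
#' @param delays gate delays (ps).
#' @param tau1,tau2,beta decay truth (ps, ps, fraction).
#' @param shift IRF shift (ps) including t0 and any per-column offset.
#' @return numeric vector summing to 1 over the gates.
#' @export
sim_unit_decay <- function(config, delays, tau1, tau2 = NULL, beta = 0,
                           shift = 0) {
  if (config$independent_forward) {
    # quadrature over the continuous gate-response density (trapezoid, 1 ps)
    blur <- config$edge_blur_ps
    lo <- config$pulse_ps - config$gate_width_ps + shift
    hi <- config$pulse_ps + shift
    one <- function(tau) {
      vapply(delays, function(d) {
        up <- min(d, hi + 5 * blur)
        lo2 <- lo - 5 * blur
        if (up <= lo2) return(0)
        u <- seq(lo2, up, by = 1)
        v <- exp(-pmax(d - u, 0) / tau) * (u <= d) *
          sim_irf_density(u, lo, hi, blur)
        sum((v[-1] + v[-length(v)]) / 2 * diff(u))
      }, numeric(1))
    }
    m <- (1 - beta) * one(tau1)
    if (!is.null(tau2) && beta > 0) m <- m + beta * one(tau2)
  } else {
    irf <- sim_true_irf(config)
    m <- convolve_with_irf(decay_params(max(tau1, tau2), min(tau1, tau2),
                                        beta = if (is.null(tau2)) 0 else
                                          if (tau2 <= tau1) beta else 1 - beta,
                                        shift_ps = shift),
                           irf, delays)
  }
  if (sum(m) <= 0) stop("decay model has no support at the requested delays")
  m / sum(m)
}

# random elliptical cells: returns integer label matrix
sim_cell_labels <- function(config) {
  lab <- matrix(0L, config$n_row, config$n_col)
  xs <- matrix(rep(seq_len(config$n_col), each = config$n_row),
               config$n_row)
  ys <- matrix(rep(seq_len(config$n_row), config$n_col), config$n_row)
  for (k in seq_len(config$n_cells)) {
    cx <- runif(1, 4, config$n_col - 3)
    cy <- runif(1, 4, config$n_row - 3)
    a <- stats::rlnorm(1, log(config$cell_radius_px), config$cell_sdlog)
    b <- stats::rlnorm(1, log(config$cell_radius_px), config$cell_sdlog)
    phi <- runif(1, 0, pi)
    xr <- (xs - cx) * cos(phi) + (ys - cy) * sin(phi)
    yr <- -(xs - cx) * sin(phi) + (ys - cy) * cos(phi)
    lab[(xr / a)^2 + (yr / b)^2 <= 1] <- k
  }
  lab
}

#' Simulate one field of view
#'
#' Produces a time-gated stack of cell-shaped regions decaying with the
#' condition's ground-truth parameters on a dark background, plus the truth
#' record. Expected counts per pixel and gate are the IRF-convolved decay
#' (with that column's IRF arrival offset and the global t0) plus the
#' time-varying medium background; Poisson noise is applied and the constant
#' camera offset added. Uses the current RNG state — seed via
#' [simulate_plate()] or `set.seed()`.
#'
#' @param config a [sim_config()].
#' @param condition list with `name`, `tau1_ps`, optional `tau2_ps`, `beta`;
#'   `photons = 0` gives a pure-background field.
#' @param well,fov identifiers stamped on the stack.
#' @return list with `stack` (a [flim_stack()]) and `truth` (`tau1_ps`,
#'   `tau2_ps`, `beta`, `tau_mean_ps`, `labels`, `amplitude_map`).
#' @export
simulate_fov <- function(config, condition, well = NA_character_,
                         fov = NA_integer_) {
  d <- config$sample_delays
  photons <- condition$photons %||% config$photons_per_pixel
  tau2 <- condition$tau2_ps %||% NULL
  beta <- condition$beta %||% 0
  shifts <- sim_shift_cols(config)

  expected <- array(0, c(config$n_row, config$n_col, length(d)))
  labels <- matrix(0L, config$n_row, config$n_col)
  amp <- matrix(0, config$n_row, config$n_col)
  if (photons > 0) {
    labels <- sim_cell_labels(config)
    bright <- stats::rlnorm(max(labels), 0, config$brightness_sdlog)
    amp[labels > 0] <- photons * bright[labels[labels > 0]]
    for (cc in which(colSums(labels > 0) > 0)) {
      m <- sim_unit_decay(config, d, condition$tau1_ps, tau2, beta,
                          shift = config$t0_ps + shifts[cc])
      rows <- which(labels[, cc] > 0)
      expected[rows, cc, ] <- outer(amp[rows, cc], m)
    }
  }
  if (config$tvb_photons > 0 && !isFALSE(condition$tvb)) {
    # the empty well carries no culture medium, hence no TVB
    mtvb <- sim_unit_decay(config, d, config$tvb_tau_ps, shift = config$t0_ps)
    for (g in seq_along(d))
      expected[, , g] <- expected[, , g] + config$tvb_photons * mtvb[g]
  }
  counts <- array(rpois(length(expected), expected), dim(expected)) +
    config$camera_offset
  st <- flim_stack(counts, d, width_ps = config$gate_width_ps,
                   integration_ms = config$integration_ms,
                   n_accumulations = config$n_accumulations,
                   well = well, fov = fov)
  list(stack = st,
       truth = list(tau1_ps = condition$tau1_ps, tau2_ps = tau2, beta = beta,
                    tau_mean_ps = mean_lifetime(condition$tau1_ps, tau2, beta),
                    labels = labels, amplitude_map = amp))
}

#' Simulate calibration acquisitions
#'
#' `simulate_irf_stack` scans the scattered-light IRF at 25 ps steps with the
#' configured column-wise arrival-time gradient (no t0 — the scattered IRF
#' defines the reference timing). `simulate_reference_dye` images a
#' monoexponential reference dye whose decay is convolved with the IRF
#' shifted by the true t0. `simulate_camera_background` returns the exact
#' offset frame.
#'
#' @param config a [sim_config()].
#' @return a [flim_stack()] (or [camera_background()]).
#' @export
simulate_irf_stack <- function(config) {
  d <- config$irf_scan
  dt <- d[2] - d[1]
  shifts <- sim_shift_cols(config)
  nr <- config$dye_dim; nc <- config$dye_dim
  shifts <- shifts[round(seq(1, config$n_col, length.out = nc))]
  expected <- array(0, c(nr, nc, length(d)))
  for (cc in seq_len(nc)) {
    lo <- config$pulse_ps - config$gate_width_ps + shifts[cc]
    hi <- config$pulse_ps + shifts[cc]
    mass <- pmax(sim_irf_mass(d - dt / 2, d + dt / 2, lo, hi,
                              config$edge_blur_ps), 0)
    expected[, cc, ] <- matrix(config$photons_irf * mass / sum(mass),
                               nr, length(d), byrow = TRUE)
  }
  counts <- array(rpois(length(expected), expected), dim(expected)) +
    config$camera_offset
  flim_stack(counts, d, width_ps = config$gate_width_ps,
             integration_ms = config$integration_ms,
             n_accumulations = config$n_accumulations, well = "IRF")
}

#' @rdname simulate_irf_stack
#' @export
simulate_reference_dye <- function(config) {
  d <- config$dye_scan
  shifts <- sim_shift_cols(config)
  nr <- config$dye_dim; nc <- config$dye_dim
  shifts <- shifts[round(seq(1, config$n_col, length.out = nc))]
  expected <- array(0, c(nr, nc, length(d)))
  for (cc in seq_len(nc)) {
    m <- sim_unit_decay(config, d, config$reference_lifetime_ps,
                        shift = config$t0_ps + shifts[cc])
    expected[, cc, ] <- matrix(config$photons_dye * m, nr, length(d),
                               byrow = TRUE)
  }
  counts <- array(rpois(length(expected), expected), dim(expected)) +
    config$camera_offset
  flim_stack(counts, d, width_ps = config$gate_width_ps,
             integration_ms = config$integration_ms,
             n_accumulations = config$n_accumulations, well = "H4")
}

#' @rdname simulate_irf_stack
#' @param nrow,ncol frame size; defaults to the FOV size.
#' @export
simulate_camera_background <- function(config, nrow = config$n_row,
                                       ncol = config$n_col) {
  camera_background(matrix(config$camera_offset, nrow, ncol),
                    integration_ms = config$integration_ms,
                    n_accumulations = config$n_accumulations)
}

# medium-only / empty / unlabeled control fields reuse simulate_fov
sim_control_condition <- function(config, role) {
  switch(role,
         medium_only = list(name = "medium", tau1_ps = config$tvb_tau_ps,
                            photons = 0),
         empty = list(name = "empty", tau1_ps = 1000, photons = 0,
                      tvb = FALSE),
         unlabeled_cells = list(name = "unlabeled", tau1_ps = 1500,
                                photons = config$autofluor_photons),
         stop("no control condition for role ", role))
}

#' Simulate a whole multiwell plate
#'
#' Generates sample FOVs for every sample well of the layout plus the
#' control-row acquisitions (empty, medium-only, unlabeled cells, reference
#' dye), the scattered-light IRF scan and the camera background.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param layout a [plate_layout()]; sample wells must have conditions named
#'   in `truths`.
#' @param truths named list of per-condition truth lists
#'   (`tau1_ps`, optional `tau2_ps`, `beta`).
#' @param n_fov fields of view per sample well.
#' @return list with `fovs` (tibble: `well`, `fov`, `role`, `condition`,
#'   `stack` list-column), `layout`, `truth` (tibble), `irf_stack`,
#'   `dye_stack`, `background`, `config`.
#' @export
simulate_plate <- function(config, layout, truths, n_fov = 4) {
  set.seed(config$seed)
  irf_stack <- simulate_irf_stack(config)
  dye_stack <- simulate_reference_dye(config)
  background <- simulate_camera_background(config)
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    w <- layout$well[i]; role <- layout$role[i]
    if (role == "reference_dye") next
    if (role %in% c("sample", "positive_control", "negative_control")) {
      cond <- truths[[layout$condition[i]]]
      if (is.null(cond)) stop("no truth supplied for condition ",
                              layout$condition[i])
      cond$name <- layout$condition[i]
      nf <- n_fov
    } else {
      cond <- sim_control_condition(config, role)
      nf <- if (role == "medium_only") n_fov else 1L
    }
    for (f in seq_len(nf)) {
      sim <- simulate_fov(config, cond, well = w, fov = f)
      rows[[length(rows) + 1]] <-
        tibble::tibble(well = w, fov = f, role = role,
                       condition = layout$condition[i],
                       stack = list(sim$stack), truth = list(sim$truth))
    }
  }
  truth_tbl <- purrr::map_dfr(names(truths), function(nm) {
    tr <- truths[[nm]]
    tibble::tibble(condition = nm, tau1_ps = tr$tau1_ps,
                   tau2_ps = tr$tau2_ps %||% NA_real_,
                   beta = tr$beta %||% 0,
                   tau_mean_ps = mean_lifetime(tr$tau1_ps, tr$tau2_ps %||% NULL,
                                               tr$beta %||% 0))
  })
  list(fovs = dplyr::bind_rows(rows), layout = layout, truth = truth_tbl,
       irf_stack = irf_stack, dye_stack = dye_stack, background = background,
       config = config)
}

#' Plate presets mirroring the exemplar experiments
#'
#' `simulate_construct_plate`: FRET model constructs (mTq5A/5V/17V/32V) with
#' monoexponential per-well mean-lifetime truths of 4008, 2717, 3004 and
#' 3133 ps. `simulate_dose_plate`: an inhibitor titration — 9 doses, 2
#' replicate wells each, 8 FOV per well — whose well-truth lifetime follows
#' the one-site logistic with the configured IC50, plus positive
#' (full-inhibition) and negative (vehicle) control wells.
#'
#' @param config a [sim_config()].
#' @param truths named vector of per-construct lifetimes (ps).
#' @param n_wells_per_condition sample wells per construct.
#' @param n_fov fields of view per well.
#' @return as [simulate_plate()]; the dose plate adds `dose_truth`.
#' @export
simulate_construct_plate <- function(config = sim_config(),
                                     truths = c(mTq5A = 4008, mTq5V = 2717,
                                                mTq17V = 3004, mTq32V = 3133),
                                     n_wells_per_condition = 3, n_fov = 4) {
  layout <- layout_construct_plate(names(truths),
                                   n_cols_per_condition = 1,
                                   n_sample_rows = n_wells_per_condition)
  simulate_plate(config, layout,
                 purrr::map(as.list(truths), ~ list(tau1_ps = .x)),
                 n_fov = n_fov)
}

#' @rdname simulate_construct_plate
#' @param ic50_M true IC50 (molar).
#' @param doses dose series (molar).
#' @param tau_neg_ps,tau_pos_ps negative (vehicle) and positive (full
#'   inhibition) control lifetimes (ps).
#' @param n_replicates replicate wells per dose.
#' @param compound compound label.
#' @export
simulate_dose_plate <- function(config = sim_config(n_row = 32, n_col = 32),
                                ic50_M = 38e-9,
                                doses = 10^seq(-9, -5, length.out = 9),
                                tau_neg_ps = 2600, tau_pos_ps = 2900,
                                n_replicates = 2, n_fov = 8,
                                compound = "ICL13") {
  tau_of <- function(c) tau_neg_ps + (tau_pos_ps - tau_neg_ps) * c / (c + ic50_M)
  wells <- character(0); roles <- character(0); conds <- character(0)
  concs <- numeric(0)
  for (i in seq_along(doses)) for (r in seq_len(n_replicates)) {
    wells <- c(wells, paste0(LETTERS[r], i + 1))
    roles <- c(roles, "sample")
    conds <- c(conds, sprintf("%s_d%02d", compound, i))
    concs <- c(concs, doses[i])
  }
  for (r in seq_len(n_replicates)) {
    wells <- c(wells, paste0(LETTERS[r], 1), paste0(LETTERS[r], 11))
    roles <- c(roles, "positive_control", "negative_control")
    conds <- c(conds, "positive", "negative")
    concs <- c(concs, NA, NA)
  }
  wells <- c(wells, "H1", "H2", "H4")
  roles <- c(roles, "empty", "medium_only", "reference_dye")
  conds <- c(conds, NA, NA, "coumarin6")
  concs <- c(concs, NA, NA, NA)
  layout <- plate_layout(wells, roles, conds, concs, "M")
  truths <- c(
    setNames(purrr::map(seq_along(doses),
                        ~ list(tau1_ps = tau_of(doses[.x]))),
             sprintf("%s_d%02d", compound, seq_along(doses))),
    list(positive = list(tau1_ps = tau_pos_ps),
         negative = list(tau1_ps = tau_neg_ps)))
  out <- simulate_plate(config, layout, truths, n_fov = n_fov)
  out$dose_truth <- tibble::tibble(compound = compound, ic50_M = ic50_M,
                                   doses_M = list(doses),
                                   tau_neg_ps = tau_neg_ps,
                                   tau_pos_ps = tau_pos_ps)
  out
}

#' Simulate a FRET biosensor time course
#'
#' One field of view imaged repeatedly; the FRETing donor fraction steps from
#' `beta_before` to `beta_after` at `step_s` (biosensor opening after
#' forskolin addition) while the component lifetimes stay fixed. The cell
#' layout is static so one segmentation mask serves all time points.
#'
#' @param config a [sim_config()].
#' @param times_s acquisition times (s).
#' @param tau1_ps,tau2_ps non-FRETing and FRETing donor lifetimes (ps).
#' @param beta_before,beta_after FRETing fractions before/after the step.
#' @param step_s time of the stimulus (s).
#' @return list with `stacks` (list of [flim_stack()]), `times_s`, `mask`
#'   (truth cell labels), `beta_truth`, `config`.
#' @export
simulate_timecourse <- function(config = sim_config(sample_delays =
                                  c(1300, 4300, 4919, 6656, 8035, 10391, 16000)),
                                times_s = seq(0, 600, by = 10),
                                tau1_ps = 3964, tau2_ps = 3022,
                                beta_before = 0.4, beta_after = 0.1,
                                step_s = 120) {
  set.seed(config$seed)
  labels <- sim_cell_labels(config)
  bright <- stats::rlnorm(max(labels), 0, config$brightness_sdlog)
  amp <- matrix(0, config$n_row, config$n_col)
  amp[labels > 0] <- config$photons_per_pixel * bright[labels[labels > 0]]
  shifts <- sim_shift_cols(config)
  d <- config$sample_delays
  beta_truth <- ifelse(times_s < step_s, beta_before, beta_after)
  mtvb <- sim_unit_decay(config, d, config$tvb_tau_ps, shift = config$t0_ps)
  stacks <- purrr::map(seq_along(times_s), function(i) {
    expected <- array(0, c(config$n_row, config$n_col, length(d)))
    for (cc in which(colSums(labels > 0) > 0)) {
      m <- sim_unit_decay(config, d, tau1_ps, tau2_ps, beta_truth[i],
                          shift = config$t0_ps + shifts[cc])
      rows <- which(labels[, cc] > 0)
      expected[rows, cc, ] <- outer(amp[rows, cc], m)
    }
    for (g in seq_along(d))
      expected[, , g] <- expected[, , g] + config$tvb_photons * mtvb[g]
    counts <- array(rpois(length(expected), expected), dim(expected)) +
      config$camera_offset
    flim_stack(counts, d, width_ps = config$gate_width_ps,
               integration_ms = config$integration_ms,
               n_accumulations = config$n_accumulations,
               well = "A1", fov = 1L)
  })
  list(stacks = stacks, times_s = times_s, mask = labels,
       beta_truth = beta_truth, tau1_ps = tau1_ps, tau2_ps = tau2_ps,
       config = config)
}

#' Calibrate a simulated plate
#'
#' Runs the standard calibration chain on a simulated plate's ancillary
#' acquisitions: camera background, TVB from the medium-only well, IRF
#' profile and shift map from the scattered-light scan, and t0 from the
#' reference dye.
#'
#' @param plate output of [simulate_plate()] or a preset.
#' @param use_tvb include the TVB model (default yes).
#' @param shift_map_fov estimate the shift map at FOV resolution by scaling
#'   the calibration-frame map to the FOV size (the simulator's gradient is
#'   column-wise).
#' @return a [flim_calibration()].
#' @export
calibrate_simulated_plate <- function(plate, use_tvb = TRUE,
                                      shift_map_fov = TRUE) {
  cfg <- plate$config
  bg_cal <- camera_background(matrix(cfg$camera_offset, cfg$dye_dim,
                                     cfg$dye_dim),
                              cfg$integration_ms, cfg$n_accumulations)
  irf <- create_irf_profile(plate$irf_stack, bg_cal)
  sm_small <- create_irf_shift_map(plate$irf_stack, bg_cal,
                                   min_counts = cfg$photons_irf / 10)
  t0 <- estimate_t0(plate$dye_stack, irf, cfg$reference_lifetime_ps,
                    shift_map = sm_small, background = bg_cal)
  tvb <- NULL
  if (use_tvb) {
    med <- plate$fovs$stack[plate$fovs$role == "medium_only"]
    if (length(med) > 0)
      tvb <- create_tvb(med, plate$background)
  }
  shift_map <- NULL
  if (shift_map_fov) {
    # calibration frames are column-parallel to the FOV; rescale columns
    colshift <- colMeans(sm_small)
    idx <- round(seq(1, length(colshift), length.out = cfg$n_col))
    shift_map <- matrix(colshift[idx], cfg$n_row, cfg$n_col, byrow = TRUE)
    shift_map <- shift_map - mean(shift_map)
  }
  flim_calibration(irf, t0 = as.numeric(t0), shift_map = shift_map,
                   background = plate$background, tvb = tvb)
}
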