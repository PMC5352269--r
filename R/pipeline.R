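#' End-to-end analysis pipeline
#'
#' Wires the stages of a plate analysis in acquisition-protocol order:
#' background check, TVB construction, IRF shift map, t0 from the reference
#' dye, decay fitting, and plate reporting. Operates on a simulated plate
#' (or any object with the same structure) and writes its artifacts — layout,
#' well summaries, plate map, calibration bundle and the verbatim
#' configuration with its hash — to `out_dir`.
#'
#' @param plate a [simulate_plate()]-shaped object.
#' @param out_dir output directory.
#' @param model `"mono"` or `"biexp"` (pixel-wise fitting is monoexponential;
#'   `"biexp"` adds a globally binned two-component fit per FOV).
#' @param options a [fit_options()].
#' @param use_tvb set `FALSE` to skip TVB correction (recorded in the run
#'   info).
#' @param background_warn_fraction warn when a control well's mean intensity
#'   exceeds this fraction of the sample signal (protocol acceptance check,
#'   default 1%).
#' @return list with `summaries` (well tibble), `calibration`, `fit`,
#'   `artifacts` (paths), invisibly writable diagnostics in `checks`.
#' @export
run_pipeline <- function(plate, out_dir, model = "mono",
                         options = fit_options(), use_tvb = TRUE,
                         background_warn_fraction = 0.01) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage: background acceptance check (control vs donor-only signal)
  checks <- stage("background-check", {
    samp <- plate$fovs |> dplyr::filter(.data$role == "sample")
    ctrl <- plate$fovs |> dplyr::filter(.data$role %in%
                                          c("empty", "medium_only",
                                            "unlabeled_cells"))
    if (nrow(samp) == 0) stop("plate has no sample FOVs")
    sig <- mean(purrr::map_dbl(samp$stack[seq_len(min(4, nrow(samp)))],
                               ~ mean(total_intensity_image(
                                 subtract_camera_background(.x, plate$background)))))
    purrr::map_dfr(seq_len(nrow(ctrl)), function(i) {
      r <- mean(total_intensity_image(
        subtract_camera_background(ctrl$stack[[i]], plate$background))) / sig
      if (r > background_warn_fraction)
        warning("well ", ctrl$well[i], " (", ctrl$role[i], ") background is ",
                signif(100 * r, 3), "% of the sample signal", call. = FALSE)
      tibble::tibble(well = ctrl$well[i], role = ctrl$role[i],
                     background_fraction = r)
    })
  })

  # stages: TVB, shift map, t0 (calibration products)
  calibration <- stage("calibration", {
    if (is.null(plate$irf_stack)) stop("missing IRF calibration acquisition")
    calibrate_simulated_plate(plate, use_tvb = use_tvb)
  })

  # stage: fit
  fit <- stage("fit", {
    samp <- plate$fovs |> dplyr::filter(.data$role %in%
                                          c("sample", "positive_control",
                                            "negative_control"))
    fit_pixelwise(samp$stack, calibration, options)
  })

  # stage: report
  artifacts <- stage("report", {
    summaries <- aggregate_plate(fit, plate$layout, level = "well")
    paths <- list(
      layout = file.path(out_dir, "layout.csv"),
      summaries = file.path(out_dir, "well_summaries.csv"),
      calibration = file.path(out_dir, "calibration"),
      config = file.path(out_dir, "config.json"),
      run_info = file.path(out_dir, "run_info.json"))
    write_plate_layout(plate$layout, paths$layout)
    write.csv(summaries[, !vapply(summaries, is.list, TRUE)],
              paths$summaries, row.names = FALSE)
    write_calibration(calibration, paths$calibration)
    cfg <- plate$config
    jsonlite::write_json(cfg[!vapply(cfg, is.function, TRUE)], paths$config,
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(
      list(config_md5 = unname(tools::md5sum(paths$config)),
           use_tvb = use_tvb, model = model,
           t0_ps = calibration$t0,
           n_fovs_fit = length(unique(paste(fit$pixels$well,
                                            fit$pixels$fov)))),
      paths$run_info, auto_unbox = TRUE, digits = NA)
    paths
  })
  summaries <- aggregate_plate(fit, plate$layout, level = "well")
  list(summaries = summaries, calibration = calibration, fit = fit,
       checks = checks, artifacts = artifacts)
}
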