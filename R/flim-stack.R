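#' Time-gated FLIM image stack
#'
#' A `flim_stack` holds one field of view of wide-field time-gated FLIM data:
#' a cube of detected counts, one 2-D frame per gate delay, together with the
#' acquisition metadata needed downstream (gate width, camera integration time,
#' frame accumulations). Counts are stored `[row, col, gate]` with gates in
#' strictly increasing delay order.
#'
#' @param counts numeric array `[row, col, gate]` of non-negative counts, or a
#'   matrix for a single gate.
#' @param delay_ps numeric vector of gate delays (ps), one per gate plane.
#' @param width_ps gate width (ps); the gated optical intensifier's gate
#'   duration, typically 4000 ps.
#' @param integration_ms camera integration time per frame (ms).
#' @param n_accumulations number of frames summed per gate (>= 1).
#' @param well,fov optional identifiers (e.g. `"A1"`, `1L`).
#'
#' @return An object of class `flim_stack` with elements `counts`, `gates`
#'   (a tibble with one row per gate), `well`, `fov`.
#' @export
#' @examples
#' st <- flim_stack(array(1, c(4, 4, 3)), delay_ps = c(1000, 2000, 4000))
#' total_intensity_image(st)
flim_stack <- function(counts, delay_ps, width_ps = 4000,
                       integration_ms = 250, n_accumulations = 1,
                       well = NA_character_, fov = NA_integer_) {
  if (is.matrix(counts)) counts <- array(counts, c(dim(counts), 1L))
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  delay_ps <- as.numeric(delay_ps)
  if (length(delay_ps) != dim(counts)[3L])
    stop("number of delays (", length(delay_ps),
         ") does not match number of gate planes (", dim(counts)[3L], ")")
  if (anyNA(delay_ps)) stop("gate delays must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  ord <- order(delay_ps)
  if (any(diff(delay_ps[ord]) <= 0)) stop("gate delays must be distinct")
  counts <- counts[, , ord, drop = FALSE]
  gates <- tibble::tibble(
    delay_ps = delay_ps[ord],
    width_ps = rep_len(as.numeric(width_ps), length(delay_ps)),
    integration_ms = rep_len(as.numeric(integration_ms), length(delay_ps)),
    n_accumulations = rep_len(as.integer(n_accumulations), length(delay_ps))
  )
  if (any(gates$width_ps <= 0) || any(gates$integration_ms <= 0) ||
      any(gates$n_accumulations < 1L))
    stop("gate width and integration time must be positive, accumulations >= 1")
  structure(
    list(counts = counts, gates = gates,
         well = well, fov = fov),
    class = "flim_stack"
  )
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat("<flim_stack> ", d[1], "x", d[2], " px, ", d[3], " gates (",
      min(x$gates$delay_ps), "-", max(x$gates$delay_ps), " ps)",
      if (!is.na(x$well)) paste0(", well ", x$well),
      if (!is.na(x$fov)) paste0(" fov ", x$fov), "\n", sep = "")
  invisible(x)
}

#' @rdname flim_stack
#' @param x object to test.
#' @export
is_flim_stack <- function(x) inherits(x, "flim_stack")

#' Gate delays of a stack
#' @param stack a [flim_stack()].
#' @return numeric vector of delays (ps), ascending.
#' @export
gate_delays <- function(stack) stack$gates$delay_ps

#' Total (time-integrated) intensity image
#'
#' Sums detected counts over all gates, giving the steady-state-like intensity
#' image used for display overlays and intensity thresholding.
#'
#' @param stack a [flim_stack()].
#' @return numeric matrix `[row, col]`.
#' @export
total_intensity_image <- function(stack) {
  stopifnot(is_flim_stack(stack))
  rowSums(stack$counts, dims = 2L)
}

#' Threshold a stack on total intensity
#'
#' Selects pixels whose summed intensity over gates exceeds `threshold`,
#' returning a segmentation mask (1 = selected, 0 = background).
#'
#' @param stack a [flim_stack()].
#' @param threshold non-negative intensity cutoff (counts, summed over gates).
#' @return integer label matrix, same spatial shape as one gate frame.
#' @export
apply_intensity_threshold <- function(stack, threshold) {
  stopifnot(threshold >= 0)
  tot <- total_intensity_image(stack)
  mask <- matrix(0L, nrow(tot), ncol(tot))
  mask[tot > threshold] <- 1L
  mask
}

#' Pool pixel decays over a region of interest (global binning)
#'
#' Aggregates detected photons over the selected pixels at each gate, the
#' "global binning" step that supplies enough photons to fit complex decay
#' models. Photons are conserved: the output sums to the total masked counts.
#'
#' @param stack a [flim_stack()].
#' @param mask integer label matrix matching the stack's spatial shape;
#'   pixels with label > 0 are pooled. Alternatively a logical matrix.
#' @param by_label if `TRUE`, return one pooled decay per non-zero label
#'   (e.g. per segmented cell) instead of pooling all selected pixels.
#' @return A tibble with columns `delay_ps`, `counts` (and `label` when
#'   `by_label = TRUE`).
#' @export
bin_pixels <- function(stack, mask, by_label = FALSE) {
  stopifnot(is_flim_stack(stack))
  if (is.logical(mask)) mask <- array(as.integer(mask), dim(mask))
  if (!identical(dim(mask), dim(stack$counts)[1:2]))
    stop("mask shape does not match stack frames")
  sel <- mask > 0L
  if (!any(sel)) stop("empty ROI: no pixels selected")
  ng <- dim(stack$counts)[3L]
  flat <- matrix(stack$counts, ncol = ng)  # pixels x gates
  if (!by_label) {
    return(tibble::tibble(delay_ps = stack$gates$delay_ps,
                          counts = colSums(flat[as.vector(sel), , drop = FALSE])))
  }
  labs <- sort(unique(mask[sel]))
  purrr::map_dfr(labs, function(l) {
    tibble::tibble(label = l, delay_ps = stack$gates$delay_ps,
                   counts = colSums(flat[as.vector(mask == l), , drop = FALSE]))
  })
}
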