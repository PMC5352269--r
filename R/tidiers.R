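#' Tidy a FLIM fit
#'
#' For binned/global fits, the parameter table (term, estimate, std_error);
#' for map fits, the per-pixel tibble.
#'
#' @param x a `flim_fit`.
#' @param ... unused.
#' @export
tidy.flim_fit <- function(x, ...) {
  if (!is.null(x$params)) return(x$params)
  x$pixels
}

#' @rdname tidy.flim_fit
#' @export
glance.flim_fit <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    n_exp = x$model$n_exp,
    n_pixels = if (!is.null(x$pixels)) nrow(x$pixels) else x$n_pixels %||% NA,
    chisq_reduced = x$chisq %||%
      if (!is.null(x$pixels) && "chisq" %in% names(x$pixels))
        median(x$pixels$chisq) else NA_real_,
    degenerate = isTRUE(x$degenerate))
}

#' @rdname tidy.flim_fit
#' @export
tidy.dose_response <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.flim_fit
#' @export
glance.dose_response <- function(x, ...) {
  tibble::tibble(ic50_M = ic50(x),
                 ci_low_M = attr(x, "ci95_M")[1],
                 ci_high_M = attr(x, "ci95_M")[2],
                 flag_residual = attr(x, "flag_residual"))
}
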