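#' Multiwell plate layouts
#'
#' A plate layout maps wells ("A1"-style: row letter + 1-based column) to the
#' condition in each well. `role` follows the control-well semantics of a FLIM
#' FRET screening plate: sample wells plus an empty well (static plate
#' background), a medium-only well (time-varying background), an
#' unlabeled-cells well (autofluorescence check) and a reference-dye well
#' (t0 calibration).
#'
#' @param well character vector of well ids ("A1" ... "H12").
#' @param role one of `"sample"`, `"positive_control"`, `"negative_control"`,
#'   `"empty"`, `"medium_only"`, `"unlabeled_cells"`, `"reference_dye"`.
#' @param condition construct/compound name (NA for non-sample wells).
#' @param concentration numeric dose (NA where not applicable).
#' @param concentration_units units string, e.g. `"M"`.
#' @param n_rows,n_cols plate geometry (default 8 x 12, a 96-well plate).
#' @return A tibble of class `plate_layout`.
#' @export
plate_layout <- function(well, role, condition = NA_character_,
                         concentration = NA_real_,
                         concentration_units = NA_character_,
                         n_rows = 8, n_cols = 12) {
  roles <- c("sample", "positive_control", "negative_control", "empty",
             "medium_only", "unlabeled_cells", "reference_dye")
  if (!all(role %in% roles))
    stop("unknown role(s): ", paste(setdiff(role, roles), collapse = ", "))
  if (anyDuplicated(well)) stop("each well may appear only once in a layout")
  ok <- grepl("^[A-Z][0-9]+$", well) &
    match(substr(well, 1, 1), LETTERS) <= n_rows &
    as.integer(sub("^[A-Z]", "", well)) <= n_cols
  if (!all(ok)) stop("well ids outside plate geometry: ",
                     paste(well[!ok], collapse = ", "))
  out <- tibble::tibble(well = well, role = role,
                        condition = rep_len(condition, length(well)),
                        concentration = rep_len(concentration, length(well)),
                        concentration_units = rep_len(concentration_units,
                                                      length(well)))
  attr(out, "n_rows") <- n_rows
  attr(out, "n_cols") <- n_cols
  class(out) <- c("plate_layout", class(out))
  out
}

#' Row letter and column number of a well id
#' @param well character vector of "A1"-style ids.
#' @return tibble with `row` (integer), `col` (integer).
#' @export
well_position <- function(well) {
  tibble::tibble(row = match(substr(well, 1, 1), LETTERS),
                 col = as.integer(sub("^[A-Z]", "", well)))
}

#' Read / write a plate layout CSV
#'
#' CSV columns: `well,role,condition,concentration,concentration_units`.
#'
#' @param path file path.
#' @return `read_plate_layout` returns a [plate_layout()].
#' @export
read_plate_layout <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "condition", "concentration", "concentration_units")
  if (!all(need %in% names(d)))
    stop("layout CSV must have columns: ", paste(need, collapse = ", "))
  plate_layout(d$well, d$role, d$condition, as.numeric(d$concentration),
               d$concentration_units)
}

#' @rdname read_plate_layout
#' @param layout a [plate_layout()].
#' @export
write_plate_layout <- function(layout, path) {
  write.csv(as.data.frame(layout)[, c("well", "role", "condition",
                                      "concentration", "concentration_units")],
            path, row.names = FALSE)
  invisible(path)
}

#' Construct-plate layout with protocol-style control row
#'
#' Builds a 96-well layout in which sample constructs occupy blocks of columns
#' in rows A-G and row H carries the control wells: H1 empty, H2 medium only,
#' H3 unlabeled cells, H4 reference dye.
#'
#' @param conditions character vector of construct names, assigned to
#'   consecutive column blocks.
#' @param n_cols_per_condition columns per construct block.
#' @param n_sample_rows number of sample rows (from row A).
#' @return A [plate_layout()].
#' @export
layout_construct_plate <- function(conditions = c("mTq5A", "mTq5V", "mTq17V", "mTq32V"),
                                   n_cols_per_condition = 3,
                                   n_sample_rows = 7) {
  wells <- character(0); roles <- character(0); conds <- character(0)
  for (i in seq_along(conditions)) {
    cols <- (i - 1) * n_cols_per_condition + seq_len(n_cols_per_condition)
    for (cc in cols) for (r in seq_len(n_sample_rows)) {
      wells <- c(wells, paste0(LETTERS[r], cc))
      roles <- c(roles, "sample")
      conds <- c(conds, conditions[i])
    }
  }
  wells <- c(wells, "H1", "H2", "H3", "H4")
  roles <- c(roles, "empty", "medium_only", "unlabeled_cells", "reference_dye")
  conds <- c(conds, NA, NA, NA, "coumarin6")
  plate_layout(wells, roles, conds)
}
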