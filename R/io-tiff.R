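#' Read a time-gated stack from a TIFF series
#'
#' One 16-bit grayscale TIFF per gate; each filename encodes its gate delay in
#' picoseconds in a fixed-width token `_DEL<ps>_` (e.g. `fov1_DEL004300_.tif`).
#' Gates are sorted ascending by delay on read.
#'
#' @param directory directory containing the series.
#' @param pattern filename filter (regular expression).
#' @param width_ps,integration_ms,n_accumulations acquisition metadata not
#'   carried by plain TIFF; supplied by the caller.
#' @param well,fov identifiers attached to the stack.
#' @return A [flim_stack()].
#' @export
read_tiff_series <- function(directory, pattern = "\\.tiff?$",
                             width_ps = 4000, integration_ms = 250,
                             n_accumulations = 1,
                             well = NA_character_, fov = NA_integer_) {
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) stop("no TIFF files found in ", directory)
  m <- regmatches(basename(files), regexpr("_DEL[0-9]+_", basename(files)))
  if (length(m) != length(files))
    stop("format error: some filenames lack a _DEL<ps>_ delay token")
  delays <- as.numeric(gsub("[^0-9]", "", m))
  if (anyDuplicated(delays))
    stop("format error: duplicate gate delay in TIFF series: ",
         paste(delays[duplicated(delays)], collapse = ", "))
  imgs <- lapply(files, read_counts_tiff)
  dims <- unique(lapply(imgs, dim))
  if (length(dims) != 1)
    stop("shape error: TIFF series images have inconsistent dimensions")
  counts <- array(unlist(imgs), c(dims[[1]], length(imgs)))
  flim_stack(counts, delays, width_ps = width_ps,
             integration_ms = integration_ms,
             n_accumulations = n_accumulations, well = well, fov = fov)
}

#' @rdname read_tiff_series
#' @param stack a [flim_stack()].
#' @param prefix filename prefix for the written series.
#' @export
write_tiff_series <- function(stack, directory, prefix = "gate") {
  stopifnot(is_flim_stack(stack))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(directory, sprintf("%s_DEL%06d_.tif", prefix,
                                        round(stack$gates$delay_ps)))
  for (g in seq_len(nrow(stack$gates)))
    write_counts_tiff(stack$counts[, , g], paths[g])
  invisible(paths)
}

# 16-bit grayscale count image; tiff stores data in [0,1]
read_counts_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  round(x * 65535)
}

write_counts_tiff <- function(img, path) {
  if (any(img < 0) || any(img > 65535))
    stop("counts outside 16-bit range cannot be written")
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read / write a segmentation mask as a 16-bit label TIFF
#' @param path file path.
#' @return `read_mask_tiff` returns an integer label matrix (0 = background).
#' @export
read_mask_tiff <- function(path) {
  m <- read_counts_tiff(path)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_mask_tiff
#' @param mask integer label matrix.
#' @export
write_mask_tiff <- function(mask, path) write_counts_tiff(mask, path)

#' OME-TIFF-style stack I/O
#'
#' Writes a multi-page 16-bit TIFF with planes along the T dimension and an
#' OME companion XML file (`<stem>.companion.ome`) recording, per plane, the
#' gate delay under the annotation key `flim:delay_ps`, plus image-level gate
#' width, integration time and accumulation count. The reader requires the
#' companion file and re-sorts planes ascending by delay, so write-then-read
#' is the identity on counts (bit-exact) and delays regardless of plane order
#' in the file.
#'
#' @param path path to the `.ome.tif` file; the companion sits next to it.
#' @param stack a [flim_stack()].
#' @param plane_order optional permutation of gate indices controlling the
#'   physical plane order in the file (metadata follows; mainly for testing).
#' @return `read_ome_tiff` returns a [flim_stack()].
#' @export
write_ome_tiff <- function(stack, path, plane_order = NULL) {
  stopifnot(is_flim_stack(stack))
  ng <- nrow(stack$gates)
  if (is.null(plane_order)) plane_order <- seq_len(ng)
  plane_order <- as.integer(plane_order)
  stopifnot(all(sort(plane_order) == seq_len(ng)))
  planes <- lapply(plane_order, function(g) stack$counts[, , g] / 65535)
  if (any(unlist(planes) < 0) || any(unlist(planes) > 1))
    stop("counts outside 16-bit range cannot be written")
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)

  doc <- xml2::xml_new_root("OME", "xmlns:flim" = "urn:gatedflim:flim-annotations")
  img <- xml2::xml_add_child(doc, "Image")
  if (!is.na(stack$well)) xml2::xml_set_attr(img, "Well", stack$well)
  if (!is.na(stack$fov)) xml2::xml_set_attr(img, "FOV", stack$fov)
  px <- xml2::xml_add_child(img, "Pixels", SizeT = as.character(ng),
                            `flim:width_ps` = format(stack$gates$width_ps[1]),
                            `flim:integration_ms` = format(stack$gates$integration_ms[1]),
                            `flim:n_accumulations` = format(stack$gates$n_accumulations[1]))
  for (i in seq_len(ng))
    xml2::xml_add_child(px, "Plane", TheT = as.character(i - 1),
                        `flim:delay_ps` = format(stack$gates$delay_ps[plane_order[i]],
                                                 scientific = FALSE))
  xml2::write_xml(doc, companion_path(path))
  invisible(path)
}

#' @rdname write_ome_tiff
#' @export
read_ome_tiff <- function(path) {
  comp <- companion_path(path)
  if (!file.exists(comp))
    stop("format error: OME companion file not found: ", comp)
  doc <- xml2::read_xml(comp)
  planes_md <- xml2::xml_find_all(doc, ".//Plane")
  delays <- as.numeric(flim_attr(planes_md, "delay_ps"))
  if (length(delays) == 0 || anyNA(delays))
    stop("format error: per-plane flim:delay_ps metadata absent")
  px <- xml2::xml_find_first(doc, ".//Pixels")
  img <- xml2::xml_find_first(doc, ".//Image")
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) != length(delays))
    stop("format error: plane count does not match metadata")
  thet <- as.integer(xml2::xml_attr(planes_md, "TheT")) + 1L
  counts <- array(0, c(dim(planes[[1]]), length(planes)))
  for (i in seq_along(planes)) counts[, , i] <- round(planes[[thet[i]]] * 65535)
  fov <- xml2::xml_attr(img, "FOV")
  flim_stack(counts, delays,
             width_ps = as.numeric(flim_attr(px, "width_ps")),
             integration_ms = as.numeric(flim_attr(px, "integration_ms")),
             n_accumulations = as.numeric(flim_attr(px, "n_accumulations")),
             well = xml2::xml_attr(img, "Well"),
             fov = if (is.na(fov)) NA_integer_ else as.integer(fov))
}

# namespaced annotation lookup tolerant of prefix handling differences
flim_attr <- function(node, name) {
  a <- xml2::xml_attr(node, name)
  miss <- is.na(a)
  if (any(miss))
    a[miss] <- xml2::xml_attr(node, paste0("flim:", name))[miss]
  a
}

companion_path <- function(path) {
  paste0(sub("\\.ome\\.tiff?$|\\.tiff?$", "", path), ".companion.ome")
}

# 32-bit float map TIFF with range stored in a JSON sidecar so arbitrary
# (incl. negative) values survive the tiff package's [0,1] data model
write_map_tiff <- function(map, path) {
  rng <- range(map, finite = TRUE)
  scaled <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  jsonlite::write_json(list(min = rng[1], max = rng[2]),
                       paste0(path, ".range.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_map_tiff <- function(path) {
  rng <- jsonlite::read_json(paste0(path, ".range.json"))
  x <- tiff::readTIFF(path)
  x * (rng$max - rng$min) + rng$min
}
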