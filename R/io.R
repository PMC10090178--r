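#' Read a TIFF slide as a matrix (or RGB array)
#'
#' @param path TIFF file path.
#' @return Integer matrix (grayscale) scaled back to its stored bit depth,
#'   or a numeric array for RGB input (pass to [to_8bit_gray()]).
#' @export
read_slide_tiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (is.matrix(x)) matrix(as.integer(x), nrow(x), ncol(x)) else x
}

#' Write an 8-bit grayscale image to TIFF
#'
#' @param img Matrix with values 0..255.
#' @param path Output path.
#' @export
write_image_tiff <- function(img, path) {
  tiff::writeTIFF(img / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write an instance label map to 16-bit TIFF
#'
#' @param labels Integer matrix (0 = background); must not exceed 65535.
#' @param path Output path.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535L) abort("More than 65535 instances.")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label map TIFF
#'
#' @param path TIFF path written by [write_labels_tiff()].
#' @return Integer label matrix.
#' @export
read_labels_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

#' Read an ROI polygon JSON
#'
#' Expected shape: `{"label": str, "pixel_size_um": num,
#' "vertices_px": [[row, col], ...]}` with 0-based pixel indices; vertices
#' are converted to the package's 1-based convention.
#'
#' @param path JSON path.
#' @return List with `label`, `pixel_size_um`, `vertices` (1-based matrix).
#' @export
read_roi_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  v <- matrix(as.numeric(unlist(x$vertices_px)), ncol = 2, byrow = !is.matrix(x$vertices_px))
  if (is.matrix(x$vertices_px)) v <- x$vertices_px
  list(label = x$label, pixel_size_um = x$pixel_size_um,
       vertices = v + 1)
}

#' Write an ROI polygon JSON
#'
#' @param vertices 1-based (row, col) vertex matrix.
#' @param label Subregion label.
#' @param pixel_size_um Pixel size.
#' @param path Output path.
#' @export
write_roi_json <- function(vertices, label, pixel_size_um, path) {
  jsonlite::write_json(
    list(label = label, pixel_size_um = pixel_size_um,
         vertices_px = unname(as.matrix(vertices)) - 1),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Provenance sidecar: config hash, seed, package versions, free-form fields.
write_sidecar <- function(path, config = list(), seed = NULL, ...) {
  jsonlite::write_json(
    list(config_hash = rlang::hash(config), seed = seed,
         nisslcount_version = as.character(packageVersion("nisslcount")),
         r_version = R.version.string,
         created = format(Sys.time(), tz = "UTC"), ...),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the per-segment ledger CSV
#'
#' Columns: partition_id, segment_id, pixel_count, mean_gray, minor_px,
#' diameter_um, status, removal_reason.
#'
#' @param records Segment-record tibble.
#' @param partition_id Identifier written into every row.
#' @param path Output CSV path.
#' @export
write_ledger_csv <- function(records, partition_id, path) {
  out <- records %>%
    mutate(partition_id = partition_id) %>%
    select("partition_id", segment_id = "id", "pixel_count", "mean_gray",
           "minor_px", "diameter_um", "status", "removal_reason")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
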