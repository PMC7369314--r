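# File formats: 8-bit grayscale TIFF for micrographs, 0/255 PNG for masks,
# JSON for ground truth, CSV for section series and cohorts, YAML for image
# specs.

#' Read and write micrographs as 8-bit grayscale TIFF
#'
#' Images are numeric matrices on the 0--255 scale in memory and 8-bit
#' grayscale TIFF on disk.
#'
#' @param image Numeric matrix with intensities in \[0, 255\].
#' @param path File path.
#' @return `read_micrograph()` returns the image matrix;
#'   `write_micrograph()` returns `path` invisibly.
#' @export
write_micrograph <- function(image, path) {
  check_image_matrix(image)
  tiff::writeTIFF(image / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_micrograph
#' @export
read_micrograph <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- to_grayscale(x * 255) else x <- round(x * 255)
  check_image_matrix(x)
  x
}

#' Read and write ROI masks as 0/255 PNG
#'
#' @param mask Logical matrix (TRUE = inside the ROI).
#' @param path File path.
#' @return `read_roi_mask()` returns a logical matrix; `write_roi_mask()`
#'   returns `path` invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("'mask' must be a logical matrix", call. = FALSE)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x > 0.5
}

#' Read and write micrograph ground truth as JSON
#'
#' Serializes the `truth` element of a [generate_micrograph()] result: the
#' cell centres, the cell count, and the artifact pixel sets.
#'
#' @param truth Ground-truth list (`cell_centers`, `n_cells`,
#'   `artifact_pixels`).
#' @param path File path.
#' @return `read_ground_truth()` returns the ground-truth list;
#'   `write_ground_truth()` returns `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(cell_centers = truth$cell_centers,
         n_cells = truth$n_cells,
         artifact_pixels = truth$artifact_pixels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cell_centers <- as.data.frame(x$cell_centers)
  x$n_cells <- as.integer(x$n_cells)
  x$artifact_pixels <- lapply(x$artifact_pixels, as.integer)
  x
}

#' Read and write section tables as CSV
#'
#' Section tables hold one row per sampled section with columns `animal_id`,
#' `bregma_mm`, `area_mm2`, `count`.
#'
#' @param series A [section_series()].
#' @param path File path.
#' @param animal_id Animal identifier written with each row.
#' @return `read_section_table()` returns a data frame;
#'   `write_section_table()` returns `path` invisibly.
#' @export
write_section_table <- function(series, path, animal_id = "animal_1") {
  stopifnot(inherits(series, "section_series"))
  df <- cbind(animal_id = animal_id, series$records)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_section_table
#' @export
read_section_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "bregma_mm", "area_mm2", "count")
  if (!all(req %in% names(df)))
    stop("section table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  df
}

#' Read and write cohort tables as CSV
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @param path File path.
#' @return `read_cohort_csv()` returns the cohort data frame (class
#'   `cohort`); `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  if (!is.data.frame(cohort)) stop("'cohort' must be a data frame", call. = FALSE)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("animal_id", "sex", "time_point", "region"))
    if (!col %in% names(df))
      stop(sprintf("cohort table lacks required column '%s'", col), call. = FALSE)
  class(df) <- c("cohort", "data.frame")
  df
}

#' Read an image spec from a YAML file
#'
#' The YAML keys mirror the arguments of [image_spec()]; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return An [image_spec()].
#' @export
read_image_spec_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(image_spec))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown image spec field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(image_spec, vals)
}
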