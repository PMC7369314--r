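#' Assign a bregma coordinate to the dorsal or ventral dentate gyrus
#'
#' Dorsal sections span bregma -1.80 to -4.52 mm and ventral sections
#' -4.52 to -6.80 mm. The shared boundary at -4.52 mm is assigned to the
#' ventral region (dorsal is the half-open interval (-4.52, -1.80]), so the
#' two regions partition the coordinate range without overlap. Coordinates
#' outside both ranges return `"out_of_range"`.
#'
#' @param bregma_mm Numeric vector of bregma coordinates in mm (caudal
#'   negative).
#' @return Character vector: `"dorsal"`, `"ventral"`, or `"out_of_range"`.
#' @examples
#' classify_region(c(-3.8, -6.8, -1.0))
#' @export
classify_region <- function(bregma_mm) {
  if (!is.numeric(bregma_mm) || anyNA(bregma_mm) || !all(is.finite(bregma_mm)))
    stop("'bregma_mm' must be finite numeric", call. = FALSE)
  out <- rep("out_of_range", length(bregma_mm))
  out[bregma_mm <= -1.80 & bregma_mm > -4.52] <- "dorsal"
  out[bregma_mm <= -4.52 & bregma_mm >= -6.80] <- "ventral"
  out
}

#' Construct a systematically sampled section series
#'
#' A section series holds the per-section records of a 1-in-`interval`
#' systematic sample through a region: bregma coordinate, traced area, and
#' the cell count for the marker of interest. Records are kept sorted by
#' bregma (rostral first).
#'
#' @param records Data frame with columns `bregma_mm`, `area_mm2`, `count`.
#' @param sampling_interval Positive integer; 10 for the standard 1-in-10
#'   series.
#' @param section_thickness_um Section thickness in micrometres.
#' @return An object of class `section_series`.
#' @export
section_series <- function(records, sampling_interval = 10L,
                           section_thickness_um = 30) {
  req <- c("bregma_mm", "area_mm2", "count")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("'records' must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L)
    stop("'records' must contain at least one section", call. = FALSE)
  if (!is_count(sampling_interval, 1L))
    stop("'sampling_interval' must be an integer >= 1", call. = FALSE)
  if (!is_number(section_thickness_um, 1e-12))
    stop("'section_thickness_um' must be positive", call. = FALSE)
  if (anyNA(records[req])) stop("section records must not contain NA", call. = FALSE)
  if (any(records$area_mm2 < 0)) stop("section areas must be >= 0", call. = FALSE)
  if (any(records$count < 0) || any(records$count != round(records$count)))
    stop("section counts must be non-negative integers", call. = FALSE)
  records <- records[order(records$bregma_mm, decreasing = TRUE), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 sampling_interval = as.integer(sampling_interval),
                 section_thickness_um = section_thickness_um),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("Section series: %d sections, 1-in-%d sampling, %g um thick\n",
              nrow(x$records), x$sampling_interval, x$section_thickness_um))
  cat(sprintf("  bregma %g to %g mm, total count %d\n",
              max(x$records$bregma_mm), min(x$records$bregma_mm),
              sum(x$records$count)))
  invisible(x)
}

#' Estimate the total cell number from a sampled series
#'
#' The aggregate count over the sampled sections multiplied by the sampling
#' interval (e.g. aggregate x 10 for a 1-in-10 series).
#'
#' @param series A [section_series()].
#' @return Estimated total number of cells in the region.
#' @export
estimate_total <- function(series) {
  stopifnot(inherits(series, "section_series"))
  sum(series$records$count) * series$sampling_interval
}

#' Cavalieri volume of the sectioned region
#'
#' Summed traced areas multiplied by the distance between sampled sections
#' (section thickness x sampling interval). With 30-um sections and 1-in-10
#' sampling the effective spacing is 300 um = 0.3 mm.
#'
#' @param series A [section_series()].
#' @return Volume in mm^3.
#' @examples
#' s <- section_series(data.frame(bregma_mm = c(-2.0, -2.3),
#'                                area_mm2 = c(1, 1), count = c(0, 0)))
#' cavalieri_volume(s)  # 2 x 0.3 = 0.6 mm^3
#' @export
cavalieri_volume <- function(series) {
  stopifnot(inherits(series, "section_series"))
  spacing_mm <- um_to_mm(series$section_thickness_um) * series$sampling_interval
  sum(series$records$area_mm2) * spacing_mm
}

#' Cell density of a sampled region
#'
#' Estimated total cell number divided by the Cavalieri volume, returned
#' together with both intermediate quantities so that
#' `density x volume = total` holds by construction.
#'
#' @param series A [section_series()].
#' @param region Optional region label ("dorsal"/"ventral") carried through
#'   to the result.
#' @return An object of class `region_estimate`: list with `region`,
#'   `est_total_cells`, `volume_mm3`, `density_cells_per_mm3`.
#' @export
cell_density <- function(series, region = NA_character_) {
  stopifnot(inherits(series, "section_series"))
  vol <- cavalieri_volume(series)
  if (vol <= 0) {
    if (all(series$records$area_mm2 == 0))
      stop("zero volume: all traced section areas are zero", call. = FALSE)
    stop("zero volume: the series contains no usable sections", call. = FALSE)
  }
  total <- estimate_total(series)
  structure(list(region = region,
                 est_total_cells = total,
                 volume_mm3 = vol,
                 density_cells_per_mm3 = total / vol),
            class = "region_estimate")
}

#' @export
print.region_estimate <- function(x, ...) {
  cat(sprintf("Region estimate%s: %g cells, %.4g mm^3, %.5g cells/mm^3\n",
              if (is.na(x$region)) "" else paste0(" (", x$region, ")"),
              x$est_total_cells, x$volume_mm3, x$density_cells_per_mm3))
  invisible(x)
}

#' Per-region density estimates from one animal's section series
#'
#' Splits the series into dorsal and ventral sections by bregma coordinate
#' (see [classify_region()]) and returns a [cell_density()] estimate for each
#' region present. Out-of-range sections are dropped with a warning.
#'
#' @param series A [section_series()].
#' @return Named list of `region_estimate` objects (`dorsal`, `ventral`).
#' @export
density_by_region <- function(series) {
  stopifnot(inherits(series, "section_series"))
  reg <- classify_region(series$records$bregma_mm)
  if (any(reg == "out_of_range"))
    warning(sum(reg == "out_of_range"),
            " section(s) outside the dorsal/ventral bregma range were dropped")
  out <- list()
  for (r in c("dorsal", "ventral")) {
    rec <- series$records[reg == r, , drop = FALSE]
    if (nrow(rec) > 0L)
      out[[r]] <- cell_density(
        section_series(rec, series$sampling_interval,
                       series$section_thickness_um),
        region = r)
  }
  out
}
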