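#' Counting parameters for the automated cell counter
#'
#' Bundles the tunable parameters of [count_cells()]. Defaults follow the
#' published working configuration of the algorithm: a disk structuring
#' element of radius 10 px (roughly the average cell size at the acquisition
#' magnification), four background subtractions (midpoint of the documented
#' useful range of 3--5), Otsu binarization within the region of interest,
#' and size bounds of 10\%--300\% of the nominal cell area
#' (\eqn{\pi \cdot 10^2 \approx 314} px, hence \[31, 943\] px).
#'
#' @param disk_radius_px Radius, in pixels, of the disk structuring element
#'   used to estimate the background by grayscale morphological opening.
#' @param n_subtractions Number of background-subtraction/contrast passes
#'   applied before binarization (documented useful range 3--5).
#' @param threshold Either `"otsu"` (threshold chosen by Otsu's method over
#'   ROI pixels) or `"fixed"` (use `threshold_value`).
#' @param threshold_value Fixed threshold in \[0, 255\]; required when
#'   `threshold = "fixed"`.
#' @param size_min_px,size_max_px Connected components with pixel area
#'   outside \[`size_min_px`, `size_max_px`\] are discarded as artifacts.
#' @param connectivity Pixel connectivity for component labelling, 4 or 8.
#' @param contrast Contrast operator used between subtractions; see
#'   [subtract_and_enhance()].
#' @param smooth_background If `TRUE` (default), the background is the
#'   opening of a 3x3 median-smoothed copy of the image, so it tracks the
#'   local illumination rather than the lower noise envelope; the image
#'   being enhanced and thresholded is never smoothed.
#' @return An object of class `count_params`.
#' @seealso [count_cells()]
#' @export
count_params <- function(disk_radius_px = 10L, n_subtractions = 4L,
                         threshold = c("otsu", "fixed"), threshold_value = NULL,
                         size_min_px = 31L, size_max_px = 943L,
                         connectivity = 8L,
                         contrast = c("bright_median", "minmax"),
                         smooth_background = TRUE) {
  threshold <- match.arg(threshold)
  contrast <- match.arg(contrast)
  if (!is_count(disk_radius_px, min = 1L))
    stop("'disk_radius_px' must be a positive integer", call. = FALSE)
  if (!is_count(n_subtractions, min = 1L))
    stop("'n_subtractions' must be an integer >= 1", call. = FALSE)
  if (!is_count(size_min_px, min = 1L) || !is_count(size_max_px, min = 1L))
    stop("size bounds must be positive integers", call. = FALSE)
  if (size_min_px >= size_max_px)
    stop("'size_min_px' must be strictly smaller than 'size_max_px'", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("'connectivity' must be 4 or 8", call. = FALSE)
  if (threshold == "fixed") {
    if (!is_number(threshold_value, min = 0) || threshold_value > 255)
      stop("'threshold_value' must be a number in [0, 255] when threshold = \"fixed\"",
           call. = FALSE)
  }
  structure(list(disk_radius_px = as.integer(disk_radius_px),
                 n_subtractions = as.integer(n_subtractions),
                 threshold = threshold,
                 threshold_value = threshold_value,
                 size_min_px = as.integer(size_min_px),
                 size_max_px = as.integer(size_max_px),
                 connectivity = as.integer(connectivity),
                 contrast = contrast,
                 smooth_background = isTRUE(smooth_background)),
            class = "count_params")
}

#' Convert an image to 8-bit grayscale
#'
#' Grayscale input (a numeric matrix) is returned unchanged. RGB input (a
#' height x width x 3 array) is collapsed with the standard luminance
#' weights 0.299 R + 0.587 G + 0.114 B; single-channel arrays are dropped to
#' a matrix.
#'
#' @param image Numeric matrix in \[0, 255\], or an array with 1 or 3 planes.
#' @param weights Length-3 luminance weights for RGB input; must sum to 1.
#' @return A numeric matrix with intensities in \[0, 255\].
#' @export
to_grayscale <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(image)) {
    check_image_matrix(image)
    return(image)
  }
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("'image' must be a matrix or a 3-dimensional array", call. = FALSE)
  nc <- dim(image)[3]
  if (nc == 1L) {
    out <- image[, , 1L]
  } else if (nc == 3L) {
    if (length(weights) != 3L || abs(sum(weights) - 1) > 1e-9)
      stop("'weights' must be three numbers summing to 1", call. = FALSE)
    out <- image[, , 1L] * weights[1] + image[, , 2L] * weights[2] +
      image[, , 3L] * weights[3]
  } else {
    stop(sprintf("unsupported channel count: %d (expected 1 or 3)", nc),
         call. = FALSE)
  }
  check_image_matrix(out, "converted image")
  out
}

#' Disk structuring element
#'
#' Binary disk kernel: a (2r+1) x (2r+1) matrix with 1 where
#' \eqn{dx^2 + dy^2 \le r^2}.
#'
#' @param radius_px Disk radius in pixels (positive integer).
#' @return A 0/1 numeric matrix.
#' @export
disk_kernel <- function(radius_px) {
  if (!is_count(radius_px, min = 1L))
    stop("'radius_px' must be a positive integer", call. = FALSE)
  off <- -radius_px:radius_px
  outer(off, off, function(dx, dy) as.numeric(dx^2 + dy^2 <= radius_px^2))
}

#' Estimate the image background by grayscale morphological opening
#'
#' Opening (erosion followed by dilation) with a flat disk removes bright
#' structures strictly smaller than the disk -- here, the immunoreactive
#' cells -- leaving an estimate of the uneven background illumination. The
#' result never exceeds the input pixelwise.
#'
#' @param gray Numeric matrix in \[0, 255\].
#' @param disk_radius_px Disk radius in pixels; must fit inside the image.
#' @return Background image, same dimensions as `gray`.
#' @export
estimate_background <- function(gray, disk_radius_px = 10L) {
  check_image_matrix(gray, "gray")
  if (!is_count(disk_radius_px, min = 1L))
    stop("'disk_radius_px' must be a positive integer", call. = FALSE)
  if (2L * disk_radius_px + 1L > min(dim(gray)))
    stop(sprintf("disk of radius %d does not fit in a %dx%d image",
                 disk_radius_px, nrow(gray), ncol(gray)), call. = FALSE)
  kern <- disk_kernel(disk_radius_px)
  # EBImage grayscale morphology assumes intensities in [0, 1]; erosion and
  # dilation commute with the affine rescale
  opened <- EBImage::dilate(EBImage::erode(gray / 255, kern), kern)
  matrix(as.numeric(opened) * 255, nrow(gray), ncol(gray))
}

# 3x3 median smoothing. Opening a raw noisy image tracks the lower noise
# envelope (the erosion dips ~2 sd below the local illumination, unevenly);
# estimating the background from a median-smoothed copy removes that bias,
# as rolling-ball background subtractors do. The image being enhanced and
# thresholded is never smoothed.
median3 <- function(img) {
  matrix(as.numeric(EBImage::medianFilter(img / 255, 1L)) * 255,
         nrow(img), ncol(img))
}

# Linear contrast rescale to [0, 255] with the range taken over ROI pixels.
# "bright_median" anchors the white point on the median of the pixels in the
# upper half of the range (the bright, cell-like population), saturating
# roughly half of every cell core at 255 each pass. Anchoring on the bright
# population rather than the single maximum is what keeps all cells -- not
# just the brightest one -- stable under repeated background subtraction:
# with a plain min-max rescale the per-pass gain compensates the renewed
# subtraction only for the global maximum, and every dimmer cell decays
# geometrically. "minmax" gives the plain rescale. A flat ROI rescales to
# all zeros.
rescale_contrast <- function(img, roi, contrast = "bright_median") {
  v <- img[roi]
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) return(matrix(0, nrow(img), ncol(img)))
  if (contrast == "bright_median") {
    anchor <- stats::median(v[v >= (lo + hi) / 2])
    if (anchor > lo) hi <- anchor
  }
  clamp255((img - lo) / (hi - lo) * 255)
}

#' Iterated background subtraction with contrast enhancement
#'
#' Each pass subtracts the *original* background image (clipping at zero) and
#' then linearly rescales the ROI intensity range to \[0, 255\]. Repeating
#' the subtraction suppresses residual background and faint artifacts while
#' the bright cells, pinned near the top of the range by the rescale, are
#' preserved; 3--5 passes is the documented working range.
#'
#' @param gray Grayscale image matrix in \[0, 255\].
#' @param background Background estimate from [estimate_background()].
#' @param n_subtractions Number of subtract-and-rescale passes (>= 1).
#' @param roi Logical ROI mask (defaults to the whole image); the contrast
#'   range is computed over ROI pixels.
#' @param contrast Contrast operator applied after each subtraction:
#'   `"bright_median"` (default) anchors the white point on the median of
#'   the upper-half-range pixels, so every cell core -- not only the
#'   brightest pixel -- is pinned near white on each pass; `"minmax"` is a
#'   plain min--max rescale (under which all but the brightest structure
#'   decays across passes).
#' @return Enhanced image matrix in \[0, 255\].
#' @export
subtract_and_enhance <- function(gray, background, n_subtractions = 4L,
                                 roi = NULL,
                                 contrast = c("bright_median", "minmax")) {
  check_image_matrix(gray, "gray")
  check_image_matrix(background, "background")
  check_congruent(gray, background, c("gray", "background"))
  if (!is_count(n_subtractions, min = 1L))
    stop("'n_subtractions' must be an integer >= 1", call. = FALSE)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(gray), ncol(gray))
  check_congruent(gray, roi, c("gray", "roi"))
  contrast <- match.arg(contrast)
  cur <- gray
  for (k in seq_len(n_subtractions)) {
    cur <- pmax(cur - background, 0)
    cur <- rescale_contrast(cur, roi, contrast)
  }
  cur
}

# Label connected foreground pixels (4- or 8-connectivity) via the pixel
# adjacency graph. Returns an integer matrix, 0 = background.
label_components <- function(binary, connectivity = 8L) {
  h <- nrow(binary); w <- ncol(binary)
  fg <- which(binary)
  lab <- matrix(0L, h, w)
  if (length(fg) == 0L) return(lab)
  rank <- integer(h * w)
  rank[fg] <- seq_along(fg)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  ii <- ((fg - 1L) %% h) + 1L
  jj <- ((fg - 1L) %/% h) + 1L
  for (s in shifts) {
    i2 <- ii + s[1]; j2 <- jj + s[2]
    ok <- i2 >= 1L & i2 <= h & j2 >= 1L & j2 <= w
    nb <- (j2[ok] - 1L) * h + i2[ok]
    hit <- binary[nb]
    if (any(hit)) edges <- c(edges, rbind(rank[fg[ok][hit]], rank[nb[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}

#' Binarize an enhanced image and size-filter the components
#'
#' Thresholds the enhanced image (Otsu's method over ROI pixels by default,
#' or a fixed threshold), restricts the foreground to the ROI, labels
#' connected components at the requested connectivity, and discards
#' components whose pixel area falls outside
#' \[`size_min_px`, `size_max_px`\] or whose centroid lies outside the ROI.
#' Surviving components are relabelled compactly 1..n.
#'
#' A degenerate image (constant within the ROI) yields zero components, not
#' an error; an empty ROI is an error.
#'
#' @param enhanced Enhanced grayscale image from [subtract_and_enhance()].
#' @param roi Logical ROI mask, congruent with `enhanced`, with at least one
#'   `TRUE` pixel.
#' @param params A [count_params()] object.
#' @return Integer label map (0 = background) with attribute `"threshold"`.
#' @export
binarize_and_filter <- function(enhanced, roi, params = count_params()) {
  check_image_matrix(enhanced, "enhanced")
  stopifnot(inherits(params, "count_params"))
  if (!is.logical(roi)) stop("'roi' must be a logical mask", call. = FALSE)
  check_congruent(enhanced, roi, c("enhanced", "roi"))
  if (!any(roi)) stop("empty ROI: the mask selects no pixels", call. = FALSE)
  v <- enhanced[roi]
  if (params$threshold == "otsu") {
    if (max(v) <= min(v)) {
      lab <- matrix(0L, nrow(enhanced), ncol(enhanced))
      attr(lab, "threshold") <- NA_real_
      return(lab)
    }
    thr <- EBImage::otsu(EBImage::Image(matrix(v / 255, ncol = 1)),
                         range = c(0, 1), levels = 256) * 255
  } else {
    thr <- params$threshold_value
  }
  binary <- (enhanced > thr) & roi
  lab <- label_components(binary, params$connectivity)
  n0 <- max(lab)
  if (n0 > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n0)
    keep <- areas >= params$size_min_px & areas <= params$size_max_px
    # components touching the ROI border are kept only if their centroid is
    # inside the ROI
    if (any(keep)) {
      h <- nrow(lab)
      idx <- which(lab > 0L)
      li <- factor(lab[idx], levels = seq_len(n0))
      ci <- round(tapply(((idx - 1L) %% h) + 1L, li, mean))
      cj <- round(tapply(((idx - 1L) %/% h) + 1L, li, mean))
      keep <- keep & roi[cbind(ci, cj)]
    }
    relabel <- integer(n0)
    relabel[keep] <- seq_len(sum(keep))
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
  }
  attr(lab, "threshold") <- as.numeric(thr)
  lab
}

#' Count immunoreactive cells in a fluorescence micrograph
#'
#' End-to-end automated counter: convert to grayscale, estimate the
#' background by morphological opening with a disk, subtract the background
#' repeatedly with contrast rescaling, binarize within the region of
#' interest, size-filter the connected components, and count. The returned
#' object also reports the ROI area and total cell area in pixels, and echoes
#' the parameters for provenance.
#'
#' @param image Numeric matrix in \[0, 255\], or an RGB array (converted via
#'   [to_grayscale()]).
#' @param roi Logical ROI mask congruent with the image.
#' @param params A [count_params()] object.
#' @return An object of class `count_result`: a list with elements
#'   `n_cells`, `roi_area_px`, `cell_area_px`, `label_map`, `threshold`, and
#'   `params`.
#' @examples
#' spec <- image_spec(width_px = 240, height_px = 240, n_cells = 4,
#'                    n_small_artifacts = 0, n_large_artifacts = 0, seed = 7)
#' sim <- generate_micrograph(spec)
#' res <- count_cells(sim$image, sim$roi)
#' res$n_cells
#' @export
count_cells <- function(image, roi, params = count_params()) {
  gray <- to_grayscale(image)
  if (!is.logical(roi)) stop("'roi' must be a logical mask", call. = FALSE)
  check_congruent(gray, roi, c("image", "roi"))
  if (!any(roi)) stop("empty ROI: the mask selects no pixels", call. = FALSE)
  src <- if (params$smooth_background) median3(gray) else gray
  bg <- estimate_background(src, params$disk_radius_px)
  enh <- subtract_and_enhance(gray, bg, params$n_subtractions, roi,
                              contrast = params$contrast)
  lab <- binarize_and_filter(enh, roi, params)
  structure(list(n_cells = max(lab),
                 roi_area_px = sum(roi),
                 cell_area_px = sum(lab > 0L),
                 label_map = lab,
                 threshold = attr(lab, "threshold"),
                 params = params),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat("Automated cell count\n")
  cat(sprintf("  cells counted : %d\n", x$n_cells))
  cat(sprintf("  ROI area      : %d px\n", x$roi_area_px))
  cat(sprintf("  cell area     : %d px\n", x$cell_area_px))
  cat(sprintf("  parameters    : disk r=%d px, %d subtractions, %s threshold, size [%d, %d] px, %d-connectivity\n",
              x$params$disk_radius_px, x$params$n_subtractions,
              x$params$threshold, x$params$size_min_px, x$params$size_max_px,
              x$params$connectivity))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper used for counter self-consistency checks (e.g.
#' counts at 4 versus 5 background subtractions) and inter-variable
#' correlations. Errors on degenerate input rather than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite and free of missing values", call. = FALSE)
  if (stats::var(x) == 0) stop("'x' has zero variance", call. = FALSE)
  if (stats::var(y) == 0) stop("'y' has zero variance", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}
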