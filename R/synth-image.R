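#' Specification for a synthetic fluorescence micrograph
#'
#' Describes a ground-truthed synthetic micrograph: bright quasi-circular
#' cells (truncated Gaussian spots) over a linearly shaded background with
#' Gaussian pixel noise, plus bright artifacts that straddle the size-filter
#' bounds of the counting algorithm -- "small" speckles well below the
#' nominal cell area and "large" clumps of merged cell-like staining well
#' above it.
#'
#' Cells must be brighter than the local background:
#' `cell_peak_intensity > background_level + gradient_amplitude / 2`.
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param n_cells Number of cells to place (>= 0).
#' @param cell_radius_px Mean cell radius in pixels; the Gaussian spot
#'   profile uses sigma = radius / 2 truncated at 2 sigma, so a cell's
#'   footprint is the stated radius.
#' @param radius_jitter Fractional jitter of the per-cell radius
#'   (uniform in `[-radius_jitter, +radius_jitter]`).
#' @param cell_peak_intensity Peak intensity added at a cell centre, on the
#'   8-bit scale.
#' @param background_level Mean background intensity.
#' @param gradient_amplitude Peak-to-peak amplitude of a linear left-to-right
#'   shading of the background.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param n_small_artifacts Number of bright speckles (area well below the
#'   default `size_min_px`).
#' @param n_large_artifacts Number of bright clumps of merged cell-like
#'   spots (area well above the default `size_max_px`).
#' @param min_center_separation_px Minimum pairwise distance between placed
#'   object centres; default 4 cell radii, which keeps thresholded cells
#'   well separated.
#' @param seed Integer seed; identical specs give bit-identical images.
#' @return An object of class `image_spec`.
#' @seealso [generate_micrograph()]
#' @export
image_spec <- function(width_px = 640L, height_px = 640L, n_cells = 20L,
                       cell_radius_px = 10, radius_jitter = 0.1,
                       cell_peak_intensity = 200, background_level = 50,
                       gradient_amplitude = 30, noise_sd = 8,
                       n_small_artifacts = 2L, n_large_artifacts = 1L,
                       min_center_separation_px = 4 * cell_radius_px,
                       seed = 1L) {
  if (!is_count(width_px, 1L) || !is_count(height_px, 1L))
    stop("image dimensions must be positive integers", call. = FALSE)
  if (!is_count(n_cells, 0L)) stop("'n_cells' must be a non-negative integer", call. = FALSE)
  if (!is_number(cell_radius_px, min = 1e-9))
    stop("'cell_radius_px' must be positive", call. = FALSE)
  if (!is_number(radius_jitter, 0) || radius_jitter >= 1)
    stop("'radius_jitter' must be in [0, 1)", call. = FALSE)
  for (nm in c("cell_peak_intensity", "background_level", "gradient_amplitude")) {
    v <- get(nm)
    if (!is_number(v, 0) || v > 255)
      stop(sprintf("'%s' must be in [0, 255]", nm), call. = FALSE)
  }
  if (!is_number(noise_sd, 0)) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (!is_count(n_small_artifacts, 0L) || !is_count(n_large_artifacts, 0L))
    stop("artifact counts must be non-negative integers", call. = FALSE)
  if (!is_number(min_center_separation_px, 0))
    stop("'min_center_separation_px' must be non-negative", call. = FALSE)
  if (!is_count(seed)) stop("'seed' must be an integer", call. = FALSE)
  if (cell_peak_intensity <= background_level + gradient_amplitude / 2)
    stop("cells must be brighter than the local background: require ",
         "cell_peak_intensity > background_level + gradient_amplitude/2",
         call. = FALSE)
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 n_cells = as.integer(n_cells), cell_radius_px = cell_radius_px,
                 radius_jitter = radius_jitter,
                 cell_peak_intensity = cell_peak_intensity,
                 background_level = background_level,
                 gradient_amplitude = gradient_amplitude, noise_sd = noise_sd,
                 n_small_artifacts = as.integer(n_small_artifacts),
                 n_large_artifacts = as.integer(n_large_artifacts),
                 min_center_separation_px = min_center_separation_px,
                 seed = as.integer(seed)),
            class = "image_spec")
}

# Rejection-sample n points uniformly in [lo_x, hi_x] x [lo_y, hi_y], each at
# least `self_sep` from one another and at least `sep` from every point set in
# `avoid` (a list of list(pts = 2-column matrix, sep = distance)).
place_points <- function(n, lo_x, hi_x, lo_y, hi_y, self_sep,
                         avoid = list(), what = "cells") {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  if (hi_x < lo_x || hi_y < lo_y)
    stop(sprintf("field too small to place %s at the requested separation", what),
         call. = FALSE)
  too_close <- function(p, pts, sep) {
    nrow(pts) > 0L &&
      min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) < sep
  }
  out <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  max_attempts <- 2000L * n
  while (nrow(out) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("failed to place %d %s with ",
                          "min_center_separation_px = %g after %d attempts; ",
                          "the separation constraint is unsatisfiable in this field"),
                   n, what, self_sep, max_attempts), call. = FALSE)
    p <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
    if (too_close(p, out, self_sep)) next
    blocked <- FALSE
    for (a in avoid) if (too_close(p, a$pts, a$sep)) { blocked <- TRUE; break }
    if (!blocked) out <- rbind(out, p)
  }
  rownames(out) <- NULL
  out
}

# Add a truncated Gaussian spot of the given amplitude at centre (cx, cy).
# sigma = radius/2 and the support is truncated at 2 sigma, so the spot's
# footprint is exactly the stated radius -- no larger than the disk
# structuring element sized to "the average size of the cells", which is what
# lets the opening remove cells from the background completely.
# Coordinates: x = column, y = row.
add_spot <- function(img, cx, cy, radius, amplitude) {
  sigma <- radius / 2
  ext <- ceiling(2 * sigma)
  h <- nrow(img); w <- ncol(img)
  rows <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
  cols <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  spot <- amplitude * exp(-d2 / (2 * sigma^2))
  spot[d2 > (2 * sigma)^2] <- 0
  img[rows, cols] <- img[rows, cols] + spot
  img
}

# A clump of overlapping cell-like spots (grid spacing 0.6r within 1.5r of
# the centre): merged staining too large to be a single cell. Returns the
# clump intensity canvas and its support pixels.
clump_canvas <- function(h, w, cx, cy, radius, amplitude) {
  step <- 0.6 * radius
  off <- expand.grid(dx = seq(-1.8 * radius, 1.8 * radius, by = step),
                     dy = seq(-1.8 * radius, 1.8 * radius, by = step))
  off <- off[off$dx^2 + off$dy^2 <= (1.5 * radius)^2, ]
  canvas <- matrix(0, h, w)
  for (i in seq_len(nrow(off)))
    canvas <- add_spot(canvas, cx + off$dx[i], cy + off$dy[i], radius, amplitude)
  canvas
}

#' Generate a ground-truthed synthetic micrograph
#'
#' Renders the micrograph described by an [image_spec()]: a linearly shaded
#' background, `n_cells` truncated Gaussian spots at pairwise-separated
#' random centres, bright small speckles and large merged clumps as
#' artifacts, and Gaussian noise, quantized to 8 bits. The region of
#' interest is the image minus a one-cell-radius border; all cells are
#' placed so their core lies inside the ROI.
#'
#' @param spec An [image_spec()].
#' @return A list of class `micrograph_sim` with elements `image` (numeric
#'   matrix, \[0, 255\]), `roi` (logical mask), and `truth` (list:
#'   `cell_centers` data frame with columns `x`, `y`; `n_cells`;
#'   `artifact_pixels`, a list of linear-index vectors).
#' @examples
#' sim <- generate_micrograph(image_spec(width_px = 200, height_px = 200,
#'                                       n_cells = 5, n_small_artifacts = 0,
#'                                       n_large_artifacts = 0, seed = 3))
#' sim$truth$n_cells
#' @export
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  h <- spec$height_px; w <- spec$width_px
  r <- spec$cell_radius_px
  roi_margin <- ceiling(r)
  roi <- matrix(FALSE, h, w)
  if (h > 2 * roi_margin && w > 2 * roi_margin) {
    roi[(roi_margin + 1):(h - roi_margin), (roi_margin + 1):(w - roi_margin)] <- TRUE
  } else {
    roi[] <- TRUE
  }

  with_seed(spec$seed, {
    m <- roi_margin + ceiling(2 * r)

    # large artifacts first (they need the most clearance): clumps of
    # overlapping cell-like spots whose merged area exceeds the default
    # size_max_px
    clump_ext <- ceiling(2.5 * r)  # spot centres within 1.5r, support +r
    clump_clear <- clump_ext + r + 5
    lg <- place_points(spec$n_large_artifacts,
                       m + clump_ext, w - m - clump_ext,
                       m + clump_ext, h - m - clump_ext,
                       2 * clump_clear, what = "large artifacts")

    # cell centres stay one spot-support inside the ROI
    centers <- place_points(spec$n_cells, m, w - m, m, h - m,
                            spec$min_center_separation_px,
                            avoid = list(list(pts = lg, sep = clump_clear)),
                            what = "cells")

    # small artifacts: bright plus-shaped speckles (5 px), far below the
    # nominal cell area
    small_sep <- max(spec$min_center_separation_px, 3 * r)
    sm <- place_points(spec$n_small_artifacts, m, w - m, m, h - m,
                       small_sep,
                       avoid = list(list(pts = centers, sep = small_sep),
                                    list(pts = lg, sep = clump_clear)),
                       what = "small artifacts")

    # background with linear left-to-right shading
    gx <- spec$background_level +
      spec$gradient_amplitude * (((seq_len(w) - 1) / max(1L, w - 1L)) - 0.5)
    img <- matrix(gx, h, w, byrow = TRUE)

    amp <- spec$cell_peak_intensity - spec$background_level
    radii <- r * (1 + stats::runif(spec$n_cells, -spec$radius_jitter,
                                   spec$radius_jitter))
    for (i in seq_len(spec$n_cells))
      img <- add_spot(img, centers[i, 1], centers[i, 2], radii[i], amp)

    artifact_pixels <- list()
    for (i in seq_len(spec$n_small_artifacts)) {
      ci <- round(sm[i, 2]); cj <- round(sm[i, 1])
      px <- c((cj - 1L) * h + ci,
              (cj - 1L) * h + ci - 1L, (cj - 1L) * h + ci + 1L,
              (cj - 2L) * h + ci, cj * h + ci)
      img[px] <- img[px] + amp
      artifact_pixels <- c(artifact_pixels, list(sort(px)))
    }
    for (i in seq_len(spec$n_large_artifacts)) {
      canvas <- clump_canvas(h, w, lg[i, 1], lg[i, 2], r, amp)
      px <- which(canvas > 0)
      img <- img + canvas
      artifact_pixels <- c(artifact_pixels, list(px))
    }

    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    img <- round(clamp255(img))

    truth <- list(cell_centers = data.frame(x = centers[, 1], y = centers[, 2]),
                  n_cells = spec$n_cells,
                  artifact_pixels = artifact_pixels)
    structure(list(image = img, roi = roi, truth = truth, spec = spec),
              class = "micrograph_sim")
  })
}

#' @export
print.micrograph_sim <- function(x, ...) {
  cat(sprintf("Synthetic micrograph: %dx%d px, %d cells, %d artifact(s), seed %d\n",
              x$spec$width_px, x$spec$height_px, x$truth$n_cells,
              length(x$truth$artifact_pixels), x$spec$seed))
  invisible(x)
}
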