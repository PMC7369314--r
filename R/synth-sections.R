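#' Simulate a systematically sampled section series
#'
#' Places cells through a full coronal section stack by a uniform 3-D Poisson
#' process at the stated density, then returns the counts of every
#' `interval`-th section (systematic sampling with a random start), the way a
#' 1-in-`interval` series is counted in practice. The total cell number is
#' drawn once for the whole stack and split across sections in proportion to
#' section volume, so with `interval = 1` the returned counts sum exactly to
#' the true total.
#'
#' @param true_density True cell density in cells/mm^3 (>= 0).
#' @param area_profile_mm2 Traced section areas in mm^2, one per section of
#'   the full stack, ordered rostral to caudal.
#' @param thickness_um Section thickness in micrometres (> 0).
#' @param interval Sampling interval (1 keeps every section; 10 is the
#'   standard 1-in-10 series).
#' @param seed Integer seed.
#' @param bregma_start_mm Bregma coordinate (mm) of the first section;
#'   subsequent sections step caudally by one thickness.
#' @return A list with `series` (a [section_series()] of the sampled
#'   sections) and `true_total` (integer, cells in the full stack).
#' @examples
#' sim <- generate_section_series(1000, rep(1, 100), thickness_um = 30,
#'                                interval = 10, seed = 2)
#' estimate_total(sim$series)  # estimate of sim$true_total
#' @export
generate_section_series <- function(true_density, area_profile_mm2,
                                    thickness_um = 30, interval = 10L,
                                    seed = 1L, bregma_start_mm = -1.80) {
  if (!is_number(true_density, 0))
    stop("'true_density' must be a non-negative number", call. = FALSE)
  if (length(area_profile_mm2) == 0L)
    stop("'area_profile_mm2' must contain at least one section", call. = FALSE)
  if (anyNA(area_profile_mm2) || any(area_profile_mm2 < 0))
    stop("section areas must be non-negative", call. = FALSE)
  if (!is_number(thickness_um, 1e-12))
    stop("'thickness_um' must be positive", call. = FALSE)
  if (!is_count(interval, 1L))
    stop("'interval' must be an integer >= 1", call. = FALSE)
  n_sec <- length(area_profile_mm2)
  if (interval > n_sec)
    stop(sprintf("sampling interval (%d) exceeds the number of sections (%d)",
                 interval, n_sec), call. = FALSE)
  if (!is_count(seed)) stop("'seed' must be an integer", call. = FALSE)

  vol_mm3 <- area_profile_mm2 * um_to_mm(thickness_um)
  total_vol <- sum(vol_mm3)
  with_seed(seed, {
    n_total <- stats::rpois(1, true_density * total_vol)
    counts <- if (n_total > 0L && total_vol > 0) {
      as.vector(stats::rmultinom(1, n_total, prob = vol_mm3))
    } else {
      integer(n_sec)
    }
    offset <- sample.int(interval, 1)
    keep <- seq.int(offset, n_sec, by = interval)
    bregma <- bregma_start_mm - (seq_len(n_sec) - 1) * um_to_mm(thickness_um)
    series <- section_series(
      data.frame(bregma_mm = bregma[keep],
                 area_mm2 = area_profile_mm2[keep],
                 count = counts[keep]),
      sampling_interval = interval,
      section_thickness_um = thickness_um)
    list(series = series, true_total = as.integer(n_total))
  })
}
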