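time_levels <- c("2h", "24h", "1w", "2w", "3w")
sex_levels <- c("male", "female")
region_levels <- c("dorsal", "ventral")

#' Default cohort calibration table
#'
#' Illustrative group-truth values for the synthetic cohort generator, shaped
#' like the sex-by-time design the pipeline targets: a male 1-week peak in
#' BrdU-ir cell density followed by a halving between 1 and 2 weeks, a flat
#' female trajectory, faster male NeuN maturation (males well ahead of
#' females at 2 weeks, both at ~90\% by 3 weeks), a female rise in DCX
#' co-expression between 2 and 24 hours, higher male Ki67 density, a male
#' dorsal advantage in Sox2-ir density with a female ventral > dorsal
#' difference, and Sox2 co-expression decaying from near-complete at 2 hours.
#' The values are plausible magnitudes for the rat dentate gyrus, not
#' measurements.
#'
#' @return Data frame with one row per sex x time x region: true mean
#'   densities (`brdu_density`, `ki67_density`, `sox2_density`, cells/mm^3),
#'   co-expression probabilities (`p_neun`, `p_dcx`, `p_sox2`), and the DCX
#'   morphology mixture (`dcx_pA`, `dcx_pB`, `dcx_pC`).
#' @export
default_calibration <- function() {
  g <- expand.grid(region = region_levels, time_point = time_levels,
                   sex = sex_levels, stringsAsFactors = FALSE)
  g <- g[, c("sex", "time_point", "region")]
  key <- function(sex, time, region) {
    g$sex == sex & g$time_point == time & g$region == region
  }
  val <- function(tbl) {
    out <- numeric(nrow(g))
    for (i in seq_len(nrow(tbl)))
      out[key(tbl$sex[i], tbl$time[i], tbl$region[i])] <- tbl$v[i]
    out
  }
  grid_tbl <- function(male_d, male_v, female_d, female_v) {
    data.frame(sex = rep(sex_levels, each = 2 * length(time_levels)),
               time = rep(rep(time_levels, each = 2), 2),
               region = rep(region_levels, 2 * length(time_levels)),
               v = c(rbind(male_d, male_v), rbind(female_d, female_v)))
  }
  # BrdU-ir density: male 1w peak with 1w -> 2w halving; flat female
  g$brdu_density <- val(grid_tbl(
    male_d = c(9000, 11000, 16000, 8000, 7000),
    male_v = c(7000, 9000, 13000, 6500, 6000),
    female_d = c(6000, 7000, 7500, 7000, 6800),
    female_v = c(5500, 6500, 7000, 6800, 6600)))
  # Ki67-ir density: constant across time, higher in males
  g$ki67_density <- val(grid_tbl(
    male_d = rep(12500, 5), male_v = rep(11000, 5),
    female_d = rep(8000, 5), female_v = rep(7500, 5)))
  # Sox2-ir density: male dorsal advantage, female ventral > dorsal
  g$sox2_density <- val(grid_tbl(
    male_d = rep(90000, 5), male_v = rep(88000, 5),
    female_d = rep(65000, 5), female_v = rep(85000, 5)))
  # co-expression probabilities among sampled BrdU-ir cells
  g$p_neun <- val(grid_tbl(
    male_d = c(0.01, 0.01, 0.15, 0.65, 0.90),
    male_v = c(0.01, 0.01, 0.15, 0.65, 0.90),
    female_d = c(0.01, 0.01, 0.13, 0.25, 0.90),
    female_v = c(0.01, 0.01, 0.13, 0.25, 0.90)))
  g$p_dcx <- val(grid_tbl(
    male_d = c(0.40, 0.45, 0.85, 0.55, 0.20),
    male_v = c(0.40, 0.45, 0.85, 0.55, 0.20),
    female_d = c(0.35, 0.75, 0.85, 0.55, 0.20),
    female_v = c(0.35, 0.75, 0.85, 0.55, 0.20)))
  g$p_sox2 <- val(grid_tbl(
    male_d = c(0.95, 0.85, 0.40, 0.15, 0.08),
    male_v = c(0.90, 0.88, 0.40, 0.15, 0.08),
    female_d = c(0.95, 0.85, 0.40, 0.15, 0.08),
    female_v = c(0.90, 0.88, 0.40, 0.15, 0.08)))
  # DCX morphology mixture: maturation shift from type A to type C, with a
  # male type-C lead at 2w
  mixes <- list(male = list("2h" = c(0.80, 0.18, 0.02),
                            "24h" = c(0.70, 0.27, 0.03),
                            "1w" = c(0.35, 0.50, 0.15),
                            "2w" = c(0.15, 0.40, 0.45),
                            "3w" = c(0.10, 0.35, 0.55)),
                female = list("2h" = c(0.80, 0.18, 0.02),
                              "24h" = c(0.70, 0.27, 0.03),
                              "1w" = c(0.35, 0.50, 0.15),
                              "2w" = c(0.20, 0.55, 0.25),
                              "3w" = c(0.10, 0.35, 0.55)))
  g$dcx_pA <- g$dcx_pB <- g$dcx_pC <- NA_real_
  for (i in seq_len(nrow(g))) {
    mx <- mixes[[g$sex[i]]][[g$time_point[i]]]
    g$dcx_pA[i] <- mx[1]; g$dcx_pB[i] <- mx[2]; g$dcx_pC[i] <- mx[3]
  }
  g
}

#' Design of a synthetic sex-by-time cohort
#'
#' Bundles the ground truth and sampling rules for [generate_cohort()]:
#' per-group true densities and co-expression probabilities (the
#' calibration table), the log-normal between-animal dispersion of
#' densities, the co-expression sampling target (50 cells), and hormone
#' distributions (female serum estradiol in pg/ml, male testosterone in
#' ng/ml; defaults match a non-proestrous female range around 14 pg/ml and
#' a male range around 1 ng/ml).
#'
#' @param n_per_group Animals per sex x time group (default 5, i.e. roughly
#'   22 animals per sex over five perfusion time points).
#' @param calibration Calibration table in the format of
#'   [default_calibration()]; unknown sex or time-point labels are an error.
#' @param density_cv Between-animal coefficient of variation of densities
#'   (log-normal).
#' @param n_sample_target Co-expression sampling target per animal/region.
#' @param estradiol_meanlog,estradiol_sdlog Log-normal parameters of female
#'   serum estradiol (pg/ml).
#' @param testosterone_meanlog,testosterone_sdlog Log-normal parameters of
#'   male serum testosterone (ng/ml).
#' @param seed Integer seed; identical designs give identical cohorts.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 5L, calibration = default_calibration(),
                          density_cv = 0.25, n_sample_target = 50L,
                          estradiol_meanlog = log(14), estradiol_sdlog = 0.2,
                          testosterone_meanlog = log(1.0),
                          testosterone_sdlog = 0.6, seed = 1L) {
  if (!is_count(n_per_group, 1L))
    stop("'n_per_group' must be a positive integer", call. = FALSE)
  if (!is_number(density_cv, 0)) stop("'density_cv' must be >= 0", call. = FALSE)
  if (!is_count(n_sample_target, 1L))
    stop("'n_sample_target' must be a positive integer", call. = FALSE)
  if (!is_count(seed)) stop("'seed' must be an integer", call. = FALSE)
  req <- c("sex", "time_point", "region", "brdu_density", "ki67_density",
           "sox2_density", "p_neun", "p_dcx", "p_sox2",
           "dcx_pA", "dcx_pB", "dcx_pC")
  if (!is.data.frame(calibration) || !all(req %in% names(calibration)))
    stop("'calibration' must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  bad_sex <- setdiff(unique(calibration$sex), sex_levels)
  if (length(bad_sex))
    stop("unknown sex label(s) ", paste(bad_sex, collapse = ", "),
         "; allowed: ", paste(sex_levels, collapse = ", "), call. = FALSE)
  bad_time <- setdiff(unique(calibration$time_point), time_levels)
  if (length(bad_time))
    stop("unknown time point(s) ", paste(bad_time, collapse = ", "),
         "; allowed: ", paste(time_levels, collapse = ", "), call. = FALSE)
  bad_region <- setdiff(unique(calibration$region), region_levels)
  if (length(bad_region))
    stop("unknown region label(s) ", paste(bad_region, collapse = ", "),
         "; allowed: ", paste(region_levels, collapse = ", "), call. = FALSE)
  dens <- as.matrix(calibration[c("brdu_density", "ki67_density", "sox2_density")])
  if (anyNA(dens) || any(dens < 0))
    stop("true densities must be non-negative", call. = FALSE)
  probs <- as.matrix(calibration[c("p_neun", "p_dcx", "p_sox2",
                                   "dcx_pA", "dcx_pB", "dcx_pC")])
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  mix_sum <- calibration$dcx_pA + calibration$dcx_pB + calibration$dcx_pC
  if (any(abs(mix_sum - 1) > 1e-9))
    stop("DCX morphology mixture (dcx_pA + dcx_pB + dcx_pC) must sum to 1",
         call. = FALSE)
  if (anyDuplicated(calibration[c("sex", "time_point", "region")]))
    stop("duplicated sex x time_point x region rows in calibration", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group),
                 calibration = calibration, density_cv = density_cv,
                 n_sample_target = as.integer(n_sample_target),
                 estradiol_meanlog = estradiol_meanlog,
                 estradiol_sdlog = estradiol_sdlog,
                 testosterone_meanlog = testosterone_meanlog,
                 testosterone_sdlog = testosterone_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generate a synthetic animal cohort
#'
#' Draws a full cohort from a [cohort_design()]: for every animal and region,
#' densities are log-normal around the group truth (log-normal keeps
#' densities positive and right-skewed at small n), co-label counts are
#' binomial draws at the 50-cell sampling target, the DCX morphology mixture
#' is a multinomial over the DCX-co-labelled cells of the sample, and serum
#' hormones are log-normal per animal with proestrus status derived from the
#' estradiol rule.
#'
#' @param design A [cohort_design()].
#' @return A data frame of class `cohort`, one row per animal x region, with
#'   columns `animal_id`, `sex`, `time_point`, `region`, the observed
#'   densities (`brdu_density`, `ki67_density`, `sox2_density`,
#'   `brdu_dcx_density`, `brdu_sox2_density`), co-expression percentages
#'   (`pct_neun`, `pct_dcx`, `pct_sox2`), `n_sampled`, the observed DCX
#'   morphology fractions (`dcx_pA`, `dcx_pB`, `dcx_pC`),
#'   `estradiol_pg_ml` (females), `testosterone_ng_ml` (males), and
#'   `proestrus`.
#' @examples
#' cohort <- generate_cohort(cohort_design(n_per_group = 3, seed = 11))
#' head(cohort)
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  cal <- design$calibration
  sdlog <- sqrt(log(1 + design$density_cv^2))
  groups <- unique(cal[c("sex", "time_point")])
  rows <- list()
  with_seed(design$seed, {
    for (gi in seq_len(nrow(groups))) {
      sex <- groups$sex[gi]; tp <- groups$time_point[gi]
      for (a in seq_len(design$n_per_group)) {
        id <- sprintf("%s_%s_%02d", substr(sex, 1, 1), tp, a)
        e2 <- if (sex == "female")
          stats::rlnorm(1, design$estradiol_meanlog, design$estradiol_sdlog) else NA_real_
        testo <- if (sex == "male")
          stats::rlnorm(1, design$testosterone_meanlog, design$testosterone_sdlog) else NA_real_
        pro <- if (sex == "female") classify_proestrus_estradiol(e2) else FALSE
        for (region in region_levels) {
          tr <- cal[cal$sex == sex & cal$time_point == tp & cal$region == region, ]
          if (nrow(tr) != 1L) next
          draw_dens <- function(mu) {
            if (mu <= 0) return(0)
            stats::rlnorm(1, log(mu) - sdlog^2 / 2, sdlog)
          }
          brdu <- draw_dens(tr$brdu_density)
          ki67 <- draw_dens(tr$ki67_density)
          sox2 <- draw_dens(tr$sox2_density)
          n_s <- design$n_sample_target
          k_neun <- stats::rbinom(1, n_s, tr$p_neun)
          k_dcx <- stats::rbinom(1, n_s, tr$p_dcx)
          k_sox2 <- stats::rbinom(1, n_s, tr$p_sox2)
          if (k_dcx > 0) {
            mix <- as.vector(stats::rmultinom(1, k_dcx,
                                              c(tr$dcx_pA, tr$dcx_pB, tr$dcx_pC))) / k_dcx
          } else {
            mix <- c(NA_real_, NA_real_, NA_real_)
          }
          pct_neun <- as.numeric(coexpression_pct(n_s, k_neun, target = n_s))
          pct_dcx <- as.numeric(coexpression_pct(n_s, k_dcx, target = n_s))
          pct_sox2 <- as.numeric(coexpression_pct(n_s, k_sox2, target = n_s))
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = id, sex = sex, time_point = tp, region = region,
            brdu_density = brdu, ki67_density = ki67, sox2_density = sox2,
            brdu_dcx_density = double_label_density(brdu, pct_dcx),
            brdu_sox2_density = double_label_density(brdu, pct_sox2),
            pct_neun = pct_neun, pct_dcx = pct_dcx, pct_sox2 = pct_sox2,
            n_sampled = n_s,
            dcx_pA = mix[1], dcx_pB = mix[2], dcx_pC = mix[3],
            estradiol_pg_ml = e2, testosterone_ng_ml = testo,
            proestrus = pro, stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  out
}
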