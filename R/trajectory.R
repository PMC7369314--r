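cohort_endpoints <- c("brdu_density", "ki67_density", "sox2_density",
                      "brdu_dcx_density", "brdu_sox2_density",
                      "pct_neun", "pct_dcx", "pct_sox2",
                      "dcx_pA", "dcx_pB", "dcx_pC")

#' Trajectory summary of a cohort endpoint
#'
#' Group means and standard errors per sex x region x time point for one
#' endpoint of a per-animal cohort table -- the tidy analogue of the
#' "mean (+/- SEM)" trajectory panels. SEM uses the sample standard
#' deviation (n - 1 denominator) divided by sqrt(n); groups with a single
#' animal report the mean with SEM absent. Missing endpoint values are
#' dropped per group. The result is stats-ready: feed it (or the underlying
#' cohort table) to any ANOVA machinery.
#'
#' @param cohort Data frame with columns `sex`, `region`, `time_point` and
#'   the endpoint (e.g. from [generate_cohort()] or [read_cohort_csv()]).
#' @param endpoint Name of the endpoint column to summarize.
#' @return Data frame of class `trajectory_summary` with columns `endpoint`,
#'   `sex`, `region`, `time_point`, `n`, `mean`, `sem`, ordered by sex,
#'   region, and time.
#' @examples
#' cohort <- generate_cohort(cohort_design(n_per_group = 4, seed = 2))
#' summarize_trajectory(cohort, "brdu_density")
#' @export
summarize_trajectory <- function(cohort, endpoint) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("'cohort' must be a non-empty data frame", call. = FALSE)
  for (col in c("sex", "region", "time_point"))
    if (!col %in% names(cohort))
      stop(sprintf("'cohort' lacks required column '%s'", col), call. = FALSE)
  known <- intersect(cohort_endpoints, names(cohort))
  if (length(endpoint) != 1L || !endpoint %in% known)
    stop("unknown endpoint '", endpoint, "'; available endpoints: ",
         paste(known, collapse = ", "), call. = FALSE)
  x <- cohort[[endpoint]]
  grp <- interaction(cohort$sex, cohort$region, cohort$time_point, drop = TRUE)
  parts <- split(x, grp)
  keys <- do.call(rbind, strsplit(names(parts), ".", fixed = TRUE))
  n <- vapply(parts, function(v) sum(!is.na(v)), integer(1))
  mu <- vapply(parts, function(v) mean(v, na.rm = TRUE), numeric(1))
  sem <- vapply(parts, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  out <- data.frame(endpoint = endpoint, sex = keys[, 1], region = keys[, 2],
                    time_point = keys[, 3], n = n, mean = mu, sem = sem,
                    stringsAsFactors = FALSE)
  tord <- match(out$time_point, time_levels)
  out <- out[order(out$sex, out$region, tord), , drop = FALSE]
  out <- out[out$n > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trajectory_summary", "data.frame")
  out
}

#' @export
print.trajectory_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Trajectory summary: %s (mean +/- SEM per sex x region x time)\n",
              x$endpoint[1]))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Attrition (or growth) of a group mean between two time points
#'
#' Signed percentage change of a group mean between two time points:
#' `100 * (mean(t_to) - mean(t_from)) / mean(t_from)`. Negative values are
#' attrition, e.g. the drop in BrdU-ir cell density between 1 and 2 weeks
#' after mitosis.
#'
#' @param summary A [summarize_trajectory()] result.
#' @param sex,region Group selectors.
#' @param t_from,t_to Time-point labels (e.g. `"1w"`, `"2w"`).
#' @return Signed percentage change.
#' @export
attrition <- function(summary, sex, region, t_from, t_to) {
  stopifnot(inherits(summary, "trajectory_summary"))
  pick <- function(tp) {
    row <- summary[summary$sex == sex & summary$region == region &
                     summary$time_point == tp, ]
    if (nrow(row) != 1L)
      stop(sprintf("no summary row for %s / %s at time '%s'", sex, region, tp),
           call. = FALSE)
    row$mean
  }
  m_from <- pick(t_from)
  m_to <- pick(t_to)
  if (m_from == 0)
    stop(sprintf("mean at '%s' is zero; relative change undefined", t_from),
         call. = FALSE)
  100 * (m_to - m_from) / m_from
}

#' Cohen's d for two independent groups
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled standard deviation weighted by degrees of freedom (n - 1).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Effect size d (positive when `group_a` has the larger mean).
#' @examples
#' cohens_d(c(2, 3, 4), c(1, 2, 3))
#' @export
cohens_d <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0)
    stop("pooled standard deviation is zero; d is undefined", call. = FALSE)
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Partial eta squared
#'
#' `ss_effect / (ss_effect + ss_error)` from the sums of squares of an
#' ANOVA effect and its error term. Provided as a primitive for effect-size
#' reporting alongside externally computed ANOVAs.
#'
#' @param ss_effect,ss_error Non-negative sums of squares, not both zero.
#' @return Effect size in \[0, 1\].
#' @export
partial_eta_sq <- function(ss_effect, ss_error) {
  if (!is_number(ss_effect, 0) || !is_number(ss_error, 0))
    stop("sums of squares must be non-negative numbers", call. = FALSE)
  if (ss_effect == 0 && ss_error == 0)
    stop("ss_effect and ss_error cannot both be zero", call. = FALSE)
  ss_effect / (ss_effect + ss_error)
}

#' Sex-contrast effect sizes per region and time point
#'
#' Cohen's d for the male - female contrast of one endpoint at every
#' region x time cell with at least two animals per sex.
#'
#' @param cohort Per-animal cohort table.
#' @param endpoint Endpoint column name (see [summarize_trajectory()]).
#' @return Data frame with columns `endpoint`, `region`, `time_point`,
#'   `cohens_d` (male minus female).
#' @export
sex_contrasts <- function(cohort, endpoint) {
  summ <- summarize_trajectory(cohort, endpoint)  # validates inputs
  cells <- unique(summ[c("region", "time_point")])
  res <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- cohort[cohort$region == cells$region[i] &
                    cohort$time_point == cells$time_point[i], ]
    a <- sub[[endpoint]][sub$sex == "male"]
    b <- sub[[endpoint]][sub$sex == "female"]
    if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
      d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
      res[[length(res) + 1L]] <- data.frame(
        endpoint = endpoint, region = cells$region[i],
        time_point = cells$time_point[i], cohens_d = d,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
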