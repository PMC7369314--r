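#' Co-expression percentage from a sampled cell set
#'
#' The co-expression estimator: randomly sample (a target of) 50
#' BrdU-labelled cells per animal and report the percentage that co-express
#' a second marker (NeuN, DCX, or Sox2). Samples smaller than the target are
#' allowed -- when an animal has fewer labelled cells than the target, all
#' are scored -- and are flagged via the `"under_target"` attribute.
#'
#' @param n_sampled Number of cells scored (>= 1); vectorized.
#' @param n_colabeled Number of those co-expressing the marker.
#' @param target Sampling target (default 50 cells).
#' @return Percentage(s) in \[0, 100\], with a logical attribute
#'   `under_target` marking samples with `n_sampled < target`.
#' @examples
#' coexpression_pct(50, 45)  # 90%
#' @export
coexpression_pct <- function(n_sampled, n_colabeled, target = 50L) {
  if (any(!is.finite(n_sampled)) || any(n_sampled < 1) ||
      any(n_sampled != round(n_sampled)))
    stop("'n_sampled' must be positive integers", call. = FALSE)
  if (any(!is.finite(n_colabeled)) || any(n_colabeled < 0) ||
      any(n_colabeled != round(n_colabeled)))
    stop("'n_colabeled' must be non-negative integers", call. = FALSE)
  if (length(n_sampled) != length(n_colabeled))
    stop("'n_sampled' and 'n_colabeled' must have equal length", call. = FALSE)
  if (any(n_colabeled > n_sampled))
    stop("'n_colabeled' cannot exceed 'n_sampled'", call. = FALSE)
  out <- 100 * n_colabeled / n_sampled
  attr(out, "under_target") <- n_sampled < target
  out
}

#' Double-label density
#'
#' Density of double-labelled cells: the BrdU-ir cell density multiplied by
#' the percentage of sampled BrdU-ir cells that express the second marker.
#'
#' @param brdu_density Density of BrdU-ir cells (cells/mm^3, >= 0);
#'   vectorized.
#' @param pct Co-expression percentage in \[0, 100\].
#' @return Density of double-labelled cells (cells/mm^3).
#' @export
double_label_density <- function(brdu_density, pct) {
  if (any(!is.finite(brdu_density)) || any(brdu_density < 0))
    stop("'brdu_density' must be non-negative", call. = FALSE)
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stop("'pct' must lie in [0, 100]", call. = FALSE)
  brdu_density * pct / 100
}

#' Classify DCX-expressing cell morphology
#'
#' Maturation staging of doublecortin-expressing cells from their dendritic
#' morphology: type A (proliferative) cells have no or short plump
#' processes; type B (intermediate) cells have medium-length processes or an
#' apical dendrite reaching the molecular layer; type C (postmitotic) cells
#' have an apical dendrite with at least one branch in the molecular layer.
#' The classifier operates on symbolic descriptors (scoring was visual, not
#' image-based) and is total: type C iff the dendrite branches in the
#' molecular layer, else type B iff processes are medium-length or reach the
#' molecular layer, else type A.
#'
#' @param process_class One of `"none_or_short_plump"`,
#'   `"medium_or_apical_to_ML"`, `"branched_in_ML"`; vectorized.
#' @param reaches_molecular_layer Logical: does the apical dendrite reach
#'   the molecular layer?
#' @param branches_in_molecular_layer Logical: does it branch there?
#'   Branching implies reaching.
#' @return Character vector: `"type_A"`, `"type_B"`, or `"type_C"`.
#' @examples
#' classify_dcx_morphology("none_or_short_plump", FALSE, FALSE)
#' @export
classify_dcx_morphology <- function(process_class,
                                    reaches_molecular_layer,
                                    branches_in_molecular_layer) {
  allowed <- c("none_or_short_plump", "medium_or_apical_to_ML", "branched_in_ML")
  if (!all(process_class %in% allowed))
    stop("'process_class' must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  n <- length(process_class)
  if (length(reaches_molecular_layer) != n ||
      length(branches_in_molecular_layer) != n)
    stop("descriptor vectors must have equal length", call. = FALSE)
  if (any(branches_in_molecular_layer & !reaches_molecular_layer))
    stop("a dendrite that branches in the molecular layer must reach it",
         call. = FALSE)
  out <- rep("type_A", n)
  out[process_class == "medium_or_apical_to_ML" | reaches_molecular_layer] <- "type_B"
  out[branches_in_molecular_layer | process_class == "branched_in_ML"] <- "type_C"
  out
}

#' Proestrus classification from serum estradiol
#'
#' A female is classified as proestrous when serum 17beta-estradiol is
#' 50 pg/ml or higher (inclusive cutoff).
#'
#' @param e2_pg_ml Serum estradiol in pg/ml (>= 0); vectorized.
#' @return Logical vector.
#' @examples
#' classify_proestrus_estradiol(c(21.08, 50, 10.99))
#' @export
classify_proestrus_estradiol <- function(e2_pg_ml) {
  if (any(!is.finite(e2_pg_ml)) || any(e2_pg_ml < 0))
    stop("'e2_pg_ml' must be non-negative", call. = FALSE)
  e2_pg_ml >= 50
}

#' Proestrus classification from vaginal lavage cytology
#'
#' A female is classified as proestrous when at least 70\% of lavage cells
#' are nucleated epithelial cells (the threshold is read as inclusive).
#'
#' @param nucleated_fraction Fraction of nucleated epithelial cells in
#'   \[0, 1\]; vectorized.
#' @return Logical vector.
#' @export
classify_proestrus_lavage <- function(nucleated_fraction) {
  if (any(!is.finite(nucleated_fraction)) || any(nucleated_fraction < 0) ||
      any(nucleated_fraction > 1))
    stop("'nucleated_fraction' must lie in [0, 1]", call. = FALSE)
  nucleated_fraction >= 0.70
}

#' Draw the 50-cell co-expression sample
#'
#' Samples up to `target` detected BrdU-ir cells uniformly without
#' replacement and scores co-labelling; when fewer than `target` cells are
#' available, all of them are used and the sample is flagged under-target.
#'
#' @param is_colabeled Logical vector, one entry per detected BrdU-ir cell.
#' @param target Sampling target (default 50).
#' @param seed Integer seed.
#' @return A list with `n_sampled`, `n_colabeled`, `pct` (from
#'   [coexpression_pct()]), and `under_target`.
#' @export
draw_cell_sample <- function(is_colabeled, target = 50L, seed = 1L) {
  if (!is.logical(is_colabeled) || length(is_colabeled) == 0L || anyNA(is_colabeled))
    stop("'is_colabeled' must be a non-empty logical vector", call. = FALSE)
  if (!is_count(target, 1L)) stop("'target' must be a positive integer", call. = FALSE)
  if (!is_count(seed)) stop("'seed' must be an integer", call. = FALSE)
  n <- min(length(is_colabeled), target)
  with_seed(seed, {
    idx <- sample.int(length(is_colabeled), n)
    k <- sum(is_colabeled[idx])
    pct <- coexpression_pct(n, k, target = target)
    list(n_sampled = n, n_colabeled = k, pct = as.numeric(pct),
         under_target = n < target)
  })
}
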