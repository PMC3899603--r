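#' Leptin response ratios by maternal diet group
#'
#' For each gene, the log2 leptin-vs-saline expression difference averaged
#' (unweighted) over the two postweaning diets, computed separately within
#' the ad-libitum-fed (AD) and undernourished (UN) maternal groups:
#' `ad_ratio = mean_C [ mean(AD,Lep,C) - mean(AD,Sal,C) ]`, and
#' analogously for `un_ratio`. Opposite signs of the two ratios define the
#' "leptin reversal" pattern.
#'
#' @param eset A [prog_eset()] (mask honoured).
#' @param design A [study_design()]; all 8 cohorts must be populated.
#' @param genes Optional gene subset.
#' @return A data.frame: `gene_id`, `ad_ratio`, `un_ratio` (log2 scale).
#' @export
leptin_ratio_by_maternal <- function(eset, design, genes = NULL) {
  if (!is.null(genes)) eset <- eset[genes, ]
  st <- .cell_stats(eset, design)
  if (any(st$n == 0)) stop("empty cohort cell", call. = FALSE)
  M <- st$means
  data.frame(
    gene_id = rownames(eset$exprs),
    ad_ratio = (M[, "ALC"] + M[, "ALH"]) / 2 - (M[, "ASC"] + M[, "ASH"]) / 2,
    un_ratio = (M[, "ULC"] + M[, "ULH"]) / 2 - (M[, "USC"] + M[, "USH"]) / 2,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Classify an AB interaction from its leptin ratios
#'
#' Opposite signs of the AD and UN leptin ratios give a `reversal`; the
#' same sign with a larger UN magnitude is `synergistic`, with a smaller
#' UN magnitude `partially_opposing`. An exactly zero ratio, or an exact
#' magnitude tie between same-sign ratios (which the synergistic/partial
#' dichotomy cannot split), is `degenerate` rather than being assigned
#' arbitrarily; both cases are measure-zero on real data and only matter
#' for noise-free constructions.
#'
#' @param ad_ratio,un_ratio Numeric vectors (log2 scale), finite.
#' @return Character vector in
#'   `{reversal, synergistic, partially_opposing, degenerate}`.
#' @export
classify_interaction <- function(ad_ratio, un_ratio) {
  stopifnot(length(ad_ratio) == length(un_ratio),
            all(is.finite(ad_ratio)), all(is.finite(un_ratio)))
  out <- rep("degenerate", length(ad_ratio))
  nonzero <- ad_ratio != 0 & un_ratio != 0
  opp <- nonzero & (sign(ad_ratio) != sign(un_ratio))
  out[opp] <- "reversal"
  same <- nonzero & !opp
  out[same & abs(un_ratio) > abs(ad_ratio)] <- "synergistic"
  out[same & abs(un_ratio) < abs(ad_ratio)] <- "partially_opposing"
  out
}

#' Maximum fold change across cohorts
#'
#' Per gene, `2^(max cohort mean - min cohort mean)`: the fold change
#' between the highest- and lowest-expressing treatment groups. Invariant
#' under adding a constant to the gene's row; a constant gene gives 1.
#'
#' @inheritParams leptin_ratio_by_maternal
#' @return Named numeric vector of fold changes (>= 1).
#' @export
max_fold_change <- function(eset, design, genes = NULL) {
  if (!is.null(genes)) eset <- eset[genes, ]
  M <- cohort_means(eset, design)
  fc <- 2^(apply(M, 1, max) - apply(M, 1, min))
  stats::setNames(fc, rownames(eset$exprs))
}

#' Signed fold change between two cohorts
#'
#' Log2 mean difference `delta = mean(cohort_x) - mean(cohort_y)` reported
#' in the signed-fold convention: `2^delta` when `delta >= 0`,
#' `-2^(-delta)` when `delta < 0` (so -2 means halved; no value strictly
#' between -1 and 1 is producible, and 0 difference reports as 1).
#'
#' @inheritParams leptin_ratio_by_maternal
#' @param cohort_x,cohort_y Three-letter cohort codes (e.g. `"USH"`,
#'   `"ASC"`).
#' @return Named numeric vector of signed fold changes.
#' @export
contrast_fold_change <- function(eset, design, cohort_x, cohort_y, genes = NULL) {
  if (!is.null(genes)) eset <- eset[genes, ]
  stopifnot(cohort_x %in% .COHORT_LEVELS, cohort_y %in% .COHORT_LEVELS)
  M <- cohort_means(eset, design)
  if (any(!is.finite(M[, c(cohort_x, cohort_y)]))) {
    stop("empty cohort cell", call. = FALSE)
  }
  delta <- M[, cohort_x] - M[, cohort_y]
  fc <- ifelse(delta >= 0, 2^delta, -2^(-delta))
  stats::setNames(fc, rownames(eset$exprs))
}

#' Interaction-structure summary table
#'
#' Convenience wrapper combining ratios, interaction class, maximum fold
#' change, and the signed fold change against the control cohort.
#'
#' @inheritParams leptin_ratio_by_maternal
#' @param control Control cohort code (default `"ASC"`).
#' @param affected Cohort contrasted against the control (default
#'   `"USH"`).
#' @return A data.frame: `gene_id`, `ad_ratio`, `un_ratio`, `class`,
#'   `max_fc`, `fc_vs_control`.
#' @export
interaction_table <- function(eset, design, genes = NULL,
                              control = "ASC", affected = "USH") {
  if (!is.null(genes)) eset <- eset[genes, ]
  r <- leptin_ratio_by_maternal(eset, design)
  r$class <- classify_interaction(r$ad_ratio, r$un_ratio)
  r$max_fc <- unname(max_fold_change(eset, design))
  r$fc_vs_control <- unname(contrast_fold_change(eset, design, affected, control))
  r
}
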