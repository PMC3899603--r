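#' Exclude the single furthest-from-mean replicate per gene x cohort
#'
#' For each gene and each cohort cell, the single unmasked measurement
#' furthest from the cell mean (mean over all replicates in the cell) is
#' masked. Removing exactly one point per cell eliminates noisy outliers
#' while keeping the design fully balanced (e.g. 8 -> 7 per cell). Ties in
#' distance are broken towards the lowest sample index, for
#' reproducibility. Cells that already contain a masked value are left
#' untouched, so the operation is idempotent.
#'
#' @param eset A [prog_eset()].
#' @param design A [study_design()]; every cohort needs at least 3
#'   replicates (exclusion would otherwise leave fewer than 2 for variance
#'   estimation).
#' @return The `prog_eset` with an updated exclusion mask.
#' @export
exclude_outlier_per_cell <- function(eset, design) {
  .check_alignment(eset, design)
  counts <- table(design$cohort)
  if (any(counts < 3)) {
    stop("each cohort needs >= 3 replicates for outlier exclusion; smallest has ",
         min(counts), call. = FALSE)
  }
  X <- eset$exprs
  mask <- eset$mask
  for (coh in .COHORT_LEVELS) {
    idx <- which(design$cohort == coh)
    already <- rowSums(mask[, idx, drop = FALSE]) > 0
    todo <- which(!already)
    if (length(todo) == 0L) next
    Xc <- X[todo, idx, drop = FALSE]
    d <- abs(Xc - rowMeans(Xc))
    pick <- max.col(d, ties.method = "first")
    mask[cbind(todo, idx[pick])] <- TRUE
  }
  prog_eset(X, eset$detection, mask)
}

#' Remove non-expressed genes by detection-call fraction
#'
#' Drops genes called absent in at least `absent_fraction` of **all**
#' samples (the threshold is inclusive, and detection calls are data:
#' the outlier-exclusion mask is ignored here). Gene order is preserved.
#'
#' @param eset A [prog_eset()] with detection calls.
#' @param absent_fraction Threshold in (0, 1]; default 0.75.
#' @return The filtered `prog_eset`; removed gene ids are stored in
#'   `attr(, "removed_genes")`.
#' @export
presence_filter <- function(eset, absent_fraction = 0.75) {
  if (!is.numeric(absent_fraction) || length(absent_fraction) != 1 ||
      absent_fraction <= 0 || absent_fraction > 1) {
    stop("absent_fraction must lie in (0, 1]", call. = FALSE)
  }
  frac_absent <- rowMeans(!eset$detection)
  keep <- frac_absent < absent_fraction
  out <- eset[which(keep), ]
  attr(out, "removed_genes") <- rownames(eset$exprs)[!keep]
  out
}

#' QC report for the preprocessing chain
#'
#' @param eset_in The raw [prog_eset()].
#' @param eset_out The masked/filtered `prog_eset`.
#' @return A list (serialisable to JSON): gene counts before/after, number
#'   of masked values, and the per-gene masked-sample table.
#' @export
qc_report <- function(eset_in, eset_out) {
  masked <- which(eset_out$mask, arr.ind = TRUE)
  list(
    genes_before = nrow(eset_in$exprs),
    genes_after = nrow(eset_out$exprs),
    genes_removed = nrow(eset_in$exprs) - nrow(eset_out$exprs),
    values_masked = sum(eset_out$mask),
    masked_samples = data.frame(
      gene_id = rownames(eset_out$exprs)[masked[, 1]],
      sample_id = colnames(eset_out$exprs)[masked[, 2]],
      stringsAsFactors = FALSE
    )
  )
}
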