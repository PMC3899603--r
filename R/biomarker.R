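#' Filter 1: programming-significant genes
#'
#' Keeps genes for which maternal diet (A) and leptin treatment (B) are
#' both called significant, either individually or as part of an
#' interaction term: the category set contains `AB` or `ABC`, or contains
#' both some A-involving and some B-involving category (including plain
#' `A` and `B`).
#'
#' @param assign A [assign_categories()] result.
#' @return Character vector of passing gene ids.
#' @export
filter_programming_significant <- function(assign) {
  stopifnot(inherits(assign, "category_assignment"))
  pass <- vapply(assign$categories, function(cc) {
    any(grepl("A", cc, fixed = TRUE) & grepl("B", cc, fixed = TRUE)) ||
      (any(grepl("A", cc, fixed = TRUE)) && any(grepl("B", cc, fixed = TRUE)))
  }, logical(1))
  assign$gene_id[pass]
}

#' Filter 2: fold change against the control cohort
#'
#' Keeps genes whose signed fold change between the affected cohort
#' (default `USH`, the metabolic-syndrome cohort) and the control cohort
#' (default `ASC`) has magnitude at least `threshold` (inclusive).
#'
#' @param eset A [prog_eset()]. @param design A [study_design()].
#' @param genes Gene ids entering the filter.
#' @param affected,control Cohort codes.
#' @param threshold Inclusive fold-change threshold (default 1.25).
#' @return Character vector of passing gene ids (order preserved).
#' @export
filter_fold_change <- function(eset, design, genes, affected = "USH",
                               control = "ASC", threshold = 1.25) {
  if (length(genes) == 0L) return(character(0))
  fc <- contrast_fold_change(eset, design, affected, control, genes = genes)
  genes[abs(fc) >= threshold]
}

#' Filter 3: affected cohort at an expression extreme
#'
#' Keeps genes whose affected-cohort mean is the highest or lowest of the
#' 8 cohort means (ties within `tol` count as extreme).
#'
#' @inheritParams filter_fold_change
#' @param tol Tie tolerance on the log2 scale (default 1e-9).
#' @return Character vector of passing gene ids.
#' @export
filter_extreme <- function(eset, design, genes, affected = "USH", tol = 1e-9) {
  if (length(genes) == 0L) return(character(0))
  M <- cohort_means(eset[genes, ], design)
  hi <- apply(M, 1, max)
  lo <- apply(M, 1, min)
  x <- M[, affected]
  genes[x >= hi - tol | x <= lo + tol]
}

#' Flag precursor genes
#'
#' A biomarker gene is a *precursor* when it is already perturbed in the
#' predisposed-but-healthy cohort (default `USC`, chow-fed offspring of
#' undernourished mothers): the magnitude of its fold change against the
#' control cohort is at least `threshold`, regardless of direction.
#'
#' @inheritParams filter_fold_change
#' @param precursor_cohort Cohort probed for early changes (default
#'   `"USC"`).
#' @return Named logical vector over `genes`.
#' @export
flag_precursors <- function(eset, design, genes, precursor_cohort = "USC",
                            control = "ASC", threshold = 1.25) {
  if (length(genes) == 0L) return(stats::setNames(logical(0), character(0)))
  fc <- contrast_fold_change(eset, design, precursor_cohort, control, genes = genes)
  abs(fc) >= threshold
}

#' Three-filter biomarker cascade
#'
#' Runs the filter chain on categorised genes: (1) maternal diet and
#' leptin both significant (individually or via an interaction), (2) at
#' least `fc_threshold` fold change between the affected and control
#' cohorts, (3) affected-cohort expression at an extreme among the 8
#' cohorts. Survivors are annotated with their signed fold changes in the
#' precursor and affected cohorts (vs control), an up/down direction, and
#' the precursor flag. Stage counts are monotone non-increasing by
#' construction.
#'
#' @param eset A [prog_eset()]. @param design A [study_design()].
#' @param assign A [assign_categories()] result (typically on the one-way
#'   significant subset).
#' @param affected,control,precursor_cohort Cohort codes (defaults `USH`,
#'   `ASC`, `USC`).
#' @param fc_threshold Inclusive fold-change threshold (default 1.25).
#' @param tie_tol Extremeness tie tolerance (default 1e-9).
#' @return A `biomarker_cascade` list: `records` (data.frame, one row per
#'   final gene: `gene_id`, `categories`, `fc_precursor`, `fc_affected`,
#'   `direction`, `is_precursor`), `counts` (named vector: input,
#'   filter1..filter3), `n_up`, `n_down`, `n_precursor`.
#' @export
biomarker_cascade <- function(eset, design, assign, affected = "USH",
                              control = "ASC", precursor_cohort = "USC",
                              fc_threshold = 1.25, tie_tol = 1e-9) {
  g1 <- filter_programming_significant(assign)
  g2 <- filter_fold_change(eset, design, g1, affected, control, fc_threshold)
  g3 <- filter_extreme(eset, design, g2, affected, tie_tol)
  counts <- c(input = length(assign$gene_id), filter1 = length(g1),
              filter2 = length(g2), filter3 = length(g3))
  if (length(g3)) {
    fc_aff <- contrast_fold_change(eset, design, affected, control, genes = g3)
    fc_pre <- contrast_fold_change(eset, design, precursor_cohort, control, genes = g3)
    catstr <- vapply(assign$categories[match(g3, assign$gene_id)],
                     paste, character(1), collapse = ";")
    records <- data.frame(
      gene_id = g3,
      categories = catstr,
      fc_precursor = unname(fc_pre),
      fc_affected = unname(fc_aff),
      direction = ifelse(fc_aff >= 1, "up", "down"),
      is_precursor = unname(abs(fc_pre) >= fc_threshold),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    records <- data.frame(gene_id = character(0), categories = character(0),
                          fc_precursor = numeric(0), fc_affected = numeric(0),
                          direction = character(0), is_precursor = logical(0),
                          stringsAsFactors = FALSE)
  }
  structure(list(records = records, counts = counts,
                 n_up = sum(records$direction == "up"),
                 n_down = sum(records$direction == "down"),
                 n_precursor = sum(records$is_precursor)),
            class = "biomarker_cascade")
}

#' @export
print.biomarker_cascade <- function(x, ...) {
  cat("biomarker_cascade:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " -> "), "\n")
  cat("  up:", x$n_up, " down:", x$n_down, " precursors:", x$n_precursor, "\n")
  invisible(x)
}

#' Pairwise differential expression between two cohorts
#'
#' Per-gene two-sample t-test (pooled variance by default, for consistency
#' with the ANOVA framework; Welch optional) between two cohorts, with BH
#' correction across all tested genes. Zero pooled variance is handled
#' deterministically: p = 1 when the means agree, p = 0 otherwise.
#'
#' @param eset A [prog_eset()] (mask honoured).
#' @param design A [study_design()].
#' @param cohort_x,cohort_y Cohort codes; each needs >= 2 unmasked
#'   replicates per gene.
#' @param alpha FDR level for the `significant` column (default 0.05).
#' @param var_equal Pooled-variance t-test (default `TRUE`); `FALSE` gives
#'   Welch.
#' @return A data.frame: `gene_id`, `t`, `p`, `q`, `fc` (signed fold
#'   change x vs y), `significant`.
#' @export
pairwise_cohort_test <- function(eset, design, cohort_x, cohort_y,
                                 alpha = 0.05, var_equal = TRUE) {
  st <- .cell_stats(eset, design)
  for (coh in c(cohort_x, cohort_y)) {
    if (!coh %in% .COHORT_LEVELS) stop("unknown cohort: ", coh, call. = FALSE)
    if (any(st$n[, coh] < 2)) stop("cohort ", coh, " needs >= 2 unmasked replicates",
                                   call. = FALSE)
  }
  nx <- st$n[, cohort_x]; ny <- st$n[, cohort_y]
  mx <- st$means[, cohort_x]; my <- st$means[, cohort_y]
  vx <- (st$sumsq[, cohort_x] - nx * mx^2) / (nx - 1)
  vy <- (st$sumsq[, cohort_y] - ny * my^2) / (ny - 1)
  vx <- pmax(vx, 0); vy <- pmax(vy, 0)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero <- se == 0 | !is.finite(se)
  p[zero] <- ifelse(mx[zero] == my[zero], 1, 0)
  tstat[zero] <- ifelse(mx[zero] == my[zero], 0, Inf * sign(mx[zero] - my[zero]))
  fdr <- bh_fdr(p, alpha)
  delta <- mx - my
  data.frame(gene_id = rownames(eset$exprs), t = tstat, p = p, q = fdr$q,
             fc = ifelse(delta >= 0, 2^delta, -2^(-delta)),
             significant = fdr$reject,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Direction concordance of two cohorts against a reference
#'
#' Counts genes for which two cohorts deviate from a reference cohort in
#' the same direction: `sign(mean_x - mean_ref) == sign(mean_y -
#' mean_ref)`, with an exactly zero difference counted as discordant.
#'
#' @param genes Gene ids to score (non-empty).
#' @param eset A [prog_eset()]. @param design A [study_design()].
#' @param cohort_x,cohort_y,reference Cohort codes.
#' @return A list: `n_same_sign`, `n_total`.
#' @export
direction_concordance <- function(genes, eset, design, cohort_x, cohort_y,
                                  reference) {
  stopifnot(length(genes) > 0)
  M <- cohort_means(eset[genes, ], design)
  sx <- sign(M[, cohort_x] - M[, reference])
  sy <- sign(M[, cohort_y] - M[, reference])
  list(n_same_sign = sum(sx == sy & sx != 0), n_total = length(genes))
}
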