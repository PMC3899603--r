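#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH adjustment (`q_(i) = min_{j>=i} p_(j) * m / j`, clipped to 1)
#' with an inclusive rejection rule `q <= alpha`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha Target FDR (default 0.05).
#' @return A list: `q` (adjusted p-values) and `reject` (logical mask).
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) return(list(q = numeric(0), reject = logical(0)))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

# Relative tolerance used to call a sum of squares "zero".
.SS_EPS <- 1e-12

#' One-way ANOVA across the eight cohorts, per gene
#'
#' Classical fixed-effects one-way ANOVA of each gene's unmasked values
#' over the treatment cohorts (all eight in the full design; restrictions
#' to a cohort subset are supported), with BH q-values across all tested
#' genes.
#' Degenerate genes are handled deterministically: if the total sum of
#' squares is (numerically) zero the gene carries no signal and p = 1; if
#' the within-cell variance is zero but the between-cell variance is not,
#' p = 0.
#'
#' @param eset A [prog_eset()] (mask honoured).
#' @param design A [study_design()]; every cohort needs >= 2 unmasked
#'   replicates for every gene.
#' @param alpha FDR level used for the `significant` column.
#' @return A data.frame: `gene_id`, `F`, `p`, `q`, `df_between`,
#'   `df_within`, `significant`.
#' @export
one_way_anova <- function(eset, design, alpha = 0.05) {
  st <- .cell_stats(eset, design)
  present <- .COHORT_LEVELS[tabulate(design$cohort, 8L) > 0]
  st <- lapply(st, function(m) m[, present, drop = FALSE])
  if (any(st$n < 2)) {
    stop("every populated cohort needs >= 2 unmasked replicates per gene",
         call. = FALSE)
  }
  k <- length(present)
  N <- rowSums(st$n)
  grand <- rowSums(st$sum) / N
  ss_cells <- rowSums(st$sum^2 / st$n)
  ss_between <- ss_cells - N * grand^2
  ss_within <- rowSums(st$sumsq) - ss_cells
  ss_total <- ss_between + ss_within
  df_b <- k - 1L
  df_w <- N - k
  scale <- pmax(rowSums(st$sumsq), 1)
  zero_tot <- ss_total <= .SS_EPS * scale
  zero_win <- ss_within <= .SS_EPS * scale

  F <- (ss_between / df_b) / (ss_within / df_w)
  p <- stats::pf(F, df_b, df_w, lower.tail = FALSE)
  p[zero_tot] <- 1
  F[zero_tot] <- 0
  deg_sig <- zero_win & !zero_tot
  p[deg_sig] <- 0
  F[deg_sig] <- Inf
  fdr <- bh_fdr(p, alpha)
  data.frame(gene_id = rownames(eset$exprs), F = F, p = p, q = fdr$q,
             df_between = df_b, df_within = df_w,
             significant = fdr$reject,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Effect-coded single-df contrasts over the 8 cohorts (canonical order).
.threeway_contrasts <- function() {
  a <- rep(c(-1, 1), each = 4)
  b <- rep(rep(c(-1, 1), each = 2), 2)
  cc <- rep(c(-1, 1), 4)
  cbind(A = a, B = b, C = cc, AB = a * b, AC = a * cc, BC = b * cc,
        ABC = a * b * cc)
}

#' Full three-way factorial ANOVA per gene
#'
#' Fits the saturated 2x2x2 model with seven single-df terms (A = maternal
#' diet, B = neonatal treatment, C = postweaning diet, and the AB/AC/BC/ABC
#' interactions) plus residual, using the classical balanced-design sum of
#' squares decomposition (types I/II/III coincide under balance). Per-term
#' F = MS_term / MS_residual; per-term q-values by BH across the supplied
#' gene subset. Unbalanced input (unequal unmasked replicate counts across
#' cells) is refused rather than approximated, since the orthogonal
#' decomposition would not hold.
#'
#' @param eset A [prog_eset()]. @param design A [study_design()].
#' @param genes Optional gene ids/indices to analyse (default: all).
#' @return A `threeway_result` list: `gene_id`, `terms`, matrices `ss`,
#'   `F`, `p`, `q` (genes x 7 terms), `ss_resid`, `df_resid`.
#' @export
three_way_anova <- function(eset, design, genes = NULL) {
  if (!is.null(genes)) eset <- eset[genes, ]
  st <- .cell_stats(eset, design)
  n1 <- st$n[, 1]
  if (any(st$n != n1)) {
    stop("unbalanced design: unequal unmasked replicate counts across cells",
         call. = FALSE)
  }
  if (any(n1 < 2)) stop("need >= 2 unmasked replicates per cell", call. = FALSE)
  K <- .threeway_contrasts()
  M <- st$means
  ss_term <- (M %*% K)^2 * n1 / 8
  ss_resid <- rowSums(st$sumsq) - rowSums(st$sum^2 / st$n)
  df_resid <- 8 * (n1 - 1)
  scale <- pmax(rowSums(st$sumsq), 1)
  ss_total <- ss_resid + rowSums(ss_term)
  zero_tot <- ss_total <= .SS_EPS * scale
  zero_res <- ss_resid <= .SS_EPS * scale

  F <- ss_term / (ss_resid / df_resid)
  p <- stats::pf(F, 1, df_resid, lower.tail = FALSE)
  for (j in seq_len(ncol(p))) {
    pj <- p[, j]
    pj[zero_tot] <- 1
    deg <- zero_res & !zero_tot & ss_term[, j] > .SS_EPS * scale
    pj[deg] <- 0
    zero_term <- zero_res & ss_term[, j] <= .SS_EPS * scale
    pj[zero_term & !zero_tot] <- 1
    p[, j] <- pj
  }
  q <- apply(p, 2, function(x) bh_fdr(x)$q)
  if (is.null(dim(q))) q <- matrix(q, nrow = 1, dimnames = list(NULL, colnames(p)))
  structure(list(gene_id = rownames(eset$exprs), terms = colnames(K),
                 ss = ss_term, F = F, p = p, q = q,
                 ss_resid = ss_resid, df_resid = df_resid),
            class = "threeway_result")
}

#' @export
print.threeway_result <- function(x, ...) {
  cat("threeway_result:", length(x$gene_id), "genes x",
      length(x$terms), "terms (df_resid =", x$df_resid[1], ")\n")
  invisible(x)
}

#' Tidy a threeway_result into a long data.frame
#'
#' @param x A `threeway_result`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Long data.frame: `gene_id`, `term`, `ss`, `F`, `p`, `q`.
#' @export
as.data.frame.threeway_result <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    gene_id = rep(x$gene_id, times = length(x$terms)),
    term = rep(x$terms, each = length(x$gene_id)),
    ss = as.vector(x$ss), F = as.vector(x$F),
    p = as.vector(x$p), q = as.vector(x$q),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Iterative non-confounded category assignment
#'
#' Tiered classification of each gene from its per-term q-values:
#' \enumerate{
#'   \item a significant three-way interaction assigns the gene to
#'     category `ABC` and nothing else;
#'   \item otherwise every significant two-way interaction (`AB`, `AC`,
#'     `BC`) becomes a category;
#'   \item a main effect (`A`, `B`, `C`) becomes a category only when it is
#'     significant and no significant interaction term contains that
#'     factor (so `AB` blocks `A` and `B` but not `C`);
#'   \item a gene with no surviving term is `uncategorised`.
#' }
#' Categories are not mutually exclusive: a gene with additive effects of
#' two factors and no interaction sits in both main-effect categories.
#'
#' @param threeway A [three_way_anova()] result.
#' @param alpha Per-term FDR threshold for "significant" (default 0.05).
#' @return A `category_assignment` list: `gene_id`, `categories` (list of
#'   character vectors), `alpha`.
#' @export
assign_categories <- function(threeway, alpha = 0.05) {
  stopifnot(inherits(threeway, "threeway_result"))
  sig <- !is.na(threeway$q) & threeway$q <= alpha
  colnames(sig) <- threeway$terms
  abc <- sig[, "ABC"]
  cats <- vector("list", length(threeway$gene_id))
  blockA <- sig[, "AB"] | sig[, "AC"]
  blockB <- sig[, "AB"] | sig[, "BC"]
  blockC <- sig[, "AC"] | sig[, "BC"]
  for (g in seq_along(cats)) {
    if (abc[g]) {
      cats[[g]] <- "ABC"
      next
    }
    out <- c("AB", "AC", "BC")[sig[g, c("AB", "AC", "BC")]]
    if (sig[g, "A"] && !blockA[g]) out <- c(out, "A")
    if (sig[g, "B"] && !blockB[g]) out <- c(out, "B")
    if (sig[g, "C"] && !blockC[g]) out <- c(out, "C")
    cats[[g]] <- if (length(out)) out else "uncategorised"
  }
  structure(list(gene_id = threeway$gene_id, categories = cats, alpha = alpha),
            class = "category_assignment")
}

#' @export
print.category_assignment <- function(x, ...) {
  cat("category_assignment:", length(x$gene_id), "genes\n")
  print(category_counts(x))
  invisible(x)
}

#' Category membership counts (with optional fold-change qualification)
#'
#' Counts how many genes carry each category label (a gene with two labels
#' is counted in both rows). When per-gene maximum fold changes are
#' supplied, a second column restricts the count to genes at or above the
#' fold-change threshold, mirroring the parenthetical counts of the
#' published category table.
#'
#' @param assign A [assign_categories()] result.
#' @param max_fc Optional named per-gene fold changes
#'   (see [max_fold_change()]).
#' @param fc_threshold Inclusive fold-change threshold (default 1.25).
#' @return A data.frame: `category`, `n`, and `n_fc` when `max_fc` given.
#' @export
category_counts <- function(assign, max_fc = NULL, fc_threshold = 1.25) {
  stopifnot(inherits(assign, "category_assignment"))
  levels <- c("A", "B", "C", "AB", "AC", "BC", "ABC", "uncategorised")
  has <- vapply(levels, function(lv)
    vapply(assign$categories, function(cc) lv %in% cc, logical(1)),
    logical(length(assign$gene_id)))
  if (is.null(dim(has))) has <- matrix(has, nrow = 1, dimnames = list(NULL, levels))
  out <- data.frame(category = levels, n = colSums(has),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(max_fc)) {
    fc <- max_fc[assign$gene_id]
    out$n_fc <- colSums(has & !is.na(fc) & fc >= fc_threshold)
  }
  out
}
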