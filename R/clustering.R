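#' Cohort residual profiles after removing the postweaning-diet effect
#'
#' For each gene, the 8 cohort means are centred on the grand mean and the
#' postweaning-diet *main* effect is subtracted:
#' `residual(c) = mean(c) - grand - s_c * d`, where
#' `d = (mean over HF cohorts - mean over Chow cohorts) / 2` and `s_c` is
#' +1 for high-fat, -1 for chow cohorts. What remains is the expression
#' change attributable to maternal diet and/or leptin treatment (plus any
#' diet-involving interaction, which is deliberately retained). Residuals
#' sum to zero across the 8 cohorts, and the operation is idempotent.
#'
#' @param eset A [prog_eset()] (mask honoured).
#' @param design A [study_design()].
#' @param genes Optional gene subset.
#' @return Numeric matrix genes x 8 (canonical cohort order).
#' @export
remove_diet_effect <- function(eset, design, genes = NULL) {
  if (!is.null(genes)) eset <- eset[genes, ]
  M <- cohort_means(eset, design)
  .remove_diet_effect_means(M)
}

.remove_diet_effect_means <- function(M) {
  hf <- grepl("H$", colnames(M))
  grand <- rowMeans(M)
  d <- (rowMeans(M[, hf, drop = FALSE]) - rowMeans(M[, !hf, drop = FALSE])) / 2
  sgn <- ifelse(hf, 1, -1)
  R <- M - grand - outer(d, sgn)
  dimnames(R) <- dimnames(M)
  R
}

# Row z-standardisation; zero-variance rows come back as NA rows.
.standardise_rows <- function(R) {
  mu <- rowMeans(R)
  sd <- apply(R, 1, stats::sd)
  Z <- (R - mu) / sd
  Z[sd == 0, ] <- NA_real_
  Z
}

#' Hierarchically cluster genes by residual response shape
#'
#' Agglomerative clustering of per-gene residual profiles, by default on
#' row-standardised profiles with correlation distance (1 - Pearson) and
#' average linkage, cut to exactly `k` clusters. Correlation distance
#' groups genes by the *shape* of their cohort response rather than its
#' amplitude. Genes with constant profiles cannot be standardised and are
#' excluded with a warning. Deterministic for a fixed input.
#'
#' @param profiles Genes x 8 residual matrix (see [remove_diet_effect()]).
#' @param k Number of clusters (default 6).
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param standardise Row-standardise profiles first (default `TRUE`).
#' @return A `cluster_result` list: `labels` (named integer vector, 1..k),
#'   `centroids` (k x 8 matrix of mean member profiles), `hclust` (the
#'   linkage tree), `profiles` (the matrix that was clustered), `excluded`
#'   (ids of constant-profile genes).
#' @export
cluster_genes <- function(profiles, k = 6, metric = c("correlation", "euclidean"),
                          linkage = "average", standardise = TRUE) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(profiles), nrow(profiles) >= k, k >= 1)
  Z <- if (standardise) .standardise_rows(profiles) else profiles
  bad <- rowSums(is.na(Z)) > 0 | apply(Z, 1, stats::sd) == 0
  if (any(bad)) {
    warning(sum(bad), " constant-profile gene(s) excluded from clustering")
    Z <- Z[!bad, , drop = FALSE]
  }
  if (nrow(Z) < k) stop("fewer than k non-constant profiles", call. = FALSE)
  D <- if (metric == "correlation") {
    stats::as.dist(1 - stats::cor(t(Z)))
  } else {
    stats::dist(Z)
  }
  hc <- stats::hclust(D, method = linkage)
  labels <- stats::cutree(hc, k = k)
  centroids <- rowsum(Z, labels) / as.vector(table(labels))
  rownames(centroids) <- paste0("cluster_", sort(unique(labels)))
  structure(list(labels = labels, centroids = centroids, hclust = hc,
                 profiles = Z,
                 excluded = rownames(profiles)[bad]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$labels), "genes in",
      nrow(x$centroids), "clusters\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Per-cluster centroid profiles
#'
#' Arithmetic mean of the member profiles of each cluster; for a singleton
#' cluster the centroid equals the member profile.
#'
#' @param result A [cluster_genes()] result.
#' @return Numeric matrix, clusters x 8 cohorts.
#' @export
centroid_table <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  result$centroids
}

#' Export the clustering linkage tree as Newick
#'
#' @param result A [cluster_genes()] result.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
cluster_tree_newick <- function(result, file = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  phy <- ape::as.phylo(result$hclust)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' Simple residual-profile heatmap for QC
#'
#' Minimal PNG heatmap of the clustered profiles (row order follows the
#' linkage tree); intended as a quick sanity check, not a publication
#' figure.
#'
#' @param result A [cluster_genes()] result.
#' @param file Output PNG path.
#' @return The file path, invisibly.
#' @export
residual_heatmap <- function(result, file) {
  stopifnot(inherits(result, "cluster_result"))
  grDevices::png(file, width = 800, height = 1000)
  on.exit(grDevices::dev.off())
  stats::heatmap(result$profiles, Rowv = stats::as.dendrogram(result$hclust),
                 Colv = NA, scale = "none",
                 labRow = NA, margins = c(6, 2))
  invisible(file)
}
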