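# Shared fixture builders. All fixtures are built in code; nothing is
# loaded from disk.

# Build a prog_eset whose gene rows realise given per-cohort values.
# `cells` is a list of genes; each gene is an 8 x n matrix (rows = cohorts
# in canonical order) or a length-8 vector of cell means replicated n
# times exactly (noise-free).
eset_from_cells <- function(cells, n_per_cell = 4) {
  design <- factorial_design(n_per_cell)
  rows <- lapply(cells, function(g) {
    if (is.matrix(g)) {
      stopifnot(nrow(g) == 8, ncol(g) == n_per_cell)
      as.vector(t(g))
    } else {
      stopifnot(length(g) == 8)
      rep(g, each = n_per_cell)
    }
  })
  X <- do.call(rbind, rows)
  colnames(X) <- design$sample_id
  rownames(X) <- if (is.null(names(cells))) {
    sprintf("g%03d", seq_along(cells))
  } else names(cells)
  list(eset = prog_eset(X), design = design)
}

# Random balanced dataset: G genes, n per cell, iid N(0, sd) around
# per-gene random cell means scaled by effect.
random_eset <- function(G = 10, n_per_cell = 4, effect = 1, sd = 1, seed = 1) {
  set.seed(seed)
  design <- factorial_design(n_per_cell)
  mu <- matrix(rnorm(G * 8, 0, effect), G, 8)
  X <- mu[, as.integer(design$cohort), drop = FALSE] +
    matrix(rnorm(G * nrow(design), 0, sd), G, nrow(design))
  colnames(X) <- design$sample_id
  rownames(X) <- sprintf("g%03d", seq_len(G))
  list(eset = prog_eset(X), design = design, mu = mu)
}

# Independent regression oracle: per-term F from full-vs-reduced lm fits
# on effect-coded regressors (so dropping a term genuinely removes a
# column; under balance this equals the classical decomposition).
lm_term_F <- function(values, design, keep = rep(TRUE, length(values))) {
  a <- ifelse(design$maternal_diet == "UN", 1, -1)[keep]
  b <- ifelse(design$neonatal_treatment == "Lep", 1, -1)[keep]
  cc <- ifelse(design$postweaning_diet == "HF", 1, -1)[keep]
  Xf <- cbind(A = a, B = b, C = cc, AB = a * b, AC = a * cc, BC = b * cc,
              ABC = a * b * cc)
  y <- values[keep]
  full <- lm(y ~ Xf)
  rss_full <- sum(residuals(full)^2)
  df_resid <- df.residual(full)
  sapply(colnames(Xf), function(tt) {
    red <- lm(y ~ Xf[, setdiff(colnames(Xf), tt)])
    (sum(residuals(red)^2) - rss_full) / (rss_full / df_resid)
  })
}

# Minimal hand-built threeway_result with prescribed significant terms.
fake_threeway <- function(sig_terms_list, alpha = 0.05) {
  terms <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  G <- length(sig_terms_list)
  q <- matrix(0.5, G, 7, dimnames = list(NULL, terms))
  for (g in seq_len(G)) q[g, sig_terms_list[[g]]] <- 0.01
  structure(list(gene_id = sprintf("g%03d", seq_len(G)), terms = terms,
                 ss = q * 0, F = q * 0, p = q, q = q,
                 ss_resid = rep(1, G), df_resid = rep(56, G)),
            class = "threeway_result")
}
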