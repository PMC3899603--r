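test_that("bh_fdr reproduces the hand-computed step-up adjustment", {
  r <- bh_fdr(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_equal(r$q, c(0.03, 0.03, 0.04), tolerance = 1e-12)
  expect_true(all(r$reject))

  r1 <- bh_fdr(0.5)
  expect_equal(r1$q, 0.5)
  expect_false(r1$reject)

  # boundary is inclusive: q == alpha rejects
  m <- 10
  rb <- bh_fdr(rep(0.05, m), alpha = 0.05)
  expect_equal(rb$q, rep(0.05, m))
  expect_true(all(rb$reject))

  expect_identical(bh_fdr(numeric(0))$q, numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("one-way F matches a direct sum-of-squares oracle and lm", {
  fx <- random_eset(G = 15, n_per_cell = 7, seed = 8)
  res <- one_way_anova(fx$eset, fx$design)
  for (g in seq_len(15)) {
    x <- fx$eset$exprs[g, ]
    grp <- fx$design$cohort
    means <- tapply(x, grp, mean)
    ssb <- sum(tapply(x, grp, length) * (means - mean(x))^2)
    ssw <- sum((x - means[grp])^2)
    F_oracle <- (ssb / 7) / (ssw / (length(x) - 8))
    expect_equal(res$F[g], F_oracle, tolerance = 1e-10)
    # independent route: aov
    F_lm <- summary(aov(x ~ grp))[[1]]$`F value`[1]
    expect_equal(res$F[g], F_lm, tolerance = 1e-8)
  }
  expect_equal(res$df_between, rep(7, 15))
  expect_equal(res$df_within, rep(7 * 8 * 7 / 7 - 8, 15))
})

test_that("one-way handles degenerate zero-variance genes deterministically", {
  cells <- list(
    signal_no_noise = c(0, 0, 0, 0, 1, 1, 1, 1),
    constant        = rep(2, 8)
  )
  fx <- eset_from_cells(cells, n_per_cell = 4)
  res <- one_way_anova(fx$eset, fx$design)
  expect_equal(res$p[1], 0)   # between-cell signal, zero within variance
  expect_true(res$significant[1])
  expect_equal(res$p[2], 1)   # no signal at all
  expect_false(res$significant[2])
})

test_that("one-way on a two-cohort restriction equals the squared pooled t", {
  set.seed(9)
  design2 <- study_design(data.frame(
    sample_id = sprintf("s%02d", 1:12),
    maternal_diet = rep(c("AD", "UN"), each = 6),
    neonatal_treatment = "Sal", postweaning_diet = "Chow"
  ))
  X <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(sprintf("g%d", 1:5), design2$sample_id))
  res <- one_way_anova(prog_eset(X), design2)
  for (g in 1:5) {
    t <- t.test(X[g, 1:6], X[g, 7:12], var.equal = TRUE)$statistic
    expect_equal(res$F[g], unname(t^2), tolerance = 1e-10)
  }
  expect_equal(res$df_between[1], 1)
  expect_equal(res$df_within[1], 10)
})

test_that("three-way SS isolate planted single-term patterns", {
  cells <- list(
    pure_A  = c(0, 0, 0, 0, 1, 1, 1, 1),
    pure_AB = c(1, 1, -1, -1, -1, -1, 1, 1)  # +d,-d,-d,+d over AxB, flat in C
  )
  fx <- eset_from_cells(cells, n_per_cell = 4)
  # add reproducible noise-free jitter-free matrix; SS checked structurally
  tw <- three_way_anova(fx$eset, fx$design)
  ssA <- tw$ss[1, ]
  expect_gt(ssA[["A"]], 0)
  expect_equal(unname(ssA[setdiff(names(ssA), "A")]), rep(0, 6),
               tolerance = 1e-12)
  ssAB <- tw$ss[2, ]
  expect_gt(ssAB[["AB"]], 0)
  expect_equal(unname(ssAB[setdiff(names(ssAB), "AB")]), rep(0, 6),
               tolerance = 1e-12)
})

test_that("three-way F matches the full-vs-reduced regression oracle", {
  fx <- random_eset(G = 8, n_per_cell = 5, seed = 10)
  tw <- three_way_anova(fx$eset, fx$design)
  for (g in seq_len(8)) {
    F_oracle <- lm_term_F(fx$eset$exprs[g, ], fx$design)
    expect_equal(unname(tw$F[g, ]), unname(F_oracle), tolerance = 1e-8)
  }
})

test_that("balanced-design SS are orthogonal and label-permutation covariant", {
  fx <- random_eset(G = 12, n_per_cell = 4, seed = 11)
  tw <- three_way_anova(fx$eset, fx$design)
  x <- fx$eset$exprs
  ss_total <- rowSums((x - rowMeans(x))^2)
  recomposed <- rowSums(tw$ss) + tw$ss_resid
  expect_equal(recomposed, ss_total, tolerance = 1e-8, ignore_attr = TRUE)

  # swapping the A and B factor labels permutes term SS, never changes them
  design_sw <- study_design(data.frame(
    sample_id = fx$design$sample_id,
    maternal_diet = ifelse(fx$design$neonatal_treatment == "Lep", "UN", "AD"),
    neonatal_treatment = ifelse(fx$design$maternal_diet == "UN", "Lep", "Sal"),
    postweaning_diet = fx$design$postweaning_diet
  ))
  tw_sw <- three_way_anova(fx$eset, design_sw)
  perm <- c(A = "B", B = "A", C = "C", AB = "AB", AC = "BC", BC = "AC",
            ABC = "ABC")
  expect_equal(unname(tw_sw$ss[, perm]), unname(tw$ss), tolerance = 1e-9)
})

test_that("three-way refuses unbalanced designs", {
  fx <- random_eset(G = 4, n_per_cell = 4, seed = 12)
  es <- fx$eset
  es$mask[, 1] <- TRUE  # knock one replicate out of one cell only
  expect_error(three_way_anova(es, fx$design), "unbalanced")
})

test_that("category assignment follows the iterative non-confounding rules", {
  tw <- fake_threeway(list(
    c("ABC", "AB", "A"),   # three-way dominates everything
    c("AB", "C"),          # C not confounded by AB
    c("A", "B"),           # additive: both mains kept
    character(0),          # nothing -> uncategorised
    c("AB", "A", "C"),     # AB blocks A, C survives
    c("AC", "BC", "B")     # B blocked by BC; AC and BC kept
  ))
  res <- assign_categories(tw)
  expect_identical(res$categories[[1]], "ABC")
  expect_setequal(res$categories[[2]], c("AB", "C"))
  expect_setequal(res$categories[[3]], c("A", "B"))
  expect_identical(res$categories[[4]], "uncategorised")
  expect_setequal(res$categories[[5]], c("AB", "C"))
  expect_setequal(res$categories[[6]], c("AC", "BC"))

  counts <- category_counts(res)
  expect_equal(counts$n[counts$category == "AB"], 2)
  expect_equal(counts$n[counts$category == "C"], 2)
  expect_equal(counts$n[counts$category == "uncategorised"], 1)
})

test_that("fold-change-qualified category counts respect the threshold", {
  tw <- fake_threeway(list("A", "A", "B"))
  res <- assign_categories(tw)
  fc <- setNames(c(1.5, 1.1, 1.25), res$gene_id)
  counts <- category_counts(res, max_fc = fc)
  expect_equal(counts$n_fc[counts$category == "A"], 1)
  expect_equal(counts$n_fc[counts$category == "B"], 1)  # 1.25 inclusive
})
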