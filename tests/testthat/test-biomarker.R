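test_that("filter 1 requires both programming factors, alone or in interaction", {
  tw <- fake_threeway(list("AB", c("A", "B"), c("A", "C"), "ABC", "C",
                           character(0)))
  assign <- assign_categories(tw)
  pass <- filter_programming_significant(assign)
  expect_setequal(pass, c("g001", "g002", "g004"))
})

test_that("fold-change and extremeness filters apply their boundary rules", {
  d <- log2(1.25)
  fx <- eset_from_cells(list(
    at_boundary = c(0, 0, 0, 0, 0, d, 0, 0),        # USH fold exactly +1.25
    down_past   = c(0, 0, 0, 0, 0, -log2(1.30), 0, 0),
    too_small   = c(0, 0, 0, 0, 0, log2(1.10), 0, 0),
    not_extreme = c(0, 0.9, 0, 0, 0, 0.6, 0, 0),    # USH 2nd highest
    tied_min    = c(0.5, 0.5, 0.5, 0.5, 0.5, 0, 0, 0.5)  # USH ties ULC for min
  ))
  genes <- rownames(fx$eset$exprs)
  f2 <- filter_fold_change(fx$eset, fx$design, genes)
  expect_setequal(f2, c("at_boundary", "down_past", "not_extreme", "tied_min"))
  f3 <- filter_extreme(fx$eset, fx$design, f2)
  expect_setequal(f3, c("at_boundary", "down_past", "tied_min"))
})

test_that("precursor flag is a direction-agnostic 1.25-fold rule", {
  fx <- eset_from_cells(list(
    strong_up = c(0, 0, 0, 0, log2(2.95), log2(3.52), 0, 0),
    weak      = c(0, 0, 0, 0, log2(1.24), log2(1.77), 0, 0),
    down      = c(0, 0, 0, 0, -log2(1.38), -log2(3.51), 0, 0)
  ))
  genes <- rownames(fx$eset$exprs)
  flags <- flag_precursors(fx$eset, fx$design, genes)
  expect_identical(unname(flags), c(TRUE, FALSE, TRUE))
  fc <- contrast_fold_change(fx$eset, fx$design, "USC", "ASC")
  expect_equal(unname(fc), c(2.95, 1.24, -1.38), tolerance = 1e-9)
})

test_that("the noise-free cascade returns exactly the planted gene set", {
  # planted biomarkers: AB-significant, >=1.25 fold in USH vs ASC, USH at
  # an extreme; decoys fail exactly one filter each
  planted_up <- c(0, 0, 0.6, 0.6, 0.6, 1.0, 0, 0)       # AB-ish, USH max
  planted_dn <- -planted_up
  decoy_cat <- c(0, 0.8, 0, 0.8, 0, 0.8, 0, 0.8)        # pure C effect
  decoy_fc <- c(0, 0, 0.6, 0.6, 0.6, 0.3, 0, 0)         # USH fold 2^0.3 < 1.25
  decoy_ext <- c(0, 1.2, 0.6, 0.6, 0.6, 1.0, 0, 0)      # USH not extreme
  base <- list(bio_up = planted_up, bio_dn = planted_dn,
               dec_cat = decoy_cat, dec_fc = decoy_fc, dec_ext = decoy_ext)
  # add tiny fixed replicate jitter so ANOVA variances are positive
  set.seed(40)
  cells <- lapply(base, function(mu)
    matrix(rep(mu, 4), 8, 4) + matrix(rnorm(32, 0, 1e-3), 8, 4))
  fx <- eset_from_cells(cells, n_per_cell = 4)
  tw <- three_way_anova(fx$eset, fx$design)
  assign <- assign_categories(tw)
  casc <- biomarker_cascade(fx$eset, fx$design, assign)
  expect_setequal(casc$records$gene_id, c("bio_up", "bio_dn"))
  expect_true(all(diff(casc$counts) <= 0))  # monotone non-increasing chain
  expect_identical(casc$records$direction[casc$records$gene_id == "bio_up"], "up")
  expect_identical(casc$records$direction[casc$records$gene_id == "bio_dn"], "down")
  expect_equal(casc$n_up + casc$n_down, nrow(casc$records))
})

test_that("pairwise cohort test is calibrated, powered, and t^2-consistent", {
  fx <- random_eset(G = 30, n_per_cell = 7, seed = 41)
  X <- fx$eset$exprs
  # make the two compared cohorts identical: zero DE genes
  asc <- fx$design$cohort == "ASC"
  alc <- fx$design$cohort == "ALC"
  X[, alc] <- X[, asc]
  es <- prog_eset(X)
  r0 <- pairwise_cohort_test(es, fx$design, "ASC", "ALC")
  expect_equal(sum(r0$significant), 0)

  # one gene shifted by 10 sigma is detected
  X2 <- X
  X2[5, alc] <- X2[5, alc] + 10
  r1 <- pairwise_cohort_test(prog_eset(X2), fx$design, "ASC", "ALC")
  expect_true(r1$significant[5])
  expect_equal(sum(r1$significant), 1)

  # t^2 equals the two-cohort one-way F
  sub <- fx$design$cohort %in% c("ASC", "ALC")
  design2 <- study_design(as.data.frame(fx$design)[sub,
    c("sample_id", "maternal_diet", "neonatal_treatment", "postweaning_diet")])
  ow <- one_way_anova(prog_eset(fx$eset$exprs[, sub]), design2)
  r2 <- pairwise_cohort_test(fx$eset, fx$design, "ASC", "ALC")
  expect_equal(r2$t^2, ow$F, tolerance = 1e-10)
})

test_that("direction concordance counts signed agreement against a reference", {
  fx <- random_eset(G = 20, n_per_cell = 4, seed = 42)
  genes <- rownames(fx$eset$exprs)
  X <- fx$eset$exprs
  # cohort ULH copied onto USC: fully concordant vs reference ASC
  X[, fx$design$cohort == "USC"] <- X[, fx$design$cohort == "ULH"]
  es <- prog_eset(X)
  cc <- direction_concordance(genes, es, fx$design, "USC", "ULH", "ASC")
  expect_equal(cc$n_same_sign, 20)
  expect_equal(cc$n_total, 20)

  # cohort equal to the reference: zero signs, all discordant
  X2 <- fx$eset$exprs
  X2[, fx$design$cohort == "USC"] <- X2[, fx$design$cohort == "ASC"]
  cc0 <- direction_concordance(genes, prog_eset(X2), fx$design,
                               "USC", "ULH", "ASC")
  expect_equal(cc0$n_same_sign, 0)

  # random data vs brute-force sign table
  M <- cohort_means(fx$eset, fx$design)
  sx <- sign(M[, "ALC"] - M[, "ASC"]); sy <- sign(M[, "USH"] - M[, "ASC"])
  cc2 <- direction_concordance(genes, fx$eset, fx$design, "ALC", "USH", "ASC")
  expect_equal(cc2$n_same_sign, sum(sx == sy & sx != 0))
})
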