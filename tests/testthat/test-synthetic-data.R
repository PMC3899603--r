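test_that("sim_config validates its proportions and probabilities", {
  expect_s3_class(sim_config(n_genes = 10), "sim_config")
  bad_mix <- c(null = 0.9, A = 0.2, B = 0, C = 0, AB_reversal = 0,
               AB_synergistic = 0, AB_partial = 0, ABC = 0)
  expect_error(sim_config(category_mix = bad_mix), "sum to 1")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(sim_config(absent_prob = 1.5), "probabilities")
  expect_error(sim_config(category_mix = c(null = 1)), "named over")
})

test_that("noise-free null genes have equal planted and realised cell means", {
  cfg <- sim_config(n_genes = 20, noise_sd = 0, outlier_prob = 0,
                    absent_prob = 0,
                    category_mix = c(null = 1, A = 0, B = 0, C = 0,
                                     AB_reversal = 0, AB_synergistic = 0,
                                     AB_partial = 0, ABC = 0),
                    seed = 3)
  dat <- generate_factorial_expression(cfg)
  M <- cohort_means(dat$eset, dat$design)
  expect_equal(apply(M, 1, max) - apply(M, 1, min), rep(0, 20),
               ignore_attr = TRUE)
  expect_true(all(dat$truth$genes$category == "null"))
  # ground-truth invariant: null => all planted cell means equal
  expect_equal(apply(dat$truth$cell_means, 1, stats::sd), rep(0, 20),
               ignore_attr = TRUE)
})

test_that("noise-free reversal genes realise the planted leptin ratios", {
  cfg <- sim_config(n_genes = 12, noise_sd = 0, outlier_prob = 0,
                    absent_prob = 0, effect_size = 0.5,
                    category_mix = c(null = 0, A = 0, B = 0, C = 0,
                                     AB_reversal = 1, AB_synergistic = 0,
                                     AB_partial = 0, ABC = 0),
                    seed = 5)
  dat <- generate_factorial_expression(cfg)
  r <- leptin_ratio_by_maternal(dat$eset, dat$design)
  s <- dat$truth$genes$sign
  expect_equal(r$ad_ratio, 0.5 * s, tolerance = 1e-12)
  expect_equal(r$un_ratio, -0.5 * s, tolerance = 1e-12)
  expect_true(all(classify_interaction(r$ad_ratio, r$un_ratio) == "reversal"))
})

test_that("generation is deterministic and its stream is partitioned by gene", {
  cfg <- sim_config(n_genes = 40, absent_prob = 0.3, seed = 11)
  a <- generate_factorial_expression(cfg)
  b <- generate_factorial_expression(cfg)
  expect_identical(a$eset$exprs, b$eset$exprs)
  expect_identical(a$eset$detection, b$eset$detection)
  expect_identical(a$truth, b$truth)
  # enlarging the gene set must not perturb earlier genes
  big <- generate_factorial_expression(sim_config(n_genes = 80,
                                                  absent_prob = 0.3, seed = 11))
  expect_identical(a$eset$exprs, big$eset$exprs[1:40, ])
  expect_identical(a$truth$genes$category, big$truth$genes$category[1:40])
})

test_that("absent genes are called absent in at least 75% of samples", {
  cfg <- sim_config(n_genes = 200, absent_prob = 0.5, seed = 13)
  dat <- generate_factorial_expression(cfg)
  absent <- dat$truth$genes$absent
  expect_gt(sum(absent), 50)
  frac_absent <- rowMeans(!dat$eset$detection)
  expect_true(all(frac_absent[absent] >= 0.75))
  expect_true(all(frac_absent[!absent] < 0.75))
})

test_that("empirical cell means converge to planted means at sigma/sqrt(n)", {
  cfg <- sim_config(n_genes = 5, n_per_cell = 1000, noise_sd = 0.25,
                    outlier_prob = 0, absent_prob = 0, seed = 17)
  dat <- generate_factorial_expression(cfg)
  M <- cohort_means(dat$eset, dat$design)
  err <- abs(M - dat$truth$cell_means)
  # 5 sigma/sqrt(n) bound on each of 40 cell means
  expect_true(all(err < 5 * 0.25 / sqrt(1000)))
})

test_that("growth generator recovers planted relative curves", {
  flat <- setNames(rep(1, 8), cohort_levels())
  g0 <- generate_growth_data(flat, days = c(1, 10, 20), n_per_cohort = 4,
                             noise_sd = 0, animal_sd = 0, seed = 1)
  rc <- relative_growth_curve(g0, "ULH", "ASC")
  expect_equal(rc$pct, rep(100, 3), tolerance = 1e-12)

  m <- flat; m["ULH"] <- 0.9
  g1 <- generate_growth_data(m, days = c(1, 10, 20), n_per_cohort = 4,
                             noise_sd = 0, animal_sd = 0, seed = 1)
  rc1 <- relative_growth_curve(g1, "ULH", "ASC")
  expect_equal(rc1$pct, rep(90, 3), tolerance = 1e-12)

  # Monte-Carlo: noisy cohort mean within 3 s.e.m. of the planted value
  g2 <- generate_growth_data(m, days = c(30), n_per_cohort = 8,
                             noise_sd = 0.05, animal_sd = 0.03, seed = 7)
  rc2 <- relative_growth_curve(g2, "ULH", "ASC")
  expect_lt(abs(rc2$pct - 90), 3 * rc2$sem + 3 * 100 * 0.06 / sqrt(8))

  bad <- flat; bad["ASC"] <- -1
  expect_error(generate_growth_data(bad, days = c(1, 10)), "positive")
})

test_that("phenotype generator plants recoverable factorial effects", {
  design <- factorial_design(8)
  # noise-free planted postweaning-diet effect: only the C term fires
  ph <- generate_phenotypes(design, effects = list(fat = c(C = 10)),
                            baselines = c(fat = 20), noise_sd = 0, seed = 1)
  res <- phenotype_threeway_anova(ph)
  sig <- res[res$significant, ]
  expect_identical(sig$term, "C")
  expect_equal(ph$fat[ph$postweaning_diet == "HF"][1] -
                 ph$fat[ph$postweaning_diet == "Chow"][1], 10)

  # simulation power check: planted F close to its expectation
  spec <- default_phenotype_spec()
  Fs <- replicate(20, {
    p <- generate_phenotypes(design, spec$effects, spec$baselines,
                             spec$noise_sd, seed = sample.int(1e6, 1))
    r <- phenotype_threeway_anova(p)
    r$F[r$trait == "body_fat_pct" & r$term == "C"]
  })
  expect_gt(mean(Fs), 100)  # planted for E[F] ~ 150 at n = 64
  expect_lt(mean(Fs), 220)
})

test_that("unknown phenotype terms are refused", {
  design <- factorial_design(2)
  expect_error(generate_phenotypes(design, effects = list(x = c(AD = 1))),
               "unknown term")
})
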