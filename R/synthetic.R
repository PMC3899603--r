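#' Simulation configuration for the factorial expression generator
#'
#' Defaults emulate the study design this package targets: a rat liver
#' array of ~22,000 probes of which ~8,500 are expressed, profiled over
#' 8 cohorts (2x2x2 factorial) with 8 replicates each. The category mix
#' defaults reproduce the published relative frequencies of significant
#' gene classes among expressed genes (the large majority of
#' maternal-diet-by-leptin interactions being of the "reversal" type).
#'
#' @param n_genes Number of probes to simulate.
#' @param n_per_cell Replicates per cohort (8 cohorts).
#' @param category_mix Named proportions over
#'   `null, A, B, C, AB_reversal, AB_synergistic, AB_partial, ABC`;
#'   must sum to 1. Applied to expressed (non-absent) genes; absent genes
#'   are always effect-free.
#' @param effect_size Planted effect, log2 units (see
#'   [generate_factorial_expression()] for the per-category shapes).
#' @param noise_sd Residual Gaussian sd, log2 units.
#' @param outlier_prob Probability that a gene x cohort cell contains one
#'   shifted outlier replicate.
#' @param outlier_shift Magnitude of the outlier shift, log2 units.
#' @param absent_prob Probability that a gene is globally low-expressed
#'   (absent detection calls in at least 75% of samples).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 22000,
                       n_per_cell = 8,
                       category_mix = c(null = 0.7042, A = 0.0433, B = 0.0235,
                                        C = 0.1165, AB_reversal = 0.1025,
                                        AB_synergistic = 0.0067,
                                        AB_partial = 0.0025, ABC = 0.0008),
                       effect_size = 0.5,
                       noise_sd = 0.25,
                       outlier_prob = 0.01,
                       outlier_shift = 1.5,
                       absent_prob = 0.6122,
                       seed = 1L) {
  cats <- c("null", "A", "B", "C", "AB_reversal", "AB_synergistic",
            "AB_partial", "ABC")
  if (!setequal(names(category_mix), cats)) {
    stop("category_mix must be named over: ", paste(cats, collapse = ", "),
         call. = FALSE)
  }
  category_mix <- category_mix[cats]
  if (any(category_mix < 0)) stop("category_mix proportions must be >= 0", call. = FALSE)
  if (abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix must sum to 1 (got ", sum(category_mix), ")", call. = FALSE)
  }
  if (n_genes < 1 || n_per_cell < 2) stop("need n_genes >= 1 and n_per_cell >= 2", call. = FALSE)
  if (noise_sd < 0 || outlier_shift < 0) stop("sds/shifts must be non-negative", call. = FALSE)
  for (p in c(outlier_prob, absent_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_cell = as.integer(n_per_cell),
                 category_mix = category_mix, effect_size = effect_size,
                 noise_sd = noise_sd, outlier_prob = outlier_prob,
                 outlier_shift = outlier_shift, absent_prob = absent_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Relative planted cohort-mean patterns (canonical cohort order), in units
# of effect_size (delta). Reversal is the "either intervention, not both"
# shape: both single interventions raise expression, the combination does
# not, so the leptin response flips sign between maternal-diet groups.
# Synergistic/partial keep the same response sign in both groups with the
# undernourished response respectively doubled or halved (interaction
# deviation = delta in both cases).
.category_pattern <- function(category) {
  # order: ASC ASH ALC ALH USC USH ULC ULH
  switch(category,
    null           = rep(0, 8),
    A              = c(0, 0, 0, 0, 1, 1, 1, 1),
    B              = c(0, 0, 1, 1, 0, 0, 1, 1),
    C              = c(0, 1, 0, 1, 0, 1, 0, 1),
    AB_reversal    = c(0, 0, 1, 1, 1, 1, 0, 0),
    AB_synergistic = c(0, 0, 1, 1, 0, 0, 2, 2),
    AB_partial     = c(0, 0, 2, 2, 0, 0, 1, 1),
    ABC            = c(0, 0.5, 0.5, 0, 0.5, 0, 0, 0.5) * 2 - 0.5,
    stop("unknown category: ", category, call. = FALSE)
  )
}

# The ABC pattern above is (delta/2) * a*b*c effect coding shifted to be
# expressible via switch; verify once at load time.
local({
  a <- rep(c(-1, 1), each = 4); b <- rep(rep(c(-1, 1), each = 2), 2)
  cc <- rep(c(-1, 1), 4)
  stopifnot(all(.category_pattern("ABC") == 0.5 * a * b * cc))
})

#' Build the balanced 2x2x2 design used by the simulators
#'
#' @param n_per_cell Replicates per cohort.
#' @return A [study_design()] with `8 * n_per_cell` samples, cohorts in
#'   canonical order, sample ids like `"USC_3"`.
#' @export
factorial_design <- function(n_per_cell = 8) {
  lev <- parse_cohort_code(rep(.COHORT_LEVELS, each = n_per_cell))
  lev$sample_id <- paste0(rep(.COHORT_LEVELS, each = n_per_cell), "_",
                          rep(seq_len(n_per_cell), times = 8))
  lev$animal_id <- lev$sample_id
  study_design(lev)
}

#' Generate a factorial expression dataset with known ground truth
#'
#' Simulates a genes x samples log2-scale expression matrix under the
#' balanced 2x2x2 design. Each gene draws a baseline level, a planted
#' category (with additive log2-scale cohort-mean shifts of magnitude
#' `effect_size` in the category's shape, random overall sign), i.i.d.
#' Gaussian noise, sporadic outlier replicates, and per-sample detection
#' calls. A fraction `absent_prob` of genes is globally low-expressed and
#' called absent in at least 75% of samples.
#'
#' The random stream is partitioned by gene index: gene g's draws depend
#' only on `seed` and g, so enlarging `n_genes` never perturbs earlier
#' genes.
#'
#' @param config A [sim_config()].
#' @return A list with elements `eset` ([prog_eset()]), `design`
#'   ([study_design()]) and `truth` (a list with `genes`, a data.frame of
#'   per-gene category/sign/absent flags, and `cell_means`, the planted
#'   genes x 8 cohort-mean matrix).
#' @export
generate_factorial_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  design <- factorial_design(config$n_per_cell)
  G <- config$n_genes
  N <- nrow(design)
  npc <- config$n_per_cell
  cats <- names(config$category_mix)

  set.seed(config$seed)
  gene_seed <- sample.int(.Machine$integer.max, G)

  X <- matrix(0, G, N,
              dimnames = list(sprintf("gene_%05d", seq_len(G)), design$sample_id))
  D <- matrix(TRUE, G, N, dimnames = dimnames(X))
  category <- character(G)
  sign_flip <- integer(G)
  absent <- logical(G)
  cell_means <- matrix(0, G, 8, dimnames = list(rownames(X), .COHORT_LEVELS))
  cohort_of <- as.integer(design$cohort)

  for (g in seq_len(G)) {
    set.seed(gene_seed[g])
    absent[g] <- stats::runif(1) < config$absent_prob
    category[g] <- if (absent[g]) "null" else
      sample(cats, 1L, prob = config$category_mix)
    sign_flip[g] <- if (stats::runif(1) < 0.5) 1L else -1L
    baseline <- if (absent[g]) stats::runif(1, 4.5, 6) else stats::runif(1, 7, 13)
    mu <- baseline + sign_flip[g] * config$effect_size *
      .category_pattern(category[g])
    cell_means[g, ] <- mu
    x <- mu[cohort_of] + stats::rnorm(N, 0, config$noise_sd)
    # sporadic outlier replicates, at most one per cohort cell
    hit <- stats::runif(8) < config$outlier_prob
    if (any(hit)) {
      for (k in which(hit)) {
        j <- which(cohort_of == k)[sample.int(npc, 1L)]
        x[j] <- x[j] + sample(c(-1, 1), 1L) * config$outlier_shift
      }
    }
    X[g, ] <- x
    if (absent[g]) {
      n_present <- min(stats::rbinom(1, N, 0.08), floor(0.25 * N))
      pres <- logical(N)
      if (n_present > 0) pres[sample.int(N, n_present)] <- TRUE
      D[g, ] <- pres
    } else {
      D[g, ] <- stats::runif(N) >= 0.02
    }
  }

  truth <- list(
    genes = data.frame(gene_id = rownames(X), category = category,
                       sign = sign_flip, absent = absent,
                       stringsAsFactors = FALSE),
    cell_means = cell_means
  )
  list(eset = prog_eset(X, detection = D), design = design, truth = truth)
}

#' Planted reversal-archetype residual shapes
#'
#' Six canonical response-pattern archetypes on the 8-cohort grid,
#' mirroring the broad cluster groups seen in programmed livers: patterns
#' 1-3 are induced by either single intervention (maternal undernutrition
#' or neonatal leptin) but not their combination -- uniformly (1), on chow
#' only (2) or on high-fat only (3) -- and patterns 4-6 are their
#' mirror-image repressed versions.
#'
#' @return A 6 x 8 numeric matrix (rows = archetypes, columns = cohorts in
#'   canonical order), in units of the planted effect size.
#' @export
archetype_profiles <- function() {
  g1 <- c(0, 0, 1, 1, 1, 1, 0, 0)
  g2 <- c(0, 0, 1, 0, 1, 0, 0, 0)
  g3 <- c(0, 0, 0, 1, 0, 1, 0, 0)
  m <- rbind(arch1 = g1, arch2 = g2, arch3 = g3,
             arch4 = -g1, arch5 = -g2, arch6 = -g3)
  colnames(m) <- .COHORT_LEVELS
  m
}

#' Simulate expression planted on the six reversal archetypes
#'
#' @param n_per_archetype Genes per archetype.
#' @param delta Effect size, log2 units.
#' @param noise_sd Residual sd, log2 units.
#' @param n_per_cell Replicates per cohort.
#' @param seed Integer seed.
#' @return A list with `eset`, `design` and `labels` (integer archetype
#'   label per gene, 1..6).
#' @export
simulate_archetype_expression <- function(n_per_archetype = 40, delta = 0.75,
                                          noise_sd = 0.25, n_per_cell = 8,
                                          seed = 1L) {
  design <- factorial_design(n_per_cell)
  arch <- archetype_profiles()
  labels <- rep(seq_len(nrow(arch)), each = n_per_archetype)
  G <- length(labels)
  set.seed(seed)
  baseline <- stats::runif(G, 7, 13)
  mu <- baseline + delta * arch[labels, , drop = FALSE]
  cohort_of <- as.integer(design$cohort)
  X <- mu[, cohort_of, drop = FALSE] +
    matrix(stats::rnorm(G * nrow(design), 0, noise_sd), G, nrow(design))
  colnames(X) <- design$sample_id
  rownames(X) <- sprintf("arch%d_gene_%04d", labels, seq_len(G))
  list(eset = prog_eset(X), design = design, labels = labels)
}

#' Generate longitudinal weight data
#'
#' Per-animal weight trajectories around a shared base growth curve, with a
#' per-cohort multiplier that may vary by day (a cohort x day matrix) to
#' emulate transient growth restriction and catch-up. Noise is
#' multiplicative Gaussian -- a per-animal scale plus per-measurement
#' jitter -- so spread grows with body size and the cohort mean converges
#' to `base_curve * multiplier`.
#'
#' @param cohort_multipliers Either a named numeric vector (one scalar per
#'   cohort) or a cohorts x days matrix with dimnames.
#' @param days Measurement days (strictly increasing).
#' @param base_curve Base weights (grams) per day; defaults to a logistic
#'   growth curve typical of female rats.
#' @param n_per_cohort Animals per cohort.
#' @param noise_sd Fractional per-measurement sd.
#' @param animal_sd Fractional per-animal (shared across days) sd.
#' @param seed Integer seed.
#' @return A long-format data.frame: `animal_id`, `cohort`, `day`,
#'   `weight_g`.
#' @export
generate_growth_data <- function(cohort_multipliers = default_growth_multipliers(),
                                 days = default_growth_days(),
                                 base_curve = NULL,
                                 n_per_cohort = 8,
                                 noise_sd = 0.06,
                                 animal_sd = 0.04,
                                 seed = 1L) {
  if (is.null(base_curve)) base_curve <- rat_base_curve(days)
  stopifnot(length(base_curve) == length(days), all(diff(days) > 0))
  if (is.matrix(cohort_multipliers)) {
    M <- cohort_multipliers[.COHORT_LEVELS, as.character(days), drop = FALSE]
  } else {
    M <- matrix(cohort_multipliers[.COHORT_LEVELS], 8, length(days),
                dimnames = list(.COHORT_LEVELS, days))
  }
  if (any(!is.finite(M)) || any(M <= 0)) {
    stop("cohort multipliers must be positive for all cohorts and days",
         call. = FALSE)
  }
  planted <- sweep(M, 2, base_curve, `*`)
  if (any(planted <= 0)) stop("planted weights must be positive", call. = FALSE)

  set.seed(seed)
  out <- vector("list", 8)
  for (k in seq_len(8)) {
    coh <- .COHORT_LEVELS[k]
    u <- stats::rnorm(n_per_cohort, 0, animal_sd)
    e <- matrix(stats::rnorm(n_per_cohort * length(days), 0, noise_sd),
                n_per_cohort, length(days))
    w <- outer(1 + u, planted[k, ]) + sweep(e, 2, planted[k, ], `*`)
    out[[k]] <- data.frame(
      animal_id = rep(paste0(coh, "_a", seq_len(n_per_cohort)), times = length(days)),
      cohort = coh,
      day = rep(days, each = n_per_cohort),
      weight_g = as.vector(w),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Default measurement days for simulated growth series
#' @return Integer vector of postnatal days.
#' @export
default_growth_days <- function() c(1L, 3L, 7L, 14L, 21L, 30L, 60L, 90L, 108L, 135L, 171L)

#' Logistic base growth curve for a female rat
#'
#' @param days Postnatal days.
#' @param w0 Birth-range weight (g). @param wmax Adult asymptote (g).
#' @param k Growth rate (1/day). @param midpoint Inflection day.
#' @return Weights in grams, one per day.
#' @export
rat_base_curve <- function(days, w0 = 6, wmax = 280, k = 0.055, midpoint = 45) {
  w0 + (wmax - w0) / (1 + exp(-k * (days - midpoint)))
}

#' Default cohort growth-multiplier table
#'
#' Emulates the female growth series of the study this package models:
#' leptin-treated pups of ad-libitum mothers show a transient deficit
#' (95.7% of control at day 3, 89.8% at day 14) with later catch-up;
#' offspring of undernourished mothers are born lighter and catch up
#' partially; the UN/leptin cohorts show a postweaning fallback (88.0% of
#' control at day 30) and then remain stably below control (92.3% at day
#' 108, 89.8% at day 171). High-fat cohorts gain extra weight after
#' weaning.
#'
#' @return An 8 x 11 matrix of multipliers (cohorts x days).
#' @export
default_growth_multipliers <- function() {
  days <- default_growth_days()
  M <- matrix(1, 8, length(days), dimnames = list(.COHORT_LEVELS, days))
  al <- c(1.00, 0.957, 0.92, 0.898, 0.93, 0.96, 0.99, 1.00, 1.00, 1.00, 1.00)
  us <- c(0.85, 0.86, 0.88, 0.90, 0.92, 0.94, 0.96, 0.97, 0.97, 0.97, 0.97)
  ul <- c(0.85, 0.84, 0.85, 0.87, 0.95, 0.880, 0.91, 0.92, 0.923, 0.91, 0.898)
  M["ALC", ] <- M["ALH", ] <- al
  M["USC", ] <- M["USH", ] <- us
  M["ULC", ] <- M["ULH", ] <- ul
  # extra postweaning gain on the high-fat diet (days > 21)
  hf_gain <- ifelse(days > 21, 1.10, 1.00)
  for (coh in c("ASH", "ALH", "USH", "ULH")) M[coh, ] <- M[coh, ] * hf_gain
  M
}

#' Generate endpoint phenotype data under the factorial design
#'
#' Each trait is a baseline plus additive effect-coded contributions for
#' any of the seven model terms plus Gaussian noise. An `effects` entry
#' `c(C = 10, AB = -6)` means: the difference between postweaning-diet
#' level means is +10 trait units and the AB interaction contrast
#' (difference-of-differences halved) is -6 units.
#'
#' @param design A [study_design()].
#' @param effects Named list: trait -> named numeric vector over terms
#'   `A, B, C, AB, AC, BC, ABC` (level-difference scale).
#' @param baselines Named numeric vector of trait baselines (default 0).
#' @param noise_sd Named numeric vector (or scalar) of residual sds.
#' @param seed Integer seed.
#' @return A data.frame, one row per animal: `animal_id`, the three design
#'   factors, then one column per trait.
#' @export
generate_phenotypes <- function(design, effects, baselines = NULL,
                                noise_sd = 1, seed = 1L) {
  stopifnot(inherits(design, "study_design"), length(effects) >= 1)
  traits <- names(effects)
  if (is.null(baselines)) baselines <- stats::setNames(rep(0, length(traits)), traits)
  if (length(noise_sd) == 1L) noise_sd <- stats::setNames(rep(noise_sd, length(traits)), traits)
  a <- ifelse(design$maternal_diet == "UN", 1, -1)
  b <- ifelse(design$neonatal_treatment == "Lep", 1, -1)
  cc <- ifelse(design$postweaning_diet == "HF", 1, -1)
  coding <- cbind(A = a, B = b, C = cc, AB = a * b, AC = a * cc,
                  BC = b * cc, ABC = a * b * cc)
  set.seed(seed)
  out <- data.frame(animal_id = design$animal_id,
                    maternal_diet = design$maternal_diet,
                    neonatal_treatment = design$neonatal_treatment,
                    postweaning_diet = design$postweaning_diet,
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    eff <- effects[[tr]]
    bad <- setdiff(names(eff), colnames(coding))
    if (length(bad)) stop("unknown term(s) for trait ", tr, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
    mu <- baselines[[tr]] +
      as.vector(coding[, names(eff), drop = FALSE] %*% (eff / 2))
    out[[tr]] <- mu + stats::rnorm(nrow(design), 0, noise_sd[[tr]])
  }
  out
}

#' Default phenotype emulation settings
#'
#' Traits, baselines, residual sds and planted term effects emulating the
#' endpoint phenotype battery of the modelled study. Effect sizes for the
#' four headline statistics (body-fat postweaning-diet and AB terms,
#' plasma-leptin AB, fasting C-peptide AB) are back-derived from the
#' published F statistics at n = 64 via the noncentral-F mean, so that a
#' simulated 64-animal series reproduces those F values in expectation.
#'
#' @return A list with `effects`, `baselines`, `noise_sd` suitable for
#'   [generate_phenotypes()].
#' @export
default_phenotype_spec <- function() {
  # lambda = F * (df-2)/df - 1 at df = 56; effect = 2 * sigma * sqrt(lambda/64)
  eff_from_F <- function(F, sigma, n = 64, df = 56) {
    lambda <- F * (df - 2) / df - 1
    2 * sigma * sqrt(lambda / n)
  }
  list(
    effects = list(
      body_fat_pct  = c(C = eff_from_F(150.5, 2),  A = 1.2, B = 1.2,
                        AB = -eff_from_F(22.25, 2)),
      plasma_leptin = c(C = 4.5, AB = -eff_from_F(11.32, 3)),
      c_peptide     = c(AB = -eff_from_F(13.13, 0.5)),
      insulin       = c(C = 0.5, AB = -0.25),
      ghrelin       = c(C = -1.2),
      triglycerides = c(C = 0.8)
    ),
    baselines = c(body_fat_pct = 20, plasma_leptin = 8, c_peptide = 2,
                  insulin = 1.5, ghrelin = 6, triglycerides = 1.8),
    noise_sd = c(body_fat_pct = 2, plasma_leptin = 3, c_peptide = 0.5,
                 insulin = 0.5, ghrelin = 1.5, triglycerides = 0.6)
  )
}
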