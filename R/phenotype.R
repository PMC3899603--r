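#' Three-factor ANOVA across endpoint phenotypes
#'
#' Applies the same saturated 2x2x2 model as [three_way_anova()] to each
#' trait of a per-animal phenotype table (the traits are stacked into a
#' traits x animals matrix and sent down the identical code path), then
#' applies BH correction per model term across the trait battery.
#'
#' @param pheno A data.frame with columns `animal_id`, `maternal_diet`,
#'   `neonatal_treatment`, `postweaning_diet` and one numeric column per
#'   trait; the design must be balanced.
#' @param traits Optional character vector selecting trait columns
#'   (default: every numeric non-design column).
#' @param alpha FDR level for the `significant` column (default 0.05).
#' @return Long data.frame: `trait`, `term`, `ss`, `F`, `p`, `q`,
#'   `df_resid`, `significant`.
#' @export
phenotype_threeway_anova <- function(pheno, traits = NULL, alpha = 0.05) {
  design_cols <- c("animal_id", "maternal_diet", "neonatal_treatment",
                   "postweaning_diet")
  miss <- setdiff(design_cols, names(pheno))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(traits)) {
    traits <- setdiff(names(pheno)[vapply(pheno, is.numeric, logical(1))],
                      design_cols)
  }
  if (length(traits) == 0L) stop("no trait columns found", call. = FALSE)
  design <- study_design(data.frame(
    sample_id = as.character(pheno$animal_id),
    maternal_diet = pheno$maternal_diet,
    neonatal_treatment = pheno$neonatal_treatment,
    postweaning_diet = pheno$postweaning_diet,
    stringsAsFactors = FALSE
  ))
  X <- t(as.matrix(pheno[, traits, drop = FALSE]))
  rownames(X) <- traits
  colnames(X) <- design$sample_id
  tw <- three_way_anova(prog_eset(X), design)
  out <- as.data.frame(tw)
  names(out)[names(out) == "gene_id"] <- "trait"
  out$df_resid <- rep(tw$df_resid, times = length(tw$terms))
  out$significant <- !is.na(out$q) & out$q <= alpha
  out
}

#' Percent-of-control growth curve
#'
#' For every shared measurement day, each animal's weight in `cohort` is
#' expressed as a percentage of the reference cohort's *mean* weight that
#' day; the curve reports the mean, s.e.m. and n of those per-animal
#' percentages (reference uncertainty is not propagated, so the reference
#' cohort relative to itself averages 100% with an s.e.m. reflecting its
#' own spread). Days missing from the reference are skipped with a
#' warning; there is no interpolation between measurement days.
#'
#' @param growth Long data.frame: `animal_id`, `cohort`, `day`,
#'   `weight_g`.
#' @param cohort,reference_cohort Cohort codes.
#' @return A data.frame: `day`, `pct`, `sem`, `n`.
#' @export
relative_growth_curve <- function(growth, cohort, reference_cohort) {
  need <- c("animal_id", "cohort", "day", "weight_g")
  stopifnot(all(need %in% names(growth)))
  gx <- growth[growth$cohort == cohort, ]
  gr <- growth[growth$cohort == reference_cohort, ]
  if (nrow(gx) == 0L || nrow(gr) == 0L) stop("cohort not present in growth table",
                                             call. = FALSE)
  days <- sort(unique(gx$day))
  missing_ref <- setdiff(days, unique(gr$day))
  if (length(missing_ref)) {
    warning("day(s) missing in reference cohort, skipped: ",
            paste(missing_ref, collapse = ", "))
    days <- setdiff(days, missing_ref)
  }
  out <- lapply(days, function(d) {
    ref_mean <- mean(gr$weight_g[gr$day == d])
    p <- 100 * gx$weight_g[gx$day == d] / ref_mean
    data.frame(day = d, pct = mean(p),
               sem = stats::sd(p) / sqrt(length(p)), n = length(p))
  })
  do.call(rbind, out)
}

#' Absolute weight gain on high fat relative to chow
#'
#' For each (high-fat cohort, chow cohort) pair, the difference of mean
#' weights at a given day, in grams.
#'
#' @param growth Long growth table (see [relative_growth_curve()]).
#' @param day Measurement day (must be present for both cohorts).
#' @param group_pairs A list of length-2 character vectors
#'   `c(hf_cohort, chow_cohort)`, or a 2-column matrix.
#' @return A data.frame: `hf_cohort`, `chow_cohort`, `day`, `gain_g`.
#' @export
weight_gain_contrast <- function(growth, day, group_pairs) {
  if (is.matrix(group_pairs)) {
    group_pairs <- split(group_pairs, row(group_pairs))
  }
  out <- lapply(group_pairs, function(pr) {
    stopifnot(length(pr) == 2)
    wh <- growth$weight_g[growth$cohort == pr[1] & growth$day == day]
    wc <- growth$weight_g[growth$cohort == pr[2] & growth$day == day]
    if (length(wh) == 0L || length(wc) == 0L) {
      stop("day ", day, " absent for pair ", pr[1], "/", pr[2], call. = FALSE)
    }
    data.frame(hf_cohort = pr[1], chow_cohort = pr[2], day = day,
               gain_g = mean(wh) - mean(wc), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
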