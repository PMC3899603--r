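#' @keywords internal
"_PACKAGE"

# Canonical cohort order used everywhere: maternal diet slowest, then
# neonatal treatment, then postweaning diet.
.COHORT_LEVELS <- c("ASC", "ASH", "ALC", "ALH", "USC", "USH", "ULC", "ULH")

.FACTOR_LEVELS <- list(
  maternal_diet      = c("AD", "UN"),
  neonatal_treatment = c("Sal", "Lep"),
  postweaning_diet   = c("Chow", "HF")
)

#' Cohort codes for the 2x2x2 design
#'
#' Each cohort is written as a three-letter code: maternal diet
#' (`A` = ad libitum, `U` = undernourished), neonatal treatment
#' (`S` = saline, `L` = leptin), postweaning diet (`C` = chow, `H` = high
#' fat). The control cohort is `ASC`.
#'
#' @return Character vector of the eight cohort codes in canonical order.
#' @export
#' @examples
#' cohort_levels()
cohort_levels <- function() .COHORT_LEVELS

#' Build a cohort code from factor levels
#'
#' @param maternal_diet `"AD"` or `"UN"` (vectorised).
#' @param neonatal_treatment `"Sal"` or `"Lep"`.
#' @param postweaning_diet `"Chow"` or `"HF"`.
#' @return Character vector of three-letter cohort codes.
#' @export
#' @examples
#' cohort_code("UN", "Sal", "HF") # "USH"
cohort_code <- function(maternal_diet, neonatal_treatment, postweaning_diet) {
  a <- c(AD = "A", UN = "U")[as.character(maternal_diet)]
  b <- c(Sal = "S", Lep = "L")[as.character(neonatal_treatment)]
  c <- c(Chow = "C", HF = "H")[as.character(postweaning_diet)]
  if (anyNA(a) || anyNA(b) || anyNA(c)) {
    stop("factor levels must be AD/UN, Sal/Lep, Chow/HF", call. = FALSE)
  }
  unname(paste0(a, b, c))
}

#' Parse cohort codes back into factor levels
#'
#' Inverse of [cohort_code()]; the two form a bijection over the eight
#' cohorts.
#'
#' @param code Character vector of three-letter codes (e.g. `"ULH"`).
#' @return A data.frame with columns `maternal_diet`, `neonatal_treatment`,
#'   `postweaning_diet`.
#' @export
parse_cohort_code <- function(code) {
  code <- as.character(code)
  if (!all(code %in% .COHORT_LEVELS)) {
    stop("unknown cohort code(s): ",
         paste(setdiff(code, .COHORT_LEVELS), collapse = ", "), call. = FALSE)
  }
  data.frame(
    maternal_diet      = c(A = "AD", U = "UN")[substr(code, 1, 1)],
    neonatal_treatment = c(S = "Sal", L = "Lep")[substr(code, 2, 2)],
    postweaning_diet   = c(C = "Chow", H = "HF")[substr(code, 3, 3)],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Construct a validated study design
#'
#' Validates a per-sample table for the 2x2x2 factorial design and attaches
#' the cohort code of each sample. Sample identifiers must be unique.
#'
#' @param samples A data.frame with columns `sample_id`, `maternal_diet`
#'   (`AD`/`UN`), `neonatal_treatment` (`Sal`/`Lep`), `postweaning_diet`
#'   (`Chow`/`HF`) and optionally `animal_id`.
#' @return A `study_design` object (a data.frame with an added `cohort`
#'   factor over the eight canonical cohort levels).
#' @export
study_design <- function(samples) {
  need <- c("sample_id", "maternal_diet", "neonatal_treatment", "postweaning_diet")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  for (f in names(.FACTOR_LEVELS)) {
    bad <- setdiff(unique(as.character(samples[[f]])), .FACTOR_LEVELS[[f]])
    if (length(bad)) stop("invalid level(s) for ", f, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  samples$cohort <- factor(
    cohort_code(samples$maternal_diet, samples$neonatal_treatment,
                samples$postweaning_diet),
    levels = .COHORT_LEVELS
  )
  if (is.null(samples$animal_id)) samples$animal_id <- samples$sample_id
  class(samples) <- c("study_design", "data.frame")
  samples
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", nrow(x), "samples\n")
  print(table(cohort = x$cohort))
  invisible(x)
}

#' Expression matrix container
#'
#' Bundles a genes x samples matrix of log2-scale intensities with the
#' platform's present/absent detection calls and an optional per-value
#' exclusion mask (set by [exclude_outlier_per_cell()]). Masked values stay
#' in the matrix but are ignored by every downstream mean/ANOVA
#' computation; detection calls are data and are never masked.
#'
#' @param exprs Numeric matrix (genes x samples), finite values, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param detection Logical matrix of the same shape, `TRUE` = present.
#'   Defaults to all-present.
#' @param mask Logical matrix of the same shape, `TRUE` = excluded.
#'   Defaults to nothing excluded.
#' @return A `prog_eset` object.
#' @export
prog_eset <- function(exprs, detection = NULL, mask = NULL) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (!all(is.finite(exprs))) stop("expression values must be finite", call. = FALSE)
  if (is.null(rownames(exprs))) {
    rownames(exprs) <- sprintf("gene_%05d", seq_len(nrow(exprs)))
  }
  if (is.null(colnames(exprs))) {
    colnames(exprs) <- sprintf("sample_%02d", seq_len(ncol(exprs)))
  }
  if (anyDuplicated(colnames(exprs))) stop("sample ids must be unique", call. = FALSE)
  if (is.null(detection)) {
    detection <- matrix(TRUE, nrow(exprs), ncol(exprs), dimnames = dimnames(exprs))
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(exprs), ncol(exprs), dimnames = dimnames(exprs))
  }
  stopifnot(is.logical(detection), identical(dim(detection), dim(exprs)),
            is.logical(mask), identical(dim(mask), dim(exprs)))
  dimnames(detection) <- dimnames(exprs)
  dimnames(mask) <- dimnames(exprs)
  structure(list(exprs = exprs, detection = detection, mask = mask),
            class = "prog_eset")
}

#' @export
dim.prog_eset <- function(x) dim(x$exprs)

#' @export
print.prog_eset <- function(x, ...) {
  cat("prog_eset:", nrow(x$exprs), "genes x", ncol(x$exprs), "samples;",
      sum(x$mask), "values masked\n")
  invisible(x)
}

#' Subset a prog_eset by gene and/or sample
#'
#' @param x A `prog_eset`.
#' @param i Gene index/ids. @param j Sample index/ids.
#' @param ... Unused. @param drop Ignored; dimensions are always kept.
#' @export
`[.prog_eset` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$exprs))
  if (missing(j)) j <- seq_len(ncol(x$exprs))
  prog_eset(x$exprs[i, j, drop = FALSE],
            x$detection[i, j, drop = FALSE],
            x$mask[i, j, drop = FALSE])
}

# Check that the design rows match the eset columns one-to-one, in order.
.check_alignment <- function(eset, design) {
  if (!inherits(eset, "prog_eset")) stop("not a prog_eset", call. = FALSE)
  if (!inherits(design, "study_design")) stop("not a study_design", call. = FALSE)
  if (!identical(as.character(design$sample_id), colnames(eset$exprs))) {
    stop("design sample_id must match expression columns (same order)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Per-gene, per-cohort sufficient statistics over unmasked replicates:
# counts, sums, sums of squares and means, columns in canonical cohort order.
.cell_stats <- function(eset, design, use_mask = TRUE) {
  .check_alignment(eset, design)
  X <- eset$exprs
  W <- if (use_mask) !eset$mask else matrix(TRUE, nrow(X), ncol(X))
  G <- nrow(X)
  lev <- .COHORT_LEVELS
  n <- s <- s2 <- matrix(0, G, length(lev), dimnames = list(rownames(X), lev))
  for (k in seq_along(lev)) {
    idx <- which(design$cohort == lev[k])
    if (length(idx) == 0L) next
    Wk <- W[, idx, drop = FALSE]
    Xk <- X[, idx, drop = FALSE]
    n[, k]  <- rowSums(Wk)
    s[, k]  <- rowSums(Xk * Wk)
    s2[, k] <- rowSums(Xk * Xk * Wk)
  }
  list(n = n, sum = s, sumsq = s2, means = s / ifelse(n > 0, n, NA_real_))
}

#' Per-gene cohort means
#'
#' Mean log2 expression of each gene within each of the eight cohorts,
#' computed over unmasked replicates only.
#'
#' @param eset A [prog_eset()]. @param design A [study_design()].
#' @param use_mask Honour the outlier-exclusion mask (default `TRUE`).
#' @return Numeric matrix, genes x 8 cohorts (canonical order).
#' @export
cohort_means <- function(eset, design, use_mask = TRUE) {
  .cell_stats(eset, design, use_mask = use_mask)$means
}
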