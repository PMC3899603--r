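#' Pipeline configuration
#'
#' Defaults mirror the analytic choices of the modelled study: 5% FDR at
#' both the selection and categorisation steps, 1.25-fold thresholds,
#' 75% absent-call presence filter, six response-pattern clusters, and
#' `ASC` (ad-libitum / saline / chow) as the control cohort with `USH`
#' (undernourished / saline / high-fat) as the affected cohort and `USC`
#' as the predisposed (precursor) cohort.
#'
#' @param alpha FDR level for selection, categorisation and pairwise
#'   tests.
#' @param fc_threshold Inclusive fold-change threshold.
#' @param presence_threshold Absent-call fraction for the presence filter,
#'   in (0, 1].
#' @param k Number of residual-profile clusters.
#' @param metric,linkage Clustering metric / agglomeration method.
#' @param standardise Row-standardise residual profiles before clustering.
#' @param control,affected,precursor_cohort Cohort codes.
#' @param exclude_outliers Run per-cell outlier exclusion (default
#'   `TRUE`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, fc_threshold = 1.25,
                            presence_threshold = 0.75, k = 6,
                            metric = "correlation", linkage = "average",
                            standardise = TRUE,
                            control = "ASC", affected = "USH",
                            precursor_cohort = "USC",
                            exclude_outliers = TRUE) {
  stopifnot(alpha > 0, alpha < 1, fc_threshold >= 1,
            presence_threshold > 0, presence_threshold <= 1,
            k >= 1,
            control %in% .COHORT_LEVELS, affected %in% .COHORT_LEVELS,
            precursor_cohort %in% .COHORT_LEVELS)
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 presence_threshold = presence_threshold, k = as.integer(k),
                 metric = metric, linkage = linkage,
                 standardise = isTRUE(standardise),
                 control = control, affected = affected,
                 precursor_cohort = precursor_cohort,
                 exclude_outliers = isTRUE(exclude_outliers)),
            class = "pipeline_config")
}

# Stable md5 hash of the configuration, stamped into every output.
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full programming-detection pipeline
#'
#' Executes, in order: per-cell outlier exclusion, presence filtering,
#' one-way ANOVA selection with BH-FDR, three-way ANOVA categorisation of
#' the selected genes, interaction typing of the AB-category genes,
#' residual-profile clustering of the AB set, and the three-filter
#' biomarker cascade. One structured log line per stage reports its
#' input/output gene counts so the chain can be compared against a
#' reference analysis. Identical inputs and configuration give identical
#' outputs.
#'
#' @param eset A [prog_eset()]. @param design A [study_design()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-stage TSV/JSON
#'   outputs are written there, each stamped with the config hash.
#' @param quiet Suppress stage log lines (default `FALSE`).
#' @return A `prog_pipeline` list with elements `qc`, `oneway`,
#'   `threeway`, `categories`, `category_table`, `interactions`,
#'   `clusters`, `cascade`, `counts`, `config`, `config_hash`.
#' @export
run_pipeline <- function(eset, design, config = pipeline_config(),
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  .check_alignment(eset, design)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  hash <- .config_hash(config)
  n0 <- nrow(eset$exprs)

  masked <- if (config$exclude_outliers) {
    exclude_outlier_per_cell(eset, design)
  } else eset
  say("outlier_exclusion", "masked %d values across %d genes",
      sum(masked$mask), n0)

  expressed <- presence_filter(masked, config$presence_threshold)
  say("presence_filter", "%d -> %d genes", n0, nrow(expressed$exprs))

  ow <- one_way_anova(expressed, design, alpha = config$alpha)
  selected <- ow$gene_id[ow$significant]
  say("one_way_selection", "%d -> %d genes at FDR %.2g",
      nrow(expressed$exprs), length(selected), config$alpha)

  if (length(selected) == 0L) {
    say("pipeline", "no significant genes; downstream stages empty")
    empty_assign <- structure(list(gene_id = character(0),
                                   categories = list(), alpha = config$alpha),
                              class = "category_assignment")
    res <- list(qc = qc_report(eset, expressed), oneway = ow, threeway = NULL,
                categories = empty_assign,
                category_table = category_counts(empty_assign),
                interactions = NULL, clusters = NULL,
                cascade = biomarker_cascade(expressed, design, empty_assign,
                                            affected = config$affected,
                                            control = config$control,
                                            precursor_cohort = config$precursor_cohort,
                                            fc_threshold = config$fc_threshold),
                counts = c(input = n0, expressed = nrow(expressed$exprs),
                           selected = 0L, filter1 = 0L, filter2 = 0L,
                           filter3 = 0L),
                config = config, config_hash = hash)
    class(res) <- "prog_pipeline"
    if (!is.null(out_dir)) .write_pipeline_outputs(res, expressed, out_dir)
    return(res)
  }

  tw <- three_way_anova(expressed, design, genes = selected)
  assign <- assign_categories(tw, alpha = config$alpha)
  mfc <- max_fold_change(expressed, design, genes = selected)
  cat_table <- category_counts(assign, max_fc = mfc,
                               fc_threshold = config$fc_threshold)
  say("categorisation", "%d genes over %d categories", length(selected),
      sum(cat_table$n > 0))

  ab_genes <- assign$gene_id[vapply(assign$categories, function(cc)
    "AB" %in% cc, logical(1))]
  interactions <- if (length(ab_genes)) {
    interaction_table(expressed, design, genes = ab_genes,
                      control = config$control, affected = config$affected)
  } else NULL
  say("interaction_typing", "%d AB-category genes", length(ab_genes))

  clusters <- NULL
  if (length(ab_genes) >= config$k) {
    profiles <- remove_diet_effect(expressed, design, genes = ab_genes)
    clusters <- tryCatch(
      cluster_genes(profiles, k = config$k, metric = config$metric,
                    linkage = config$linkage,
                    standardise = config$standardise),
      error = function(e) {
        say("clustering", "skipped: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(clusters)) {
      say("clustering", "%d genes into %d clusters",
          length(clusters$labels), config$k)
    }
  } else {
    say("clustering", "skipped: fewer AB genes (%d) than k (%d)",
        length(ab_genes), config$k)
  }

  cascade <- biomarker_cascade(expressed, design, assign,
                               affected = config$affected,
                               control = config$control,
                               precursor_cohort = config$precursor_cohort,
                               fc_threshold = config$fc_threshold)
  say("biomarker_cascade", "%s",
      paste(names(cascade$counts), cascade$counts, sep = "=", collapse = " -> "))

  res <- list(qc = qc_report(eset, expressed), oneway = ow, threeway = tw,
              categories = assign, category_table = cat_table,
              interactions = interactions, clusters = clusters,
              cascade = cascade,
              counts = c(input = n0, expressed = nrow(expressed$exprs),
                         selected = length(selected),
                         cascade$counts[c("filter1", "filter2", "filter3")]),
              config = config, config_hash = hash)
  class(res) <- "prog_pipeline"
  if (!is.null(out_dir)) .write_pipeline_outputs(res, expressed, out_dir)
  res
}

#' @export
print.prog_pipeline <- function(x, ...) {
  cat("prog_pipeline (config", substr(x$config_hash, 1, 8), ")\n")
  cat(" ", paste(names(x$counts), x$counts, sep = "=", collapse = " -> "), "\n")
  invisible(x)
}

.write_pipeline_outputs <- function(res, expressed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) {
    attr(df, "config_hash") <- res$config_hash
    df
  }
  utils::write.table(stamp(res$oneway), file.path(out_dir, "oneway_anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$threeway)) {
    tw <- as.data.frame(res$threeway)
    cats <- vapply(res$categories$categories, paste, character(1), collapse = ";")
    tw$categories <- cats[match(tw$gene_id, res$categories$gene_id)]
    utils::write.table(tw, file.path(out_dir, "threeway_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$interactions)) {
    utils::write.table(res$interactions,
                       file.path(out_dir, "interaction_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$clusters)) {
    lab <- data.frame(gene_id = names(res$clusters$labels),
                      cluster = unname(res$clusters$labels))
    utils::write.table(lab, file.path(out_dir, "cluster_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cent <- data.frame(cluster = rownames(res$clusters$centroids),
                       res$clusters$centroids, check.names = FALSE)
    utils::write.table(cent, file.path(out_dir, "cluster_centroids.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cluster_tree_newick(res$clusters, file.path(out_dir, "cluster_tree.nwk"))
  }
  utils::write.table(res$cascade$records,
                     file.path(out_dir, "biomarker_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = res$config_hash,
         counts = as.list(res$counts),
         category_table = res$category_table,
         cascade = list(counts = as.list(res$cascade$counts),
                        n_up = res$cascade$n_up, n_down = res$cascade$n_down,
                        n_precursor = res$cascade$n_precursor),
         qc = res$qc[c("genes_before", "genes_after", "values_masked")]),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate, analyse, and score recovery against ground truth
#'
#' Generates a synthetic dataset, runs [run_pipeline()], and scores the
#' result against the planted truth: per-category recall and precision
#' (planted `AB_*` categories map to recovered `AB`, planted `A`/`B`/`C`/
#' `ABC` to themselves), their macro averages, the empirical false
#' discovery proportion of the one-way selection (fraction of selected
#' genes that were planted null), and the reversal-typing confusion among
#' planted AB genes recovered in category AB.
#'
#' @param sim A [sim_config()].
#' @param config A [pipeline_config()].
#' @param quiet Passed to [run_pipeline()].
#' @return A list: `pipeline`, `truth`, `selection` (n_selected,
#'   empirical_fdr), `category_recall`, `category_precision`,
#'   `macro_recall`, `macro_precision`, `reversal` (n_ab_recovered,
#'   n_reversal_true, n_reversal_called, fraction_correct), `confusion`
#'   (planted category x called class table).
#' @export
simulate_and_validate <- function(sim = sim_config(), config = pipeline_config(),
                                  quiet = TRUE) {
  dat <- generate_factorial_expression(sim)
  res <- run_pipeline(dat$eset, dat$design, config, quiet = quiet)
  truth <- dat$truth$genes

  sel <- res$oneway$gene_id[res$oneway$significant]
  true_cat <- truth$category[match(sel, truth$gene_id)]
  empirical_fdr <- if (length(sel)) mean(true_cat == "null") else 0

  map <- c(A = "A", B = "B", C = "C", AB_reversal = "AB",
           AB_synergistic = "AB", AB_partial = "AB", ABC = "ABC")
  called <- res$categories
  has_cat <- function(gid, lab) {
    i <- match(gid, called$gene_id)
    !is.na(i) & vapply(seq_along(i), function(j)
      !is.na(i[j]) && lab[j] %in% called$categories[[i[j]]], logical(1))
  }
  planted_cats <- intersect(names(map), unique(truth$category))
  recall <- vapply(planted_cats, function(pc) {
    gid <- truth$gene_id[truth$category == pc & !truth$absent]
    if (!length(gid)) return(NA_real_)
    mean(has_cat(gid, rep(map[[pc]], length(gid))))
  }, numeric(1))
  precision <- vapply(unique(map[planted_cats]), function(lab) {
    gid <- called$gene_id[vapply(called$categories, function(cc)
      lab %in% cc, logical(1))]
    if (!length(gid)) return(NA_real_)
    tc <- truth$category[match(gid, truth$gene_id)]
    mean(map[tc] == lab, na.rm = TRUE)
  }, numeric(1))

  ab_true <- truth$gene_id[truth$category == "AB_reversal"]
  reversal <- list(n_ab_recovered = 0L, n_reversal_true = length(ab_true),
                   n_reversal_called = 0L, fraction_correct = NA_real_)
  confusion <- NULL
  if (!is.null(res$interactions) && nrow(res$interactions)) {
    it <- res$interactions
    tc <- truth$category[match(it$gene_id, truth$gene_id)]
    confusion <- table(planted = tc, called = it$class)
    gated <- it$gene_id %in% ab_true
    reversal$n_ab_recovered <- sum(gated)
    reversal$n_reversal_called <- sum(gated & it$class == "reversal")
    reversal$fraction_correct <- if (any(gated)) {
      mean(it$class[gated] == "reversal")
    } else NA_real_
  }

  list(pipeline = res, truth = truth,
       selection = list(n_selected = length(sel), empirical_fdr = empirical_fdr),
       category_recall = recall, category_precision = precision,
       macro_recall = mean(recall, na.rm = TRUE),
       macro_precision = mean(precision, na.rm = TRUE),
       reversal = reversal, confusion = confusion)
}
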