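#' Write / read the standard expression inputs
#'
#' The pipeline's on-disk formats are plain text: a tab-separated
#' expression table (`gene_id` plus one column per sample), a
#' detection-call table of the same shape (`P`/`A`), and a sample sheet
#' CSV (`sample_id, maternal_diet, neonatal_treatment, postweaning_diet,
#' animal_id`).
#'
#' @param eset A [prog_eset()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
write_expression_tsv <- function(eset, path) {
  df <- data.frame(gene_id = rownames(eset$exprs), eset$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @export
write_detection_tsv <- function(eset, path) {
  calls <- ifelse(eset$detection, "P", "A")
  df <- data.frame(gene_id = rownames(eset$exprs), calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname expression_io
#' @param design A [study_design()].
#' @export
write_sample_sheet <- function(design, path) {
  utils::write.csv(
    design[, c("sample_id", "maternal_diet", "neonatal_treatment",
               "postweaning_diet", "animal_id")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the expression inputs back into a prog_eset and study_design
#'
#' @param expression_path Expression TSV (see [write_expression_tsv()]).
#' @param sample_sheet_path Sample sheet CSV.
#' @param detection_path Optional detection TSV; defaults to all-present.
#' @return A list: `eset`, `design`.
#' @export
read_expression_data <- function(expression_path, sample_sheet_path,
                                 detection_path = NULL) {
  ex <- utils::read.delim(expression_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(ex[, -1, drop = FALSE])
  rownames(X) <- ex$gene_id
  D <- NULL
  if (!is.null(detection_path)) {
    dt <- utils::read.delim(detection_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!identical(dt$gene_id, ex$gene_id)) {
      stop("detection table gene order differs from expression table",
           call. = FALSE)
    }
    D <- as.matrix(dt[, -1, drop = FALSE]) == "P"
    rownames(D) <- dt$gene_id
  }
  sheet <- utils::read.csv(sample_sheet_path, stringsAsFactors = FALSE)
  design <- study_design(sheet)
  if (!identical(as.character(design$sample_id), colnames(X))) {
    stop("sample sheet order differs from expression columns", call. = FALSE)
  }
  list(eset = prog_eset(X, detection = D), design = design)
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of [generate_factorial_expression()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(genes = truth$genes,
         cell_means = as.data.frame(truth$cell_means)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Accepts any subset of the [pipeline_config()] fields; unspecified
#' fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
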