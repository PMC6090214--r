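## TSV dialects: samples as rows; expression files carry sample_id, group,
## then one column per gene; an empty cell or "NA" means undetectable.

#' Read a wide quantification-cycle (or expression) TSV
#'
#' @param path file with columns \code{sample_id}, optional \code{group},
#'   then numeric gene columns; empty cells or \code{"NA"} are missing.
#' @return A data frame (genes numeric).
#' @export
read_cq_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", na.strings = c("", "NA"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(df))
  df
}

#' Read a log2 relative-expression TSV as an expression dataset
#'
#' Missing cells are undetectable.
#'
#' @inheritParams read_cq_tsv
#' @return An \code{expr_dataset}.
#' @export
read_expression_tsv <- function(path) {
  df <- read_cq_tsv(path)
  meta <- intersect(c("sample_id", "group"), names(df))
  genes <- setdiff(names(df), meta)
  values <- as.matrix(df[genes])
  expr_dataset(values, !is.na(values), as.character(df$sample_id),
               group = if ("group" %in% meta) as.character(df$group) else NULL)
}

#' Read a clinical covariate/outcome TSV
#'
#' Columns: \code{sample_id}, \code{age_years}, \code{figo_stage}
#' (III|IV), \code{residual_tumor} (yes|no|NA), \code{os_months},
#' \code{os_event} (0|1).
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", na.strings = c("", "NA"),
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "age_years", "figo_stage", "residual_tumor",
            "os_months", "os_event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_named("clinical TSV lacks columns: %s",
               paste(missing_cols, collapse = ", "),
               class = "oatpnet_bad_input")
  }
  stopifnot(all(df$os_months >= 0), all(df$os_event %in% 0:1))
  df
}

#' Read a per-sample signature-score TSV
#'
#' Columns: \code{sample_id}, \code{nm_m}, \code{o_t}, \code{emt},
#' \code{yoshihara} (1|2).
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_signatures_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", na.strings = c("", "NA"),
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "nm_m", "o_t", "emt", "yoshihara")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_named("signature TSV lacks columns: %s",
               paste(missing_cols, collapse = ", "),
               class = "oatpnet_bad_input")
  }
  stopifnot(all(df$yoshihara %in% c(1, 2)))
  df
}

#' Write an expression dataset as a TSV pair plus a JSON report
#'
#' Emits \code{<prefix>_values.tsv} (log2 values, blank where
#' undetected), \code{<prefix>_mask.tsv} (0/1 detection mask) and
#' \code{<prefix>_report.json} (threshold, excluded samples and genes).
#'
#' @param expr an \code{expr_dataset}.
#' @param prefix output path prefix.
#' @param threshold detection threshold recorded in the report.
#' @param excluded_genes genes recorded as excluded in the report.
#' @return Invisibly, the three file paths.
#' @export
write_expression_tsv <- function(expr, prefix, threshold = 35,
                                 excluded_genes = character()) {
  vals <- data.frame(sample_id = expr$sample_id, stringsAsFactors = FALSE)
  if (!is.null(expr$group)) vals$group <- expr$group
  vals <- cbind(vals, as.data.frame(expr$values))
  mask <- data.frame(sample_id = expr$sample_id,
                     as.data.frame(expr$detected + 0L),
                     stringsAsFactors = FALSE)
  paths <- paste0(prefix, c("_values.tsv", "_mask.tsv", "_report.json"))
  write.table(vals, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mask, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    threshold = attr(expr, "threshold") %||% threshold,
    n_samples = nrow(expr$values), n_genes = ncol(expr$values),
    excluded_samples = as.character(attr(expr, "excluded_samples") %||% character(0)),
    excluded_genes = as.character(excluded_genes),
    detection_limited = names(which(expr$gene_status == "limited")))
  jsonlite::write_json(report, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Write a result table as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_result_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
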