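#' Expression dataset with detection mask
#'
#' Container for log2 relative expression values together with a boolean
#' detection mask. Values are defined exactly where the mask is \code{TRUE};
#' undetectable measurements (quantification cycle above the detection
#' threshold, or missing) are stored as \code{NA}.
#'
#' @param values numeric matrix, samples x genes, \code{NA} where undetected.
#' @param detected logical matrix of the same shape.
#' @param sample_id character vector of unique sample identifiers.
#' @param group optional per-sample group label (e.g. \code{"tumor"} /
#'   \code{"benign"}).
#'
#' @return An object of class \code{expr_dataset}: a list with elements
#'   \code{values}, \code{detected}, \code{sample_id}, \code{gene},
#'   \code{group} and \code{gene_status} (\code{"complete"} for genes
#'   detected in every sample, \code{"limited"} otherwise).
#' @export
expr_dataset <- function(values, detected, sample_id, group = NULL) {
  values <- as.matrix(values)
  detected <- as.matrix(detected)
  stopifnot(identical(dim(values), dim(detected)), is.logical(detected))
  if (anyDuplicated(sample_id)) {
    stop_named("sample ids must be unique", class = "oatpnet_bad_input")
  }
  if (any(is.na(values) & detected) || any(!is.na(values) & !detected)) {
    stop_named("values must be defined exactly where detected is TRUE",
               class = "oatpnet_bad_input")
  }
  rownames(values) <- rownames(detected) <- sample_id
  status <- ifelse(colSums(!detected) == 0, "complete", "limited")
  names(status) <- colnames(values)
  structure(
    list(values = values, detected = detected,
         sample_id = as.character(sample_id), gene = colnames(values),
         group = group, gene_status = status),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("expr_dataset: %d samples x %d genes (%d complete, %d detection-limited)\n",
              nrow(x$values), ncol(x$values),
              sum(x$gene_status == "complete"), sum(x$gene_status == "limited")))
  invisible(x)
}

#' Subset an expression dataset by sample
#'
#' @param x an \code{expr_dataset}.
#' @param samples sample identifiers or a logical vector.
#' @return An \code{expr_dataset} restricted to the chosen samples.
#' @export
expr_subset <- function(x, samples) {
  if (is.logical(samples)) samples <- x$sample_id[samples]
  idx <- match(samples, x$sample_id)
  if (anyNA(idx)) stop_named("unknown sample id", class = "oatpnet_bad_input")
  expr_dataset(x$values[idx, , drop = FALSE], x$detected[idx, , drop = FALSE],
               x$sample_id[idx],
               group = if (!is.null(x$group)) x$group[idx] else NULL)
}

#' Relative expression from quantification cycles
#'
#' Converts a wide table of raw qPCR quantification cycles (Cq) to log2
#' relative expression by the delta-delta-Cq method. Each gene's Cq is
#' normalized to the geometric mean of the reference-gene relative
#' quantities, which on the Cq (log2) scale is the arithmetic mean of the
#' reference Cq values, then shifted by a per-gene calibrator offset. The
#' stored value is \code{-(Cq - mean(reference Cq) - calibrator)}, i.e.
#' minus delta-delta-Cq, so larger values mean higher expression. A Cq
#' above \code{threshold} (or missing) marks the gene undetectable in that
#' sample.
#'
#' @param cq data frame with columns \code{sample_id}, optionally
#'   \code{group}, then one numeric Cq column per gene. Empty cells /
#'   \code{NA} mean undetectable.
#' @param reference_genes character vector of reference (housekeeping)
#'   gene columns; these must be detected in every sample and are consumed
#'   by the normalization (not returned as panel genes).
#' @param calibrator_dcq per-gene calibrator delta-Cq offset: a single
#'   number recycled to all genes or a named vector. Names not present in
#'   the panel are an error. Default 0 (values relative to the
#'   reference-gene mean only).
#' @param threshold detection threshold in cycles; Cq strictly greater is
#'   treated as not expressed. Default 35.
#' @param on_bad_reference what to do with a sample in which a reference
#'   gene is undetected: \code{"error"} (default) or \code{"drop"} the
#'   sample, recording it in the \code{excluded_samples} attribute.
#'
#' @return An \code{expr_dataset} over the non-reference genes, with an
#'   \code{excluded_samples} attribute listing dropped samples.
#' @export
compute_relative_expression <- function(cq, reference_genes,
                                        calibrator_dcq = 0,
                                        threshold = 35,
                                        on_bad_reference = c("error", "drop")) {
  on_bad_reference <- match.arg(on_bad_reference)
  stopifnot(is.data.frame(cq), "sample_id" %in% names(cq))
  meta_cols <- intersect(c("sample_id", "group"), names(cq))
  genes_all <- setdiff(names(cq), meta_cols)
  if (!all(reference_genes %in% genes_all)) {
    stop_named("reference genes missing from table: %s",
               paste(setdiff(reference_genes, genes_all), collapse = ", "),
               class = "oatpnet_bad_input")
  }
  panel <- setdiff(genes_all, reference_genes)
  if (length(panel) == 0) {
    stop_named("no panel genes left after removing reference genes",
               class = "oatpnet_bad_input")
  }
  calib <- if (length(calibrator_dcq) == 1 && is.null(names(calibrator_dcq))) {
    setNames(rep(as.numeric(calibrator_dcq), length(panel)), panel)
  } else {
    unknown <- setdiff(names(calibrator_dcq), panel)
    if (length(unknown)) {
      stop_named("calibrator offsets for unknown genes: %s",
                 paste(unknown, collapse = ", "), class = "oatpnet_bad_calibrator")
    }
    out <- setNames(rep(0, length(panel)), panel)
    out[names(calibrator_dcq)] <- as.numeric(calibrator_dcq)
    out
  }

  refs <- as.matrix(cq[reference_genes])
  bad <- apply(refs, 1L, function(r) any(is.na(r) | r > threshold))
  excluded <- character(0)
  if (any(bad)) {
    ids <- as.character(cq$sample_id[bad])
    if (on_bad_reference == "error") {
      stop_named("reference gene undetected in sample(s): %s",
                 paste(ids, collapse = ", "), class = "oatpnet_bad_reference")
    }
    warning(sprintf("dropping %d sample(s) with undetected reference genes: %s",
                    length(ids), paste(ids, collapse = ", ")))
    excluded <- ids
    cq <- cq[!bad, , drop = FALSE]
    refs <- refs[!bad, , drop = FALSE]
  }

  ref_mean <- rowMeans(refs)
  raw <- as.matrix(cq[panel])
  detected <- !is.na(raw) & raw <= threshold
  ## value = -ddCq = -(Cq - ref_mean - calibrator_dcq)
  values <- -(raw - ref_mean) + matrix(calib[panel], nrow(raw), ncol(raw),
                                       byrow = TRUE)
  values[!detected] <- NA_real_

  out <- expr_dataset(values, detected, as.character(cq$sample_id),
                      group = if ("group" %in% names(cq)) as.character(cq$group) else NULL)
  attr(out, "excluded_samples") <- excluded
  attr(out, "threshold") <- threshold
  out
}

#' Cohort summary table
#'
#' Summarizes a clinical table the way cohort description tables are
#' printed: numeric columns by median and interquartile range
#' (linear-interpolation quartiles), categorical columns by count and
#' percentage among non-missing values (nearest-integer rounding), and the
#' survival outcome by the number of events and its percentage of the full
#' cohort.
#'
#' @param clinical data frame with columns \code{sample_id},
#'   \code{age_years}, \code{figo_stage}, \code{residual_tumor},
#'   \code{os_months}, \code{os_event}; extra columns are summarized by
#'   type.
#' @return A data frame with one row per numeric variable or category
#'   level: \code{variable}, \code{level}, \code{count}, \code{percent},
#'   \code{median}, \code{q25}, \code{q75}.
#' @export
cohort_summary <- function(clinical) {
  if (!is.data.frame(clinical) || nrow(clinical) == 0) {
    stop_named("clinical table is empty", class = "oatpnet_bad_input")
  }
  n_all <- nrow(clinical)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)
  for (v in setdiff(names(clinical), "sample_id")) {
    x <- clinical[[v]]
    if (v == "os_event") {
      d <- sum(x == 1, na.rm = TRUE)
      add(variable = v, level = "event", count = d,
          percent = round(100 * d / n_all), median = NA_real_,
          q25 = NA_real_, q75 = NA_real_)
    } else if (is.numeric(x)) {
      q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
      add(variable = v, level = NA_character_, count = sum(!is.na(x)),
          percent = NA_real_, median = unname(q[2]), q25 = unname(q[1]),
          q75 = unname(q[3]))
    } else {
      x <- as.character(x)
      x[x %in% c("", "NA")] <- NA_character_
      n_rec <- sum(!is.na(x))
      for (lev in sort(unique(x[!is.na(x)]))) {
        cnt <- sum(x == lev, na.rm = TRUE)
        add(variable = v, level = lev, count = cnt,
            percent = round(100 * cnt / n_rec), median = NA_real_,
            q25 = NA_real_, q75 = NA_real_)
      }
      if (n_rec < length(x)) {
        add(variable = v, level = "missing", count = length(x) - n_rec,
            percent = NA_real_, median = NA_real_, q25 = NA_real_,
            q75 = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}
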