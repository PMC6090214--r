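#' Spearman correlations between model features and signature scores
#'
#' Rank correlation (midranks for ties) of every continuous feature column
#' (gene expression, network PC1 scores, clinical covariates) with each
#' signature score. Cells with a constant vector are returned as \code{NA}
#' (undefined), not zero.
#'
#' @param fm a \code{feature_matrix}; indicator (\code{"_2K"}) columns are
#'   skipped.
#' @param signatures data frame with \code{sample_id}, \code{nm_m},
#'   \code{o_t}, \code{emt}, \code{yoshihara} (class 1/2).
#' @param digits rounding for display, as printed in correlation tables
#'   (default 2); use \code{NULL} for full precision.
#' @return Data frame with one row per feature and columns
#'   \code{nM_M}, \code{O_T}, \code{EMT}, \code{Yoshihara}.
#' @export
spearman_matrix <- function(fm, signatures, digits = 2) {
  stopifnot(all(c("sample_id", "nm_m", "o_t", "emt", "yoshihara") %in%
                  names(signatures)))
  sig <- signatures[match(fm$sample_id, signatures$sample_id), , drop = FALSE]
  if (anyNA(sig$sample_id)) {
    stop_named("signature sample ids do not cover the cohort",
               class = "oatpnet_bad_input")
  }
  keep <- fm$provenance != "gene-indicator"
  X <- fm$X[, keep, drop = FALSE]
  S <- cbind(nM_M = sig$nm_m, O_T = sig$o_t, EMT = sig$emt,
             Yoshihara = as.numeric(sig$yoshihara))
  out <- matrix(NA_real_, ncol(X), ncol(S),
                dimnames = list(colnames(X), colnames(S)))
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(S))) {
    ok <- !is.na(X[, i]) & !is.na(S[, j])
    if (sum(ok) < 3) next
    if (sd(X[ok, i]) == 0 || sd(S[ok, j]) == 0) next   # undefined, stays NA
    out[i, j] <- cor(X[ok, i], S[ok, j], method = "spearman")
  }
  if (!is.null(digits)) out <- round(out, digits)
  data.frame(feature = rownames(out), out, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Overlap regions of named feature selections
#'
#' Exact membership of every nonempty intersection pattern among 2 to 5
#' named feature sets (the regions of a Venn diagram).
#'
#' @param selections named list of character vectors (e.g. features
#'   selected by the survival model and by each signature model).
#' @return A list of class \code{overlap_report}: \code{regions} (named by
#'   the \code{"+"}-joined set combination, each a character vector of
#'   members), \code{counts}, \code{union_size}.
#' @export
overlap_sets <- function(selections) {
  if (length(selections) < 2 || length(selections) > 5) {
    stop_named("need 2 to 5 sets", class = "oatpnet_bad_input")
  }
  nm <- names(selections)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop_named("sets must have unique nonempty names", class = "oatpnet_bad_input")
  }
  all_feats <- sort(unique(unlist(selections)))
  regions <- list()
  if (length(all_feats)) {
    membership <- vapply(selections, function(s) all_feats %in% s,
                         logical(length(all_feats)))
    membership <- matrix(membership, nrow = length(all_feats),
                         dimnames = list(all_feats, nm))
    pattern <- apply(membership, 1, function(r) paste(nm[r], collapse = "+"))
    regions <- split(all_feats, pattern)
  }
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 union_size = length(all_feats), set_names = nm),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report over {%s}: %d feature(s) in %d region(s)\n",
              paste(x$set_names, collapse = ", "), x$union_size,
              length(x$regions)))
  for (r in names(x$regions)) {
    cat(sprintf("  %s: %s\n", r, paste(x$regions[[r]], collapse = ", ")))
  }
  invisible(x)
}

#' Signature association analysis
#'
#' Runs grouped-lasso selection of features against each signature: a
#' logistic model for the binary molecular subclass and linear models for
#' the continuous scores, then reports the per-model selected feature
#' sets and their overlap with a reference set (typically the survival
#' selection).
#'
#' @param fm a \code{feature_matrix} (the clinical group is unpenalized
#'   and always carried).
#' @param signatures signature data frame (see
#'   \code{\link{spearman_matrix}}).
#' @param os_selected character vector of groups selected by the survival
#'   model, included in the overlap as \code{"OS"}.
#' @param folds,seed cross-validation controls.
#' @return List with \code{fits} (per-signature \code{lasso_fit}),
#'   \code{selections} (named list of group sets) and \code{overlap}
#'   (an \code{overlap_report}).
#' @export
signature_association <- function(fm, signatures, os_selected = character(),
                                  folds = 10L, seed = 1L) {
  sig <- signatures[match(fm$sample_id, signatures$sample_id), , drop = FALSE]
  yos <- as.numeric(sig$yoshihara)
  stopifnot(all(yos %in% c(1, 2)))
  targets <- list(
    Yoshihara = list(y = as.numeric(yos == 2), family = "logistic"),
    EMT = list(y = sig$emt, family = "linear"),
    O_T = list(y = sig$o_t, family = "linear"),
    nM_M = list(y = sig$nm_m, family = "linear"))
  fits <- lapply(targets, function(tg) {
    grouped_lasso_glm(fm, tg$y, family = tg$family, folds = folds,
                      seed = seed)
  })
  selections <- lapply(fits, `[[`, "selected")
  all_sets <- c(list(OS = os_selected), selections)
  list(fits = fits, selections = selections,
       overlap = overlap_sets(all_sets))
}
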