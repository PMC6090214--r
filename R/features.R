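#' Model-ready feature matrix with group structure
#'
#' @param X numeric matrix, samples x columns.
#' @param group integer vector assigning each column to a group.
#' @param group_names character names, one per group index.
#' @param multiplier per-group penalty multiplier (0 = unpenalized).
#' @param provenance per-column tag: \code{"clinical"},
#'   \code{"gene-continuous"}, \code{"gene-indicator"} or
#'   \code{"network-PC1"}.
#' @param sample_id row identifiers.
#' @return An object of class \code{feature_matrix}.
#' @export
feature_matrix <- function(X, group, group_names, multiplier, provenance,
                           sample_id = rownames(X)) {
  X <- as.matrix(X)
  stopifnot(length(group) == ncol(X), length(provenance) == ncol(X),
            length(multiplier) == length(group_names),
            all(group %in% seq_along(group_names)))
  rownames(X) <- sample_id
  structure(list(X = X, group = as.integer(group), group_names = group_names,
                 multiplier = as.numeric(multiplier), provenance = provenance,
                 sample_id = sample_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d columns in %d groups (%d unpenalized)\n",
              nrow(x$X), ncol(x$X), length(x$group_names),
              sum(x$multiplier == 0)))
  invisible(x)
}

#' Columns of a feature-matrix group
#' @param fm a \code{feature_matrix}.
#' @param g group index or name.
#' @return Integer column indices of that group.
#' @export
group_columns <- function(fm, g) {
  if (is.character(g)) g <- match(g, fm$group_names)
  which(fm$group == g)
}

#' Encode expression and clinical data as model columns
#'
#' Builds the model-ready feature matrix with the group structure used by
#' all downstream penalized models. A gene detected in every sample
#' contributes one standardized continuous column in its own group. A
#' detection-limited gene contributes two columns sharing one group: the
#' continuous log2 values centered at the detected-value mean with
#' undetected entries imputed at that mean (0 after centering, so the
#' continuous coefficient is inert for them), and a 0/1 detection
#' indicator suffixed \code{"_2K"}. Both columns enter or leave any model
#' jointly. Each network is summarized by its standardized first principal
#' component score in a singleton group; genes absorbed into a network are
#' not additionally emitted as single genes. The clinical block (age, FIGO
#' IV vs III, residual tumor yes vs no) forms a single unpenalized group.
#'
#' @param expr an \code{expr_dataset}.
#' @param clinical clinical data frame with \code{sample_id},
#'   \code{age_years}, \code{figo_stage}, \code{residual_tumor} (samples
#'   with missing residual status are dropped with a warning).
#' @param networks list of \code{network_summary} objects (see
#'   \code{\link{extract_networks}}); may be empty.
#' @param exclude genes to drop before encoding (e.g. rarely expressed
#'   ones).
#' @param clinical_block include the clinical covariate group
#'   (default \code{TRUE}).
#' @return A \code{feature_matrix}.
#' @export
encode_features <- function(expr, clinical = NULL, networks = list(),
                            exclude = character(), clinical_block = !is.null(clinical)) {
  samp <- expr$sample_id
  if (!is.null(clinical)) {
    if (!setequal(samp, clinical$sample_id)) {
      stop_named("expression and clinical sample ids do not align",
                 class = "oatpnet_bad_input")
    }
    clinical <- clinical[match(samp, clinical$sample_id), , drop = FALSE]
    if (clinical_block && anyNA(clinical$residual_tumor)) {
      drop <- is.na(clinical$residual_tumor)
      warning(sprintf("dropping %d sample(s) with missing residual-tumor status",
                      sum(drop)))
      keep <- samp[!drop]
      expr <- expr_subset(expr, keep)
      clinical <- clinical[!drop, , drop = FALSE]
      samp <- keep
      networks <- lapply(networks, function(nw) {
        nw$scores <- nw$scores[match(keep, names(nw$scores))]
        nw$scores <- nw$scores - mean(nw$scores)
        nw
      })
    }
  }
  n <- length(samp)
  absorbed <- unlist(lapply(networks, `[[`, "members"))
  genes <- setdiff(expr$gene, c(exclude, absorbed))

  cols <- list(); grp <- integer(0); prov <- character(0)
  gnames <- character(0); mult <- numeric(0)
  new_group <- function(name, m) {
    gnames <<- c(gnames, name); mult <<- c(mult, m); length(gnames)
  }
  add_col <- function(name, x, g, p) {
    cols[[name]] <<- x; grp <<- c(grp, g); prov <<- c(prov, p)
  }

  if (clinical_block) {
    g <- new_group("clinical", 0)
    figo <- as.character(clinical$figo_stage)
    resid <- as.character(clinical$residual_tumor)
    if (anyNA(clinical$age_years) || anyNA(figo)) {
      stop_named("missing age or FIGO stage", class = "oatpnet_bad_input")
    }
    add_col("age", as.numeric(clinical$age_years), g, "clinical")
    add_col("figo_iv", as.numeric(figo == "IV"), g, "clinical")
    add_col("residual_yes", as.numeric(resid == "yes"), g, "clinical")
  }

  for (nw in networks) {
    label <- paste(nw$members, collapse = "_")
    g <- new_group(label, 1)
    add_col(label, standardize(as.numeric(nw$scores)), g, "network-PC1")
  }

  for (gene in genes) {
    det <- expr$detected[, gene]
    vals <- expr$values[, gene]
    n_det <- sum(det)
    if (n_det < 3) {
      stop_named("gene %s has fewer than 3 detected values", gene,
                 class = "oatpnet_too_few_detected")
    }
    limited <- expr$gene_status[[gene]] == "limited"
    if (limited && n_det == n) {
      warning(sprintf("gene %s declared detection-limited but detected in all samples; treating as complete",
                      gene))
      limited <- FALSE
    }
    if (!limited) {
      g <- new_group(gene, 1)
      add_col(gene, standardize(vals), g, "gene-continuous")
    } else {
      g <- new_group(gene, 1)
      ## centered at the detected mean; imputed entries sit exactly at 0,
      ## which is also the column mean, so scaling preserves them
      cont <- ifelse(det, vals - mean(vals[det]), 0)
      add_col(gene, cont / sd(cont), g, "gene-continuous")
      add_col(paste0(gene, "_2K"), as.numeric(det), g, "gene-indicator")
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  feature_matrix(X, grp, gnames, mult, prov, sample_id = samp)
}
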