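#' Two-part test for detection-limited expression
#'
#' Compares two groups of gene-expression measurements in which some
#' samples fall below the detection limit. The test combines a point-mass
#' component — a pooled two-proportion z statistic on the detection
#' fractions (no continuity correction) — with a continuous component — a
#' Wilcoxon rank-sum test on the detected values. When both components are
#' available, the combined statistic \eqn{X^2 = z_B^2 + z_W^2} is referred
#' to a chi-square distribution with 2 degrees of freedom. A degenerate
#' component (no undetectables anywhere, pooled detection fraction 0 or 1,
#' or fewer than 2 detected values in either group) is dropped and the
#' remaining component's own p-value is reported with 1 df.
#'
#' The continuous part uses the exact Wilcoxon null distribution when both
#' detected counts are at most 12 and there are no ties, otherwise the
#' normal approximation with tie correction (no continuity correction).
#' The working z for the continuous part is derived from its two-sided
#' p-value with the sign of the rank-sum shift, so the combined statistic
#' is consistent across branches.
#'
#' @param values_a,values_b numeric vectors of detected values per group.
#' @param n_undet_a,n_undet_b counts of undetectable samples per group.
#' @return A list of class \code{two_part_result}: \code{z_W}, \code{z_B}
#'   (NA when dropped), \code{X2}, \code{df}, \code{p_value}, and per-group
#'   detection rates.
#' @export
two_part_test <- function(values_a, n_undet_a, values_b, n_undet_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  n_a <- length(values_a) + n_undet_a
  n_b <- length(values_b) + n_undet_b
  if (n_a < 2 || n_b < 2) {
    stop_named("each group needs at least 2 samples", class = "oatpnet_bad_input")
  }

  ## point-mass part: pooled two-proportion z on detection fractions
  p_a <- length(values_a) / n_a
  p_b <- length(values_b) / n_b
  p_pool <- (length(values_a) + length(values_b)) / (n_a + n_b)
  binom_ok <- (n_undet_a + n_undet_b) > 0 && p_pool > 0 && p_pool < 1
  z_B <- if (binom_ok) {
    (p_a - p_b) / sqrt(p_pool * (1 - p_pool) * (1 / n_a + 1 / n_b))
  } else NA_real_

  ## continuous part: Wilcoxon rank-sum on detected values
  cont_ok <- length(values_a) >= 2 && length(values_b) >= 2
  z_W <- NA_real_; p_W <- NA_real_
  if (cont_ok) {
    m <- length(values_a); n <- length(values_b)
    r <- rank(c(values_a, values_b))
    W <- sum(r[seq_len(m)]) - m * (m + 1) / 2   # Mann-Whitney U for group a
    ties <- anyDuplicated(c(values_a, values_b)) > 0
    mu <- m * n / 2
    if (!ties && m <= 12 && n <= 12) {
      p_W <- min(1, 2 * min(pwilcox(W, m, n), 1 - pwilcox(W - 1, m, n)))
    } else {
      tie_tab <- table(r)
      sig2 <- m * n / 12 * ((m + n + 1) -
        sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
      z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
      p_W <- 2 * pnorm(-abs(z))
    }
    z_W <- sign(W - mu) * qnorm(1 - p_W / 2)
    if (!is.finite(z_W)) z_W <- 0   # p_W = 1 exactly
  }

  if (!binom_ok && !cont_ok) {
    stop_named("untestable gene: both components degenerate",
               class = "oatpnet_untestable")
  }

  if (binom_ok && cont_ok) {
    X2 <- z_B^2 + z_W^2
    df <- 2L
    p <- pchisq(X2, df = 2, lower.tail = FALSE)
  } else if (cont_ok) {
    X2 <- z_W^2; df <- 1L; p <- p_W
  } else {
    X2 <- z_B^2; df <- 1L
    p <- 2 * pnorm(-abs(z_B))
  }

  structure(list(z_W = z_W, z_B = z_B, X2 = X2, df = df, p_value = p,
                 detection_rate_a = p_a, detection_rate_b = p_b),
            class = "two_part_result")
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values, clipped at 1, in the input order.
#'
#' @param p_values numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted values of the same length and order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_named("p-values must lie in [0, 1]", class = "oatpnet_bad_input")
  }
  p.adjust(p, method = "BH")
}

#' Per-gene two-part comparison of two sample groups
#'
#' Runs \code{\link{two_part_test}} for every non-excluded gene of an
#' expression dataset, comparing the two levels of \code{groups}, and
#' adjusts the p-values across the tested panel by Benjamini-Hochberg.
#' Genes undetected in both groups, and genes whose test is degenerate in
#' both components, are dropped and listed in the \code{excluded}
#' attribute.
#'
#' @param expr an \code{expr_dataset}.
#' @param groups per-sample labels with exactly two levels; the first
#'   level sorted (or \code{"tumor"} if present) is group A.
#' @param exclude genes to skip.
#' @return Data frame with one row per tested gene: medians and detection
#'   rates per group, the component statistics, \code{p_value} and
#'   \code{fdr}; attribute \code{excluded} lists skipped genes.
#' @export
compare_groups <- function(expr, groups = expr$group, exclude = character()) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) {
    stop_named("groups must have exactly two levels", class = "oatpnet_bad_input")
  }
  if ("tumor" %in% lev) lev <- c("tumor", setdiff(lev, "tumor"))
  a <- groups == lev[1]; b <- groups == lev[2]
  if (sum(a) < 2 || sum(b) < 2) {
    stop_named("each group needs at least 2 samples", class = "oatpnet_bad_input")
  }
  rows <- list(); dropped <- character(0)
  for (gene in setdiff(expr$gene, exclude)) {
    det <- expr$detected[, gene]; val <- expr$values[, gene]
    if (!any(det[a]) && !any(det[b])) { dropped <- c(dropped, gene); next }
    res <- tryCatch(
      two_part_test(val[a & det], sum(a & !det), val[b & det], sum(b & !det)),
      oatpnet_untestable = function(e) NULL)
    if (is.null(res)) { dropped <- c(dropped, gene); next }
    med <- function(x) if (length(x) == 0) NA_real_ else unname(median(x))
    rows[[gene]] <- data.frame(
      gene = gene,
      median_a = med(val[a & det]), median_b = med(val[b & det]),
      detection_rate_a = res$detection_rate_a,
      detection_rate_b = res$detection_rate_b,
      z_W = res$z_W, z_B = res$z_B, X2 = res$X2, df = res$df,
      p_value = res$p_value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    stop_named("no testable genes", class = "oatpnet_bad_input")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$p_value)
  attr(out, "excluded") <- dropped
  attr(out, "group_levels") <- lev
  out
}
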