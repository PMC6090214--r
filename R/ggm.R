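#' Select an undirected gene graph by a K-penalized residual criterion
#'
#' Estimates a Gaussian graphical model over genes with complete
#' expression: candidate graphs are generated by three families and the
#' one minimizing an additive penalized residual criterion is returned.
#' For a graph \eqn{G} with neighborhoods \eqn{ne_G(a)},
#' \deqn{Crit_K(G) = \sum_a [ RSS_a(ne_G(a)) + K |ne_G(a)| \log(p-1) ],}
#' where \eqn{RSS_a(S)} is the residual sum of squares of regressing the
#' standardized column \eqn{a} on the standardized columns in \eqn{S}.
#' Larger \code{K} selects sparser graphs.
#'
#' Candidate families:
#' \describe{
#'   \item{corr01}{threshold grid on the edge score
#'     \eqn{s_{ab} = \min(|cor(a,b)|, \min_c |pcor(a,b|c)|)} (zero- and
#'     first-order partial-correlation screening).}
#'   \item{lasso-and}{per-node lasso paths over a 30-point penalty grid,
#'     an edge requiring selection in both directions (AND rule).}
#'   \item{adaptive}{the same with per-coefficient weights
#'     \eqn{1/(|ridge| + 10^{-6})} from a ridge fit.}
#' }
#' Candidate graphs whose maximum degree exceeds \code{d_max} are
#' discarded. Ties in the criterion are broken toward fewer edges, then
#' the lexicographically smallest edge set.
#'
#' @param X numeric matrix, samples x genes (complete, no missing values);
#'   standardized internally.
#' @param K positive penalty multiplier.
#' @param families subset of \code{c("corr01", "lasso-and", "adaptive")}.
#' @param d_max maximum node degree; default \code{min(10, n - 3, p - 1)}.
#' @param extra_candidates optional list of additional candidate edge
#'   matrices (2-column, node indices) to include in the search, e.g. an
#'   exhaustive enumeration for small panels.
#' @return An object of class \code{gene_graph}: node labels, the selected
#'   edge matrix (2 columns of node labels, each row sorted), \code{K},
#'   the criterion value, and the per-node degree.
#' @export
select_graph <- function(X, K, families = c("corr01", "lasso-and", "adaptive"),
                         d_max = NULL, extra_candidates = list()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2) stop_named("need at least 2 genes", class = "oatpnet_bad_input")
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(p))
  csd <- apply(X, 2, sd)
  if (any(csd == 0)) {
    stop_named("constant expression column: %s",
               paste(colnames(X)[csd == 0], collapse = ", "),
               class = "oatpnet_constant")
  }
  if (n < p + 2) warning("fewer samples than genes + 2; selection may be unstable")
  families <- match.arg(families, several.ok = TRUE)
  Z <- scale(X)
  if (is.null(d_max)) d_max <- min(10L, n - 3L, p - 1L)

  cand <- c(candidate_graphs(Z, families), lapply(extra_candidates, normalize_edges, p = p))
  cand <- c(cand, list(matrix(integer(0), 0, 2)))   # empty graph always a candidate
  keys <- vapply(cand, edge_key, character(1))
  cand <- cand[!duplicated(keys)]
  degs <- lapply(cand, function(e) tabulate(c(e[, 1], e[, 2]), nbins = p))
  ok <- vapply(degs, function(d) max(d) <= d_max, logical(1))
  cand <- cand[ok]

  crit <- vapply(cand, function(e) graph_criterion(Z, e, K), numeric(1))
  nedge <- vapply(cand, nrow, integer(1))
  keys <- vapply(cand, edge_key, character(1))
  ord <- order(crit, nedge, keys)
  best <- cand[[ord[1]]]

  edges <- matrix(colnames(X)[best], ncol = 2)
  structure(list(nodes = colnames(X), edges = edges, edge_index = best,
                 K = K, criterion = crit[ord[1]],
                 degree = setNames(tabulate(c(best[, 1], best[, 2]), nbins = p),
                                   colnames(X)),
                 n = n),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  cat(sprintf("gene_graph: %d nodes, %d edges (K = %g, criterion = %.3f)\n",
              length(x$nodes), nrow(x$edges), x$K, x$criterion))
  invisible(x)
}

## canonical form: each row sorted, rows ordered; integer node indices
normalize_edges <- function(e, p) {
  e <- matrix(as.integer(e), ncol = 2)
  if (nrow(e) == 0) return(e)
  if (any(e[, 1] == e[, 2])) stop_named("self-loop in edge set", class = "oatpnet_bad_input")
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

edge_key <- function(e) paste(e[, 1], e[, 2], sep = "-", collapse = ";")

## additive criterion: sum over nodes of RSS on neighborhood + K * deg * log(p-1)
graph_criterion <- function(Z, edges, K) {
  p <- ncol(Z)
  nbr <- vector("list", p)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
    }
  }
  tot <- 0
  for (a in seq_len(p)) {
    S <- nbr[[a]]
    rss <- if (length(S) == 0) {
      sum(Z[, a]^2)
    } else {
      sum(stats::lm.fit(Z[, S, drop = FALSE], Z[, a])$residuals^2)
    }
    tot <- tot + rss + K * length(S) * log(p - 1)
  }
  tot
}

candidate_graphs <- function(Z, families) {
  p <- ncol(Z)
  out <- list()
  if ("corr01" %in% families) out <- c(out, corr01_candidates(Z))
  if ("lasso-and" %in% families) out <- c(out, lasso_and_candidates(Z, adaptive = FALSE))
  if ("adaptive" %in% families) out <- c(out, lasso_and_candidates(Z, adaptive = TRUE))
  lapply(out, normalize_edges, p = p)
}

## zero/first-order partial correlation screening: nested graphs over a
## threshold grid on s_ab = min(|cor|, min_c |pcor(a,b|c)|)
corr01_candidates <- function(Z) {
  p <- ncol(Z)
  R <- cor(Z)
  S <- abs(R)
  if (p > 2) {
    for (a in seq_len(p - 1)) for (b in (a + 1):p) {
      for (c0 in setdiff(seq_len(p), c(a, b))) {
        den <- (1 - R[a, c0]^2) * (1 - R[b, c0]^2)
        pc <- if (den <= 0) 0 else (R[a, b] - R[a, c0] * R[b, c0]) / sqrt(den)
        S[a, b] <- S[b, a] <- min(S[a, b], abs(pc))
      }
    }
  }
  ut <- upper.tri(S)
  thr <- sort(unique(S[ut]), decreasing = TRUE)
  lapply(thr, function(t0) which(S >= t0 & ut, arr.ind = TRUE))
}

## per-node lasso (optionally adaptive via ridge weights) with AND rule
lasso_and_candidates <- function(Z, adaptive = FALSE, nlambda = 30L) {
  p <- ncol(Z); n <- nrow(Z)
  if (p < 3) return(list())   # single possible edge: corr01 grid covers it
  sel <- array(FALSE, dim = c(p, p, nlambda))
  lam_max <- max(abs(crossprod(Z))[upper.tri(diag(p))]) / n
  lambdas <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = nlambda))
  for (a in seq_len(p)) {
    Xa <- Z[, -a, drop = FALSE]; ya <- Z[, a]
    pf <- rep(1, p - 1)
    if (adaptive) {
      ridge <- solve(crossprod(Xa) + diag(0.1 * n, p - 1), crossprod(Xa, ya))
      pf <- 1 / (abs(as.numeric(ridge)) + 1e-6)
      pf <- pf / mean(pf)
    }
    fit <- glmnet::glmnet(Xa, ya, lambda = lambdas, penalty.factor = pf,
                          standardize = FALSE, intercept = FALSE)
    B <- as.matrix(fit$beta)   # (p-1) x length(fit$lambda)
    used <- match(round(fit$lambda, 12), round(lambdas, 12))
    for (j in seq_along(used)) {
      if (is.na(used[j])) next
      sel[a, setdiff(seq_len(p), a), used[j]] <- B[, j] != 0
    }
  }
  lapply(seq_len(nlambda), function(k) {
    A <- sel[, , k] & t(sel[, , k])   # AND rule
    which(A & upper.tri(A), arr.ind = TRUE)
  })
}

#' Connected components of a gene graph as network summaries
#'
#' Components with at least two members become networks, each summarized
#' by the first principal component of its standardized member columns.
#' The sign convention orients PC1 so the member with the largest absolute
#' loading has a positive loading; scores have zero mean.
#'
#' @param graph a \code{gene_graph}.
#' @param X samples x genes matrix containing at least the graph's nodes.
#' @return A list with \code{networks} (list of \code{network_summary}:
#'   \code{members}, \code{scores} named by sample, \code{loadings},
#'   \code{explained}) and \code{singletons} (genes in no network).
#' @export
extract_networks <- function(graph, X) {
  X <- as.matrix(X)
  if (!all(graph$nodes %in% colnames(X))) {
    stop_named("graph nodes missing from X", class = "oatpnet_bad_input")
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  networks <- list()
  for (k in seq_len(comp$no)) {
    members <- sort(graph$nodes[comp$membership == k])
    if (length(members) < 2) next
    networks[[length(networks) + 1L]] <- network_pc1(X[, members, drop = FALSE], members)
  }
  singles <- graph$nodes[comp$membership %in% which(comp$csize == 1)]
  list(networks = networks, singletons = singles)
}

network_pc1 <- function(Xm, members) {
  pc <- prcomp(Xm, center = TRUE, scale. = TRUE)
  load <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (load[which.max(abs(load))] < 0) { load <- -load; scores <- -scores }
  if (is.null(rownames(Xm))) names(scores) <- NULL else names(scores) <- rownames(Xm)
  structure(list(members = members, scores = scores,
                 loadings = setNames(as.numeric(load), members),
                 explained = pc$sdev[1]^2 / sum(pc$sdev^2)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("network_summary: {%s}, PC1 explains %.1f%% of variance\n",
              paste(x$members, collapse = ", "), 100 * x$explained))
  invisible(x)
}
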