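test_that("two correlated genes gain an edge; criterion matches direct evaluation", {
  set.seed(21)
  n <- 200
  z <- rnorm(n)
  X <- cbind(A = z + rnorm(n, sd = sqrt(1 / 0.81 - 1)), B = z)
  ## sample correlation near 0.9 by construction
  g <- select_graph(X, K = 4)
  expect_equal(nrow(g$edges), 1)
  ## the criterion of the selected graph beats the empty graph, and both
  ## match an independent evaluation
  Z <- scale(X)
  crit_edge <- oracle_criterion(Z, matrix(c(1, 2), 1, 2), 4)
  crit_empty <- oracle_criterion(Z, matrix(integer(0), 0, 2), 4)
  expect_equal(g$criterion, crit_edge, tolerance = 1e-8)
  expect_lt(crit_edge, crit_empty)
})

test_that("independent genes yield the empty graph at rates the criterion implies", {
  ## under the additive criterion a spurious edge needs a chi-square(1)
  ## residual drop above K * log(p-1); with p = 6 and 15 candidate pairs
  ## that caps the nonempty rate near 16% at K = 4 and under 1% at K = 8
  hits4 <- 0L; hits8 <- 0L
  reps <- 50L
  for (s in seq_len(reps)) {
    set.seed(1000 + s)
    X <- matrix(rnorm(500 * 6), 500, 6)
    if (nrow(select_graph(X, K = 4)$edges) == 0) hits4 <- hits4 + 1L
    if (nrow(select_graph(X, K = 8)$edges) == 0) hits8 <- hits8 + 1L
  }
  expect_gte(hits4 / reps, 0.75)
  expect_gte(hits8 / reps, 0.95)
})

test_that("selection agrees with exhaustive criterion minimization for small panels", {
  for (s in 1:3) {
    set.seed(300 + s)
    n <- 80; p <- 4
    ## one planted pair plus noise genes
    z <- rnorm(n)
    X <- cbind(z + rnorm(n, sd = 0.8), z + rnorm(n, sd = 0.8),
               rnorm(n), rnorm(n))
    colnames(X) <- paste0("g", 1:p)
    Z <- scale(X)
    graphs <- all_graphs(p)
    for (K in c(1, 4)) {
      crits <- vapply(graphs, function(e) oracle_criterion(Z, e, K), numeric(1))
      nedges <- vapply(graphs, nrow, integer(1))
      keys <- vapply(graphs, function(e) {
        if (nrow(e) == 0) "" else paste(t(apply(e, 1, sort)), collapse = ";")
      }, character(1))
      best <- graphs[[order(crits, nedges, keys)[1]]]
      got <- select_graph(X, K, extra_candidates = graphs)
      expect_equal(sort(edge_strings(got$edge_index)),
                   sort(edge_strings(best)),
                   info = sprintf("seed %d K %g", s, K))
    }
  }
})

test_that("edge count is non-increasing in K and invariant to sample order", {
  set.seed(77)
  d <- generate_dataset(synthetic_config(n = 150), seed = 8)
  comp <- names(which(d$expr$gene_status == "complete"))
  X <- d$expr$values[, comp]
  counts <- vapply(1:8, function(K) nrow(select_graph(X, K)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))

  perm <- sample(nrow(X))
  g1 <- select_graph(X, 4)
  g2 <- select_graph(X[perm, ], 4)
  expect_equal(sort(edge_strings(g1$edges)), sort(edge_strings(g2$edges)))
})

test_that("constant columns and single genes are rejected", {
  X <- cbind(a = rnorm(30), b = rep(1, 30))
  expect_error(select_graph(X, 2), class = "oatpnet_constant")
  expect_error(select_graph(X, 2), "b")
  expect_error(select_graph(X[, 1, drop = FALSE], 2),
               class = "oatpnet_bad_input")
})

test_that("networks are connected components with oriented, centered PC1", {
  set.seed(31)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- LETTERS[1:6]
  rownames(X) <- sprintf("s%d", 1:n)
  g <- list(nodes = LETTERS[1:6],
            edges = rbind(c("A", "B"), c("B", "C"), c("D", "E")),
            edge_index = rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L)))
  class(g) <- "gene_graph"
  nets <- extract_networks(g, X)
  expect_length(nets$networks, 2)
  expect_identical(nets$networks[[1]]$members, c("A", "B", "C"))
  expect_identical(nets$networks[[2]]$members, c("D", "E"))
  expect_identical(nets$singletons, "F")
  for (nw in nets$networks) {
    expect_equal(mean(nw$scores), 0, tolerance = 1e-12)
    expect_gt(nw$loadings[which.max(abs(nw$loadings))], 0)
  }

  ## two identical standardized columns: PC1 explains everything
  X2 <- cbind(P = X[, 1], Q = X[, 1])
  g2 <- list(nodes = c("P", "Q"), edges = rbind(c("P", "Q")),
             edge_index = rbind(c(1L, 2L)))
  class(g2) <- "gene_graph"
  nw2 <- extract_networks(g2, X2)$networks[[1]]
  expect_equal(nw2$explained, 1, tolerance = 1e-12)
  expect_equal(cor(nw2$scores, X[, 1]), 1, tolerance = 1e-12)

  ## negating a member re-orients PC1 up to the sign convention
  X3 <- cbind(P = X[, 1], Q = -X[, 1])
  nw3 <- extract_networks(g2, X3)$networks[[1]]
  expect_equal(abs(cor(nw3$scores, nw2$scores)), 1, tolerance = 1e-12)
})
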