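## shared fixture builders -- everything generated in code

## tiny wide Cq table: 2 reference genes, 3 panel genes
toy_cq <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    group = c("tumor", "tumor", "benign", "benign"),
    R1 = c(20, 21, 19, 20), R2 = c(20, 19, 21, 20),
    GA = c(25, 26, 27, 24),
    GB = c(30, 36, 31, NA),       # detection-limited
    GC = c(22, 23, 21, 22),
    stringsAsFactors = FALSE)
}

## small survival dataset with a single binary covariate, no ties
toy_surv <- function() {
  list(x = c(0, 1, 0, 1, 1, 0),
       time = c(2, 4, 6, 8, 10, 12),
       event = c(1, 1, 1, 0, 1, 1))
}

## feature matrix + outcome from the synthetic generator, small n
small_cohort <- function(n = 100, seed = 42) {
  d <- generate_dataset(synthetic_config(n = n), seed = seed)
  fm <- encode_features(d$expr, d$clinical)
  out <- surv_outcome(d$clinical$os_months, d$clinical$os_event)
  list(d = d, fm = fm, outcome = out)
}

## independent exact two-sided Wilcoxon p by exhaustive enumeration of
## rank assignments (tie-free data)
enum_wilcox_p <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  us <- apply(sets, 2, function(idx) sum(seq_len(m + n)[idx]) - m * (m + 1) / 2)
  2 * min(mean(us <= u_obs), mean(us >= u_obs))
}

## independent step-up BH implementation
enum_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## independent graph criterion: RSS via lm plus additive penalty
oracle_criterion <- function(Z, edges, K) {
  p <- ncol(Z)
  nbr <- lapply(seq_len(p), function(a) {
    unique(c(edges[edges[, 1] == a, 2], edges[edges[, 2] == a, 1]))
  })
  tot <- 0
  for (a in seq_len(p)) {
    S <- nbr[[a]]
    rss <- if (length(S) == 0) sum(Z[, a]^2) else {
      fit <- lm(Z[, a] ~ Z[, S, drop = FALSE] - 1)
      sum(residuals(fit)^2)
    }
    tot <- tot + rss + K * length(S) * log(p - 1)
  }
  tot
}

## all graphs on p nodes as edge matrices
all_graphs <- function(p) {
  pairs <- t(utils::combn(p, 2))
  n_e <- nrow(pairs)
  lapply(0:(2^n_e - 1), function(mask) {
    keep <- bitwAnd(mask, 2^(seq_len(n_e) - 1)) > 0
    pairs[keep, , drop = FALSE]
  })
}

edge_strings <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  apply(edges, 1, function(r) paste(sort(r), collapse = "|"))
}

jaccard <- function(a, b) {
  if (length(union(a, b)) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
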