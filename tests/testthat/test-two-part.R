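test_that("exact small-sample branch matches exhaustive rank enumeration", {
  r <- two_part_test(c(1, 2, 3), 0, c(4, 5, 6), 0)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, enum_wilcox_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$p_value, 0.1)

  ## a few more tie-free configurations against the enumeration oracle
  set.seed(7)
  for (i in 1:5) {
    a <- sample(seq(1, 40), 4)
    b <- sample(seq(41, 90), 5)   # disjoint support, no ties
    got <- two_part_test(a, 0, b, 0)$p_value
    expect_equal(got, enum_wilcox_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical groups give X2 = 0, p = 1; df-2 combination is z_B^2 + z_W^2", {
  r <- two_part_test(c(1, 2, 3, 4), 2, c(1, 2, 3, 4), 2)
  expect_equal(r$X2, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2L)

  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(18, 0.5)
    r <- two_part_test(a, 5, b, 2)
    expect_equal(r$df, 2L)
    expect_equal(r$X2, r$z_B^2 + r$z_W^2, tolerance = 1e-10)
    expect_equal(r$p_value, pchisq(r$X2, 2, lower.tail = FALSE))
  }
})

test_that("all-or-nothing detection drops the continuous part with the closed-form z", {
  ## 0/20 detected vs 20/20: pooled p = 0.5, z^2 = 1 / (0.25 * (2/20)) = 40
  r <- two_part_test(numeric(0), 20, rnorm(20), 0)
  expect_equal(r$df, 1L)
  expect_equal(r$z_B^2, 40)
  expect_equal(r$p_value, 2 * pnorm(-sqrt(40)), tolerance = 1e-12)
  expect_lt(r$p_value, 1e-9)

  ## both components degenerate (nothing detected anywhere) -> untestable
  expect_error(two_part_test(numeric(0), 3, numeric(0), 2),
               class = "oatpnet_untestable")
})

test_that("with no undetectables the p-value equals the plain Wilcoxon p", {
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(20, 0.3)
    got <- two_part_test(a, 0, b, 0)$p_value
    ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    expect_equal(got, ref, tolerance = 1e-10)
  }
  ## exact branch comparison for small tie-free samples
  a <- c(0.3, 1.7, 2.9, 4.1); b <- c(0.9, 2.2, 5.5)
  expect_equal(two_part_test(a, 0, b, 0)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_fdr(0.7), 0.7)
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(3:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, enum_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "oatpnet_bad_input")
})

test_that("group comparison table: ordering, exclusions, single-gene panels", {
  set.seed(9)
  n_t <- 30; n_b <- 10
  vals <- cbind(same = c(rnorm(n_t), rnorm(n_b)),
                shift = c(rnorm(n_t, 5), rnorm(n_b, -5)),
                absent = NA_real_,
                onesided = c(rnorm(n_t), rep(NA, n_b)))
  det <- !is.na(vals)
  e <- expr_dataset(vals, det, sprintf("s%d", seq_len(n_t + n_b)),
                    group = rep(c("tumor", "benign"), c(n_t, n_b)))
  tab <- compare_groups(e)
  ## the never-detected gene is excluded with a log entry
  expect_identical(attr(tab, "excluded"), "absent")
  ## FDR ordering matches p ordering (BH is rank-preserving)
  expect_equal(order(tab$fdr), order(tab$p_value))
  ## detected-only-in-tumor gene: point-mass part df 1, tiny FDR
  row1 <- tab[tab$gene == "onesided", ]
  expect_equal(row1$df, 1L)
  expect_lt(row1$fdr, 0.001)

  ## single-gene panel: FDR equals the raw p
  e1 <- expr_dataset(vals[, "shift", drop = FALSE],
                     det[, "shift", drop = FALSE],
                     sprintf("s%d", seq_len(n_t + n_b)),
                     group = rep(c("tumor", "benign"), c(n_t, n_b)))
  tab1 <- compare_groups(e1)
  expect_equal(tab1$fdr, tab1$p_value)
})
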