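test_that("generation is deterministic and stamped with its truth", {
  d1 <- generate_dataset(synthetic_config(n = 60), seed = 5)
  d2 <- generate_dataset(synthetic_config(n = 60), seed = 5)
  expect_identical(d1$expr$values, d2$expr$values)
  expect_identical(d1$clinical, d2$clinical)
  expect_identical(d1$signatures, d2$signatures)
  d3 <- generate_dataset(synthetic_config(n = 60), seed = 6)
  expect_false(identical(d1$expr$values, d3$expr$values))
  ## planted edges are exactly the nonzero off-diagonal precision support
  Om <- d1$truth$precision
  off <- which(Om != 0 & row(Om) < col(Om), arr.ind = TRUE)
  from_precision <- sort(unname(apply(off, 1, function(r) {
    paste(sort(rownames(Om)[r]), collapse = "|")
  })))
  expect_identical(from_precision, sort(edge_strings(d1$truth$planted_edges)))
})

test_that("planted partial correlations are realized in large samples", {
  d <- generate_dataset(synthetic_config(n = 2000), seed = 9)
  X <- d$expr$values[, d$config$complete_genes]
  ## sample partial correlations from the inverse empirical covariance
  Oi <- solve(cov(X))
  Dg <- diag(1 / sqrt(diag(Oi)))
  pcor <- -Dg %*% Oi %*% Dg
  dimnames(pcor) <- dimnames(Oi)
  for (blk in d$config$blocks) {
    m <- blk$members
    for (i in seq_len(length(m) - 1)) {
      expect_lt(abs(pcor[m[i], m[i + 1]] - blk$rho), 0.1)
    }
  }
})

test_that("covariance and detection fractions match their configuration", {
  d <- generate_dataset(synthetic_config(n = 5000), seed = 10)
  genes <- c(d$config$complete_genes, d$config$limited_genes)
  Sigma <- solve(d$truth$precision)
  ## reconstruct the latent values from the mask-free complete genes and
  ## compare the empirical covariance of complete genes entrywise
  X <- d$expr$values[, d$config$complete_genes]
  emp <- cov(X)
  dev <- abs(emp - Sigma[colnames(X), colnames(X)])
  ## the strict maximum over all ~300 entries sits near 2.5-3 standard
  ## errors even when the generator is exact, so check the bulk at the
  ## entrywise band and cap the worst entry slightly above it
  expect_gte(mean(dev < 0.05), 0.99)
  expect_lt(max(dev), 0.08)
  ## detection fraction per limited gene near its configured rate
  d2 <- generate_dataset(synthetic_config(n = 1000), seed = 11)
  rates <- colMeans(d2$expr$detected[, d2$config$limited_genes])
  expect_true(all(abs(rates - d2$config$detection_rates) < 0.05))
})

test_that("event fraction calibrates to its target", {
  d <- generate_dataset(synthetic_config(n = 1000), seed = 12)
  expect_lt(abs(mean(d$clinical$os_event) - 0.61), 0.05)
  expect_true(all(d$clinical$os_months <= 120 + 1e-9))
})

test_that("true-model coefficients are recovered without material bias", {
  est <- t(vapply(1:20, function(s) {
    d <- generate_dataset(synthetic_config(n = 400), seed = 2000 + s)
    fm <- encode_features(d$expr, d$clinical)
    out <- surv_outcome(d$clinical$os_months, d$clinical$os_event)
    cols <- c("age", "figo_iv", "residual_yes", "CG07")
    fit <- fit_cox(fm$X[, cols], out)
    fit$coefficients
  }, numeric(4)))
  truth <- c(0.03, 0.5, 0.7, -0.4)
  bias <- colMeans(est) - truth
  ## CG07 is standardized in the design, matching the generator's scale
  expect_lt(abs(bias[["CG07"]]), 0.05)
  expect_lt(abs(bias[["figo_iv"]]), 0.1)
  expect_lt(abs(bias[["residual_yes"]]), 0.1)
})

test_that("non-positive-definite precision requests are rejected before sampling", {
  cfg <- synthetic_config(blocks = list(
    list(members = sprintf("CG%02d", 1:4), rho = 0.9)))
  expect_error(generate_dataset(cfg, seed = 1), class = "oatpnet_bad_config")
})

test_that("study-shaped fixture has the cohort dimensions and runs end to end", {
  fx <- study_fixture(seed = 3)
  expect_equal(sum(fx$expr$group == "tumor"), 135)
  expect_equal(sum(fx$expr$group == "benign"), 21)
  expect_equal(ncol(fx$expr$values), 28)
  ## rarely-expressed genes are flagged for exclusion
  expect_identical(fx$exclude, c("SLCO1B1", "SLCO1C1"))
  ## same seed agrees
  fx2 <- study_fixture(seed = 3)
  expect_identical(fx$expr$values, fx2$expr$values)

  ## every pipeline stage runs on the fixture
  cg <- compare_groups(fx$expr, exclude = fx$exclude)
  expect_gt(nrow(cg), 15)
  ## tumor upregulation: shifted benign means push medians down
  both <- cg[cg$detection_rate_b > 0, ]
  expect_gt(mean(both$median_a > both$median_b), 0.8)
  tum <- expr_subset(fx$expr, fx$expr$group == "tumor")
  fm <- encode_features(tum, fx$clinical, exclude = fx$exclude)
  out <- surv_outcome(fx$clinical$os_months, fx$clinical$os_event)
  expect_s3_class(fit_cox(fm$X[, 1:3], out), "cox_model")
  tab <- spearman_matrix(fm, fx$signatures)
  expect_equal(nrow(tab), sum(fm$provenance != "gene-indicator"))
})
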