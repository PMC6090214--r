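test_that("lambda at or above lambda_max zeroes all penalized groups exactly", {
  sc <- small_cohort(n = 100, seed = 4)
  lm0 <- lambda_max(sc$fm, sc$outcome)
  b <- grouped_lasso_cox(sc$fm, sc$outcome, lm0 * (1 + 1e-8))
  pen <- sc$fm$provenance != "clinical"
  expect_true(all(b[pen] == 0))
  ## clinical coefficients equal the clinical-only Cox fit (Breslow ties)
  clin <- colnames(sc$fm$X)[!pen]
  ref <- fit_cox(sc$fm$X[, clin], sc$outcome, ties = "breslow")
  expect_equal(b[clin], ref$coefficients, tolerance = 1e-4)
})

test_that("lambda = 0 matches the Newton (coxph, Breslow) oracle", {
  sc <- small_cohort(n = 90, seed = 5)
  cols <- c("age", "figo_iv", "residual_yes", "CG07", "CG01", "LG4", "LG4_2K")
  idx <- match(cols, colnames(sc$fm$X))
  fm <- feature_matrix(sc$fm$X[, idx], match(sc$fm$group[idx], unique(sc$fm$group[idx])),
                       sc$fm$group_names[unique(sc$fm$group[idx])],
                       sc$fm$multiplier[unique(sc$fm$group[idx])],
                       sc$fm$provenance[idx], sc$fm$sample_id)
  b <- grouped_lasso_cox(fm, sc$outcome, 0)
  ref <- fit_cox(fm$X, sc$outcome, ties = "breslow")
  expect_equal(as.numeric(b), unname(ref$coefficients), tolerance = 1e-4)
})

test_that("paired columns are jointly zero or jointly nonzero along the path", {
  sc <- small_cohort(n = 100, seed = 6)
  fm <- sc$fm
  lm0 <- lambda_max(fm, sc$outcome)
  lim <- names(which(sc$d$expr$gene_status == "limited"))
  for (frac in c(0.8, 0.4, 0.15, 0.05)) {
    b <- grouped_lasso_cox(fm, sc$outcome, lm0 * frac)
    for (g in lim) {
      pair <- b[c(g, paste0(g, "_2K"))]
      expect_true(all(pair == 0) || all(pair != 0),
                  info = sprintf("gene %s at frac %g", g, frac))
    }
  }
})

test_that("KKT conditions hold at reported solutions", {
  sc <- small_cohort(n = 100, seed = 7)
  lm0 <- lambda_max(sc$fm, sc$outcome)
  for (frac in c(0.5, 0.2, 0.08)) {
    lam <- lm0 * frac
    b <- grouped_lasso_cox(sc$fm, sc$outcome, lam)
    res <- kkt_residuals(sc$fm, sc$outcome, b, lam)
    expect_lt(max(res), 1e-6)
  }
})

test_that("cross-validated selection is deterministic and structured", {
  sc <- small_cohort(n = 100, seed = 8)
  cv1 <- select_lambda(sc$fm, sc$outcome, folds = 5, nlambda = 20, seed = 3)
  cv2 <- select_lambda(sc$fm, sc$outcome, folds = 5, nlambda = 20, seed = 3)
  expect_identical(cv1$lambda_star, cv2$lambda_star)
  expect_identical(cv1$cvm, cv2$cvm)
  expect_identical(cv1$selected, cv2$selected)
  expect_length(cv1$cvm, 20)
  expect_length(cv1$lambda, 20)
  expect_true(all(diff(cv1$lambda) < 0))
  ## at the largest grid lambda all penalized groups are zero
  pen <- sc$fm$provenance != "clinical"
  expect_true(all(cv1$beta[pen, 1] == 0))
})

test_that("a strong true group is selected at lambda*", {
  hits <- 0L
  reps <- 10L
  for (s in seq_len(reps)) {
    cfg <- synthetic_config(n = 400, beta_gene = c(CG07 = -0.8))
    d <- generate_dataset(cfg, seed = 5000 + s)
    fm <- encode_features(d$expr, d$clinical)
    out <- surv_outcome(d$clinical$os_months, d$clinical$os_event)
    cv <- select_lambda(fm, out, folds = 5, nlambda = 20, seed = s)
    if ("CG07" %in% cv$selected) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("linear grouped lasso at lambda = 0 matches the normal equations", {
  set.seed(15)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 1 + 0.5 * X[, "a"] - 0.3 * X[, "c"] + rnorm(n, sd = 0.4)
  fm <- feature_matrix(X, 1:3, c("a", "b", "c"), rep(1, 3),
                       rep("gene-continuous", 3), sprintf("s%d", 1:n))
  fit <- grouped_lasso_glm_fit(fm, y, family = "linear", lambda = 0)
  ref <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(unname(fit$intercept), ref[1], tolerance = 1e-6)
  expect_equal(unname(as.numeric(fit$beta)), unname(ref[-1]), tolerance = 1e-6)
})

test_that("GLM edge cases: lambda_max intercept-only model; single-class target", {
  set.seed(16)
  n <- 80
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(X[, "a"]))
  fm <- feature_matrix(X, 1:2, c("a", "b"), c(1, 1),
                       rep("gene-continuous", 2), sprintf("s%d", 1:n))
  lm0 <- lambda_max(fm, y, family = "logistic")
  fit <- grouped_lasso_glm_fit(fm, y, family = "logistic",
                               lambda = lm0 * (1 + 1e-8))
  expect_true(all(fit$beta == 0))
  expect_equal(plogis(fit$intercept), mean(y), tolerance = 1e-6)
  expect_error(grouped_lasso_glm(fm, rep(1, n), family = "logistic"),
               class = "oatpnet_bad_input")
})

test_that("coefficient paths are continuous in lambda on a fixed dataset", {
  sc <- small_cohort(n = 80, seed = 17)
  cv <- select_lambda(sc$fm, sc$outcome, folds = 5, nlambda = 40, seed = 2)
  jumps <- apply(abs(diff(t(cv$beta))), 1, max)
  expect_lt(max(jumps), 0.6)
})
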