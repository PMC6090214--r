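test_that("delta-delta-Cq arithmetic, detection masking and shift invariance", {
  cq <- toy_cq()
  e <- compute_relative_expression(cq, c("R1", "R2"),
                                   calibrator_dcq = c(GA = 3))
  ## s1: ref mean 20, GA Cq 25, calibrator dCq 3 -> -(25-20) + 3 = -2
  expect_equal(unname(e$values["s1", "GA"]), -2)
  ## GB Cq 36 > 35 -> undetectable, value absent
  expect_false(e$detected["s2", "GB"])
  expect_true(is.na(e$values["s2", "GB"]))
  ## missing cell -> undetectable
  expect_false(e$detected["s4", "GB"])
  expect_identical(unname(e$gene_status), c("complete", "limited", "complete"))

  ## adding a constant to every Cq of one sample leaves values unchanged
  cq2 <- cq
  cq2[cq2$sample_id == "s1", c("R1", "R2", "GA", "GB", "GC")] <-
    cq2[cq2$sample_id == "s1", c("R1", "R2", "GA", "GB", "GC")] + 1
  e2 <- compute_relative_expression(cq2, c("R1", "R2"),
                                    calibrator_dcq = c(GA = 3))
  expect_equal(e2$values["s1", ], e$values["s1", ])
  expect_identical(e2$detected, e$detected)

  ## round-trip through relative quantities is the identity
  rq <- 2^e$values
  expect_equal(log2(rq), e$values, tolerance = 1e-12)
})

test_that("reference-gene failures and unknown calibrators are rejected", {
  cq <- toy_cq()
  cq$R1[2] <- 36
  expect_error(compute_relative_expression(cq, c("R1", "R2")),
               class = "oatpnet_bad_reference")
  expect_error(compute_relative_expression(cq, c("R1", "R2")), "s2")
  expect_warning(
    e <- compute_relative_expression(cq, c("R1", "R2"),
                                     on_bad_reference = "drop"))
  expect_identical(attr(e, "excluded_samples"), "s2")
  expect_equal(nrow(e$values), 3)

  expect_error(
    compute_relative_expression(toy_cq(), c("R1", "R2"),
                                calibrator_dcq = c(NOPE = 1)),
    class = "oatpnet_bad_calibrator")
})

test_that("feature encoding: groups, pairing, imputation and penalties", {
  sc <- small_cohort(n = 80, seed = 3)
  fm <- sc$fm
  ## every column in exactly one group; group sizes sum to column count
  expect_equal(length(fm$group), ncol(fm$X))
  expect_equal(sum(tabulate(fm$group)), ncol(fm$X))
  ## clinical block: one group, multiplier 0
  clin <- which(fm$provenance == "clinical")
  expect_length(unique(fm$group[clin]), 1)
  expect_equal(fm$multiplier[unique(fm$group[clin])], 0)
  ## complete genes: singleton groups with multiplier 1
  for (g in c("CG07", "CG20")) {
    k <- unique(fm$group[colnames(fm$X) == g])
    expect_length(group_columns(fm, k), 1)
    expect_equal(fm$multiplier[k], 1)
  }
  ## detection-limited genes: two columns sharing one group
  d <- sc$d
  lim <- names(which(d$expr$gene_status == "limited"))
  for (g in lim) {
    k <- unique(fm$group[colnames(fm$X) %in% c(g, paste0(g, "_2K"))])
    expect_length(k, 1)
    expect_length(group_columns(fm, k), 2)
  }
  ## undetected entries: indicator 0 and continuous exactly 0
  g1 <- lim[1]
  und <- !d$expr$detected[, g1]
  expect_true(all(fm$X[und, paste0(g1, "_2K")] == 0))
  expect_true(all(fm$X[und, g1] == 0))
})

test_that("encoding errors: too few detected; all-detected limited gene demoted", {
  vals <- cbind(A = rnorm(10), B = c(rnorm(2), rep(NA, 8)))
  det <- !is.na(vals)
  e <- expr_dataset(vals, det, sprintf("s%d", 1:10))
  expect_error(encode_features(e), class = "oatpnet_too_few_detected")
  expect_error(encode_features(e), "B")

  ## a declared-limited gene detected everywhere is demoted with a warning
  vals2 <- cbind(A = rnorm(10), B = rnorm(10))
  e2 <- expr_dataset(vals2, !is.na(vals2), sprintf("s%d", 1:10))
  e2$gene_status["B"] <- "limited"
  expect_warning(fm <- encode_features(e2), "treating as complete")
  expect_false("B_2K" %in% colnames(fm$X))
})

test_that("cohort summary reproduces printed-style percentages and quartiles", {
  clin <- data.frame(
    sample_id = sprintf("P%03d", 1:135),
    age_years = rnorm(135, 57, 10),
    figo_stage = rep(c("III", "IV"), c(109, 26)),
    residual_tumor = c(rep("no", 94), rep("yes", 39), NA, NA),
    os_months = rexp(135, 1 / 48),
    os_event = rep(c(1L, 0L), c(82, 53)),
    stringsAsFactors = FALSE)
  s <- cohort_summary(clin)
  ## 82 deaths of 135 -> 61% of the full cohort
  ev <- s[s$variable == "os_event", ]
  expect_equal(ev$count, 82)
  expect_equal(ev$percent, 61)
  ## residual tumor: percentages among the 133 recorded -> "no" = 71%
  no <- s[s$variable == "residual_tumor" & s$level == "no", ]
  expect_equal(no$percent, 71)
  ## an exhaustive categorical sums to 100 +- 1 under integer rounding
  figo <- s[s$variable == "figo_stage" & s$level != "missing", ]
  expect_lte(abs(sum(figo$percent) - 100), 1)

  ## linear-interpolation quartiles
  s2 <- cohort_summary(data.frame(sample_id = letters[1:5],
                                  age_years = c(1, 2, 3, 4, 5)))
  expect_equal(s2$median, 3)
  expect_equal(s2$q25, 2)
  expect_equal(s2$q75, 4)

  expect_error(cohort_summary(data.frame()), class = "oatpnet_bad_input")
})
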