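#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure the analysis assumes: multivariate
#' normal log2 expression with a chain-structured sparse precision matrix
#' (each block is a path whose adjacent pairs have partial correlation
#' exactly \code{rho}; paths keep the matrix positive definite at the
#' planted partial-correlation values, which cliques cannot for blocks of
#' four at \eqn{\rho = 0.35}), gene-specific detection censoring below a
#' quantile threshold, clinical covariates with cohort-like marginals,
#' Weibull-baseline Cox survival with a censoring scale calibrated to a
#' target event fraction, and signature scores as linear combinations of
#' chosen genes.
#'
#' @param n number of tumor samples.
#' @param complete_genes,limited_genes gene label vectors.
#' @param detection_rates per-limited-gene detection probabilities (named
#'   or positional).
#' @param blocks list of \code{list(members, rho)} defining chain blocks
#'   over complete genes.
#' @param age_mean,age_sd,figo_iv_p,residual_p clinical marginals.
#' @param beta_clinical named numeric: \code{age} (per year), \code{figo_iv},
#'   \code{residual_yes}.
#' @param beta_gene named numeric, effect per SD of latent expression.
#' @param beta_indicator named numeric, effect of being detected (limited
#'   genes).
#' @param beta_network named numeric over block indices (effect per SD of
#'   the block-mean score).
#' @param weibull_shape,weibull_scale baseline hazard parameters (months).
#' @param event_target target event (death) fraction; the uniform
#'   censoring scale is calibrated so the expected fraction matches it.
#' @param admin_cap administrative censoring time in months.
#' @param signature_loadings named list per signature: \code{list(genes,
#'   weights, noise_sd)}; \code{yoshihara} uses a logistic rule on its
#'   linear combination.
#' @return A list of class \code{synth_config}.
#' @export
synthetic_config <- function(n = 135,
                             complete_genes = sprintf("CG%02d", 1:24),
                             limited_genes = sprintf("LG%d", 1:5),
                             detection_rates = c(0.47, 0.39, 0.47, 0.70, 0.85),
                             blocks = list(
                               list(members = sprintf("CG%02d", 1:4), rho = 0.35),
                               list(members = sprintf("CG%02d", 5:6), rho = 0.5)),
                             age_mean = 57, age_sd = 10,
                             figo_iv_p = 0.19, residual_p = 0.29,
                             beta_clinical = c(age = 0.03, figo_iv = 0.5,
                                               residual_yes = 0.7),
                             beta_gene = c(CG07 = -0.4),
                             beta_indicator = c(LG4 = -0.5),
                             beta_network = c(`1` = 0.3),
                             weibull_shape = 1.2, weibull_scale = 60,
                             event_target = 0.61, admin_cap = 120,
                             signature_loadings = list(
                               nm_m = list(genes = c("CG08", "CG01"),
                                           weights = c(0.8, 0.4), noise_sd = 0.6),
                               o_t = list(genes = c("CG09"),
                                          weights = c(0.7), noise_sd = 0.7),
                               emt = list(genes = c("CG10", "CG05"),
                                          weights = c(0.6, -0.5), noise_sd = 0.7),
                               yoshihara = list(genes = c("CG07", "CG02"),
                                                weights = c(1.2, -0.8),
                                                noise_sd = 0))) {
  cfg <- list(n = n, complete_genes = complete_genes,
              limited_genes = limited_genes,
              detection_rates = setNames(detection_rates, limited_genes),
              blocks = blocks, age_mean = age_mean, age_sd = age_sd,
              figo_iv_p = figo_iv_p, residual_p = residual_p,
              beta_clinical = beta_clinical, beta_gene = beta_gene,
              beta_indicator = beta_indicator, beta_network = beta_network,
              weibull_shape = weibull_shape, weibull_scale = weibull_scale,
              event_target = event_target, admin_cap = admin_cap,
              signature_loadings = signature_loadings)
  class(cfg) <- "synth_config"
  cfg
}

## precision matrix with chain blocks: unit diagonal, -rho on adjacent
## pairs of each block; planted partial correlation of each pair is rho
build_precision <- function(genes, blocks) {
  p <- length(genes)
  Omega <- diag(p)
  dimnames(Omega) <- list(genes, genes)
  edges <- matrix(character(0), 0, 2)
  for (blk in blocks) {
    m <- blk$members
    stopifnot(all(m %in% genes))
    for (i in seq_len(length(m) - 1)) {
      a <- m[i]; b <- m[i + 1]
      Omega[a, b] <- Omega[b, a] <- -blk$rho
      edges <- rbind(edges, sort(c(a, b)))
    }
  }
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop_named("requested precision matrix is not positive definite",
               class = "oatpnet_bad_config")
  }
  list(Omega = Omega, edges = edges)
}

#' Generate a synthetic cohort with full ground truth
#'
#' Draws expression, clinical covariates, survival outcomes and signature
#' scores under the model described in \code{\link{synthetic_config}}.
#' All randomness flows from one master seed through per-component
#' sub-streams, so e.g. enlarging the gene panel does not perturb the
#' clinical draws.
#'
#' @param config a \code{synth_config}.
#' @param seed master integer seed.
#' @return A list: \code{expr} (an \code{expr_dataset}, tumor samples),
#'   \code{clinical} (data frame), \code{signatures} (data frame) and
#'   \code{truth} (precision matrix, planted edges, thresholds, true
#'   coefficients, baseline and censoring parameters, seed).
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1L) {
  cfg <- config
  genes <- c(cfg$complete_genes, cfg$limited_genes)
  pre <- build_precision(genes, cfg$blocks)
  Sigma <- solve(pre$Omega)
  sample_id <- sprintf("S%04d", seq_len(cfg$n))

  set.seed(substream_seed(seed, "expression"))
  X <- MASS::mvrnorm(cfg$n, mu = rep(0, length(genes)), Sigma = Sigma)
  colnames(X) <- genes
  rownames(X) <- sample_id
  sd_marg <- sqrt(diag(Sigma))

  ## detection thresholds: theoretical marginal quantiles, so the
  ## expected detection fraction equals the configured rate
  thr <- setNames(qnorm(1 - cfg$detection_rates, mean = 0,
                        sd = sd_marg[cfg$limited_genes]),
                  cfg$limited_genes)
  detected <- matrix(TRUE, cfg$n, length(genes), dimnames = dimnames(X))
  for (g in cfg$limited_genes) detected[, g] <- X[, g] > thr[[g]]
  values <- X
  values[!detected] <- NA_real_

  set.seed(substream_seed(seed, "clinical"))
  age <- rnorm(cfg$n, cfg$age_mean, cfg$age_sd)
  figo <- rbinom(cfg$n, 1, cfg$figo_iv_p)
  resid <- rbinom(cfg$n, 1, cfg$residual_p)

  ## linear predictor over latent (uncensored) standardized expression
  Z <- sweep(X, 2, sd_marg, "/")
  eta <- cfg$beta_clinical[["age"]] * (age - cfg$age_mean) +
    cfg$beta_clinical[["figo_iv"]] * figo +
    cfg$beta_clinical[["residual_yes"]] * resid
  for (g in names(cfg$beta_gene)) eta <- eta + cfg$beta_gene[[g]] * Z[, g]
  for (g in names(cfg$beta_indicator)) {
    eta <- eta + cfg$beta_indicator[[g]] * as.numeric(detected[, g])
  }
  for (b in names(cfg$beta_network)) {
    mem <- cfg$blocks[[as.integer(b)]]$members
    score <- rowMeans(Z[, mem, drop = FALSE])
    eta <- eta + cfg$beta_network[[b]] * score / sd(score)
  }

  set.seed(substream_seed(seed, "survival"))
  U <- runif(cfg$n)
  T_lat <- cfg$weibull_scale * (-log(U) / exp(eta))^(1 / cfg$weibull_shape)
  c_max <- calibrate_censoring(T_lat, cfg$event_target, cfg$admin_cap)
  V <- runif(cfg$n, 0, c_max)
  C <- pmin(V, cfg$admin_cap)
  os_months <- pmin(T_lat, C)
  os_event <- as.integer(T_lat <= C)

  clinical <- data.frame(
    sample_id = sample_id, age_years = age,
    figo_stage = ifelse(figo == 1, "IV", "III"),
    residual_tumor = ifelse(resid == 1, "yes", "no"),
    os_months = os_months, os_event = os_event,
    stringsAsFactors = FALSE)

  set.seed(substream_seed(seed, "signatures"))
  sig_score <- function(ld) {
    s <- numeric(cfg$n)
    for (i in seq_along(ld$genes)) s <- s + ld$weights[i] * Z[, ld$genes[i]]
    s + rnorm(cfg$n, 0, ld$noise_sd)
  }
  yos_lin <- sig_score(cfg$signature_loadings$yoshihara)
  signatures <- data.frame(
    sample_id = sample_id,
    nm_m = sig_score(cfg$signature_loadings$nm_m),
    o_t = sig_score(cfg$signature_loadings$o_t),
    emt = sig_score(cfg$signature_loadings$emt),
    yoshihara = 1L + rbinom(cfg$n, 1, plogis(yos_lin)),
    stringsAsFactors = FALSE)

  expr <- expr_dataset(values, detected, sample_id,
                       group = rep("tumor", cfg$n))
  truth <- list(precision = pre$Omega, planted_edges = pre$edges,
                thresholds = thr, detection_rates = cfg$detection_rates,
                beta_clinical = cfg$beta_clinical,
                beta_gene = cfg$beta_gene,
                beta_indicator = cfg$beta_indicator,
                beta_network = cfg$beta_network,
                weibull = c(shape = cfg$weibull_shape,
                            scale = cfg$weibull_scale),
                censoring = c(c_max = c_max, admin_cap = cfg$admin_cap),
                eta = eta, latent_time = T_lat, seed = seed)
  list(expr = expr, clinical = clinical, signatures = signatures,
       truth = truth, config = cfg)
}

## uniform-censoring scale such that the expected event fraction over the
## drawn latent times matches the target; monotone in c_max
calibrate_censoring <- function(T_lat, target, admin_cap) {
  frac <- function(c_max) mean((T_lat <= admin_cap) * pmax(0, 1 - T_lat / c_max))
  upper <- admin_cap * 1000
  if (frac(upper) < target) {
    warning("administrative cap limits the achievable event fraction")
    return(upper)
  }
  uniroot(function(c0) frac(c0) - target,
          lower = max(min(T_lat), 1e-6), upper = upper, tol = 1e-8)$root
}

#' Study-shaped synthetic fixture
#'
#' A ready-made dataset bundle with the dimensions and gene panel of the
#' motivating study: 135 tumor samples plus 21 benign comparison samples
#' over a 28-gene transporter panel (12 SLCO, 9 ABC, PXR, PTGS2, HPGD,
#' SULT1E1, ESR1, ESR2, HER2). Two networks are planted among the
#' complete genes (SLCO2B1-ABCC3 at partial correlation 0.5 and the chain
#' ABCB2-ABCB3-ABCC4-HER2 at 0.35); five genes are detection-limited with
#' study-like detection rates; SLCO1B1 and SLCO1C1 are rarely expressed
#' (meant to be excluded downstream); SLCO5A1 is protective for survival.
#' Benign samples share the tumor covariance but are shifted down by one
#' log2 unit, so they show both lower detected values and higher
#' non-detection.
#'
#' @param seed master integer seed.
#' @return As \code{\link{generate_dataset}}, with \code{expr} holding
#'   both groups (labels \code{"tumor"} / \code{"benign"}), plus
#'   \code{exclude} (the rarely-expressed genes).
#' @export
study_fixture <- function(seed = 1L) {
  slco <- c("SLCO1A2", "SLCO1B1", "SLCO1B3", "SLCO1B7", "SLCO1C1",
            "SLCO2A1", "SLCO2B1", "SLCO3A1", "SLCO4A1", "SLCO4C1",
            "SLCO5A1", "SLCO6A1")
  abc <- c("ABCA1", "ABCB1", "ABCB2", "ABCB3", "ABCC1", "ABCC2", "ABCC3",
           "ABCC4", "ABCC10")
  other <- c("PXR", "PTGS2", "HPGD", "SULT1E1", "ESR1", "ESR2", "HER2")
  limited <- c(SLCO1A2 = 0.47, SLCO1B3 = 0.39, SLCO4C1 = 0.47,
               SLCO5A1 = 0.70, SLCO6A1 = 0.14,
               SLCO1B1 = 0.02, SLCO1C1 = 0.03)
  panel <- c(slco, abc, other)
  complete <- setdiff(panel, names(limited))
  cfg <- synthetic_config(
    n = 135,
    complete_genes = complete,
    limited_genes = names(limited),
    detection_rates = unname(limited),
    blocks = list(
      list(members = c("ABCB2", "ABCB3", "ABCC4", "HER2"), rho = 0.35),
      list(members = c("SLCO2B1", "ABCC3"), rho = 0.5)),
    beta_gene = c(SLCO5A1 = -0.4, ESR1 = -0.2, SLCO4C1 = 0.25),
    beta_indicator = c(SLCO5A1 = -0.8, SLCO4C1 = 0.6),
    beta_network = c(`1` = 0.2),
    signature_loadings = list(
      nm_m = list(genes = c("SLCO2A1", "HPGD"), weights = c(-0.7, -0.5),
                  noise_sd = 0.7),
      o_t = list(genes = c("ESR1", "SLCO3A1"), weights = c(0.5, 0.5),
                 noise_sd = 0.7),
      emt = list(genes = c("SLCO4A1"), weights = c(0.6), noise_sd = 0.8),
      yoshihara = list(genes = c("SLCO5A1", "ESR1", "SLCO2A1"),
                       weights = c(-1.0, -0.6, 1.0), noise_sd = 0)))
  ## note: beta_gene on SLCO5A1 acts on its latent (uncensored) values;
  ## downstream models see the detection-masked version
  tumor <- generate_dataset(cfg, seed)

  ## benign group: same covariance, all genes shifted down one log2 unit,
  ## detection thresholds unchanged on the tumor scale
  set.seed(substream_seed(seed, "benign"))
  genes <- c(cfg$complete_genes, cfg$limited_genes)
  Sigma <- solve(tumor$truth$precision)
  Xb <- MASS::mvrnorm(21, mu = rep(-1, length(genes)), Sigma = Sigma)
  colnames(Xb) <- genes
  det_b <- matrix(TRUE, 21, length(genes), dimnames = dimnames(Xb))
  for (g in cfg$limited_genes) det_b[, g] <- Xb[, g] > tumor$truth$thresholds[[g]]
  Xb[!det_b] <- NA_real_
  benign_id <- sprintf("B%03d", 1:21)
  rownames(Xb) <- rownames(det_b) <- benign_id

  values <- rbind(tumor$expr$values, Xb)
  detected <- rbind(tumor$expr$detected, det_b)
  expr <- expr_dataset(values, detected, c(tumor$expr$sample_id, benign_id),
                       group = c(rep("tumor", cfg$n), rep("benign", 21)))
  list(expr = expr, clinical = tumor$clinical,
       signatures = tumor$signatures, truth = tumor$truth, config = cfg,
       exclude = c("SLCO1B1", "SLCO1C1"))
}
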