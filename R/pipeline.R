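#' Sweep the graph-selection penalty and score each model by explained
#' variation
#'
#' For each value of the graph-selection tuning parameter \code{K}:
#' selects a gene graph over the complete-expression genes (tumor samples
#' only), summarizes its connected components by first principal
#' components, encodes the feature matrix (network PC1 scores, remaining
#' single genes, paired detection-limited genes, unpenalized clinical
#' block), selects the grouped-LASSO Cox penalty by cross-validation,
#' refits the selected groups unpenalized together with the clinical
#' block, and computes the model's percentage of explained variation.
#' The selected \code{K*} maximizes PEV; ties resolve to the smallest
#' \code{K}. One master seed drives the fold assignment, which is shared
#' across \code{K} so PEV differences reflect \code{K} rather than fold
#' noise.
#'
#' @param expr an \code{expr_dataset}; if it carries a \code{group}
#'   element, only \code{"tumor"} samples are used.
#' @param clinical clinical data frame aligned with the tumor samples.
#' @param K_grid penalty values to sweep (default \code{1:8}).
#' @param seed master integer seed.
#' @param exclude genes dropped before any modelling.
#' @param folds,nlambda cross-validation controls.
#' @param families,d_max graph-selection controls.
#' @param tol solver tolerance.
#' @return An object of class \code{ksweep_result}: per-K list
#'   (\code{graph}, \code{networks}, \code{singletons}, \code{fm},
#'   \code{lasso}, \code{refit}, \code{pev}), the PEV vector, \code{k_star}
#'   and the seed.
#' @export
run_k_sweep <- function(expr, clinical, K_grid = 1:8, seed = 1L,
                        exclude = character(), folds = 10L, nlambda = 50L,
                        families = c("corr01", "lasso-and", "adaptive"),
                        d_max = NULL, tol = 1e-9) {
  if (!is.null(expr$group)) {
    expr <- expr_subset(expr, expr$group == "tumor")
  }
  clinical <- clinical[match(expr$sample_id, clinical$sample_id), , drop = FALSE]
  complete <- setdiff(names(which(expr$gene_status == "complete")), exclude)
  if (length(complete) < 2) {
    stop_named("need at least 2 complete genes for graph selection",
               class = "oatpnet_bad_input")
  }
  Xc <- expr$values[, complete, drop = FALSE]
  per_k <- vector("list", length(K_grid))
  pev <- numeric(length(K_grid))
  for (i in seq_along(K_grid)) {
    K <- K_grid[i]
    res <- tryCatch({
      graph <- select_graph(Xc, K, families = families, d_max = d_max)
      nets <- extract_networks(graph, Xc)
      fm <- suppressWarnings(
        encode_features(expr, clinical, networks = nets$networks,
                        exclude = exclude))
      outcome <- clinical_outcome(clinical, fm$sample_id)
      lasso <- select_lambda(fm, outcome, folds = folds, nlambda = nlambda,
                             seed = seed, tol = tol)
      refit <- refit_selected(fm, outcome, lasso$selected)
      pv <- compute_pev(refit, outcome)
      list(graph = graph, networks = nets$networks,
           singletons = nets$singletons, fm = fm, outcome = outcome,
           lasso = lasso, refit = refit, pev = pv)
    }, error = function(e) {
      stop_named("K = %s failed: %s", K, conditionMessage(e),
                 class = "oatpnet_sweep_error")
    })
    per_k[[i]] <- res
    pev[i] <- res$pev$V
  }
  k_star <- K_grid[which.max(pev)]   # which.max takes the first (smallest K) tie
  structure(list(K_grid = K_grid, per_k = per_k, pev = pev,
                 k_star = k_star, seed = seed),
            class = "ksweep_result")
}

#' @export
print.ksweep_result <- function(x, ...) {
  cat("ksweep_result:\n")
  for (i in seq_along(x$K_grid)) {
    cat(sprintf("  K = %d: %d edges, %d network(s), %d group(s) selected, PEV = %.2f%%%s\n",
                x$K_grid[i], nrow(x$per_k[[i]]$graph$edges),
                length(x$per_k[[i]]$networks),
                length(x$per_k[[i]]$lasso$selected), 100 * x$pev[i],
                if (x$K_grid[i] == x$k_star) "  <- K*" else ""))
  }
  invisible(x)
}

clinical_outcome <- function(clinical, sample_id) {
  cl <- clinical[match(sample_id, clinical$sample_id), , drop = FALSE]
  surv_outcome(cl$os_months, cl$os_event)
}

## unpenalized Cox refit on the clinical block plus the selected groups
refit_selected <- function(fm, outcome, selected) {
  keep_groups <- which(fm$multiplier == 0 | fm$group_names %in% selected)
  cols <- colnames(fm$X)[fm$group %in% keep_groups]
  fit_cox(fm, outcome, columns = cols)
}

#' Final model, forest rows and PEV decomposition at the selected K
#'
#' Refits the unpenalized Cox model on the clinical block plus the groups
#' selected at \code{K*}, reports forest rows (2-df Wald p-values for
#' paired genes), and decomposes the explained variation: the
#' clinical-only PEV, the partial PEV of each selected factor (full-model
#' PEV minus the PEV of the full model refitted without that factor's
#' columns), and the total PEV.
#'
#' @param sweep a \code{ksweep_result}.
#' @return A list of class \code{final_model}: \code{model}
#'   (\code{cox_model}), \code{forest} (data frame), \code{pev_table}
#'   (factor / pev / partial_pev / total_pev in the cohort-table layout),
#'   \code{pev} (\code{pev_result} of the full model), \code{k_star}.
#' @export
finalize_model <- function(sweep) {
  i <- match(sweep$k_star, sweep$K_grid)
  st <- sweep$per_k[[i]]
  fm <- st$fm; outcome <- st$outcome
  model <- refit_selected(fm, outcome, st$lasso$selected)
  forest <- forest_multivariable(model, fm)
  full_pev <- compute_pev(model, outcome)

  clin_model <- refit_selected(fm, outcome, character(0))
  clin_pev <- compute_pev(clin_model, outcome)

  sel <- st$lasso$selected
  partial <- vapply(sel, function(g) {
    reduced <- refit_selected(fm, outcome, setdiff(sel, g))
    full_pev$V - compute_pev(reduced, outcome)$V
  }, numeric(1))

  pev_table <- rbind(
    data.frame(factor = "clinical (age/FIGO/residual)",
               pev = clin_pev$V, partial_pev = NA_real_,
               total_pev = NA_real_, stringsAsFactors = FALSE),
    if (length(sel)) data.frame(factor = sel, pev = NA_real_,
                                partial_pev = unname(partial),
                                total_pev = NA_real_,
                                stringsAsFactors = FALSE),
    data.frame(factor = "total", pev = NA_real_, partial_pev = NA_real_,
               total_pev = full_pev$V, stringsAsFactors = FALSE))
  rownames(pev_table) <- NULL
  structure(list(model = model, forest = forest, pev_table = pev_table,
                 pev = full_pev, clinical_pev = clin_pev,
                 k_star = sweep$k_star, fm = fm, outcome = outcome),
            class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  cat(sprintf("final_model at K* = %d: %d covariates, total PEV %.2f%% (clinical %.2f%%)\n",
              x$k_star, length(x$model$coefficients), 100 * x$pev$V,
              100 * x$clinical_pev$V))
  invisible(x)
}

#' Tercile risk stratification with model-based survival estimates
#'
#' Splits subjects into low/medium/high risk by the terciles of the final
#' model's linear predictor (ties at a cut point stay together). Each
#' group's survival curve is the average of its members' model-predicted
#' survival functions (model-based, not Kaplan-Meier), and the 5-year
#' (60-month) survival estimate is read off that curve, with a percentile
#' bootstrap confidence interval: each resample refits the unpenalized
#' final model, re-derives tercile membership, and recomputes the group
#' estimates.
#'
#' @param model the final \code{cox_model}.
#' @param outcome survival outcome.
#' @param horizon months at which to report survival (default 60); beyond
#'   the last event time the estimate at the last event time is used with
#'   a warning.
#' @param B bootstrap resamples (default 200).
#' @param seed integer seed for the bootstrap.
#' @return An object of class \code{risk_stratification}: \code{cuts},
#'   \code{group} (factor low/medium/high per subject), \code{curves}
#'   (list of times + per-group mean survival), \code{estimate}
#'   (per-group survival at the horizon), \code{ci} (2.5/97.5 percentile
#'   bounds), \code{horizon}, \code{seed}.
#' @export
risk_stratify <- function(model, outcome, horizon = 60, B = 200L, seed = 1L) {
  outcome <- as_outcome(outcome)
  lp <- as.numeric(model$X %*% model$coefficients)
  grp <- tercile_groups(lp)
  pred <- predict_survival(model)
  if (horizon > max(pred$times)) {
    warning(sprintf("horizon %g beyond last event time %g; reporting there",
                    horizon, max(pred$times)))
  }
  curves <- lapply(levels(grp), function(g) colMeans(pred$surv[grp == g, , drop = FALSE]))
  names(curves) <- levels(grp)
  est <- vapply(curves, function(s) eval_step(pred$times, s, horizon), numeric(1))

  set.seed(substream_seed(seed, "bootstrap"))
  boots <- matrix(NA_real_, B, 3, dimnames = list(NULL, levels(grp)))
  n <- nrow(model$X)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bs <- tryCatch({
      fit_b <- fit_cox(model$X[idx, , drop = FALSE],
                       surv_outcome(outcome$time[idx], outcome$event[idx]))
      lp_b <- as.numeric(fit_b$X %*% fit_b$coefficients)
      grp_b <- tercile_groups(lp_b)
      pred_b <- predict_survival(fit_b)
      vapply(levels(grp_b), function(g) {
        eval_step(pred_b$times,
                  colMeans(pred_b$surv[grp_b == g, , drop = FALSE]), horizon)
      }, numeric(1))
    }, error = function(e) rep(NA_real_, 3))
    boots[b, ] <- bs
  }
  ci <- apply(boots, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              type = 7)
  structure(list(cuts = attr(grp, "cuts"), group = grp,
                 times = pred$times, curves = curves,
                 estimate = est, ci = ci, horizon = horizon,
                 B = B, seed = seed,
                 n_boot_failed = sum(is.na(boots[, 1]))),
            class = "risk_stratification")
}

tercile_groups <- function(lp) {
  cuts <- quantile(lp, c(1 / 3, 2 / 3), type = 7)
  g <- cut(lp, breaks = c(-Inf, cuts, Inf),
           labels = c("low", "medium", "high"), right = TRUE)
  attr(g, "cuts") <- unname(cuts)
  g
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat(sprintf("risk_stratification at %g months (B = %d):\n", x$horizon, x$B))
  for (g in names(x$estimate)) {
    cat(sprintf("  %-6s n = %3d: %.1f%% [%.1f, %.1f]\n", g, sum(x$group == g),
                100 * x$estimate[[g]], 100 * x$ci[1, g], 100 * x$ci[2, g]))
  }
  invisible(x)
}

#' Run the full analysis pipeline on a cohort
#'
#' Convenience wrapper: K sweep, final model at \code{K*}, and tercile
#' risk stratification, returned together with a deterministic summary
#' serializable by \code{\link{pipeline_json}}.
#'
#' @inheritParams run_k_sweep
#' @param horizon,B risk-stratification controls.
#' @return A list of class \code{pipeline_result} with \code{sweep},
#'   \code{final}, \code{strata}.
#' @export
run_pipeline <- function(expr, clinical, K_grid = 1:8, seed = 1L,
                         exclude = character(), folds = 10L, nlambda = 50L,
                         horizon = 60, B = 200L, tol = 1e-9) {
  sweep <- run_k_sweep(expr, clinical, K_grid = K_grid, seed = seed,
                       exclude = exclude, folds = folds, nlambda = nlambda,
                       tol = tol)
  final <- finalize_model(sweep)
  strata <- risk_stratify(final$model, final$outcome, horizon = horizon,
                          B = B, seed = seed)
  structure(list(sweep = sweep, final = final, strata = strata, seed = seed),
            class = "pipeline_result")
}

#' Deterministic JSON summary of a pipeline run
#'
#' Serializes the quantities a run reports (K sweep PEVs, selected K*,
#' selected groups, forest rows, PEV decomposition, risk-group survival
#' estimates) without timestamps, so identical seeds yield byte-identical
#' output.
#'
#' @param result a \code{pipeline_result}.
#' @return A JSON string.
#' @export
pipeline_json <- function(result) {
  s <- result$sweep; f <- result$final; r <- result$strata
  obj <- list(
    seed = s$seed,
    K_grid = s$K_grid,
    pev_by_K = round(s$pev, 10),
    k_star = s$k_star,
    selected_groups = f$model$coefficients * 0 + 1,
    coefficients = round(f$model$coefficients, 10),
    forest = f$forest[c("label", "HR", "CI_low", "CI_high", "p_value", "df")],
    pev_table = f$pev_table,
    risk = list(cuts = round(r$cuts, 10),
                estimate = round(r$estimate, 10),
                ci = round(r$ci, 10))
  )
  obj$selected_groups <- names(f$model$coefficients)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "columns")
}
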