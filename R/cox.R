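#' Unpenalized Cox proportional-hazards fit
#'
#' Fits a Cox model by maximum partial likelihood (Efron tie handling by
#' default) and attaches the Breslow baseline cumulative hazard evaluated
#' at the distinct event times, for downstream per-subject survival
#' predictions \eqn{S_i(t) = \exp(-H_0(t) e^{\eta_i})}.
#'
#' @param fm a \code{feature_matrix} or plain numeric matrix of
#'   covariates.
#' @param outcome a \code{surv_outcome} or clinical data frame.
#' @param ties \code{"efron"} (default, reporting) or \code{"breslow"}.
#' @param columns optional subset of column names to fit on.
#' @return An object of class \code{cox_model}: \code{coefficients},
#'   \code{var} (inverse observed information), \code{loglik},
#'   \code{baseline} (data frame \code{time}, \code{cumhaz}),
#'   \code{converged}, \code{ties}, the design matrix \code{X} and the
#'   \code{outcome}.
#' @export
fit_cox <- function(fm, outcome, ties = c("efron", "breslow"),
                    columns = NULL) {
  ties <- match.arg(ties)
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  outcome <- as_outcome(outcome)
  if (sum(outcome$event) < 1) stop_named("no events", class = "oatpnet_bad_input")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop_named("constant covariate: %s",
               paste(colnames(X)[sds == 0], collapse = ", "),
               class = "oatpnet_constant")
  }
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))   # syntactically safe
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(df), collapse = " + ")))
  df$.time <- outcome$time; df$.event <- outcome$event
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- setNames(as.numeric(coef(fit)), colnames(X))
  if (anyNA(beta)) {
    stop_named("non-identifiable covariates: %s",
               paste(colnames(X)[is.na(beta)], collapse = ", "),
               class = "oatpnet_constant")
  }
  eta <- as.numeric(X %*% beta)
  structure(list(coefficients = beta,
                 var = matrix(fit$var, ncol(X), ncol(X),
                              dimnames = list(colnames(X), colnames(X))),
                 loglik = fit$loglik[2], ties = ties,
                 baseline = breslow_baseline(outcome, eta),
                 converged = converged, X = X, outcome = outcome),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("cox_model (%s ties): %d covariates, %d subjects, %d events, loglik %.3f%s\n",
              x$ties, length(x$coefficients), length(x$outcome$time),
              sum(x$outcome$event), x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

## Breslow cumulative baseline hazard at distinct event times
breslow_baseline <- function(outcome, eta) {
  ord <- order(outcome$time)
  t_s <- outcome$time[ord]; d_s <- outcome$event[ord]
  e <- exp(eta[ord] - max(eta))
  revcs <- rev(cumsum(rev(e)))
  first <- !duplicated(t_s)
  S0 <- revcs[match(t_s, t_s)]          # risk-set sum at each subject's time
  ev_times <- unique(t_s[d_s == 1])
  h <- vapply(ev_times, function(t0) {
    sum(d_s[t_s == t0]) / (S0[which(t_s == t0)[1]] * exp(max(eta)))
  }, numeric(1))
  data.frame(time = ev_times, cumhaz = cumsum(h))
}

#' Per-subject model-based survival curves
#'
#' Evaluates \eqn{S_i(t) = \exp(-H_0(t)\, e^{\eta_i})} on the distinct
#' event-time grid, with the Breslow baseline stored in the model.
#'
#' @param model a \code{cox_model}.
#' @param newX optional covariate matrix (defaults to the training
#'   matrix).
#' @return A \code{surv_prediction}: \code{times}, \code{surv} (subjects x
#'   times, each row starting at values \eqn{\le 1} and nonincreasing) and
#'   a \code{source} tag.
#' @export
predict_survival <- function(model, newX = NULL) {
  X <- if (is.null(newX)) model$X else as.matrix(newX)
  eta <- as.numeric(X %*% model$coefficients)
  H0 <- model$baseline$cumhaz
  S <- exp(-outer(exp(eta), H0))
  surv_prediction(model$baseline$time, S, source = "cox-model")
}

#' Survival-prediction container
#'
#' @param times increasing evaluation grid (the distinct event times).
#' @param surv subjects x times matrix of survival probabilities.
#' @param source tag, e.g. \code{"null-KM"} or \code{"cox-model"}.
#' @return An object of class \code{surv_prediction}.
#' @export
surv_prediction <- function(times, surv, source = "cox-model") {
  surv <- as.matrix(surv)
  stopifnot(length(times) == ncol(surv), !is.unsorted(times),
            all(surv >= -1e-12 & surv <= 1 + 1e-12))
  structure(list(times = as.numeric(times), surv = surv, source = source),
            class = "surv_prediction")
}

## right-continuous step evaluation; S = 1 before the first grid time
eval_step <- function(times, values, t0) {
  j <- findInterval(t0, times)
  if (j == 0) 1 else values[j]
}

#' Group-level forest table from simple per-group Cox models
#'
#' Fits, for every group of the feature matrix, a Cox model containing
#' only that group's columns, and reports hazard ratios with 95 percent
#' Wald confidence intervals. Paired detection-limited genes (continuous
#' plus \code{"_2K"} indicator) report a joint Wald chi-square p-value on
#' 2 degrees of freedom (\eqn{\beta' \Sigma^{-1} \beta}) on both rows;
#' other columns report their 1-df Wald p. Groups whose fit fails are
#' reported with a failure note, not dropped.
#'
#' @param fm a \code{feature_matrix}.
#' @param outcome survival outcome.
#' @return Data frame of forest rows: \code{label}, \code{group},
#'   \code{HR}, \code{CI_low}, \code{CI_high}, \code{p_value}, \code{df},
#'   \code{model}, \code{note}.
#' @export
univariate_screen <- function(fm, outcome) {
  outcome <- as_outcome(outcome)
  rows <- list()
  for (k in seq_along(fm$group_names)) {
    idx <- group_columns(fm, k)
    labs <- colnames(fm$X)[idx]
    fit <- tryCatch(fit_cox(fm$X[, idx, drop = FALSE], outcome),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = labs, group = fm$group_names[k], HR = NA_real_,
        CI_low = NA_real_, CI_high = NA_real_, p_value = NA_real_,
        df = NA_integer_, model = "simple",
        note = conditionMessage(fit), stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      forest_block(fit$coefficients, fit$var, labs, fm$group_names[k],
                   paired = is_paired_group(fm, k), model = "simple")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

is_paired_group <- function(fm, k) {
  idx <- group_columns(fm, k)
  length(idx) == 2 && any(fm$provenance[idx] == "gene-indicator")
}

forest_block <- function(beta, V, labs, group, paired, model) {
  se <- sqrt(diag(V))
  hr <- exp(beta); lo <- exp(beta - 1.96 * se); hi <- exp(beta + 1.96 * se)
  if (paired) {
    W <- tryCatch(as.numeric(t(beta) %*% solve(V, beta)),
                  error = function(e) NA_real_)
    p <- pchisq(W, df = length(beta), lower.tail = FALSE)
    pv <- rep(p, length(beta)); df <- rep(length(beta), length(beta))
  } else {
    pv <- 2 * pnorm(-abs(beta / se)); df <- rep(1L, length(beta))
  }
  data.frame(label = labs, group = group, HR = unname(hr),
             CI_low = unname(lo), CI_high = unname(hi),
             p_value = unname(pv), df = as.integer(df), model = model,
             note = "", stringsAsFactors = FALSE)
}

#' Forest table of a fitted multivariable Cox model
#'
#' One row per coefficient of a joint fit; paired detection-limited genes
#' report the 2-df Wald p computed from the joint covariance block.
#'
#' @param model a \code{cox_model} fitted on (a subset of) the feature
#'   matrix columns.
#' @param fm the \code{feature_matrix} the columns came from (provides the
#'   group structure).
#' @return Forest-row data frame with \code{model = "multivariable"}.
#' @export
forest_multivariable <- function(model, fm) {
  labs <- names(model$coefficients)
  rows <- list()
  for (k in seq_along(fm$group_names)) {
    idx <- intersect(colnames(fm$X)[group_columns(fm, k)], labs)
    if (length(idx) == 0) next
    rows[[length(rows) + 1L]] <-
      forest_block(model$coefficients[idx],
                   model$var[idx, idx, drop = FALSE],
                   idx, fm$group_names[k],
                   paired = is_paired_group(fm, k), model = "multivariable")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
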