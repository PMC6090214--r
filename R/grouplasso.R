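## Grouped LASSO by proximal gradient (FISTA with backtracking) for the
## Breslow-tie Cox partial likelihood and for logistic / linear losses.
## Groups shrink jointly to exactly zero; groups with penalty multiplier 0
## (the clinical block, the GLM intercept) are never penalized.

#' Survival outcome container
#'
#' @param time nonnegative follow-up times (months).
#' @param event 0/1 event indicators (1 = death).
#' @return A list of class \code{surv_outcome}.
#' @export
surv_outcome <- function(time, event) {
  time <- as.numeric(time); event <- as.integer(event)
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0L, 1L)))
  structure(list(time = time, event = event), class = "surv_outcome")
}

as_outcome <- function(x) {
  if (inherits(x, "surv_outcome")) return(x)
  if (is.data.frame(x) && all(c("os_months", "os_event") %in% names(x))) {
    return(surv_outcome(x$os_months, x$os_event))
  }
  if (is.list(x) && all(c("time", "event") %in% names(x))) {
    return(surv_outcome(x$time, x$event))
  }
  stop_named("cannot interpret outcome", class = "oatpnet_bad_input")
}

## ---- losses: value and gradient in the linear predictor eta ------------

## (1/n) negative Breslow log partial likelihood
cox_breslow_loss <- function(time, event) {
  n <- length(time)
  ord <- order(time, -event)   # events before censorings at tied times
  t_s <- time[ord]; d_s <- event[ord]
  ## tie blocks share the risk-set sum S0(t)
  first_of_block <- !duplicated(t_s)
  block_id <- cumsum(first_of_block)
  block_first <- match(unique(block_id), block_id)
  block_last <- c(block_first[-1] - 1L, n)
  list(
    value = function(eta) {
      e <- eta[ord] - max(eta)
      revcs <- rev(cumsum(rev(exp(e))))
      S0 <- revcs[block_first][block_id]
      -(sum((e - log(S0))[d_s == 1])) / n
    },
    grad_eta = function(eta) {
      e <- eta[ord] - max(eta)
      ee <- exp(e)
      revcs <- rev(cumsum(rev(ee)))
      S0 <- revcs[block_first][block_id]
      inc <- d_s / S0
      cum <- cumsum(inc)
      H <- cum[block_last][block_id]   # sum over event times <= T_j (ties included)
      g <- numeric(n)
      g[ord] <- (-d_s + ee * H)
      g / n
    },
    ## unnormalized log partial likelihood (for cross-validation)
    logpl = function(eta) {
      e <- eta[ord] - max(eta)
      revcs <- rev(cumsum(rev(exp(e))))
      S0 <- revcs[block_first][block_id]
      sum((e - log(S0))[d_s == 1])
    }
  )
}

logistic_loss <- function(y) {
  n <- length(y)
  list(
    value = function(eta) sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) / n,
    grad_eta = function(eta) (plogis(eta) - y) / n
  )
}

linear_loss <- function(y) {
  n <- length(y)
  list(
    value = function(eta) sum((y - eta)^2) / (2 * n),
    grad_eta = function(eta) (eta - y) / n
  )
}

## ---- standardized problem ----------------------------------------------

## center/scale every column; penalized-group weights w_g = m_g * sqrt(p_g)
build_problem <- function(fm, lambda_weights = TRUE) {
  X <- fm$X
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(!is.finite(X))) stop_named("non-finite feature value", class = "oatpnet_bad_input")
  if (any(scl == 0)) {
    stop_named("constant feature column: %s",
               paste(colnames(X)[scl == 0], collapse = ", "),
               class = "oatpnet_constant")
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  sizes <- tabulate(fm$group, nbins = length(fm$group_names))
  w <- fm$multiplier * sqrt(sizes)
  list(Z = Z, center = ctr, scale = scl, group = fm$group, w = w,
       group_names = fm$group_names)
}

prox_group <- function(z, group, thr_per_group) {
  out <- z
  for (g in which(thr_per_group > 0)) {
    idx <- which(group == g)
    nz <- sqrt(sum(z[idx]^2))
    out[idx] <- if (nz <= thr_per_group[g]) 0 else (1 - thr_per_group[g] / nz) * z[idx]
  }
  out
}

penalty_value <- function(beta, group, w, lambda) {
  if (lambda == 0) return(0)
  s <- 0
  for (g in which(w > 0)) s <- s + w[g] * sqrt(sum(beta[group == g]^2))
  lambda * s
}

## FISTA with backtracking line search and restart; stops when the
## relative objective change is below tol AND the KKT residual of the
## current iterate is below kkt_tol (checked periodically)
grplasso_solve <- function(Z, loss, lambda, group, w, beta0 = NULL,
                           tol = 1e-9, max_iter = 20000L, kkt_tol = 1e-7) {
  p <- ncol(Z)
  beta <- beta0 %||% numeric(p)
  yv <- beta
  t_step <- 1
  theta <- 1
  fy <- loss$value(Z %*% yv)
  obj_old <- loss$value(Z %*% beta) + penalty_value(beta, group, w, lambda)
  kkt_ok <- function(b) {
    g <- as.numeric(crossprod(Z, loss$grad_eta(Z %*% b)))
    worst <- 0
    for (k in unique(group)) {
      idx <- which(group == k)
      wk <- if (length(w) == 1) w else w[k]
      r <- if (wk == 0) {
        sqrt(sum(g[idx]^2))
      } else if (all(b[idx] == 0)) {
        max(0, sqrt(sum(g[idx]^2)) - lambda * wk)
      } else {
        nb <- sqrt(sum(b[idx]^2))
        sqrt(sum((g[idx] + lambda * wk * b[idx] / nb)^2))
      }
      worst <- max(worst, r)
    }
    worst <= kkt_tol
  }
  for (it in seq_len(max_iter)) {
    gy <- as.numeric(crossprod(Z, loss$grad_eta(Z %*% yv)))
    repeat {
      cand <- prox_group(yv - t_step * gy, group, t_step * lambda * w)
      dlt <- cand - yv
      f_cand <- loss$value(Z %*% cand)
      if (f_cand <= fy + sum(gy * dlt) + sum(dlt^2) / (2 * t_step) + 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-14) break
    }
    obj_new <- f_cand + penalty_value(cand, group, w, lambda)
    if (obj_new > obj_old + 1e-12) {   # restart momentum
      yv <- beta; theta <- 1
      fy <- loss$value(Z %*% yv)
      next
    }
    theta_new <- (1 + sqrt(1 + 4 * theta^2)) / 2
    yv <- cand + ((theta - 1) / theta_new) * (cand - beta)
    theta <- theta_new
    beta <- cand
    fy <- loss$value(Z %*% yv)
    if (abs(obj_new - obj_old) < tol * max(1, abs(obj_old)) &&
        (it %% 25 == 0 || it < 5) && kkt_ok(beta)) break
    obj_old <- obj_new
  }
  beta
}

make_loss <- function(family, target) {
  switch(family,
         cox = { o <- as_outcome(target); cox_breslow_loss(o$time, o$event) },
         logistic = logistic_loss(target),
         linear = linear_loss(target))
}

## solve the unpenalized block alone, return full-length beta (zeros elsewhere)
unpenalized_start <- function(prob, loss, tol = 1e-10) {
  free <- which(prob$w[prob$group] == 0)
  beta <- numeric(ncol(prob$Z))
  if (length(free)) {
    beta[free] <- grplasso_solve(prob$Z[, free, drop = FALSE], loss, 0,
                                 group = rep(1L, length(free)), w = 0,
                                 tol = tol)
  }
  beta
}

#' Largest useful group-lasso penalty
#'
#' The smallest \code{lambda} at which every penalized group is exactly
#' zero: the maximum over penalized groups of the gradient norm of the
#' loss at the unpenalized-block-only solution, divided by the group's
#' penalty weight.
#'
#' @param fm a \code{feature_matrix}.
#' @param target outcome (\code{surv_outcome} or clinical data frame for
#'   \code{family = "cox"}; numeric/binary vector otherwise).
#' @param family \code{"cox"}, \code{"logistic"} or \code{"linear"}.
#' @return A positive number.
#' @export
lambda_max <- function(fm, target, family = "cox") {
  if (family == "cox") {
    prob <- build_problem(fm)
    loss <- make_loss("cox", target)
    beta <- unpenalized_start(prob, loss)
    Z <- prob$Z; group <- prob$group; w <- prob$w
  } else {
    gp <- glm_problem(fm, target, family)
    loss <- make_loss(family, gp$y)
    beta <- numeric(ncol(gp$Z))
    free <- which(gp$w[gp$group] == 0)
    beta[free] <- grplasso_solve(gp$Z[, free, drop = FALSE], loss, 0,
                                 group = rep(1L, length(free)), w = 0,
                                 tol = 1e-10)
    Z <- gp$Z; group <- gp$group; w <- gp$w
  }
  g <- as.numeric(crossprod(Z, loss$grad_eta(Z %*% beta)))
  lm <- 0
  for (k in which(w > 0)) {
    lm <- max(lm, sqrt(sum(g[group == k]^2)) / w[k])
  }
  lm
}

#' Grouped LASSO Cox regression at a fixed penalty
#'
#' Minimizes \deqn{(1/n)\, \ell_{Breslow}(\beta) +
#'   \lambda \sum_g m_g \sqrt{p_g}\, \|\beta_g\|_2}
#' over the columns of the feature matrix by proximal gradient descent
#' with backtracking, where \eqn{\ell_{Breslow}} is the negative Breslow
#' log partial likelihood, \eqn{m_g} the group's penalty multiplier and
#' \eqn{p_g} its size. Columns are standardized internally; coefficients
#' are reported on the original column scale. Within any group the
#' coefficients are jointly zero or jointly nonzero.
#'
#' @param fm a \code{feature_matrix}.
#' @param outcome a \code{surv_outcome} or clinical data frame with
#'   \code{os_months}/\code{os_event}.
#' @param lambda nonnegative penalty.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @param beta_init optional warm start on the standardized scale.
#' @return Named coefficient vector (original scale) with attribute
#'   \code{beta_std} (standardized scale, used by \code{\link{kkt_residuals}}).
#' @export
grouped_lasso_cox <- function(fm, outcome, lambda, tol = 1e-9,
                              max_iter = 20000L, beta_init = NULL) {
  outcome <- as_outcome(outcome)
  if (sum(outcome$event) == 0) stop_named("no events", class = "oatpnet_bad_input")
  prob <- build_problem(fm)
  loss <- make_loss("cox", outcome)
  beta0 <- beta_init %||% unpenalized_start(prob, loss)
  bstd <- grplasso_solve(prob$Z, loss, lambda, prob$group, prob$w,
                         beta0 = beta0, tol = tol, max_iter = max_iter)
  beta <- setNames(bstd / prob$scale, colnames(fm$X))
  attr(beta, "beta_std") <- bstd
  beta
}

#' Karush-Kuhn-Tucker residuals of a grouped-lasso solution
#'
#' For each zero group the excess of its loss-gradient norm over the
#' penalty bound \eqn{\lambda m_g \sqrt{p_g}}; for each active group the
#' norm of the stationarity residual
#' \eqn{\nabla_g f + \lambda m_g \sqrt{p_g}\, \beta_g / \|\beta_g\|}.
#' All computed on the internally standardized problem.
#'
#' @param fm a \code{feature_matrix}.
#' @param target outcome or response, per \code{family}.
#' @param beta coefficient vector as returned by the fitting functions.
#' @param lambda the penalty at which \code{beta} was obtained.
#' @param family loss family.
#' @return Named numeric vector of per-group residuals (unpenalized
#'   groups report their plain gradient norm).
#' @export
kkt_residuals <- function(fm, target, beta, lambda, family = "cox") {
  prob <- build_problem(fm)
  loss <- make_loss(family, target)
  bstd <- attr(beta, "beta_std") %||% (as.numeric(beta) * prob$scale)
  g <- as.numeric(crossprod(prob$Z, loss$grad_eta(prob$Z %*% bstd)))
  out <- numeric(length(prob$group_names))
  for (k in seq_along(out)) {
    idx <- which(prob$group == k)
    bg <- bstd[idx]
    if (prob$w[k] == 0) {
      out[k] <- sqrt(sum(g[idx]^2))
    } else if (all(bg == 0)) {
      out[k] <- max(0, sqrt(sum(g[idx]^2)) - lambda * prob$w[k])
    } else {
      r <- g[idx] + lambda * prob$w[k] * bg / sqrt(sum(bg^2))
      out[k] <- sqrt(sum(r^2))
    }
  }
  setNames(out, prob$group_names)
}

## stratified-by-event fold assignment
make_folds <- function(event, folds, seed) {
  set.seed(seed)
  f <- integer(length(event))
  for (lev in unique(event)) {
    idx <- sample(which(event == lev))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (any(event == 1) && any(tapply(event, f, sum) == 0)) {
    warning("a fold had zero events; refolding without stratification")
    f <- sample(rep_len(seq_len(folds), length(event)))
  }
  f
}

#' Cross-validated penalty selection for the grouped LASSO Cox model
#'
#' Fits the coefficient path over a log-spaced \code{lambda} grid from
#' \code{lambda_max} down and selects the penalty minimizing the
#' cross-validated partial-likelihood deviance (Verweij-van Houwelingen:
#' minus twice the full-data log partial likelihood at the leave-fold-out
#' estimate, minus the held-in log partial likelihood at the same
#' estimate, summed over folds). Folds are stratified by event status.
#'
#' @param fm a \code{feature_matrix}.
#' @param outcome survival outcome.
#' @param folds number of cross-validation folds (default 10).
#' @param nlambda grid size (default 50).
#' @param lambda_min_ratio smallest grid value as a fraction of
#'   \code{lambda_max} (default 0.01).
#' @param seed integer seed driving the fold assignment.
#' @param tol,max_iter solver controls.
#' @return An object of class \code{lasso_fit}: \code{lambda} (decreasing
#'   grid), \code{beta} (columns per lambda, original scale),
#'   \code{cvm}/\code{cvse} (mean and standard error of CV deviance),
#'   \code{lambda_star}, \code{selected} (penalized group names active at
#'   \code{lambda_star}), \code{seed}, \code{family}.
#' @export
select_lambda <- function(fm, outcome, folds = 10L, nlambda = 50L,
                          lambda_min_ratio = 0.01, seed = 1L,
                          tol = 1e-9, max_iter = 20000L) {
  outcome <- as_outcome(outcome)
  if (sum(outcome$event) < folds) {
    stop_named("need at least as many events as folds", class = "oatpnet_bad_input")
  }
  lmax <- lambda_max(fm, outcome, "cox")
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
  ## nudge the top of the grid above the boundary so the all-zero
  ## solution there is numerically exact
  lambda[1] <- lmax * (1 + 1e-6)
  fold_id <- make_folds(outcome$event, folds, seed)

  path <- fit_path(fm, outcome, "cox", lambda, tol, max_iter)

  full_loss <- cox_breslow_loss(outcome$time, outcome$event)
  cvdev <- matrix(NA_real_, folds, nlambda)
  for (k in seq_len(folds)) {
    inb <- fold_id != k
    fm_k <- feature_matrix(fm$X[inb, , drop = FALSE], fm$group, fm$group_names,
                           fm$multiplier, fm$provenance,
                           sample_id = fm$sample_id[inb])
    out_k <- surv_outcome(outcome$time[inb], outcome$event[inb])
    path_k <- fit_path(fm_k, out_k, "cox", lambda, tol, max_iter)
    loss_k <- cox_breslow_loss(out_k$time, out_k$event)
    for (j in seq_len(nlambda)) {
      ## original-scale coefficients; the partial likelihood is invariant
      ## to the centering shift, so raw X is a valid linear predictor
      eta_full <- as.numeric(fm$X %*% path_k$beta[, j])
      cvdev[k, j] <- -2 * (full_loss$logpl(eta_full) -
                             loss_k$logpl(eta_full[inb]))
    }
  }
  cvm <- colMeans(cvdev)
  cvse <- apply(cvdev, 2, sd) / sqrt(folds)
  j_star <- which.min(cvm)
  active <- active_groups(fm, path$beta[, j_star])
  structure(list(lambda = lambda, beta = path$beta, cvm = cvm, cvse = cvse,
                 cv_deviance = cvdev,
                 lambda_star = lambda[j_star], index_star = j_star,
                 selected = active, seed = seed, family = "cox",
                 group_names = fm$group_names),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso_fit (%s): %d lambdas, lambda* = %.4g, %d group(s) selected: %s\n",
              x$family, length(x$lambda), x$lambda_star, length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

## penalized groups with any nonzero coefficient
active_groups <- function(fm, beta) {
  act <- character(0)
  for (k in seq_along(fm$group_names)) {
    if (fm$multiplier[k] > 0 && any(beta[fm$group == k] != 0)) {
      act <- c(act, fm$group_names[k])
    }
  }
  act
}

## warm-started path fit over a decreasing lambda grid (standardized scale
## kept alongside original-scale coefficients)
fit_path <- function(fm, target, family, lambda, tol, max_iter) {
  if (family == "cox") {
    prob <- build_problem(fm)
    loss <- make_loss("cox", target)
    B <- matrix(0, ncol(fm$X), length(lambda),
                dimnames = list(colnames(fm$X), NULL))
    Bs <- B
    b <- unpenalized_start(prob, loss)
    for (j in seq_along(lambda)) {
      b <- grplasso_solve(prob$Z, loss, lambda[j], prob$group, prob$w,
                          beta0 = b, tol = tol, max_iter = max_iter)
      Bs[, j] <- b
      B[, j] <- b / prob$scale
    }
    list(beta = B, beta_std = Bs)
  } else {
    glm_path(fm, target, family, lambda, tol, max_iter)
  }
}

## ---- GLM (logistic / linear) path with unpenalized intercept -----------

glm_problem <- function(fm, target, family) {
  prob <- build_problem(fm)
  if (family == "logistic") {
    y <- as.numeric(target)
    if (length(unique(y)) < 2) {
      stop_named("binary target has a single class", class = "oatpnet_bad_input")
    }
    stopifnot(all(y %in% c(0, 1)))
  } else {
    y <- as.numeric(target)
  }
  ## intercept as an explicit unpenalized singleton group on a unit column
  Z <- cbind(`(Intercept)` = 1, prob$Z)
  group <- c(max(fm$group) + 1L, prob$group)
  w <- c(prob$w, 0)
  list(Z = Z, y = y, group = group, w = w, scale = prob$scale,
       center = prob$center, group_names = c(fm$group_names, "(Intercept)"))
}

glm_path <- function(fm, target, family, lambda, tol, max_iter) {
  gp <- glm_problem(fm, target, family)
  loss <- make_loss(family, gp$y)
  B <- matrix(0, ncol(fm$X), length(lambda),
              dimnames = list(colnames(fm$X), NULL))
  Bs <- B
  icpt <- numeric(length(lambda))
  free <- which(gp$w[gp$group] == 0)
  b <- numeric(ncol(gp$Z))
  b[free] <- grplasso_solve(gp$Z[, free, drop = FALSE], loss, 0,
                            group = rep(1L, length(free)), w = 0, tol = tol)
  for (j in seq_along(lambda)) {
    b <- grplasso_solve(gp$Z, loss, lambda[j], gp$group, gp$w,
                        beta0 = b, tol = tol, max_iter = max_iter)
    Bs[, j] <- b[-1]
    B[, j] <- b[-1] / gp$scale
    ## intercept on the original column scale
    icpt[j] <- b[1] - sum(gp$center * B[, j])
  }
  list(beta = B, beta_std = Bs, intercept = icpt)
}

#' Grouped LASSO logistic or linear regression with cross-validated penalty
#'
#' Same group penalty and cross-validation machinery as
#' \code{\link{select_lambda}}, with binomial deviance (logistic) or mean
#' squared error (linear) as the loss; the intercept is unpenalized.
#'
#' @param fm a \code{feature_matrix}.
#' @param target 0/1 vector (logistic) or numeric vector (linear).
#' @param family \code{"logistic"} or \code{"linear"}.
#' @param folds,nlambda,lambda_min_ratio,seed,tol,max_iter as in
#'   \code{\link{select_lambda}}.
#' @return A \code{lasso_fit} with an additional \code{intercept} element.
#' @export
grouped_lasso_glm <- function(fm, target, family = c("logistic", "linear"),
                              folds = 10L, nlambda = 50L,
                              lambda_min_ratio = 0.01, seed = 1L,
                              tol = 1e-9, max_iter = 20000L) {
  family <- match.arg(family)
  gp <- glm_problem(fm, target, family)   # validates the target
  y <- gp$y
  ## lambda_max from the intercept/unpenalized-only fit
  loss <- make_loss(family, y)
  free <- which(gp$w[gp$group] == 0)
  b0 <- numeric(ncol(gp$Z))
  b0[free] <- grplasso_solve(gp$Z[, free, drop = FALSE], loss, 0,
                             group = rep(1L, length(free)), w = 0, tol = 1e-10)
  g <- as.numeric(crossprod(gp$Z, loss$grad_eta(gp$Z %*% b0)))
  lmax <- 0
  for (k in which(gp$w > 0)) {
    lmax <- max(lmax, sqrt(sum(g[gp$group == k]^2)) / gp$w[k])
  }
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))
  lambda[1] <- lmax * (1 + 1e-6)

  path <- glm_path(fm, y, family, lambda, tol, max_iter)

  strat <- if (family == "logistic") y else rep(0, length(y))
  fold_id <- make_folds(strat, folds, seed)
  cvloss <- matrix(NA_real_, folds, nlambda)
  for (k in seq_len(folds)) {
    inb <- fold_id != k
    fm_k <- feature_matrix(fm$X[inb, , drop = FALSE], fm$group, fm$group_names,
                           fm$multiplier, fm$provenance,
                           sample_id = fm$sample_id[inb])
    path_k <- glm_path(fm_k, y[inb], family, lambda, tol, max_iter)
    Xout <- fm$X[!inb, , drop = FALSE]
    yout <- y[!inb]
    for (j in seq_len(nlambda)) {
      eta <- path_k$intercept[j] + as.numeric(Xout %*% path_k$beta[, j])
      cvloss[k, j] <- if (family == "logistic") {
        mean(2 * (log1p(exp(-abs(eta))) + pmax(eta, 0) - yout * eta))
      } else {
        mean((yout - eta)^2)
      }
    }
  }
  cvm <- colMeans(cvloss)
  cvse <- apply(cvloss, 2, sd) / sqrt(folds)
  j_star <- which.min(cvm)
  structure(list(lambda = lambda, beta = path$beta,
                 intercept = path$intercept, cvm = cvm, cvse = cvse,
                 lambda_star = lambda[j_star], index_star = j_star,
                 selected = active_groups(fm, path$beta[, j_star]),
                 seed = seed, family = family, group_names = fm$group_names),
            class = "lasso_fit")
}

#' Grouped LASSO GLM at a fixed penalty
#'
#' Single-penalty counterpart of \code{\link{grouped_lasso_glm}}.
#'
#' @inheritParams grouped_lasso_glm
#' @param lambda nonnegative penalty.
#' @return List with \code{intercept} and named \code{beta} (original
#'   scale; attribute \code{beta_std} carries the standardized solution).
#' @export
grouped_lasso_glm_fit <- function(fm, target, family = c("logistic", "linear"),
                                  lambda, tol = 1e-9, max_iter = 20000L) {
  family <- match.arg(family)
  path <- glm_path(fm, target, family, lambda[1], tol, max_iter)
  beta <- setNames(path$beta[, 1], colnames(fm$X))
  attr(beta, "beta_std") <- path$beta_std[, 1]
  list(intercept = path$intercept[1], beta = beta)
}
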