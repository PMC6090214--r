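#' Schemper-Henderson predictive inaccuracy
#'
#' Mean absolute error of predicted survival status, weighted over the
#' distinct event times. At each event time \eqn{t_j} with \eqn{d_j}
#' events the per-subject absolute prediction error is: \eqn{1 -
#' S_i(t_j)} for subjects known event-free at \eqn{t_j}; \eqn{S_i(t_j)}
#' for subjects with an event by \eqn{t_j}; and for subjects censored at
#' \eqn{c_i < t_j} the expectation over their unknown status,
#' \deqn{\frac{S_i(t_j)}{S_i(c_i)} (1 - S_i(t_j)) +
#'   \Big(1 - \frac{S_i(t_j)}{S_i(c_i)}\Big) S_i(t_j).}
#' The time average uses weights \eqn{w_j = d_j / \hat G(t_j^-)} with
#' \eqn{\hat G} the Kaplan-Meier estimator of the censoring distribution
#' (left-continuous; at tied times events precede censorings). Event
#' times where \eqn{\hat G(t_j^-) = 0} are dropped with a warning.
#'
#' @param outcome a \code{surv_outcome}.
#' @param predictions a \code{surv_prediction} whose rows match the
#'   outcome's subjects, evaluated on the distinct event-time grid.
#' @return The weighted mean inaccuracy \code{D} (scalar), with
#'   attributes \code{weights} and \code{event_times}.
#' @export
schemper_henderson_D <- function(outcome, predictions) {
  outcome <- as_outcome(outcome)
  time <- outcome$time; event <- outcome$event
  if (sum(event) == 0) stop_named("no events", class = "oatpnet_bad_input")
  ev <- sort(unique(time[event == 1]))
  d_j <- vapply(ev, function(t0) sum(time == t0 & event == 1), numeric(1))
  G_minus <- censoring_km_left(time, event, ev)
  keep <- G_minus > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d event time(s) with zero censoring-survival weight",
                    sum(!keep)))
  }
  S <- predictions$surv
  ptimes <- predictions$times
  stopifnot(nrow(S) == length(time))
  ## S_i at each subject's own (censoring) time
  S_own <- vapply(seq_along(time), function(i) {
    eval_step(ptimes, S[i, ], time[i])
  }, numeric(1))
  M <- numeric(length(ev))
  for (j in seq_along(ev)) {
    t0 <- ev[j]
    Sj <- vapply(seq_along(time), function(i) eval_step(ptimes, S[i, ], t0),
                 numeric(1))
    dead <- event == 1 & time <= t0
    free <- time >= t0 & !dead
    cens <- event == 0 & time < t0
    m <- numeric(length(time))
    m[free] <- 1 - Sj[free]
    m[dead] <- Sj[dead]
    if (any(cens)) {
      ratio <- ifelse(S_own[cens] > 0, Sj[cens] / S_own[cens], 0)
      ratio <- pmin(ratio, 1)
      m[cens] <- ratio * (1 - Sj[cens]) + (1 - ratio) * Sj[cens]
    }
    M[j] <- mean(m)
  }
  w <- (d_j / G_minus)[keep]
  D <- sum(w * M[keep]) / sum(w)
  attr(D, "weights") <- w
  attr(D, "event_times") <- ev[keep]
  D
}

## left-continuous reversed-role Kaplan-Meier of the censoring process,
## evaluated at each requested time: G(t-) = P(C >= t). Ties: events
## leave the censoring risk set before censorings at the same time occur.
censoring_km_left <- function(time, event, at) {
  ut <- sort(unique(time))
  n <- length(time)
  G <- numeric(length(ut)); g <- 1
  for (k in seq_along(ut)) {
    t0 <- ut[k]
    at_risk <- sum(time >= t0) - sum(time == t0 & event == 1)
    c_k <- sum(time == t0 & event == 0)
    if (at_risk > 0) g <- g * (1 - c_k / at_risk) else g <- 0
    G[k] <- g
  }
  vapply(at, function(t0) {
    j <- findInterval(t0 - 1e-12, ut)   # strictly earlier censor times
    if (j == 0) 1 else G[j]
  }, numeric(1))
}

#' Null (Kaplan-Meier) survival prediction
#'
#' The overall Kaplan-Meier curve of the outcome applied to every
#' subject, evaluated at the distinct event times.
#'
#' @param outcome a \code{surv_outcome}.
#' @return A \code{surv_prediction} with \code{source = "null-KM"}.
#' @export
km_prediction <- function(outcome) {
  outcome <- as_outcome(outcome)
  sf <- survival::survfit(survival::Surv(outcome$time, outcome$event) ~ 1)
  ev <- sort(unique(outcome$time[outcome$event == 1]))
  s <- vapply(ev, function(t0) {
    j <- findInterval(t0, sf$time)
    if (j == 0) 1 else sf$surv[j]
  }, numeric(1))
  surv_prediction(ev, matrix(s, nrow = length(outcome$time),
                             ncol = length(ev), byrow = TRUE),
                  source = "null-KM")
}

#' Explained variation of a survival model
#'
#' Percentage of explained variation (PEV): the relative reduction in
#' Schemper-Henderson predictive inaccuracy when moving from the null
#' (overall Kaplan-Meier) prediction, \eqn{D_0}, to the covariate-model
#' prediction \eqn{D_x}: \eqn{V = (D_0 - D_x) / D_0}.
#'
#' @param model a \code{cox_model}, or \code{NULL} for the null model
#'   (then \eqn{V = 0} exactly).
#' @param outcome survival outcome the model was fitted on.
#' @return An object of class \code{pev_result}: \code{D0}, \code{Dx},
#'   \code{V}.
#' @export
compute_pev <- function(model, outcome) {
  outcome <- as_outcome(outcome)
  null_pred <- km_prediction(outcome)
  D0 <- as.numeric(schemper_henderson_D(outcome, null_pred))
  Dx <- if (is.null(model)) D0 else {
    as.numeric(schemper_henderson_D(outcome, predict_survival(model)))
  }
  structure(list(D0 = D0, Dx = Dx, V = (D0 - Dx) / D0),
            class = "pev_result")
}

#' @export
print.pev_result <- function(x, ...) {
  cat(sprintf("pev_result: D0 = %.4f, Dx = %.4f, PEV = %.2f%%\n",
              x$D0, x$Dx, 100 * x$V))
  invisible(x)
}
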