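#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile median cor sd prcomp qnorm pnorm pchisq pwilcox
#'   rnorm runif rbinom p.adjust coef setNames complete.cases var uniroot
#'   predict plogis
#' @importFrom utils head read.delim write.table
NULL

stop_named <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "oatpnet_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## standardize a column to mean 0, sd 1 (sd with denominator n-1)
standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop_named("cannot standardize a constant column", class = "oatpnet_constant")
  }
  (x - mean(x)) / s
}

## derive a reproducible sub-seed (< 2^31) from a master seed and a label,
## so adding draws in one component does not perturb another
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}
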