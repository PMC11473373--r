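#' @importFrom stats qnorm pnorm optimize setNames
NULL

.check_effects <- function(effects, min_k = 1) {
  stopifnot(is.data.frame(effects),
            all(c("z", "v") %in% names(effects)))
  if (nrow(effects) < min_k)
    stop("need at least ", min_k, " effect(s), got ", nrow(effects))
  if (any(effects$v <= 0)) stop("all sampling variances must be positive")
  invisible(effects)
}

#' Fixed-effect (inverse-variance) pooling on the Fisher-z scale
#'
#' The common-effect estimate z_bar = sum(w*z)/sum(w) with w = 1/v, and its
#' variance 1/sum(w). Used internally by the Q statistic and by the
#' DerSimonian-Laird moment estimator of the between-study variance.
#'
#' @param effects an `effect_table` (see [effects_from_table()]).
#' @return list with elements `z` (pooled z) and `var`.
#' @export
pool_fixed <- function(effects) {
  .check_effects(effects, 1)
  w <- 1 / effects$v
  list(z = sum(w * effects$z) / sum(w), var = 1 / sum(w))
}

#' Heterogeneity statistics Q, I-squared, and tau-squared
#'
#' Cochran's Q = sum(w * (z - z_bar_FE)^2) with fixed-effect weights
#' w = 1/v, its degrees of freedom k - 1, the I-squared percentage
#' max(0, (Q - df)/Q) * 100, and the DerSimonian-Laird moment estimate of
#' the between-study variance tau^2 = max(0, (Q - df) / (sum(w) -
#' sum(w^2)/sum(w))).
#'
#' @inheritParams pool_fixed
#' @return list with `Q`, `df`, `I2` (percent), `tau2`.
#' @export
heterogeneity <- function(effects) {
  .check_effects(effects, 2)
  w <- 1 / effects$v
  zbar <- sum(w * effects$z) / sum(w)
  Q <- sum(w * (effects$z - zbar)^2)
  df <- nrow(effects) - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  list(Q = Q, df = df, I2 = I2, tau2 = tau2)
}

# restricted maximum-likelihood estimate of tau^2 (profile over the interval
# [0, upper]); alternative to the DL moment estimator
.tau2_reml <- function(effects) {
  z <- effects$z; v <- effects$v
  if (length(z) < 2) return(0)
  nll <- function(t2) {
    w <- 1 / (v + t2)
    zbar <- sum(w * z) / sum(w)
    0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (z - zbar)^2))
  }
  upper <- max(stats::var(z) * 4, max(v) * 10, 0.1)
  opt <- optimize(nll, c(0, upper), tol = 1e-10)
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

#' Random-effects pooling of Fisher-z effects
#'
#' Pools correlations on the Fisher-z scale under a random-effects model:
#' weights w* = 1/(v + tau^2), pooled z* = sum(w* z)/sum(w*), standard
#' error 1/sqrt(sum(w*)). The Wald statistic is z*/se*, the two-sided p
#' comes from the standard normal, and the 95% (or 1-alpha) confidence
#' interval is built on the z scale and back-transformed to r together with
#' the point estimate. With a single study the pooled result is that study.
#'
#' @inheritParams pool_fixed
#' @param alpha two-sided significance level (default 0.05 for 95% CIs).
#' @param tau2_estimator `"dl"` (DerSimonian-Laird moment estimator, the
#'   default) or `"reml"`.
#' @return object of class `pooled_effect`: a list with `k`, `r` (pooled
#'   correlation), `ci_lb`, `ci_ub`, `z_stat`, `p`, `Q`, `df`, `I2`, `tau2`,
#'   plus the z-scale internals `z_pooled` and `se_z`.
#' @export
pool_random <- function(effects, alpha = 0.05,
                        tau2_estimator = c("dl", "reml")) {
  .check_effects(effects, 1)
  stopifnot(alpha > 0, alpha < 1)
  tau2_estimator <- match.arg(tau2_estimator)
  k <- nrow(effects)
  if (k == 1) {
    het <- list(Q = 0, df = 0L, I2 = 0, tau2 = 0)
  } else {
    het <- heterogeneity(effects)
    if (tau2_estimator == "reml") het$tau2 <- .tau2_reml(effects)
  }
  w <- 1 / (effects$v + het$tau2)
  z_pooled <- sum(w * effects$z) / sum(w)
  se_z <- 1 / sqrt(sum(w))
  crit <- qnorm(1 - alpha / 2)
  z_stat <- z_pooled / se_z
  structure(list(
    k = k,
    r = tanh(z_pooled),
    ci_lb = tanh(z_pooled - crit * se_z),
    ci_ub = tanh(z_pooled + crit * se_z),
    z_stat = z_stat,
    p = 2 * pnorm(-abs(z_stat)),
    Q = het$Q, df = het$df, I2 = het$I2, tau2 = het$tau2,
    z_pooled = z_pooled, se_z = se_z,
    alpha = alpha, tau2_estimator = tau2_estimator
  ), class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("Random-effects pooled correlation (k = %d, tau2 = %.4f [%s])\n",
              x$k, x$tau2, x$tau2_estimator))
  cat(sprintf("  r = %.3f, %d%% CI [%.3f, %.3f], z = %.3f, p = %.3g\n",
              x$r, round(100 * (1 - x$alpha)), x$ci_lb, x$ci_ub, x$z_stat, x$p))
  cat(sprintf("  Q = %.3f (df = %d, p = %.3g), I2 = %.2f%%\n",
              x$Q, x$df, stats::pchisq(x$Q, x$df, lower.tail = FALSE), x$I2))
  invisible(x)
}
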