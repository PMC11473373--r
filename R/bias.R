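#' Rosenthal fail-safe N
#'
#' Estimates how many unpublished null-result studies would be needed to
#' bring the combined significance of the effect set down to alpha. Uses
#' the Stouffer sum of per-study standard-normal deviates u = z/se =
#' z*sqrt(n-3): N_fs = ceiling((sum u)^2 / z_crit^2 - k), clipped at zero,
#' with the two-sided critical value z_crit = qnorm(1 - alpha/2) (1.959964
#' at alpha = 0.05). The conventional "robustness" reference threshold is
#' 5k + 10.
#'
#' @inheritParams pool_fixed
#' @param alpha two-sided significance level for the criterion.
#' @return object of class `fail_safe`: list with `n_fs`, `sum_z` (the
#'   Stouffer sum), `k`, `alpha`, and `threshold` (= 5k + 10).
#' @export
fail_safe_n <- function(effects, alpha = 0.05) {
  .check_effects(effects, 1)
  k <- nrow(effects)
  u <- effects$z / effects$se
  crit <- qnorm(1 - alpha / 2)
  raw <- sum(u)^2 / crit^2 - k
  structure(list(n_fs = max(0L, as.integer(ceiling(raw))),
                 sum_z = sum(u), k = k, alpha = alpha,
                 threshold = 5L * k + 10L),
            class = "fail_safe")
}

#' @export
print.fail_safe <- function(x, ...) {
  cat(sprintf("Fail-safe N = %d (k = %d, threshold 5k+10 = %d, alpha = %g)\n",
              x$n_fs, x$k, x$threshold, x$alpha))
  invisible(x)
}

#' Funnel-plot data export
#'
#' Returns the per-study points (Fisher-z effect vs standard error) and the
#' pseudo-confidence guide lines pooled +/- z_crit * se over the observed se
#' range, ready for plotting by any front end; no plotting is performed.
#'
#' @inheritParams pool_fixed
#' @param pooled a `pooled_effect` for the same set (see [pool_random()]).
#' @param alpha level for the guide lines.
#' @param n_grid number of se values in the guide-line grid.
#' @return list with data frames `points` (`study_id`, `z`, `se`) and
#'   `guides` (`se`, `lower`, `upper`, centred on the pooled z).
#' @export
funnel_data <- function(effects, pooled, alpha = 0.05, n_grid = 50) {
  .check_effects(effects, 1)
  stopifnot(inherits(pooled, "pooled_effect"))
  se_grid <- seq(0, max(effects$se), length.out = n_grid)
  crit <- qnorm(1 - alpha / 2)
  list(points = data.frame(study_id = effects$study_id,
                           z = effects$z, se = effects$se),
       guides = data.frame(se = se_grid,
                           lower = pooled$z_pooled - crit * se_grid,
                           upper = pooled$z_pooled + crit * se_grid))
}

#' Duval-Tweedie trim-and-fill correction for funnel asymmetry
#'
#' Iterative rank-based estimate of the number of studies suppressed on one
#' side of the funnel, using the L0 estimator: centre effects on the pooled
#' estimate of the currently trimmed set (pooled under the same
#' random-effects model as the main analysis), rank absolute deviations,
#' estimate the number of missing studies k0 from the signed-rank sum, trim
#' the k0 most extreme studies on the over-represented side, re-pool, and
#' iterate until k0 stabilizes. The trimmed studies are then mirrored about the final
#' centre and the full (observed + imputed) set is re-pooled under the
#' random-effects model, with tau^2 re-estimated on the filled set.
#'
#' @inheritParams pool_random
#' @param side which side of the funnel the suppressed studies are assumed
#'   to lie on; `"auto"` (default) assumes suppression on the side toward
#'   the null, i.e. missing studies mirror the observed excess toward zero.
#' @param maxiter maximum trimming iterations.
#' @return object of class `trim_fill`: list with `k0`, `side`, `imputed`
#'   (an `effect_table` of mirrored studies, empty when `k0 = 0`),
#'   `adjusted` (a `pooled_effect` on the filled set; equal to the
#'   unadjusted pooling when `k0 = 0`), and `iterations`.
#' @export
trim_and_fill <- function(effects, side = c("auto", "left", "right"),
                          alpha = 0.05, tau2_estimator = c("dl", "reml"),
                          maxiter = 50) {
  side <- match.arg(side)
  tau2_estimator <- match.arg(tau2_estimator)
  .check_effects(effects, 1)
  k <- nrow(effects)
  unadjusted <- pool_random(effects, alpha = alpha,
                            tau2_estimator = tau2_estimator)
  empty <- effects[0, , drop = FALSE]
  if (k < 3) {
    warning("trim-and-fill needs at least 3 studies; returning k0 = 0")
    return(structure(list(k0 = 0L, side = side, imputed = empty,
                          adjusted = unadjusted, iterations = 0L),
                     class = "trim_fill"))
  }
  if (side == "auto")
    side <- if (pool_fixed(effects)$z < 0) "right" else "left"
  # work on a flipped scale where missing studies sit on the LEFT, so the
  # observed excess (to be trimmed) is always the largest values
  flip <- if (side == "right") -1 else 1
  y <- flip * effects$z
  v <- effects$v
  ord <- order(y)
  y <- y[ord]; v <- v[ord]
  idx <- seq_len(k)[ord]
  center <- function(keep)
    pool_random(.new_effect_table(sprintf("s%d", keep), y[keep], v[keep],
                                  effects$n[idx[keep]]),
                alpha = alpha, tau2_estimator = tau2_estimator)$z_pooled
  k0 <- 0L; iter <- 0L
  repeat {
    iter <- iter + 1L
    keep <- if (k0 > 0) seq_len(k - k0) else seq_len(k)
    b <- center(keep)
    d <- y - b
    rk <- rank(abs(d), ties.method = "first")
    Tn <- sum(rk[d > 0])
    L0 <- (4 * Tn - k * (k + 1)) / (2 * k - 1)
    k0_new <- max(0L, min(k - 1L, as.integer(round(L0))))
    if (k0_new == k0 || iter >= maxiter) { k0 <- k0_new; break }
    k0 <- k0_new
  }
  if (k0 == 0L)
    return(structure(list(k0 = 0L, side = side, imputed = empty,
                          adjusted = unadjusted, iterations = iter),
                     class = "trim_fill"))
  keep <- seq_len(k - k0)
  b <- center(keep)
  trim_pos <- (k - k0 + 1):k
  imputed <- .new_effect_table(
    study_id = sprintf("fill_%02d", seq_len(k0)),
    z = flip * (2 * b - y[trim_pos]),
    v = v[trim_pos],
    n = effects$n[idx[trim_pos]])
  filled <- rbind(as.data.frame(effects), as.data.frame(imputed))
  class(filled) <- class(effects)
  adjusted <- pool_random(filled, alpha = alpha,
                          tau2_estimator = tau2_estimator)
  structure(list(k0 = k0, side = side, imputed = imputed,
                 adjusted = adjusted, iterations = iter),
            class = "trim_fill")
}

#' @export
print.trim_fill <- function(x, ...) {
  cat(sprintf("Trim-and-fill: k0 = %d imputed on the %s side (%d iteration(s))\n",
              x$k0, x$side, x$iterations))
  cat("Adjusted pooled effect:\n")
  print(x$adjusted)
  invisible(x)
}
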