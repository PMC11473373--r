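#' Fisher z transformation
#'
#' Variance-stabilizing transform for a Pearson correlation,
#' z = 0.5 * log((1 + r) / (1 - r)); strictly increasing and odd.
#' All pooling in this package happens on the z scale; the r scale is
#' presentation-only.
#'
#' @param r numeric vector of correlations, each strictly inside (-1, 1).
#' @return numeric vector of Fisher-z effects.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z is defined only for |r| < 1")
  atanh(r)
}

#' Inverse Fisher z transformation
#'
#' Back-transform r = (exp(2z) - 1) / (exp(2z) + 1) = tanh(z); numerically
#' safe for large |z|.
#'
#' @param z numeric vector of Fisher-z values.
#' @return numeric vector of correlations in (-1, 1).
#' @export
inverse_fisher_z <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  tanh(z)
}

.relationships <- c("pa_re", "pa_mh", "re_mh")
.rel_column <- c(pa_re = "r_pa_re", pa_mh = "r_pa_mh", re_mh = "r_re_mh")

.new_effect_table <- function(study_id, z, v, n) {
  structure(data.frame(study_id = as.character(study_id),
                       z = z, v = v, se = sqrt(v), n = as.integer(n),
                       stringsAsFactors = FALSE),
            class = c("effect_table", "data.frame"))
}

#' Construct an effect table from Fisher-z effects
#'
#' Direct constructor for pre-transformed effects, the container all pooling
#' and bias diagnostics operate on. Usually produced by
#' [effects_from_table()]; this entry point admits effects whose variance
#' does not come from a correlation (e.g. toy sets with chosen variances).
#'
#' @param study_id character labels.
#' @param z Fisher-z effects.
#' @param v sampling variances; defaults to `1/(n - 3)` when `n` is given.
#' @param n per-study sample sizes; defaults to `round(1/v) + 3`.
#' @return an `effect_table` data frame with columns
#'   `study_id, z, v, se, n`.
#' @export
effect_table <- function(study_id, z, v = NULL, n = NULL) {
  if (is.null(v) && is.null(n)) stop("supply v or n")
  if (is.null(v)) v <- 1 / (n - 3)
  if (is.null(n)) n <- as.integer(round(1 / v) + 3)
  stopifnot(length(z) == length(study_id), length(v) == length(z),
            all(v > 0), all(is.finite(z)))
  .new_effect_table(study_id, z, v, n)
}

#' Convert one study record to a Fisher-z effect
#'
#' Selects one of the three coded correlations and transforms it to the
#' z scale with sampling variance v = 1/(n - 3) and standard error sqrt(v).
#'
#' @param record one-row slice of a [coding_table()] (or any data frame with
#'   the coding-table columns).
#' @param which relationship: `"pa_re"` (activity-resilience), `"pa_mh"`
#'   (activity-mental health), or `"re_mh"` (resilience-mental health).
#' @return one-row `effect_table` with columns `study_id, z, v, se, n`.
#' @export
to_effect <- function(record, which) {
  which <- match.arg(which, .relationships)
  stopifnot(is.data.frame(record), nrow(record) == 1)
  if (record$n < 4) stop("n must be >= 4 for a finite Fisher-z variance")
  .new_effect_table(record$study_id,
                    fisher_z(record[[.rel_column[[which]]]]),
                    1 / (record$n - 3), record$n)
}

#' Extract one relationship's effects from a whole coding table
#'
#' Vectorized version of [to_effect()]: one Fisher-z effect per row of the
#' table, in the original row order.
#'
#' @inheritParams to_effect
#' @param table a [coding_table()].
#' @return `effect_table` with one row per study.
#' @export
effects_from_table <- function(table, which) {
  which <- match.arg(which, .relationships)
  stopifnot(inherits(table, "coding_table"))
  if (nrow(table) == 0)
    return(.new_effect_table(character(0), numeric(0), numeric(0), integer(0)))
  if (any(table$n < 4)) stop("all n must be >= 4")
  .new_effect_table(table$study_id,
                    fisher_z(table[[.rel_column[[which]]]]),
                    1 / (table$n - 3), table$n)
}
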