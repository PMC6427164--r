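#' Paired t-test on two index-paired samples
#'
#' Tests whether the mean of the within-pair differences `a - b` is zero.
#' The statistic is `t = mean(d) / (sd(d) / sqrt(n))` with the sample
#' standard deviation (n - 1 denominator) and `n - 1` degrees of freedom;
#' the p-value is the two-tailed tail probability of Student's t. Pairing
#' is by index: element `i` of `a` is compared with element `i` of `b`.
#'
#' Degenerate variance is handled explicitly: if every difference is zero
#' the samples are indistinguishable (`t = 0`, `p = 1`); if the differences
#' are identical but nonzero the statistic is unbounded (`t = +/-Inf`,
#' `p = 0`) and a warning flags the degenerate variance.
#'
#' @param a,b numeric vectors of equal length (>= 2 pairs).
#' @return An object of class `paired_t_test`: list with `n_pairs`,
#'   `mean_diff`, `sd_diff`, `t_stat`, `df`, `p_two_tailed`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(0, 0, 0))  # t = 3.46, df = 2
#' @export
paired_t_test <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    stop("`a` and `b` must be numeric vectors of equal length",
         call. = FALSE)
  }
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values in the pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      t_stat <- 0
      p <- 1
    } else {
      warning("degenerate variance: all pair differences identical and ",
              "nonzero; p-value is 0 by convention", call. = FALSE)
      t_stat <- sign(md) * Inf
      p <- 0
    }
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  }
  structure(list(n_pairs = n, mean_diff = md, sd_diff = sdd,
                 t_stat = t_stat, df = n - 1L, p_two_tailed = p),
            class = "paired_t_test")
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: t = %.4f, df = %d, two-tailed p = %.4g (mean diff %.4f)\n",
    x$t_stat, x$df, x$p_two_tailed, x$mean_diff))
  invisible(x)
}

#' Percent difference relative to a reference mean
#'
#' `100 * (mean_reference - mean_other) / mean_reference`: how much slower
#' (positive) or faster (negative) the other group is, as a percentage of
#' the reference group. Report displays round it to 1 decimal.
#'
#' @param mean_reference reference (e.g. control) mean; must be nonzero.
#' @param mean_other other (e.g. treated) mean.
#' @return The percent difference at full precision.
#' @examples
#' percent_difference(10, 5)  # 50
#' @export
percent_difference <- function(mean_reference, mean_other) {
  stopifnot_scalar_num(mean_reference, "mean_reference")
  stopifnot_scalar_num(mean_other, "mean_other")
  if (mean_reference == 0) {
    stop("`mean_reference` must be nonzero", call. = FALSE)
  }
  100 * (mean_reference - mean_other) / mean_reference
}

#' Full group-comparison report for clip velocities
#'
#' Combines the group summary, the percent difference of the treated mean
#' relative to control, and the paired two-tailed t-test at level `alpha`.
#' Pairing follows the input order; when the groups arrive as the
#' rank-sorted columns of a velocity summary table, index pairing is rank
#' pairing.
#'
#' @param control,treated numeric vectors of per-clip velocities.
#' @param alpha significance level for the `significant` flag.
#' @return list with `control_mean`, `treated_mean`,
#'   `percent_slower` (1-decimal display value in `percent_slower_display`),
#'   `t_test` (a [paired_t_test()] result), `alpha` and `significant`.
#' @export
velocity_group_report <- function(control, treated, alpha = 0.05) {
  tt <- paired_t_test(control, treated)
  cm <- mean(control)
  tm <- mean(treated)
  pd <- percent_difference(cm, tm)
  list(control_mean = cm,
       treated_mean = tm,
       percent_slower = pd,
       percent_slower_display = round(pd, 1),
       t_test = tt,
       alpha = alpha,
       significant = tt$p_two_tailed < alpha)
}
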