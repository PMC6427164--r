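## Embryo cohort endpoints: hatchability, days to hatch, abnormality rate,
## and stage-trajectory comparison between exposure groups.

# Collapse a long daily-observation table to one row per embryo.
per_embryo <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("dish", "embryo") %in% names(records)))
  key <- interaction(records$dish, records$embryo, drop = TRUE)
  first <- !duplicated(key)
  records[first, intersect(c("dish", "embryo", "abnormal", "hatch_day"),
                           names(records))]
}

#' Summarize hatching outcomes for one dish
#'
#' Computes the hatch endpoints of a dish of embryos: embryos whose hatch
#' day is missing or falls after the abandonment cutoff (embryos still
#' unhatched after 20 days are abandoned) count as unhatched. Hatchability
#' is reported as a percentage rounded to 1 decimal; mean days to hatch is
#' averaged over the hatched embryos only.
#'
#' @param records long daily-observation data.frame (layout of
#'   [simulate_embryo_cohort()]) restricted to a single dish.
#' @param abandon_after_days abandonment cutoff in days.
#' @return One-row data.frame with columns `dish`, `n_total`, `n_hatched`,
#'   `hatchability_pct`, `mean_days_to_hatch` (`NA` when nothing hatched).
#' @examples
#' rec <- data.frame(dish = 1, embryo = 1:15, day = 0, stage = 40,
#'                   abnormal = FALSE,
#'                   hatch_day = c(rep(15, 13), NA, NA))
#' summarize_dish(rec)  # 13 of 15 hatched: 86.7%
#' @export
summarize_dish <- function(records, abandon_after_days = 20) {
  stopifnot_scalar_num(abandon_after_days, "abandon_after_days", lower = 1)
  if (nrow(records) == 0L) stop("empty dish", call. = FALSE)
  if (length(unique(records$dish)) != 1L) {
    stop("records span multiple dishes; use summarize_cohort()",
         call. = FALSE)
  }
  e <- per_embryo(records)
  hatched <- !is.na(e$hatch_day) & e$hatch_day <= abandon_after_days
  n_total <- nrow(e)
  n_hatched <- sum(hatched)
  data.frame(dish = e$dish[1],
             n_total = n_total,
             n_hatched = n_hatched,
             hatchability_pct = round(100 * n_hatched / n_total, 1),
             mean_days_to_hatch = if (n_hatched > 0) {
               mean(e$hatch_day[hatched])
             } else {
               NA_real_
             })
}

#' Summarize hatching outcomes for every dish of a cohort
#'
#' @inheritParams summarize_dish
#' @param records long daily-observation data.frame covering one or more
#'   dishes.
#' @return data.frame with one [summarize_dish()] row per dish, ordered by
#'   dish id.
#' @export
summarize_cohort <- function(records, abandon_after_days = 20) {
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  dishes <- sort(unique(records$dish))
  do.call(rbind, lapply(dishes, function(d) {
    summarize_dish(records[records$dish == d, , drop = FALSE],
                   abandon_after_days = abandon_after_days)
  }))
}

#' Morphological abnormality rate of a cohort
#'
#' Percentage of embryos flagged abnormal among all embryos observed,
#' rounded to 1 decimal (2 abnormal embryos among 5 dishes of 15 give
#' 2.7%).
#'
#' @param records long daily-observation data.frame with an `abnormal`
#'   column.
#' @return Abnormality rate in percent.
#' @export
abnormality_rate <- function(records) {
  if (nrow(records) == 0L) stop("no embryo records", call. = FALSE)
  e <- per_embryo(records)
  round(100 * sum(e$abnormal) / nrow(e), 1)
}

#' Daily mean developmental stage of a cohort
#'
#' @param records long daily-observation data.frame.
#' @return Named numeric vector of mean stage per day (names are days).
#' @export
daily_mean_stage <- function(records) {
  stopifnot(all(c("day", "stage") %in% names(records)))
  agg <- tapply(records$stage, records$day, mean)
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out
}

#' Compare the stage trajectories of two exposure groups
#'
#' Pairs the two groups' daily mean stages day by day and applies the
#' two-tailed [paired_t_test()]. Inputs are either daily mean-stage vectors
#' on the same day grid (names must match when present) or long
#' daily-observation tables, which are first collapsed with
#' [daily_mean_stage()]. Note the degenerate-variance branch of the t-test
#' triggers when the two curves differ by an exact constant.
#'
#' @param group_a,group_b daily mean-stage vectors or record tables.
#' @return A [paired_t_test()] result.
#' @export
compare_stage_curves <- function(group_a, group_b) {
  if (is.data.frame(group_a)) group_a <- daily_mean_stage(group_a)
  if (is.data.frame(group_b)) group_b <- daily_mean_stage(group_b)
  if (length(group_a) != length(group_b)) {
    stop("the two groups are not on the same day grid", call. = FALSE)
  }
  if (!is.null(names(group_a)) && !is.null(names(group_b)) &&
      !identical(names(group_a), names(group_b))) {
    stop("the two groups are not on the same day grid", call. = FALSE)
  }
  paired_t_test(as.numeric(group_a), as.numeric(group_b))
}

#' Check a hatch summary table for internal consistency
#'
#' Recomputes each dish's hatchability from its counts and flags rows whose
#' printed percentage disagrees; historical summary tables occasionally
#' carry such transcription inconsistencies, and they should be surfaced,
#' not silently repaired.
#'
#' @param table data.frame with columns `n_total`, `n_hatched` and
#'   `hatchability_pct` (the printed value).
#' @return The table with logical column `consistent` appended; a warning
#'   lists inconsistent dishes, if any.
#' @export
check_hatch_table <- function(table) {
  stopifnot(all(c("n_total", "n_hatched", "hatchability_pct") %in%
                  names(table)))
  expect <- round(100 * table$n_hatched / table$n_total, 1)
  table$consistent <- abs(expect - table$hatchability_pct) < 0.05
  if (any(!table$consistent)) {
    bad <- if ("dish" %in% names(table)) {
      paste(table$dish[!table$consistent], collapse = ", ")
    } else {
      paste(which(!table$consistent), collapse = ", ")
    }
    warning("hatch table internally inconsistent for dish(es): ", bad,
            call. = FALSE)
  }
  table
}
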