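#' Medaka staging ladder used by the embryo simulator
#'
#' The integer developmental stages scored in daily observation of medaka
#' embryos, from stage 14 (pre-mid-gastrula, the stage at which embryos
#' enter the assay) to stage 40 (first fry, i.e. hatching).
#'
#' @format Integer vector of the twelve scored stages.
#' @export
medaka_stage_ladder <- c(14L, 18L, 22L, 23L, 28L, 29L, 30L, 33L, 35L, 37L,
                         39L, 40L)

#' Default day-to-stage schedule for normally developing embryos
#'
#' Expected stage on each observation day for embryos cultured at standard
#' temperature: day 0 at stage 14 through day 15 at stage 40. Days between
#' listed observation points hold the most recent listed stage.
#'
#' @format Named integer vector; names are days post-assay-start.
#' @export
medaka_stage_schedule <- c(
  "0" = 14L, "1" = 18L, "2" = 22L, "3" = 23L, "5" = 28L, "6" = 29L,
  "7" = 30L, "8" = 33L, "9" = 35L, "10" = 37L, "13" = 39L, "15" = 40L)

#' Configuration for the synthetic embryo cohort generator
#'
#' Parameters of the simulated daily-observation records: cohort layout
#' (dishes of embryos), the expected stage trajectory, observation noise,
#' and per-embryo abnormality and hatch-failure probabilities. Defaults
#' mirror the assay design this package supports: dishes of 15 embryos
#' followed daily from the pre-mid-gastrula stage (14) until hatch at stage
#' 40, with hatching at around 15 days.
#'
#' @param n_dishes,embryos_per_dish cohort layout.
#' @param stage_schedule named numeric vector mapping observation day to
#'   expected stage; must be monotone non-decreasing in day. Defaults to
#'   [medaka_stage_schedule].
#' @param stage_noise_sd standard deviation (in stage units) of the Gaussian
#'   observation noise added to the scheduled stage before snapping to the
#'   staging ladder.
#' @param p_abnormal per-embryo probability of a morphological abnormality.
#' @param p_hatch_fail per-embryo probability of never hatching.
#' @param hatch_day_mean,hatch_day_sd normal distribution of the hatch day
#'   for hatching embryos (truncated below at 1).
#' @param n_days last observation day of the daily record (day 0 is assay
#'   start).
#' @param seed integer seed.
#' @return A validated list of class `embryo_sim_config`.
#' @export
embryo_sim_config <- function(n_dishes = 5, embryos_per_dish = 15,
                              stage_schedule = medaka_stage_schedule,
                              stage_noise_sd = 1,
                              p_abnormal = 2 / 75,
                              p_hatch_fail = 0.05,
                              hatch_day_mean = 15, hatch_day_sd = 2,
                              n_days = 15,
                              seed = 1L) {
  stopifnot_scalar_num(n_dishes, "n_dishes", lower = 1, integer = TRUE)
  stopifnot_scalar_num(embryos_per_dish, "embryos_per_dish", lower = 1,
                       integer = TRUE)
  stopifnot_scalar_num(stage_noise_sd, "stage_noise_sd", lower = 0)
  stopifnot_scalar_num(p_abnormal, "p_abnormal", 0, 1)
  stopifnot_scalar_num(p_hatch_fail, "p_hatch_fail", 0, 1)
  stopifnot_scalar_num(hatch_day_mean, "hatch_day_mean", lower = 1e-9)
  stopifnot_scalar_num(hatch_day_sd, "hatch_day_sd", lower = 1e-9)
  stopifnot_scalar_num(n_days, "n_days", lower = 1, integer = TRUE)
  days <- as.numeric(names(stage_schedule))
  if (length(stage_schedule) < 1L || any(is.na(days))) {
    stop("`stage_schedule` must be a named day -> stage vector",
         call. = FALSE)
  }
  ord <- order(days)
  days <- days[ord]
  stages <- as.numeric(stage_schedule)[ord]
  if (is.unsorted(stages)) {
    stop("`stage_schedule` must be monotone non-decreasing in day",
         call. = FALSE)
  }
  structure(
    list(n_dishes = as.integer(n_dishes),
         embryos_per_dish = as.integer(embryos_per_dish),
         schedule_days = days, schedule_stages = stages,
         stage_noise_sd = stage_noise_sd,
         p_abnormal = p_abnormal, p_hatch_fail = p_hatch_fail,
         hatch_day_mean = hatch_day_mean, hatch_day_sd = hatch_day_sd,
         n_days = as.integer(n_days), seed = as.integer(seed)),
    class = "embryo_sim_config")
}

# Snap numeric stage values to the nearest ladder stage (ties toward the
# lower stage), clamping outside the ladder range. Vectorized: values in
# (mid[k-1], mid[k]] snap to ladder[k], where mid are between-stage
# midpoints, so a value exactly halfway takes the lower stage.
snap_to_ladder <- function(x, ladder = medaka_stage_ladder) {
  ladder <- sort(ladder)
  mids <- (ladder[-length(ladder)] + ladder[-1]) / 2
  ladder[findInterval(x, mids, left.open = TRUE) + 1L]
}

# Expected stage on each requested day: last-observation-carried-forward
# over the schedule (days before the first scheduled day take its stage).
schedule_stage_on <- function(days, schedule_days, schedule_stages) {
  idx <- findInterval(days, schedule_days)
  idx[idx < 1L] <- 1L
  schedule_stages[idx]
}

#' Simulate embryo cohorts with known stage dynamics
#'
#' Generates per-embryo daily stage records: the scheduled stage plus
#' rounded Gaussian observation noise, snapped to the staging ladder and
#' made monotone non-decreasing; a per-embryo abnormality flag; and a hatch
#' day drawn from a normal distribution (or no hatch at all, with
#' probability `p_hatch_fail`). The stage series and the hatch day are
#' independent draws: with `stage_noise_sd = 0` every embryo follows the
#' schedule exactly, whatever its hatch day. Real records tie the two
#' together (an embryo is at stage 40 exactly when it hatches); synthetic
#' cohorts only emulate that coupling in distribution.
#'
#' @param config an [embryo_sim_config()].
#' @return A data.frame in long daily-observation layout with one row per
#'   embryo-day and columns `dish`, `embryo`, `day`, `stage`, `abnormal`
#'   (logical), `hatch_day` (numeric, `NA` = unhatched). The configuration
#'   is attached as attribute `config`.
#' @examples
#' cohort <- simulate_embryo_cohort(embryo_sim_config(n_dishes = 1, seed = 3))
#' head(cohort)
#' @export
simulate_embryo_cohort <- function(config) {
  stopifnot(inherits(config, "embryo_sim_config"))
  local_seed(config$seed, {
    days <- 0:config$n_days
    n_days <- length(days)
    n_total <- config$n_dishes * config$embryos_per_dish
    base <- schedule_stage_on(days, config$schedule_days,
                              config$schedule_stages)
    # noise matrix: one column per embryo, one row per day
    noise <- matrix(round(stats::rnorm(n_days * n_total, 0,
                                       config$stage_noise_sd)),
                    n_days, n_total)
    abnormal <- stats::runif(n_total) < config$p_abnormal
    no_hatch <- stats::runif(n_total) < config$p_hatch_fail
    hatch_raw <- stats::rnorm(n_total, config$hatch_day_mean,
                              config$hatch_day_sd)
    hatch_day <- ifelse(no_hatch, NA_real_, pmax(1, hatch_raw))

    stage_mat <- matrix(NA_integer_, n_days, n_total)
    for (j in seq_len(n_total)) {
      stage_mat[, j] <- cummax(snap_to_ladder(base + noise[, j]))
    }

    dish <- rep(seq_len(config$n_dishes), each = config$embryos_per_dish)
    embryo <- rep(seq_len(config$embryos_per_dish),
                  times = config$n_dishes)
    out <- data.frame(
      dish = rep(dish, each = n_days),
      embryo = rep(embryo, each = n_days),
      day = rep(days, times = n_total),
      stage = as.integer(stage_mat),
      abnormal = rep(abnormal, each = n_days),
      hatch_day = rep(hatch_day, each = n_days))
    attr(out, "config") <- config
    out
  })
}

#' Write / read embryo cohort records as CSV
#'
#' Long daily-observation layout: `dish,embryo,day,stage,abnormal,hatch_day`
#' (empty `hatch_day` = unhatched).
#'
#' @param records data.frame from [simulate_embryo_cohort()].
#' @param path CSV file path.
#' @return `write_embryo_csv()` returns `path` invisibly;
#'   `read_embryo_csv()` returns the data.frame.
#' @export
write_embryo_csv <- function(records, path) {
  utils::write.csv(
    records[, c("dish", "embryo", "day", "stage", "abnormal", "hatch_day")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embryo_csv
#' @export
read_embryo_csv <- function(path) {
  out <- utils::read.csv(path)
  out$abnormal <- as.logical(out$abnormal)
  out$hatch_day <- as.numeric(out$hatch_day)
  out
}
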