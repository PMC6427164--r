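#' Bundled reference tables from the original SMF exposure assay
#'
#' Two small reference tables from the assay this package models ship with
#' the package so that the group-comparison statistics can be reproduced
#' offline.
#'
#' `smf_reference_velocities()` returns the per-clip average swimming
#' velocities (pixel/frame) of the sham-exposed control group and the
#' SMF-exposed treated group: 12 five-minute clips per group, each column
#' sorted ascending as conventionally printed, so row pairing is pairing
#' by rank.
#'
#' `smf_reference_hatch()` returns the per-dish hatch summary of the embryo
#' assay: dishes 1--5 were exposed (for 1, 3, 6, 10 and 15 days
#' respectively), dishes 6--8 were sham-exposed controls, 15 embryos per
#' dish. `hatchability_pct` is the percentage as printed in the original
#' records; pass the table through [check_hatch_table()] to surface the
#' known internal inconsistency of the dish-5 row (14 of 15 hatched but a
#' printed 100%).
#'
#' @return `smf_reference_velocities()`: data.frame with columns `video`,
#'   `control`, `treated` (12 rows). `smf_reference_hatch()`: data.frame
#'   with columns `dish`, `group`, `exposure_days`, `n_total`, `n_hatched`,
#'   `hatchability_pct`, `mean_days_to_hatch` (8 rows).
#' @export
smf_reference_velocities <- function() {
  utils::read.csv(system.file("extdata", "clip_velocities.csv",
                              package = "smftrack", mustWork = TRUE))
}

#' @rdname smf_reference_velocities
#' @export
smf_reference_hatch <- function() {
  utils::read.csv(system.file("extdata", "hatch_summary.csv",
                              package = "smftrack", mustWork = TRUE))
}
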