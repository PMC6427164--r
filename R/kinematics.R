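#' Per-clip total path length and average swimming velocity
#'
#' The total swimming distance of a clip is the superposition of the
#' Euclidean distances between the positions in consecutive frames,
#' \eqn{\sum_{i=2}^{n_c} \sqrt{(s_{x,i}-s_{x,i-1})^2 +
#' (s_{y,i}-s_{y,i-1})^2}}, where \eqn{n_c} is the number of frames.
#' Two average velocities are reported: per frame (total distance divided
#' by the \eqn{n_c - 1} frame transitions, the natural denominator for a
#' sum over `i = 2..n_c`) and per second (total distance divided by the
#' clip duration, by default the 300 s of a 5-minute clip).
#'
#' @param track positions of a single fish, ordered by frame: a data.frame
#'   with `x`, `y` columns (e.g. one fish of a [build_tracks()] result) or
#'   an n x 2 matrix.
#' @param clip_duration_s clip duration in seconds used for the per-second
#'   velocity.
#' @param clip_id optional identifier copied into the result.
#' @return One-row data.frame with columns `clip_id`, `n_frames`,
#'   `total_distance_px`, `velocity_px_per_frame`, `velocity_px_per_s`.
#' @examples
#' tr <- data.frame(x = 3 * (0:300), y = 4 * (0:300))
#' clip_velocity(tr)  # 1500 px, 5 px/frame, 5 px/s over 300 s
#' @export
clip_velocity <- function(track, clip_duration_s = 300, clip_id = NA) {
  P <- as_xy_matrix(track)
  if (nrow(P) < 2L) {
    stop("a clip needs at least 2 frames to have a velocity", call. = FALSE)
  }
  stopifnot_scalar_num(clip_duration_s, "clip_duration_s", lower = 1e-12)
  steps <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)
  total <- sum(steps)
  data.frame(clip_id = clip_id,
             n_frames = nrow(P),
             total_distance_px = total,
             velocity_px_per_frame = total / (nrow(P) - 1L),
             velocity_px_per_s = total / clip_duration_s)
}

#' Per-fish clip velocities for a multi-fish track table
#'
#' @param tracks data.frame from [build_tracks()] (columns `frame`,
#'   `fish_id`, `x`, `y`).
#' @inheritParams clip_velocity
#' @return data.frame with one row per fish, `clip_id` set to the fish id.
#' @export
clip_velocities <- function(tracks, clip_duration_s = 300) {
  stopifnot(all(c("fish_id", "frame", "x", "y") %in% names(tracks)))
  ids <- sort(unique(tracks$fish_id))
  do.call(rbind, lapply(ids, function(k) {
    tr <- tracks[tracks$fish_id == k, ]
    tr <- tr[order(tr$frame), ]
    clip_velocity(tr, clip_duration_s = clip_duration_s, clip_id = k)
  }))
}

#' Group velocity summary table
#'
#' Arranges the per-clip average velocities of a control and a treated
#' group into the standard report layout: each group's velocities sorted
#' ascending, one row per clip, with a trailing row of group means.
#'
#' @param control,treated numeric vectors of per-clip velocities (same
#'   units), at least one clip each.
#' @return An object of class `velocity_table`: list with `table` (the
#'   formatted data.frame including the trailing `Average` row),
#'   `control_mean`, `treated_mean` (full precision).
#' @export
group_velocity_table <- function(control, treated) {
  if (length(control) < 1L || length(treated) < 1L) {
    stop("each group needs at least one clip velocity", call. = FALSE)
  }
  if (anyNA(control) || anyNA(treated)) {
    stop("clip velocities must not contain NA", call. = FALSE)
  }
  n <- max(length(control), length(treated))
  pad <- function(v) c(sort(v), rep(NA_real_, n - length(v)))
  tab <- data.frame(video = c(as.character(seq_len(n)), "Average"),
                    control = c(pad(control), mean(control)),
                    treated = c(pad(treated), mean(treated)))
  structure(list(table = tab,
                 control_mean = mean(control),
                 treated_mean = mean(treated)),
            class = "velocity_table")
}

#' @export
print.velocity_table <- function(x, digits = 4, ...) {
  tab <- x$table
  tab$control <- round(tab$control, digits)
  tab$treated <- round(tab$treated, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}
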