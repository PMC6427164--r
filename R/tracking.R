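## Frame-to-frame identity assignment and track building.
##
## The cost of linking a track to a detection is the Euclidean distance
## between its last position and the detection centroid; identities are
## resolved by the injective matching that, among all matchings of maximal
## size whose pairs all lie within the gate, minimizes the total distance.

# O(k^3) shortest-augmenting-path solver for the square linear assignment
# problem (Jonker-Volgenant style with potentials). Returns, for each row,
# the assigned column.
lap_square <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)          # row potentials, rows 1..n
  v <- numeric(n + 1L)     # column potentials, cols 0..n at index j+1
  p <- integer(n + 1L)     # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used) - 1L            # columns 0..n currently in tree
      rows_used <- p[usedj + 1L]
      u[rows_used] <- u[rows_used] + delta
      v[usedj + 1L] <- v[usedj + 1L] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}

# Build the padded square cost matrix for n tracks x m detections. Real
# feasible pairs carry their true distance; matching a real track or
# detection to a dummy costs BIG (one BIG per unmatched object); pairs
# beyond the gate cost INFEAS, chosen so large that no optimal solution ever
# uses one. `forced` is an optional integer vector over tracks (NA = free,
# 0 = forced unmatched, j = forced to detection j).
padded_cost <- function(D, feasible, forced = NULL) {
  n <- nrow(D); m <- ncol(D)
  BIG <- 1e7
  INFEAS <- 1e13
  k <- n + m
  C <- matrix(0, k, k)
  if (n > 0L && m > 0L) {
    real <- ifelse(feasible, D, INFEAS)
    C[seq_len(n), seq_len(m)] <- real
  }
  if (n > 0L) C[seq_len(n), m + seq_len(n)] <- BIG
  if (m > 0L) C[n + seq_len(m), seq_len(m)] <- BIG
  if (!is.null(forced)) {
    for (i in which(!is.na(forced))) {
      C[i, seq_len(m)] <- INFEAS
      if (forced[i] == 0L) next
      # a forced match must also close the dummy escape for that row
      C[i, forced[i]] <- D[i, forced[i]]
      C[i, m + seq_len(n)] <- INFEAS
    }
  }
  C
}

# Solve a padded instance; return the real mapping (NA = unmatched), its
# size and its real total cost.
solve_padded <- function(D, feasible, forced = NULL) {
  n <- nrow(D); m <- ncol(D)
  if (n == 0L || m == 0L) {
    return(list(mapping = rep(NA_integer_, n), size = 0L, cost = 0))
  }
  C <- padded_cost(D, feasible, forced)
  a <- lap_square(C)
  mapping <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- a[i]
    if (j <= m && feasible[i, j] &&
        (is.null(forced) || is.na(forced[i]) || forced[i] == j)) {
      mapping[i] <- j
    }
  }
  matched <- which(!is.na(mapping))
  list(mapping = mapping,
       size = length(matched),
       cost = sum(D[cbind(matched, mapping[matched])]))
}

#' Assign detections to tracks by minimum total Euclidean distance
#'
#' Finds the injective matching between previous track positions and
#' current-frame detections that, among all matchings of maximal size with
#' every matched pair within `max_gate_px`, minimizes the sum of Euclidean
#' distances. Ties between equal-cost optimal matchings are broken toward
#' the lexicographically smallest (track index, detection index) mapping,
#' which makes the result fully deterministic. A greedy per-track
#' nearest-neighbor mode is available for comparison.
#'
#' @param prev_positions previous positions: an n x 2 matrix or a
#'   data.frame with `x`, `y` columns; may be empty.
#' @param detections current detections: an m x 2 matrix or a data.frame
#'   with `x`, `y` (e.g. from [detect()]); may be empty.
#' @param max_gate_px largest allowed match distance in pixels; pairs
#'   farther apart are never linked, which prevents teleporting matches
#'   after a long occlusion.
#' @param method `"optimal"` (global minimum-total-distance matching) or
#'   `"greedy"` (each track in index order takes its nearest unused
#'   detection within the gate).
#' @return An object of class `assignment_result`: list with `mapping`
#'   (integer vector over tracks; 1-based detection index or `NA` for
#'   unmatched), `total_cost` (sum of matched distances) and `n_matched`.
#' @examples
#' assign_detections(rbind(c(0, 0)), rbind(c(3, 4)))$total_cost  # 5
#' @export
assign_detections <- function(prev_positions, detections, max_gate_px = 50,
                              method = c("optimal", "greedy")) {
  method <- match.arg(method)
  P <- as_xy_matrix(prev_positions)
  Q <- as_xy_matrix(detections)
  n <- nrow(P); m <- nrow(Q)
  stopifnot_scalar_num(max_gate_px, "max_gate_px", lower = 0)
  empty <- list(mapping = rep(NA_integer_, n), total_cost = 0,
                n_matched = 0L)
  class(empty) <- "assignment_result"
  if (n == 0L || m == 0L) return(empty)
  D <- sqrt(outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2)
  feasible <- D <= max_gate_px
  if (!any(feasible)) return(empty)

  if (method == "greedy") {
    mapping <- rep(NA_integer_, n)
    used <- rep(FALSE, m)
    for (i in seq_len(n)) {
      cand <- which(feasible[i, ] & !used)
      if (length(cand) > 0L) {
        j <- cand[which.min(D[i, cand])]   # which.min takes smallest index tie
        mapping[i] <- j
        used[j] <- TRUE
      }
    }
  } else {
    base <- solve_padded(D, feasible)
    tol <- 1e-9 * (1 + abs(base$cost))
    forced <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      taken <- forced[!is.na(forced) & forced > 0L]
      cands <- c(setdiff(which(feasible[i, ]), taken), 0L)
      for (j in cands) {
        forced[i] <- j
        sol <- solve_padded(D, feasible, forced)
        if (sol$size == base$size && sol$cost <= base$cost + tol) break
        forced[i] <- NA_integer_
      }
      if (is.na(forced[i])) forced[i] <- 0L  # unreachable safeguard
    }
    mapping <- ifelse(forced == 0L, NA_integer_, forced)
  }
  matched <- which(!is.na(mapping))
  out <- list(mapping = mapping,
              total_cost = sum(D[cbind(matched, mapping[matched])]),
              n_matched = length(matched))
  class(out) <- "assignment_result"
  out
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> %d matched, total cost %.4f\n",
              x$n_matched, x$total_cost))
  invisible(x)
}

#' Build per-fish tracks from per-frame detections
#'
#' Initializes one track per fish at the first frame holding at least
#' `n_fish` detections (taking the first `n_fish` in the detection sort
#' order) and then links detections frame by frame with
#' [assign_detections()]. A track whose detection is missing in a frame
#' coasts: it repeats its last position with `observed = FALSE`, so every
#' track has exactly one position per frame from initialization onward and
#' a coasted transition contributes zero distance to the path length.
#' Surplus detections beyond the tracked identities are ignored.
#'
#' @param detections data.frame with columns `frame` (0-based), `x`, `y`
#'   (e.g. [detect_stack()] output or a detections CSV).
#' @param n_fish number of identities to track.
#' @param max_gate_px,method passed to [assign_detections()].
#' @param n_frames total frame count of the clip; defaults to
#'   `max(detections$frame) + 1`.
#' @return data.frame with columns `frame`, `fish_id`, `x`, `y`, `observed`
#'   covering every frame from the initialization frame to the last frame.
#'   Attributes: `init_frame` (0-based) and `n_swap_suspects` (matches
#'   closer than the gate but beyond 0.8 x gate, a proxy for risky links).
#' @export
build_tracks <- function(detections, n_fish, max_gate_px = 50,
                         method = c("optimal", "greedy"),
                         n_frames = NULL) {
  method <- match.arg(method)
  stopifnot_scalar_num(n_fish, "n_fish", lower = 1, integer = TRUE)
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y") %in% names(detections)))
  if (is.null(n_frames)) {
    if (nrow(detections) == 0L) {
      stop("no detections: cannot infer the frame count", call. = FALSE)
    }
    n_frames <- max(detections$frame) + 1L
  }
  by_frame <- split(detections[, c("x", "y")],
                    factor(detections$frame, levels = 0:(n_frames - 1L)))
  counts <- vapply(by_frame, nrow, integer(1))
  init <- unname(which(counts >= n_fish))[1]
  if (is.na(init)) {
    stop(sprintf(
      "track initialization failed: no frame has >= %d detections", n_fish),
      call. = FALSE)
  }
  first <- by_frame[[init]]
  first <- first[order(first$y, first$x), , drop = FALSE]
  pos <- as_xy_matrix(first[seq_len(n_fish), ])
  frames_out <- init:length(by_frame)
  n_out <- length(frames_out)
  xs <- matrix(NA_real_, n_out, n_fish)
  ys <- matrix(NA_real_, n_out, n_fish)
  obs <- matrix(TRUE, n_out, n_fish)
  xs[1, ] <- pos[, 1]; ys[1, ] <- pos[, 2]
  n_suspect <- 0L
  if (n_out > 1L) {
    for (t in 2:n_out) {
      det <- by_frame[[frames_out[t]]]
      res <- assign_detections(pos, det, max_gate_px = max_gate_px,
                               method = method)
      for (i in seq_len(n_fish)) {
        j <- res$mapping[i]
        if (!is.na(j)) {
          d <- euclid(pos[i, ], c(det$x[j], det$y[j]))
          if (d > 0.8 * max_gate_px) n_suspect <- n_suspect + 1L
          pos[i, ] <- c(det$x[j], det$y[j])
        } else {
          obs[t, i] <- FALSE          # coast: hold last position
        }
      }
      xs[t, ] <- pos[, 1]; ys[t, ] <- pos[, 2]
    }
  }
  out <- data.frame(
    frame = rep(frames_out - 1L, times = n_fish),
    fish_id = rep(seq_len(n_fish), each = n_out),
    x = as.vector(xs), y = as.vector(ys),
    observed = as.vector(obs))
  attr(out, "init_frame") <- init - 1L
  attr(out, "n_swap_suspects") <- n_suspect
  out
}

#' Write / read tracks as CSV
#'
#' Layout: `frame,fish_id,x,y,observed` with 0-based frame indices.
#'
#' @param tracks data.frame from [build_tracks()].
#' @param path CSV file path.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()`
#'   returns the data.frame.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks[, c("frame", "fish_id", "x", "y", "observed")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- utils::read.csv(path)
  if ("observed" %in% names(out)) out$observed <- as.logical(out$observed)
  out
}
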