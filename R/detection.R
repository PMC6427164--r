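#' Train a background model from a frame stack
#'
#' Builds the per-pixel reference image used for background subtraction. The
#' reference is the per-pixel median across frames, which is robust to a
#' fish transiently occupying a pixel as long as it covers that pixel in
#' fewer than half of the training frames.
#'
#' @param stack a [frame_stack()] with at least 3 frames.
#' @param diff_threshold intensity difference (0--255 units) above which a
#'   pixel is considered foreground during [detect()].
#' @return An object of class `background_model`: list with `reference`
#'   (matrix), `diff_threshold`, `width_px`, `height_px`.
#' @export
train_background <- function(stack, diff_threshold = 30) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$n_frames < 3L) {
    stop("background training needs at least 3 frames", call. = FALSE)
  }
  stopifnot_scalar_num(diff_threshold, "diff_threshold", lower = 1e-12)
  X <- matrix(unlist(stack$frames, use.names = FALSE),
              nrow = stack$height_px * stack$width_px,
              ncol = stack$n_frames)
  ref <- matrix(apply(X, 1L, stats::median),
                stack$height_px, stack$width_px)
  structure(
    list(reference = ref, diff_threshold = diff_threshold,
         width_px = stack$width_px, height_px = stack$height_px),
    class = "background_model")
}

# 3x3 median filter with edge replication, fully vectorized via the
# 19-comparator median-of-9 exchange network (Paeth). Exact for any numeric
# input, so integer-intensity images stay integer.
median_filter3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- m[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  sh <- function(dr, dc) pad[seq_len(H) + 1L + dr, seq_len(W) + 1L + dc]
  p <- list(sh(-1, -1), sh(-1, 0), sh(-1, 1),
            sh(0, -1),  sh(0, 0),  sh(0, 1),
            sh(1, -1),  sh(1, 0),  sh(1, 1))
  op <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  op(2, 3); op(5, 6); op(8, 9)
  op(1, 2); op(4, 5); op(7, 8)
  op(2, 3); op(5, 6); op(8, 9)
  op(1, 4); op(6, 9); op(5, 8)
  op(4, 7); op(2, 5); op(3, 6)
  op(5, 8); op(5, 3); op(7, 5)
  op(5, 3)
  p[[5]]
}

# 8-connected component labeling of a logical mask. Foreground pixels become
# vertices; edges join pixels adjacent horizontally, vertically or
# diagonally; components come from igraph. Returns an integer matrix with 0
# for background and 1..k component labels.
label_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0L) return(lab)
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  vid <- integer(H * W)
  vid[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + off[1]; cc <- c + off[2]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    nb <- (cc[ok] - 1L) * H + rr[ok]
    hit <- vid[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(vid[idx[ok]][hit], vid[nb][hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  member <- igraph::components(g)$membership
  lab[idx] <- as.integer(member)
  lab
}

#' Detect fish blobs in one frame by background subtraction
#'
#' The detection pipeline: absolute difference between the frame and the
#' background reference; optional 3x3 median filter on the difference image
#' (the noise-filtering step); binarization at the model's `diff_threshold`;
#' 8-connected component labeling; removal of components smaller than
#' `min_area`; centroid as the unweighted mean of member pixel coordinates.
#' The absolute difference makes the polarity irrelevant — dark fish on a
#' light background and the reverse segment identically.
#'
#' @param frame numeric matrix with the geometry of the model.
#' @param model a [train_background()] result.
#' @param min_area smallest component size (pixels) kept as a detection.
#' @param median_filter apply the 3x3 median noise filter before
#'   thresholding.
#' @return A data.frame of detections sorted by `(y, x)`, with columns `x`,
#'   `y` (0-based centroid coordinates) and `area` (pixel count). Zero rows
#'   when nothing is detected.
#' @export
detect <- function(frame, model, min_area = 20, median_filter = TRUE) {
  stopifnot(inherits(model, "background_model"))
  if (!is.matrix(frame) || nrow(frame) != model$height_px ||
      ncol(frame) != model$width_px) {
    stop("frame geometry does not match the background model", call. = FALSE)
  }
  stopifnot_scalar_num(min_area, "min_area", lower = 1, integer = TRUE)
  d <- abs(frame - model$reference)
  if (isTRUE(median_filter)) d <- median_filter3(d)
  mask <- d > model$diff_threshold
  lab <- label_components8(mask)
  if (all(lab == 0L)) {
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0)))
  }
  idx <- which(lab > 0L)
  comp <- lab[idx]
  H <- nrow(frame)
  px <- ((idx - 1L) %/% H)        # 0-based x (column)
  py <- ((idx - 1L) %% H)         # 0-based y (row)
  area <- tabulate(comp)
  keep <- which(area >= min_area)
  if (length(keep) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0)))
  }
  cx <- vapply(keep, function(k) mean(px[comp == k]), numeric(1))
  cy <- vapply(keep, function(k) mean(py[comp == k]), numeric(1))
  out <- data.frame(x = cx, y = cy, area = area[keep])
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect blobs in every frame of a stack
#'
#' Applies [detect()] frame by frame and stacks the results with a 0-based
#' `frame` column, the layout consumed by [build_tracks()].
#'
#' @inheritParams detect
#' @param stack a [frame_stack()].
#' @return data.frame with columns `frame`, `x`, `y`, `area`.
#' @export
detect_stack <- function(stack, model, min_area = 20, median_filter = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  res <- lapply(seq_len(stack$n_frames), function(i) {
    d <- detect(stack$frames[[i]], model, min_area = min_area,
                median_filter = median_filter)
    if (nrow(d) > 0L) d$frame <- i - 1L
    d
  })
  res <- res[vapply(res, nrow, integer(1)) > 0L]
  if (length(res) == 0L) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0)))
  }
  out <- do.call(rbind, res)
  out[, c("frame", "x", "y", "area")]
}

#' Write / read detections as CSV
#'
#' Layout: `frame,x,y,area` with 0-based frame indices.
#'
#' @param detections data.frame from [detect_stack()].
#' @param path CSV file path.
#' @return `write_detections()` returns `path` invisibly;
#'   `read_detections()` returns the data.frame.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections[, c("frame", "x", "y", "area")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  utils::read.csv(path)
}
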