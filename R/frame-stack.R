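#' Construct a frame stack
#'
#' A frame stack is the raw observational unit of the tracking pipeline: an
#' ordered sequence of grayscale frames sharing one pixel geometry, plus the
#' frame period. Pixel intensities are on the 0--255 scale. Coordinates used
#' throughout the package are 0-based with `x` increasing rightward (matrix
#' column) and `y` increasing downward (matrix row), and pixel centers at
#' integer coordinates, so pixel `(x, y)` is matrix element `[y + 1, x + 1]`.
#'
#' @param frames a list of numeric matrices, all with identical dimensions
#'   (rows = height, columns = width), or a single matrix.
#' @param frame_period_s time between consecutive frames in seconds.
#' @return An object of class `frame_stack`: a list with elements `frames`,
#'   `width_px`, `height_px`, `n_frames`, `frame_period_s`.
#' @export
frame_stack <- function(frames, frame_period_s = 1) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!is.list(frames) || length(frames) < 1L) {
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) {
      stop("every frame must be a numeric matrix", call. = FALSE)
    }
    dim(f)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  stopifnot_scalar_num(frame_period_s, "frame_period_s", lower = 1e-12)
  structure(
    list(frames = frames,
         width_px = dims[2, 1],
         height_px = dims[1, 1],
         n_frames = length(frames),
         frame_period_s = frame_period_s),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %.4g s/frame\n",
              x$n_frames, x$width_px, x$height_px, x$frame_period_s))
  invisible(x)
}

#' Crop every frame of a stack to a square window
#'
#' Recordings typically contain margins outside the tank; analysis crops each
#' frame to the tank area (e.g. 640 x 480 capture frames cropped to a
#' 380 x 380 working window). The coordinate origin of the returned stack is
#' the crop corner, so a detection at cropped `(0, 0)` sits at `(x0, y0)` of
#' the original frame.
#'
#' @param stack a [frame_stack()].
#' @param x0,y0 0-based pixel coordinates of the top-left corner of the crop
#'   window. Defaults center the window in the frame.
#' @param side side length of the square window in pixels.
#' @return A `frame_stack` of `side` x `side` frames, same frame count.
#' @export
crop_frames <- function(stack, x0 = NULL, y0 = NULL, side) {
  stopifnot(inherits(stack, "frame_stack"))
  stopifnot_scalar_num(side, "side", lower = 1, integer = TRUE)
  if (is.null(x0)) x0 <- floor((stack$width_px - side) / 2)
  if (is.null(y0)) y0 <- floor((stack$height_px - side) / 2)
  stopifnot_scalar_num(x0, "x0", lower = 0, integer = TRUE)
  stopifnot_scalar_num(y0, "y0", lower = 0, integer = TRUE)
  if (x0 + side > stack$width_px || y0 + side > stack$height_px) {
    stop("crop window extends outside the frame", call. = FALSE)
  }
  rows <- seq.int(y0 + 1L, y0 + side)
  cols <- seq.int(x0 + 1L, x0 + side)
  cropped <- lapply(stack$frames, function(f) f[rows, cols, drop = FALSE])
  frame_stack(cropped, frame_period_s = stack$frame_period_s)
}

#' Write a frame stack as numbered PNG files
#'
#' Frames are written as zero-padded grayscale PNGs (`frame_000000.png`, ...)
#' together with a JSON sidecar recording geometry, frame period and any
#' extra provenance fields.
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if missing).
#' @param sidecar named list of extra fields stored in `frames.json`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_frames <- function(stack, dir, sidecar = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_len(stack$n_frames) - 1L))
  for (i in seq_len(stack$n_frames)) {
    img <- pmin(pmax(stack$frames[[i]], 0), 255) / 255
    png::writePNG(img, target = paths[i])
  }
  meta <- c(list(n_frames = stack$n_frames,
                 width_px = stack$width_px,
                 height_px = stack$height_px,
                 frame_period_s = stack$frame_period_s),
            sidecar)
  jsonlite::write_json(meta, file.path(dir, "frames.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a directory of numbered PNG frames into a frame stack
#'
#' Reads the layout produced by [write_frames()]. Any PNG files in the
#' directory are read in lexicographic order; the `frames.json` sidecar, if
#' present, supplies the frame period.
#'
#' @param dir directory containing PNG frames.
#' @param frame_period_s frame period; overridden by the sidecar when one
#'   exists.
#' @return A [frame_stack()] with intensities on the 0--255 scale.
#' @export
read_frames <- function(dir, frame_period_s = 1) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no PNG frames found in ", dir, call. = FALSE)
  sidecar <- file.path(dir, "frames.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$frame_period_s)) frame_period_s <- meta$frame_period_s
  }
  frames <- lapply(files, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]  # collapse RGB(A) to gray
    img * 255
  })
  frame_stack(frames, frame_period_s = frame_period_s)
}
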