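#' Build a spatial occupancy heatmap from tracks
#'
#' Counts how often any fish was observed in each spatial bin over a
#' recording: every per-frame position increments the bin containing it
#' (bin index = floor(coordinate / bin_size)). Coasted positions (frames
#' where a track held its last position because no detection matched) are
#' included by default and can be excluded. The counts always sum to the
#' number of recorded positions.
#'
#' @param tracks data.frame of positions with columns `x`, `y` and
#'   optionally `observed` (from [build_tracks()], or a ground-truth
#'   table).
#' @param width_px,height_px frame geometry in pixels; positions must lie
#'   in `[0, width_px - 1] x [0, height_px - 1]`.
#' @param bin_size_px side of the square bins in pixels (1 = per-pixel
#'   heatmap).
#' @param include_coasted keep coasted (unobserved) positions.
#' @return An object of class `occupancy_heatmap`: list with `counts`
#'   (rows = y bins, columns = x bins), `bin_size_px`, `width_px`,
#'   `height_px`, `n_positions`.
#' @export
build_heatmap <- function(tracks, width_px, height_px, bin_size_px = 1,
                          include_coasted = TRUE) {
  stopifnot(is.data.frame(tracks), all(c("x", "y") %in% names(tracks)))
  stopifnot_scalar_num(width_px, "width_px", lower = 1, integer = TRUE)
  stopifnot_scalar_num(height_px, "height_px", lower = 1, integer = TRUE)
  stopifnot_scalar_num(bin_size_px, "bin_size_px", lower = 1, integer = TRUE)
  if (!include_coasted && "observed" %in% names(tracks)) {
    tracks <- tracks[tracks$observed, , drop = FALSE]
  }
  if (nrow(tracks) == 0L) {
    stop("no positions to bin", call. = FALSE)
  }
  if (any(tracks$x < 0 | tracks$x > width_px - 1 |
          tracks$y < 0 | tracks$y > height_px - 1)) {
    stop("positions outside the stated frame geometry", call. = FALSE)
  }
  nbx <- ceiling(width_px / bin_size_px)
  nby <- ceiling(height_px / bin_size_px)
  bx <- pmin(floor(tracks$x / bin_size_px) + 1L, nbx)
  by <- pmin(floor(tracks$y / bin_size_px) + 1L, nby)
  counts <- matrix(tabulate((bx - 1L) * nby + by, nbins = nbx * nby),
                   nby, nbx)
  structure(list(counts = counts, bin_size_px = as.integer(bin_size_px),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_positions = nrow(tracks)),
            class = "occupancy_heatmap")
}

#' @export
print.occupancy_heatmap <- function(x, ...) {
  cat(sprintf("<occupancy_heatmap> %d x %d bins (%d px), %d positions\n",
              ncol(x$counts), nrow(x$counts), x$bin_size_px,
              x$n_positions))
  invisible(x)
}

#' Define an annular magnetic-field zone
#'
#' Field zones are supplied as configuration, matching how field geometry
#' is known in practice: a disk magnet under the tank produces concentric
#' rings of field strength, described by annuli around the magnet center
#' with an optional field label in millitesla. A disk is an annulus with
#' `r_inner_px = 0`. Membership is `r_inner_px <= distance < r_outer_px`.
#'
#' @param name zone label (e.g. `"center"`, `"high_field_ring"`).
#' @param center_x,center_y annulus center in pixel coordinates.
#' @param r_inner_px,r_outer_px inner (inclusive) and outer (exclusive)
#'   radii in pixels; `r_inner_px < r_outer_px`.
#' @param field_mT optional nominal field strength label.
#' @return An object of class `field_zone`.
#' @export
annulus_zone <- function(name, center_x, center_y, r_inner_px, r_outer_px,
                         field_mT = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot_scalar_num(center_x, "center_x")
  stopifnot_scalar_num(center_y, "center_y")
  stopifnot_scalar_num(r_inner_px, "r_inner_px", lower = 0)
  stopifnot_scalar_num(r_outer_px, "r_outer_px", lower = 0)
  if (r_inner_px >= r_outer_px) {
    stop("`r_inner_px` must be smaller than `r_outer_px`", call. = FALSE)
  }
  structure(list(name = name, center_x = center_x, center_y = center_y,
                 r_inner_px = r_inner_px, r_outer_px = r_outer_px,
                 field_mT = field_mT),
            class = "field_zone")
}

#' Collect field zones into a zone map
#'
#' @param ... [annulus_zone()] objects with unique names. Zones need not
#'   tile the frame; positions in no zone fall into the implicit
#'   `"outside"` zone.
#' @return An object of class `zone_map` (list of zones).
#' @export
zone_map <- function(...) {
  zones <- list(...)
  if (length(zones) == 1L && is.list(zones[[1]]) &&
      !inherits(zones[[1]], "field_zone")) {
    zones <- zones[[1]]
  }
  ok <- vapply(zones, inherits, logical(1), what = "field_zone")
  if (length(zones) == 0L || !all(ok)) {
    stop("`zone_map()` takes one or more annulus_zone objects",
         call. = FALSE)
  }
  nm <- vapply(zones, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("zone names must be unique", call. = FALSE)
  if ("outside" %in% nm) {
    stop('"outside" is reserved for the implicit remainder zone',
         call. = FALSE)
  }
  structure(zones, class = "zone_map")
}

#' Read a zone map from a JSON config file
#'
#' Expects an array of objects with fields `name`, `center_x`, `center_y`,
#' `r_inner_px`, `r_outer_px` and optional `field_mT`.
#'
#' @param path JSON file path.
#' @return A [zone_map()].
#' @export
read_zone_map <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  zones <- lapply(entries, function(z) {
    annulus_zone(z$name, z$center_x, z$center_y, z$r_inner_px,
                 z$r_outer_px,
                 if (is.null(z$field_mT)) NA_real_ else z$field_mT)
  })
  zone_map(zones)
}

#' Fraction of observations in each field zone
#'
#' Attributes every heatmap bin to the zone containing the bin's center
#' point (the mean pixel coordinate of the bin's member pixels), a
#' deterministic rule independent of traversal order, then sums
#' observation counts per zone. Fractions over the zones plus the implicit
#' `"outside"` remainder form a probability vector.
#'
#' @param heatmap an [build_heatmap()] result.
#' @param zones a [zone_map()].
#' @return Named numeric vector of fractions (zone names plus `"outside"`)
#'   summing to 1. Bins whose center lies in more than one zone raise a
#'   warning and are attributed to the first zone that contains them.
#' @export
zone_occupancy <- function(heatmap, zones) {
  stopifnot(inherits(heatmap, "occupancy_heatmap"),
            inherits(zones, "zone_map"))
  bin <- heatmap$bin_size_px
  nbx <- ncol(heatmap$counts); nby <- nrow(heatmap$counts)
  cx <- ((seq_len(nbx) - 1L) * bin) + (bin - 1) / 2
  cy <- ((seq_len(nby) - 1L) * bin) + (bin - 1) / 2
  X <- matrix(cx, nby, nbx, byrow = TRUE)
  Y <- matrix(cy, nby, nbx)
  member <- matrix(0L, nby, nbx)   # 0 = outside, else first matching zone
  overlap <- FALSE
  for (z in seq_along(zones)) {
    zo <- zones[[z]]
    r <- sqrt((X - zo$center_x)^2 + (Y - zo$center_y)^2)
    inz <- r >= zo$r_inner_px & r < zo$r_outer_px
    overlap <- overlap || any(inz & member > 0L)
    member[inz & member == 0L] <- z
  }
  if (overlap) {
    warning("overlapping zones: bins attributed to the first matching zone",
            call. = FALSE)
  }
  total <- sum(heatmap$counts)
  fr <- vapply(seq_along(zones),
               function(z) sum(heatmap$counts[member == z]) / total,
               numeric(1))
  names(fr) <- vapply(zones, `[[`, character(1), "name")
  c(fr, outside = sum(heatmap$counts[member == 0L]) / total)
}

#' Write a heatmap as a CSV count grid or a grayscale PNG
#'
#' The CSV holds the raw count matrix (rows = y bins top to bottom); the
#' PNG renders counts linearly scaled to the maximum for quick visual
#' inspection of dwelling patterns.
#'
#' @param heatmap an [build_heatmap()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "occupancy_heatmap"))
  utils::write.table(heatmap$counts, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @export
write_heatmap_png <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "occupancy_heatmap"))
  m <- heatmap$counts
  img <- if (max(m) > 0) m / max(m) else m
  png::writePNG(img, target = path)
  invisible(path)
}
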