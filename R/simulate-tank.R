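#' Configuration for the synthetic tank video generator
#'
#' Collects and validates the parameters of the simulated overhead recording:
#' frame geometry, fish appearance, the correlated-random-walk motion model
#' and the rendering noise. Defaults emulate the analysis geometry of the
#' assay this package supports: a 380 x 380 px working window containing a
#' few dark adult fish on a light background, moving at roughly 1--4 px per
#' frame.
#'
#' The motion model is a first-order autoregressive (correlated) random walk:
#' at each frame the velocity of each fish is updated as
#' `v <- velocity_persistence * v + e + b`, where `e` is an isotropic
#' Gaussian perturbation with standard deviation `speed_scale_px` per axis
#' and `b` is a drift of fixed magnitude `center_bias` px/frame pointing at
#' the frame center (zero when `center_bias = 0`). Positions reflect
#' specularly off the walls so a fish always stays fully inside the frame.
#'
#' @param width_px,height_px frame dimensions in pixels.
#' @param n_frames number of frames to simulate.
#' @param frame_period_s seconds between frames.
#' @param n_fish number of fish (0 allowed: background-only video).
#' @param fish_axes_px length-2 vector of ellipse semi-axes (x, y) in px.
#' @param fish_intensity,background_intensity grayscale levels 0--255; must
#'   differ when `n_fish > 0`.
#' @param noise_sigma standard deviation of the additive Gaussian pixel
#'   noise (0 = clean frames).
#' @param speed_scale_px per-axis standard deviation of the per-frame
#'   velocity perturbation, in px/frame.
#' @param velocity_persistence autoregressive coefficient in `[0, 1]`; 0
#'   gives independent jumps, values near 1 give smooth fish-like paths.
#' @param center_bias magnitude of the constant drift toward the frame
#'   center, in px/frame; 0 disables the dwelling preference.
#' @param init_speed_px optional initial speed magnitude; when `NULL` the
#'   initial velocity is drawn as a Gaussian of scale `speed_scale_px`.
#'   Setting this with `velocity_persistence = 1` and `speed_scale_px = 0`
#'   yields constant-speed motion, useful for velocity-recovery checks.
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical frames and ground truth.
#' @return A validated list of class `tank_sim_config`.
#' @export
tank_sim_config <- function(width_px = 380, height_px = 380,
                            n_frames = 100, frame_period_s = 1,
                            n_fish = 1,
                            fish_axes_px = c(10, 5),
                            fish_intensity = 40,
                            background_intensity = 200,
                            noise_sigma = 0,
                            speed_scale_px = 2,
                            velocity_persistence = 0.8,
                            center_bias = 0,
                            init_speed_px = NULL,
                            seed = 1L) {
  stopifnot_scalar_num(width_px, "width_px", lower = 1, integer = TRUE)
  stopifnot_scalar_num(height_px, "height_px", lower = 1, integer = TRUE)
  stopifnot_scalar_num(n_frames, "n_frames", lower = 1, integer = TRUE)
  stopifnot_scalar_num(frame_period_s, "frame_period_s", lower = 1e-12)
  stopifnot_scalar_num(n_fish, "n_fish", lower = 0, integer = TRUE)
  if (length(fish_axes_px) != 2L || any(fish_axes_px <= 0)) {
    stop("`fish_axes_px` must be two positive semi-axes", call. = FALSE)
  }
  stopifnot_scalar_num(fish_intensity, "fish_intensity", 0, 255)
  stopifnot_scalar_num(background_intensity, "background_intensity", 0, 255)
  stopifnot_scalar_num(noise_sigma, "noise_sigma", lower = 0)
  stopifnot_scalar_num(speed_scale_px, "speed_scale_px", lower = 0)
  stopifnot_scalar_num(velocity_persistence, "velocity_persistence", 0, 1)
  stopifnot_scalar_num(center_bias, "center_bias", lower = 0)
  if (!is.null(init_speed_px)) {
    stopifnot_scalar_num(init_speed_px, "init_speed_px", lower = 0)
  }
  if (n_fish > 0) {
    if (fish_axes_px[1] >= width_px / 2 || fish_axes_px[2] >= height_px / 2) {
      stop("fish semi-axes must be smaller than half of each frame dimension",
           call. = FALSE)
    }
    if (fish_intensity == background_intensity) {
      stop("fish and background intensity must differ when n_fish > 0",
           call. = FALSE)
    }
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         n_frames = as.integer(n_frames), frame_period_s = frame_period_s,
         n_fish = as.integer(n_fish), fish_axes_px = as.numeric(fish_axes_px),
         fish_intensity = fish_intensity,
         background_intensity = background_intensity,
         noise_sigma = noise_sigma, speed_scale_px = speed_scale_px,
         velocity_persistence = velocity_persistence,
         center_bias = center_bias, init_speed_px = init_speed_px,
         seed = as.integer(seed)),
    class = "tank_sim_config")
}

# Reflect a coordinate into [lo, hi], flipping the matching velocity
# component an odd number of reflections. Returns c(pos, vel).
reflect_1d <- function(p, v, lo, hi) {
  if (hi <= lo) return(c(min(max(p, lo), hi), v))
  while (p < lo || p > hi) {
    if (p < lo) {
      p <- 2 * lo - p
      v <- -v
    } else {
      p <- 2 * hi - p
      v <- -v
    }
  }
  c(p, v)
}

# Trajectory phase of the simulator. Consumes RNG in a documented order so
# an external oracle can replay it: per fish, initial position runif(2) then
# initial velocity (rnorm(2) or a runif heading); then frame by frame, per
# fish, a rnorm(2) perturbation. Returns list of n_frames x 2 matrices.
simulate_paths <- function(config) {
  W <- config$width_px; H <- config$height_px
  ax <- config$fish_axes_px[1]; ay <- config$fish_axes_px[2]
  lo_x <- ax; hi_x <- (W - 1) - ax
  lo_y <- ay; hi_y <- (H - 1) - ay
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  n <- config$n_fish
  pos <- matrix(0, n, 2)
  vel <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    pos[k, ] <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
    if (is.null(config$init_speed_px)) {
      vel[k, ] <- stats::rnorm(2, 0, config$speed_scale_px)
    } else {
      th <- stats::runif(1, 0, 2 * pi)
      vel[k, ] <- config$init_speed_px * c(cos(th), sin(th))
    }
  }
  paths <- lapply(seq_len(n), function(k) {
    m <- matrix(NA_real_, config$n_frames, 2)
    m[1, ] <- pos[k, ]
    m
  })
  if (config$n_frames > 1L) {
    for (i in 2:config$n_frames) {
      for (k in seq_len(n)) {
        pert <- stats::rnorm(2, 0, config$speed_scale_px)
        drift <- c(0, 0)
        if (config$center_bias > 0) {
          d <- c(cx, cy) - pos[k, ]
          r <- sqrt(sum(d^2))
          if (r > 1e-9) drift <- config$center_bias * d / r
        }
        v <- config$velocity_persistence * vel[k, ] + pert + drift
        p <- pos[k, ] + v
        rx <- reflect_1d(p[1], v[1], lo_x, hi_x)
        ry <- reflect_1d(p[2], v[2], lo_y, hi_y)
        pos[k, ] <- c(rx[1], ry[1])
        vel[k, ] <- c(rx[2], ry[2])
        paths[[k]][i, ] <- pos[k, ]
      }
    }
  }
  paths
}

# Hard (non-anti-aliased) ellipse rasterization: set pixels whose centers lie
# inside the ellipse. Returns the modified frame matrix.
draw_ellipse <- function(frame, cx, cy, ax, ay, value) {
  H <- nrow(frame); W <- ncol(frame)
  x_range <- max(0, floor(cx - ax)):min(W - 1, ceiling(cx + ax))
  y_range <- max(0, floor(cy - ay)):min(H - 1, ceiling(cy + ay))
  xs <- outer(rep(1, length(y_range)), x_range)
  ys <- outer(y_range, rep(1, length(x_range)))
  inside <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
  sub <- frame[y_range + 1L, x_range + 1L, drop = FALSE]
  sub[inside] <- value
  frame[y_range + 1L, x_range + 1L] <- sub
  frame
}

#' Simulate an overhead tank video with known ground truth
#'
#' Generates a grayscale frame stack containing `n_fish` dark elliptical
#' fish moving by a correlated random walk (see [tank_sim_config()]), and
#' the exact per-frame center position of every fish. The trajectory is
#' simulated first and the frames rendered afterwards, so the ground truth
#' depends only on the motion parameters and seed, never on rendering noise.
#' Fish bodies are drawn as hard-edged filled ellipses on top of the noisy
#' background, which makes blob areas exactly countable.
#'
#' @param config a [tank_sim_config()].
#' @return A list of class `tank_sim` with elements:
#'   \describe{
#'     \item{stack}{a [frame_stack()] of rendered frames (0--255).}
#'     \item{truth}{ground-truth positions: a data.frame with columns
#'       `frame` (0-based), `fish_id` (1-based), `x`, `y`; empty when
#'       `n_fish = 0`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_tank(tank_sim_config(n_frames = 5, n_fish = 2, seed = 7))
#' head(sim$truth)
#' @export
simulate_tank <- function(config) {
  stopifnot(inherits(config, "tank_sim_config"))
  local_seed(config$seed, {
    paths <- simulate_paths(config)
    frames <- vector("list", config$n_frames)
    base <- matrix(config$background_intensity,
                   config$height_px, config$width_px)
    for (i in seq_len(config$n_frames)) {
      f <- base
      if (config$noise_sigma > 0) {
        f <- f + matrix(stats::rnorm(length(base), 0, config$noise_sigma),
                        nrow(base), ncol(base))
      }
      for (k in seq_len(config$n_fish)) {
        f <- draw_ellipse(f, paths[[k]][i, 1], paths[[k]][i, 2],
                          config$fish_axes_px[1], config$fish_axes_px[2],
                          config$fish_intensity)
      }
      frames[[i]] <- pmin(pmax(f, 0), 255)
    }
    truth <- if (config$n_fish > 0) {
      do.call(rbind, lapply(seq_len(config$n_fish), function(k) {
        data.frame(frame = seq_len(config$n_frames) - 1L,
                   fish_id = k,
                   x = paths[[k]][, 1], y = paths[[k]][, 2])
      }))
    } else {
      data.frame(frame = integer(0), fish_id = integer(0),
                 x = numeric(0), y = numeric(0))
    }
    structure(
      list(stack = frame_stack(frames, config$frame_period_s),
           truth = truth, config = config),
      class = "tank_sim")
  })
}

#' Write / read ground-truth trajectories as CSV
#'
#' The CSV layout is `frame,fish_id,x,y` with 0-based frame indices, the
#' same layout used for tracker output.
#'
#' @param truth a ground-truth data.frame from [simulate_tank()].
#' @param path CSV file path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the data.frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth[, c("frame", "fish_id", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path)
}
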