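## Independent oracles used across the suite. These deliberately avoid the
## code paths they check: brute-force enumeration instead of the assignment
## solver, direct pixel counting instead of the segmenter, a re-implemented
## motion update instead of the simulator internals, and numerical
## integration instead of the closed-form t distribution.

# Exhaustive minimum-total-distance matching: enumerates every injective
# mapping of tracks to detections within the gate, keeps the matchings of
# maximal size, then minimal cost, then the lexicographically smallest
# mapping vector (NA sorts last). Feasible only for tiny instances.
brute_force_assign <- function(prev, det, max_gate_px = 50) {
  P <- rbind(prev)
  Q <- rbind(det)
  n <- nrow(P)
  m <- nrow(Q)
  D <- sqrt(outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2)
  best <- list(size = -1L, cost = Inf, mapping = rep(NA_integer_, n))
  lex_less <- function(a, b) {
    ka <- ifelse(is.na(a), m + 1L, a)
    kb <- ifelse(is.na(b), m + 1L, b)
    for (i in seq_along(ka)) {
      if (ka[i] < kb[i]) return(TRUE)
      if (ka[i] > kb[i]) return(FALSE)
    }
    FALSE
  }
  recurse <- function(i, mapping, used) {
    if (i > n) {
      matched <- which(!is.na(mapping))
      size <- length(matched)
      cost <- if (size > 0) sum(D[cbind(matched, mapping[matched])]) else 0
      better <- size > best$size ||
        (size == best$size && cost < best$cost - 1e-12) ||
        (size == best$size && abs(cost - best$cost) <= 1e-12 &&
           lex_less(mapping, best$mapping))
      if (better) best <<- list(size = size, cost = cost, mapping = mapping)
      return(invisible())
    }
    for (j in seq_len(m)) {
      if (!used[j] && D[i, j] <= max_gate_px) {
        mapping[i] <- j
        used[j] <- TRUE
        recurse(i + 1L, mapping, used)
        used[j] <- FALSE
      }
    }
    mapping[i] <- NA_integer_
    recurse(i + 1L, mapping, used)
  }
  recurse(1L, rep(NA_integer_, n), rep(FALSE, max(m, 1L)))
  best
}

# Re-implementation of the correlated-random-walk update used by
# simulate_tank(), consuming the RNG in the same documented order, so a
# fixed seed lets us predict the ground truth without touching the
# renderer.
replay_tank_paths <- function(config) {
  ax <- config$fish_axes_px[1]
  ay <- config$fish_axes_px[2]
  lo <- c(ax, ay)
  hi <- c(config$width_px - 1 - ax, config$height_px - 1 - ay)
  ctr <- c((config$width_px - 1) / 2, (config$height_px - 1) / 2)
  bounce <- function(p, v) {
    for (d in 1:2) {
      while (p[d] < lo[d] || p[d] > hi[d]) {
        if (p[d] < lo[d]) p[d] <- 2 * lo[d] - p[d] else p[d] <- 2 * hi[d] - p[d]
        v[d] <- -v[d]
      }
    }
    list(p = p, v = v)
  }
  set.seed(config$seed)
  n <- config$n_fish
  pos <- vel <- vector("list", n)
  for (k in seq_len(n)) {
    pos[[k]] <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
    if (is.null(config$init_speed_px)) {
      vel[[k]] <- rnorm(2, 0, config$speed_scale_px)
    } else {
      th <- runif(1, 0, 2 * pi)
      vel[[k]] <- config$init_speed_px * c(cos(th), sin(th))
    }
  }
  paths <- lapply(seq_len(n), function(k) {
    m <- matrix(NA_real_, config$n_frames, 2)
    m[1, ] <- pos[[k]]
    m
  })
  for (i in seq_len(config$n_frames)[-1]) {
    for (k in seq_len(n)) {
      pert <- rnorm(2, 0, config$speed_scale_px)
      drift <- c(0, 0)
      if (config$center_bias > 0) {
        dvec <- ctr - pos[[k]]
        r <- sqrt(sum(dvec^2))
        if (r > 1e-9) drift <- config$center_bias * dvec / r
      }
      v <- config$velocity_persistence * vel[[k]] + pert + drift
      b <- bounce(pos[[k]] + v, v)
      pos[[k]] <- b$p
      vel[[k]] <- b$v
      paths[[k]][i, ] <- pos[[k]]
    }
  }
  paths
}

# Two-tailed Student-t tail probability by numerical integration of the
# density (no pt()).
t_p_two_tailed_numint <- function(t_stat, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-12,
                       abs.tol = 0)$value
}

# Rasterize a filled disk the same way an independent reader would: count
# integer pixel centers within the radius.
disk_pixels <- function(cx, cy, r, width, height) {
  xs <- 0:(width - 1)
  ys <- 0:(height - 1)
  g <- expand.grid(x = xs, y = ys)
  g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, , drop = FALSE]
}

# Paint disks onto a flat background, returning a frame matrix.
disk_frame <- function(width, height, background, disks, intensity) {
  f <- matrix(background, height, width)
  for (d in disks) {
    px <- disk_pixels(d[1], d[2], d[3], width, height)
    f[cbind(px$y + 1L, px$x + 1L)] <- intensity
  }
  f
}

# Match tracker identities to ground-truth fish by mean distance over the
# clip, then report per-frame identity flips (swaps) and centroid errors.
compare_tracks_to_truth <- function(tracks, truth) {
  ids <- sort(unique(tracks$fish_id))
  fish <- sort(unique(truth$fish_id))
  frames <- sort(intersect(unique(tracks$frame), unique(truth$frame)))
  tr <- lapply(ids, function(k) {
    d <- tracks[tracks$fish_id == k, ]
    d[match(frames, d$frame), ]
  })
  gt <- lapply(fish, function(k) {
    d <- truth[truth$fish_id == k, ]
    d[match(frames, d$frame), ]
  })
  # per-frame nearest ground-truth fish for every track
  nearest <- sapply(tr, function(t1) {
    dmat <- sapply(gt, function(g1) sqrt((t1$x - g1$x)^2 + (t1$y - g1$y)^2))
    apply(rbind(dmat), 1, which.min)
  })
  nearest <- rbind(nearest)
  swaps <- sum(apply(nearest, 2, function(v) sum(diff(v) != 0)))
  errs <- unlist(lapply(seq_along(tr), function(i) {
    g1 <- gt[[nearest[1, i]]]
    sqrt((tr[[i]]$x - g1$x)^2 + (tr[[i]]$y - g1$y)^2)
  }))
  list(swaps = swaps, max_error = max(errs), mean_error = mean(errs))
}
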