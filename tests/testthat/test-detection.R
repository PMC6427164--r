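make_stack <- function(frames, period = 1) frame_stack(frames, period)

test_that("cropping shifts the origin and preserves pixel values", {
  set.seed(1)
  frames <- replicate(3, matrix(sample(0:255, 640 * 480, TRUE), 480, 640),
                      simplify = FALSE)
  stack <- make_stack(frames)
  cropped <- crop_frames(stack, x0 = 130, y0 = 50, side = 380)
  expect_equal(cropped$width_px, 380L)
  expect_equal(cropped$height_px, 380L)
  expect_equal(cropped$n_frames, 3L)
  # pixel at cropped (0,0) is original (130,50); spot-check a few more
  expect_equal(cropped$frames[[1]][1, 1], frames[[1]][51, 131])
  expect_equal(cropped$frames[[2]][11, 21], frames[[2]][61, 151])
  # full-frame crop is the identity
  full <- crop_frames(make_stack(list(matrix(1:100, 10, 10))), 0, 0, 10)
  expect_equal(full$frames[[1]], matrix(1:100, 10, 10))
  expect_error(crop_frames(stack, 300, 200, 380), "outside")
})

test_that("background reference is the per-pixel median", {
  f <- matrix(7, 5, 5)
  expect_equal(train_background(make_stack(list(f, f, f)))$reference, f)
  g1 <- matrix(10, 4, 4); g2 <- matrix(10, 4, 4); g3 <- matrix(200, 4, 4)
  expect_equal(train_background(make_stack(list(g1, g2, g3)))$reference,
               matrix(10, 4, 4))
  expect_error(train_background(make_stack(list(f, f))), "at least 3")
})

test_that("background training recovers the clean background under fish", {
  # noise-free tank where the moving fish covers each pixel in < 50% of
  # frames: the median must equal the generator's background exactly
  cfg <- tank_sim_config(n_frames = 80, n_fish = 1, noise_sigma = 0,
                         speed_scale_px = 4, width_px = 100,
                         height_px = 100, fish_axes_px = c(6, 3),
                         background_intensity = 200, seed = 3)
  sim <- simulate_tank(cfg)
  covered <- Reduce(`+`, lapply(sim$stack$frames, function(f) f != 200))
  expect_true(max(covered) < 40)  # precondition of the check
  model <- train_background(sim$stack)
  expect_equal(model$reference, matrix(200, 100, 100))
})

test_that("a single disk is detected with exact area and centroid", {
  bg <- matrix(200, 200, 200)
  frame <- disk_frame(200, 200, 200, list(c(100, 120, 5)), 40)
  model <- structure(list(reference = bg, diff_threshold = 50,
                          width_px = 200L, height_px = 200L),
                     class = "background_model")
  det <- detect(frame, model, min_area = 10, median_filter = FALSE)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 100), 0.5)
  expect_lt(abs(det$y - 120), 0.5)
  expect_equal(det$area, nrow(disk_pixels(100, 120, 5, 200, 200)))
  # frame identical to reference -> nothing
  expect_equal(nrow(detect(bg, model)), 0L)
})

test_that("two well-separated disks give two sorted detections", {
  frame <- disk_frame(200, 200, 200,
                      list(c(60, 150, 5), c(60, 90, 5)), 40)
  model <- structure(list(reference = matrix(200, 200, 200),
                          diff_threshold = 50,
                          width_px = 200L, height_px = 200L),
                     class = "background_model")
  det <- detect(frame, model, min_area = 10, median_filter = FALSE)
  expect_equal(nrow(det), 2L)
  expect_equal(det$y, c(90, 60) + c(0, 90), tolerance = 0.5)  # sorted by y
  expect_true(det$y[1] < det$y[2])
  expect_equal(det$area,
               rep(nrow(disk_pixels(60, 90, 5, 200, 200)), 2))
})

test_that("segmentation uses 8-connectivity", {
  f <- matrix(0, 10, 10)
  f[3, 3] <- 255; f[4, 4] <- 255  # touch only diagonally
  model <- structure(list(reference = matrix(0, 10, 10),
                          diff_threshold = 100,
                          width_px = 10L, height_px = 10L),
                     class = "background_model")
  det <- detect(f, model, min_area = 1, median_filter = FALSE)
  expect_equal(nrow(det), 1L)
  expect_equal(det$area, 2L)
})

test_that("detection counts are monotone in min_area and threshold", {
  set.seed(5)
  frame <- disk_frame(150, 150, 200,
                      list(c(40, 40, 3), c(100, 100, 6), c(40, 110, 9)), 40)
  frame <- frame + matrix(rnorm(150 * 150, 0, 4), 150, 150)
  ref <- matrix(200, 150, 150)
  n_det <- function(thr, min_area) {
    model <- structure(list(reference = ref, diff_threshold = thr,
                            width_px = 150L, height_px = 150L),
                       class = "background_model")
    nrow(detect(frame, model, min_area = min_area))
  }
  areas <- c(1, 10, 30, 120, 400)
  counts_a <- vapply(areas, function(a) n_det(50, a), numeric(1))
  expect_false(is.unsorted(rev(counts_a)))
  thresholds <- c(20, 50, 100, 140, 200)
  counts_t <- vapply(thresholds, function(t) n_det(t, 5), numeric(1))
  expect_false(is.unsorted(rev(counts_t)))
})

test_that("centroids are translation-equivariant", {
  base <- disk_frame(120, 120, 200, list(c(40, 50, 5)), 40)
  ref <- matrix(200, 120, 120)
  shifted <- disk_frame(120, 120, 200, list(c(40 + 17, 50 + 9, 5)), 40)
  model <- function(r) structure(
    list(reference = r, diff_threshold = 50,
         width_px = 120L, height_px = 120L),
    class = "background_model")
  d0 <- detect(base, model(ref), min_area = 5)
  d1 <- detect(shifted, model(ref), min_area = 5)
  expect_equal(d1$x - d0$x, 17)
  expect_equal(d1$y - d0$y, 9)
})

test_that("the 3x3 median filter matches a direct median computation", {
  for (seed in 1:4) {
    set.seed(seed)
    H <- sample(5:15, 1); W <- sample(5:15, 1)
    m <- matrix(sample(0:255, H * W, TRUE), H, W)
    pad <- m[c(1, seq_len(H), H), c(1, seq_len(W), W)]
    ref <- matrix(NA_real_, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      ref[i, j] <- stats::median(pad[i:(i + 2), j:(j + 2)])
    }
    expect_equal(smftrack:::median_filter3(m), ref)
  }
})

test_that("noise-free synthetic video yields one accurate detection per fish", {
  cfg <- tank_sim_config(n_frames = 40, n_fish = 2, noise_sigma = 0,
                         width_px = 200, height_px = 200,
                         fish_axes_px = c(8, 4), seed = 11)
  sim <- simulate_tank(cfg)
  model <- train_background(sim$stack)
  det <- detect_stack(sim$stack, model)
  expect_true(all(table(det$frame) == 2))
  # each detection within 1 px of some ground-truth fish
  for (f in unique(det$frame)) {
    d <- det[det$frame == f, ]
    g <- sim$truth[sim$truth$frame == f, ]
    for (r in seq_len(nrow(d))) {
      err <- min(sqrt((g$x - d$x[r])^2 + (g$y - d$y[r])^2))
      expect_lt(err, 1)
    }
  }
})

test_that("detection CSV round trips", {
  det <- data.frame(frame = c(0L, 0L, 2L), x = c(1.5, 3, 9.25),
                    y = c(2, 4.5, 7), area = c(21L, 33L, 40L))
  p <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, p)
  expect_equal(read_detections(p), det)
})
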