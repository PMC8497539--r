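test_that("rgb_to_hsv matches the hexcone convention", {
  expect_equal(unname(rgb_to_hsv(c(1, 0, 0))[, 1]), c(0, 1, 1))
  expect_equal(unname(rgb_to_hsv(c(0, 1, 0))[, 1]), c(120, 1, 1))
  expect_equal(unname(rgb_to_hsv(c(0, 0, 1))[, 1]), c(240, 1, 1))
  gray <- rgb_to_hsv(c(0.5, 0.5, 0.5))
  expect_equal(unname(gray[2:3, 1]), c(0, 0.5))
  expect_error(rgb_to_hsv(c(1.2, 0, 0)), "\\[0, 1\\]")
  expect_error(rgb_to_hsv(c(-0.1, 0, 0)), "\\[0, 1\\]")
  # array form agrees with per-pixel form
  arr <- array(runif(2 * 3 * 3), c(2, 3, 3))
  ha <- rgb_to_hsv(arr)
  expect_equal(ha[1, 2, ], rgb_to_hsv(arr[1, 2, ])[, 1],
               ignore_attr = TRUE)
})

test_that("default hue bands are pairwise disjoint", {
  specs <- default_color_specs()
  rngs <- t(sapply(specs, function(s) s$hue_range))
  rngs <- rngs[order(rngs[, 1]), ]
  expect_true(all(rngs[-1, 1] > rngs[-nrow(rngs), 2]))
})

test_that("segment_colors finds the nine disks and nothing in a gray frame", {
  gray <- array(0.5, c(60, 80, 3))
  expect_equal(nrow(segment_colors(gray)), 0)

  ses <- generate_session(mini_spec(noise_sd = 0))
  blobs <- segment_colors(session_frame(ses, 1))
  expect_equal(nrow(blobs), 9)
  # centroids within 0.5 px of ground truth (nearest-match pairing)
  for (m in 1:9) {
    d <- sqrt((blobs$x_px - ses$truth$x_px[1, m])^2 +
                (blobs$y_px - ses$truth$y_px[1, m])^2)
    expect_lt(min(d), 0.5)
  }
  # expected color multiset
  expect_equal(sort(table(blobs$color), decreasing = TRUE),
               sort(table(ses$spec$color_assignment), decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("blobs below min_area_px are excluded", {
  frame <- array(0.5, c(60, 80, 3))
  # a 3x3 pure blue square: area 9 < 20
  frame[10:12, 10:12, ] <- rep(c(0.1, 0.2, 0.9), each = 9)
  expect_equal(nrow(segment_colors(frame, min_area_px = 20)), 0)
  expect_equal(nrow(segment_colors(frame, min_area_px = 9)), 1)
})

test_that("init_roi clips, auto-detects, and rejects degenerate boxes", {
  ses <- generate_session(mini_spec(noise_sd = 0))
  f1 <- session_frame(ses, 1)
  full <- c(1, 1, 240, 180)
  expect_equal(init_roi(f1, roi = full), full)
  expect_equal(init_roi(f1, roi = c(-10, -10, 500, 500)), full)
  expect_error(init_roi(f1, roi = c(10, 10, 10, 40)), "zero or negative")
  expect_error(init_roi(f1, roi = c(300, 10, 320, 40)), "outside")
  auto <- init_roi(f1)
  expect_true(all(ses$truth$x_px[1, ] >= auto[1] &
                    ses$truth$x_px[1, ] <= auto[3]))
  expect_true(all(ses$truth$y_px[1, ] >= auto[2] &
                    ses$truth$y_px[1, ] <= auto[4]))
  expect_error(init_roi(array(0.5, c(40, 40, 3))), "no colored blobs")
})

test_that("assign_grid labels a full grid geometrically, input-order invariant", {
  centers <- expand.grid(x = c(50, 100, 150), y = c(40, 80, 120))
  blobs <- data.frame(color = "blue", x_px = centers$x, y_px = centers$y,
                      area_px = 300, equiv_diameter_px = 20)
  canonical <- c("H1", "H2", "H3", "M1", "M2", "M3", "L1", "L2", "L3")
  a <- assign_grid(blobs)
  expect_equal(a$label, canonical)
  expect_equal(a$x_px, rep(c(50, 100, 150), 3))
  expect_equal(a$y_px, rep(c(40, 80, 120), each = 3))
  expect_true(all(a$recognized))
  for (s in 1:5) {
    perm <- sample(9)
    ap <- assign_grid(blobs[perm, ])
    expect_equal(ap, a)
  }
})

test_that("assign_grid recovers missing markers by distance to the reference", {
  ref <- as.matrix(expand.grid(x = c(50, 100, 150), y = c(40, 80, 120)))
  rownames(ref) <- c("H1", "H2", "H3", "M1", "M2", "M3", "L1", "L2", "L3")
  set.seed(21)
  for (drop in c(5, 2, 9)) {  # M2, H2, L3
    jit <- ref[-drop, ] + matrix(rnorm(16, 0, 2), 8, 2)
    blobs <- data.frame(color = "green", x_px = jit[, 1], y_px = jit[, 2],
                        area_px = 300, equiv_diameter_px = 20)
    a <- assign_grid(blobs, reference = ref)
    expect_false(a$recognized[drop])
    expect_true(all(a$recognized[-drop]))
    # agrees with exhaustive minimum-distance assignment
    oracle <- brute_force_assignment(jit, ref)
    expect_equal(a$x_px[oracle], unname(jit[, 1]))
    expect_equal(a$y_px[oracle], unname(jit[, 2]))
  }
})

test_that("more than nine blobs keeps the nine largest with a warning", {
  centers <- expand.grid(x = c(50, 100, 150), y = c(40, 80, 120))
  blobs <- data.frame(color = "blue", x_px = centers$x, y_px = centers$y,
                      area_px = 300, equiv_diameter_px = 20)
  extra <- rbind(blobs, data.frame(color = "blue", x_px = 200, y_px = 160,
                                   area_px = 25, equiv_diameter_px = 6))
  expect_warning(a <- assign_grid(extra), "9 largest")
  expect_true(all(a$x_px <= 150))
})

test_that("the Hungarian solver matches brute force on random costs", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:4, 1); m <- n + sample(0:3, 1)
    cost <- matrix(runif(n * m), n, m)
    asg <- swallowtrack:::hungarian_assign(cost)
    expect_equal(sort(unique(asg)), sort(asg))  # injective
    best <- min(vapply(all_injections(n, m), function(cols)
      sum(cost[cbind(seq_len(n), cols)]), numeric(1)))
    expect_equal(sum(cost[cbind(seq_len(n), asg)]), best, tolerance = 1e-12)
  }
})

test_that("tracking a clean session recovers every centroid within 0.5 px", {
  ses <- generate_session(mini_spec(noise_sd = 0, seed = 2))
  tr <- track_markers(ses)
  expect_true(all(tr$recognized))
  gt <- truth_long(ses)
  err <- sqrt((tr$x_px - gt$x_px)^2 + (tr$y_px - gt$y_px)^2)
  expect_lt(sqrt(mean(err^2)), 0.5)
  # determinism
  tr2 <- track_markers(ses)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
})

test_that("tracking is invariant to the order of the color specs", {
  ses <- generate_session(mini_spec(noise_sd = 0, seed = 4))
  tr1 <- track_markers(ses, colors = default_color_specs())
  tr2 <- track_markers(ses, colors = rev(default_color_specs()))
  expect_equal(as.data.frame(tr1), as.data.frame(tr2))
})

test_that("a fully dropped-out marker is never recognized", {
  p <- setNames(c(1, rep(0, 8)), c("H1", "H2", "H3", "M1", "M2", "M3",
                                   "L1", "L2", "L3"))
  ses <- generate_session(mini_spec(dropout_prob = p, seed = 6))
  tr <- track_markers(ses)
  expect_true(all(!tr$recognized[tr$label == "H1"]))
  expect_true(mean(tr$recognized[tr$label != "H1"]) > 0.99)
})

test_that("an illumination spike blanks one frame without harming neighbors", {
  ses <- generate_session(mini_spec(noise_sd = 0, seed = 8))
  frames <- lapply(1:40, function(f) session_frame(ses, f))
  spike <- 20
  frames[[spike]] <- pmin(frames[[spike]] * 0.15 + 0.85, 1)  # washed out
  tr <- track_markers(frames, fps = 10)
  expect_true(all(!tr$recognized[tr$frame == spike]))
  expect_true(all(tr$recognized[tr$frame %in% c(spike - 1, spike + 1)]))
})

test_that("tracks survive a CSV round trip", {
  ses <- generate_session(tiny_spec(seed = 2))
  tr <- track_markers(ses)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path, fps = attr(tr, "fps"))
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "n_frames"), attr(tr, "n_frames"))
})
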