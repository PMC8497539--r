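test_that("waveforms are zero outside their window and peak at the stated value", {
  for (shape in c("raised_cosine", "triangular")) {
    wf <- swallow_waveform(7.5, onset_s = 3, duration_s = 4, shape = shape)
    t <- seq(0, 12, by = 0.01)
    d <- waveform_displacement(wf, t)
    expect_true(all(d[t < 3 | t > 7] == 0))
    expect_equal(max(d), 7.5, tolerance = 1e-6)
    expect_true(all(d >= 0))
  }
  # raised cosine is continuous at the window edges
  wf <- swallow_waveform(5, 1, 2)
  eps <- 1e-8
  expect_lt(abs(waveform_displacement(wf, 1 + eps)), 1e-6)
  expect_lt(abs(waveform_displacement(wf, 3 - eps)), 1e-6)
})

test_that("ground-truth excursions follow the waveform peaks and row gains", {
  # no motion -> all excursions zero
  ses0 <- generate_session(mini_spec(peaks = c(0, 0, 0)))
  expect_equal(ses0$truth$excursion_mm, c(0, 0, 0))
  expect_equal(ses0$truth$session_distance_mm, 0)

  # equal 6 mm peaks, unit gains -> distance 6 (median of equal values)
  ses6 <- generate_session(mini_spec(peaks = c(6, 6, 6)))
  expect_equal(ses6$truth$excursion_mm, c(6, 6, 6), tolerance = 1e-9)
  expect_equal(ses6$truth$session_distance_mm, 6, tolerance = 1e-9)

  # row gains scale the mean-trajectory excursion by the mean gain
  g <- c(H = 1, M = 0.5, L = 0.25)
  sesg <- generate_session(mini_spec(peaks = c(6, 6, 6), row_gain = g))
  expect_equal(sesg$truth$session_distance_mm, 6 * mean(g), tolerance = 1e-9)
})

test_that("sessions are bit-identical under a fixed seed", {
  a <- generate_session(mini_spec(seed = 42, dropout_prob = 0.1,
                                  illumination_drift = 0.1))
  b <- generate_session(mini_spec(seed = 42, dropout_prob = 0.1,
                                  illumination_drift = 0.1))
  expect_identical(a$truth, b$truth)
  for (f in c(1, 25, 120))
    expect_identical(session_frame(a, f), session_frame(b, f))
  c2 <- generate_session(mini_spec(seed = 43))
  expect_false(identical(a$truth$x_px, c2$truth$x_px))
})

test_that("overlapping swallow windows are rejected", {
  wfs <- list(swallow_waveform(6, 2, 4), swallow_waveform(6, 5, 4),
              swallow_waveform(6, 9, 2))
  expect_error(session_spec(schedule = mini_schedule(), waveforms = wfs,
                            duration_s = 12, fps = 10),
               "overlap")
  expect_error(session_spec(duration_s = 10), "past the end")
})

test_that("dropout mask honors dropout_prob", {
  ses <- generate_session(mini_spec(dropout_prob = 0))
  expect_true(all(ses$truth$recognized))
  ses2 <- generate_session(mini_spec(dropout_prob = 0.5, seed = 3))
  frac <- mean(ses2$truth$recognized)
  expect_gt(frac, 0.4); expect_lt(frac, 0.6)
  # per-marker dropout: only H1 suppressed
  p <- setNames(c(1, rep(0, 8)), c("H1", "H2", "H3", "M1", "M2", "M3",
                                   "L1", "L2", "L3"))
  ses3 <- generate_session(mini_spec(dropout_prob = p))
  expect_true(all(!ses3$truth$recognized[, "H1"]))
  expect_true(all(ses3$truth$recognized[, -1]))
})

test_that("ground-truth mm quantities are invariant to image rescaling", {
  s1 <- mini_spec(peaks = c(4, 7, 5), seed = 9)
  s2 <- mini_spec(peaks = c(4, 7, 5), seed = 9)
  s2$image_size_px <- s2$image_size_px * 2
  s2$scale_mm_per_px <- s2$scale_mm_per_px / 2
  a <- generate_session(s1); b <- generate_session(s2)
  expect_equal(a$truth$excursion_mm, b$truth$excursion_mm, tolerance = 1e-9)
  expect_equal(a$truth$session_distance_mm, b$truth$session_distance_mm,
               tolerance = 1e-9)
})

test_that("session distance is nondecreasing in every row gain", {
  base <- c(H = 0.4, M = 0.4, L = 0.4)
  d0 <- generate_session(mini_spec(row_gain = base))$truth$session_distance_mm
  for (rw in c("H", "M", "L")) {
    up <- base; up[rw] <- 0.9
    d1 <- generate_session(mini_spec(row_gain = up))$truth$session_distance_mm
    expect_gte(d1, d0)
  }
})

test_that("written sessions round-trip through the PNG + manifest layout", {
  dir <- withr::local_tempdir()
  ses <- generate_session(tiny_spec(seed = 5))
  write_session(ses, dir, subject = "S01", timepoint = "pre")
  files <- list.files(dir)
  expect_equal(sum(grepl("^frame_\\d{6}\\.png$", files)), ses$n_frames)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$fps, 2.5)
  expect_equal(man$subject, "S01")
  gt <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(gt), ses$n_frames * 9)
  # frames read back identical to frames rendered
  fs <- frame_source(dir)
  expect_equal(fs$n_frames, ses$n_frames)
  expect_equal(fs$get(3), session_frame(ses, 3), tolerance = 1 / 255)
})

test_that("synthetic trials reproduce their target distributions", {
  # degenerate: zero variance -> exact means
  eff <- default_arm_params()
  for (a in c("AA+", "AA-")) {
    eff[[a]]$pre[2] <- 0
    for (tp in names(eff[[a]]$chg)) eff[[a]]$chg[[tp]][2] <- 0
  }
  tt <- generate_trial(n_per_arm = 2, effect = eff, seed = 1)
  expect_equal(unique(tt$distance_pre[tt$arm == "AA+"]), 3.92)
  expect_equal(unique(tt$distance_2wk[tt$arm == "AA-"] -
                        tt$distance_pre[tt$arm == "AA-"]), 2.04)

  # stochastic: published change parameters recovered within 3 SE at n = 44
  tt2 <- generate_trial(n_per_arm = 44, seed = 7)
  tt2 <- baseline_subtract(tt2)
  pars <- default_arm_params()
  for (a in c("AA+", "AA-")) for (tp in c("2wk", "3mo", "9mo")) {
    ms <- pars[[a]]$chg[[tp]]
    obs <- mean(tt2[[paste0("change_", tp)]][tt2$arm == a])
    expect_lt(abs(obs - ms[1]), 3 * ms[2] / sqrt(44))
  }
  expect_error(generate_trial(n_per_arm = 1), "at least 2")
})

test_that("null trials keep the baseline-subtracted t-test near its nominal level", {
  # both arms share one distribution; p should exceed 0.05 in >= 90/100 seeds
  eff <- default_arm_params()
  eff[["AA+"]] <- eff[["AA-"]]
  hits <- vapply(1:100, function(s) {
    tt <- baseline_subtract(generate_trial(n_per_arm = 200, effect = eff,
                                           seed = 1000 + s))
    res <- ttest_independent(tt$change_2wk[tt$arm == "AA+"],
                             tt$change_2wk[tt$arm == "AA-"])
    res$p > 0.05
  }, logical(1))
  expect_gte(sum(hits), 90)
})
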