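# Shared fixtures: compact sessions that keep the full protocol structure
# (three scheduled swallows) at a fraction of the full recording size.

mini_schedule <- function() guide_schedule(c(2, 5.5, 9), swallow_s = 2,
                                           window_s = 3)

# 240x180 px, 10 fps, 12 s: enough resolution for 20 px markers.
mini_spec <- function(peaks = c(6, 6, 6), seed = 1, ...) {
  sch <- mini_schedule()
  session_spec(image_size_px = c(240, 180), scale_mm_per_px = 0.25,
               grid_centers_mm = default_grid_centers(col_gap_mm = 12,
                                                      row_gap_mm = 9),
               schedule = sch,
               waveforms = schedule_waveforms(sch, peaks),
               duration_s = 12, fps = 10, seed = seed, ...)
}

# Tiny sessions for pipeline tests: 96x96 px, 2.5 fps.
tiny_spec <- function(peaks = c(5, 5, 5), seed = 1, ...) {
  sch <- mini_schedule()
  session_spec(image_size_px = c(96, 96), scale_mm_per_px = 0.5,
               grid_centers_mm = default_grid_centers(col_gap_mm = 10,
                                                      row_gap_mm = 8),
               schedule = sch,
               waveforms = schedule_waveforms(sch, peaks),
               duration_s = 12, fps = 2.5, seed = seed,
               place_jitter_mm = 0.5, ...)
}

# Truth centroids of a session in the same frame-major order as the long
# tracks data.frame.
truth_long <- function(session) {
  data.frame(frame = rep(seq_len(session$n_frames), each = 9),
             label = rep(colnames(session$truth$y_px),
                         session$n_frames),
             x_px = as.vector(t(session$truth$x_px)),
             y_px = as.vector(t(session$truth$y_px)))
}

# Brute-force minimum-total-distance labeling of <= 9 blobs against nine
# reference positions: enumerates every injective blob -> label map.
brute_force_assignment <- function(blobs_xy, ref_xy) {
  k <- nrow(blobs_xy)
  labs <- seq_len(nrow(ref_xy))
  best <- NULL; best_cost <- Inf
  perm_rec <- function(chosen, remaining) {
    if (length(chosen) == k) {
      cost <- sum(sqrt(rowSums((blobs_xy - ref_xy[chosen, , drop = FALSE])^2)))
      if (cost < best_cost) { best_cost <<- cost; best <<- chosen }
      return(invisible())
    }
    for (l in remaining) perm_rec(c(chosen, l), setdiff(remaining, l))
  }
  perm_rec(integer(0), labs)
  best
}

# Exact two-sided Mann-Whitney p by full enumeration of all rank splits.
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Build a marker_tracks object directly from matrices (n_frames x 9).
tracks_from_matrices <- function(y, x = NULL, recognized = NULL,
                                 diameter_px = 20, fps = 10) {
  n <- nrow(y); labs <- colnames(y)
  if (is.null(labs)) labs <- c("H1", "H2", "H3", "M1", "M2", "M3",
                               "L1", "L2", "L3")[seq_len(ncol(y))]
  if (is.null(x)) x <- y * 0 + 100
  if (is.null(recognized)) recognized <- !is.na(y)
  df <- data.frame(frame = rep(seq_len(n), each = ncol(y)),
                   label = rep(labs, n),
                   recognized = as.vector(t(recognized)),
                   x_px = as.vector(t(x)), y_px = as.vector(t(y)),
                   diameter_px = diameter_px)
  df$x_px[!df$recognized] <- NA; df$y_px[!df$recognized] <- NA
  structure(df, class = c("marker_tracks", "data.frame"),
            n_frames = n, fps = fps, roi = NULL)
}

# All injective maps 1..n -> 1..m as a list of integer vectors.
all_injections <- function(n, m) {
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == n) { out[[length(out) + 1]] <<- chosen; return() }
    for (j in remaining) rec(c(chosen, j), setdiff(remaining, j))
  }
  rec(integer(0), seq_len(m))
  out
}

# Seeded draw helper for parameterized cases.
with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
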