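# Minimum-cost assignment (Hungarian algorithm, shortest augmenting paths).
# cost: n x m matrix with n <= m. Returns an integer vector of length n
# giving the column assigned to each row. O(n^2 m); n <= 9 here.
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)   # p[j+1]: row matched to col j
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(INF, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]; p[j0 + 1] <- p[j1 + 1]; j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Label detected blobs on the 3x3 marker grid
#'
#' With a full set of nine blobs, labeling is purely geometric: blobs are
#' split into three rows by ascending y (topmost row = H), and within each
#' row ordered by ascending x into columns 1..3 (ties broken by ascending x
#' then area). With fewer than nine blobs, labels are recovered by
#' minimum-total-distance matching against reference positions (normally the
#' previous frame's labeled centroids); labels left unmatched are reported
#' unrecognized.
#'
#' If more than nine blobs survive filtering, the nine largest are kept with
#' a warning.
#'
#' @param blobs Data.frame from [segment_colors()].
#' @param reference Optional 9x2 matrix (columns x, y; rownames H1..L3) of
#'   expected positions, required when fewer than nine blobs are present.
#' @return A 9-row data.frame (label, recognized, x_px, y_px,
#'   equiv_diameter_px), one row per grid label in canonical order.
#' @export
assign_grid <- function(blobs, reference = NULL) {
  empty <- data.frame(label = MARKER_LABELS, recognized = FALSE,
                      x_px = NA_real_, y_px = NA_real_,
                      equiv_diameter_px = NA_real_)
  if (nrow(blobs) == 0) return(empty)
  if (nrow(blobs) > 9) {
    warning("more than 9 candidate blobs; keeping the 9 largest")
    blobs <- blobs[order(-blobs$area_px), ][1:9, ]
  }
  if (nrow(blobs) == 9) {
    ord <- order(blobs$y_px, blobs$x_px, blobs$area_px)
    rows <- split(ord, rep(1:3, each = 3))      # top/middle/bottom by y
    lab_order <- unlist(lapply(rows, function(r) r[order(blobs$x_px[r])]))
    out <- blobs[lab_order, c("x_px", "y_px", "equiv_diameter_px")]
    return(data.frame(label = MARKER_LABELS, recognized = TRUE, out,
                      row.names = NULL))
  }
  if (is.null(reference))
    stop("fewer than 9 blobs; reference positions are required")
  stopifnot(nrow(reference) == 9)
  reference <- reference[MARKER_LABELS, , drop = FALSE]
  cost <- outer(seq_len(nrow(blobs)), 1:9, Vectorize(function(b, l)
    sqrt((blobs$x_px[b] - reference[l, 1])^2 +
           (blobs$y_px[b] - reference[l, 2])^2)))
  asg <- hungarian_assign(cost)
  out <- empty
  out$recognized[asg] <- TRUE
  out$x_px[asg] <- blobs$x_px
  out$y_px[asg] <- blobs$y_px
  out$equiv_diameter_px[asg] <- blobs$equiv_diameter_px
  out
}
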