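TIMEPOINTS <- c("pre", "2wk", "3mo", "9mo")

#' Construct a trial table of per-subject session distances
#'
#' One row per subject: arm assignment, covariates, and the session distance
#' (mm) at baseline and the three follow-ups. Distances may be missing.
#'
#' @param df Data.frame with columns `id`, `arm` (two levels, canonically
#'   `"AA+"` / `"AA-"` for with / without the anti-adhesion agent), `sex`
#'   (`"M"`/`"F"`), `age_years`, `height_cm`, `distance_pre`,
#'   `distance_2wk`, `distance_3mo`, `distance_9mo`.
#' @param validate If `TRUE`, enforce the eligibility window (age 20-65) and
#'   nonnegative distances.
#' @return A `trial_table` (data.frame subclass) with an empty exclusion log.
#' @export
trial_table <- function(df, validate = TRUE) {
  need <- c("id", "arm", "sex", "age_years", "height_cm",
            paste0("distance_", TIMEPOINTS))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trial table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate subject ids")
  if (length(unique(df$arm)) != 2)
    stop("exactly two arms are required")
  if (validate) {
    if (any(df$age_years < 20 | df$age_years > 65, na.rm = TRUE))
      stop("age outside the 20-65 eligibility window")
    d <- as.matrix(df[, paste0("distance_", TIMEPOINTS)])
    if (any(d < 0, na.rm = TRUE)) stop("negative session distance")
  }
  structure(as.data.frame(df), class = c("trial_table", "data.frame"),
            exclusions = data.frame(id = character(), arm = character(),
                                    reason = character(),
                                    statistic = numeric()))
}

#' Baseline-subtracted distance changes
#'
#' Swallowing amplitude differs between individuals; subtracting each
#' subject's own pre-operative distance removes that inter-individual
#' variation, leaving the surgery-attributable change. Changes may be
#' negative.
#'
#' @param table A [trial_table()].
#' @return The table with added columns `change_2wk`, `change_3mo`,
#'   `change_9mo` (follow-up minus baseline; `NA` where either is missing).
#'   Subjects with no baseline are flagged in attribute `missing_baseline`.
#' @examples
#' # a control-arm subject: pre 4.1 mm, 2 weeks 6.14 mm -> change 2.04 mm
#' @export
baseline_subtract <- function(table) {
  for (tp in c("2wk", "3mo", "9mo")) {
    table[[paste0("change_", tp)]] <-
      table[[paste0("distance_", tp)]] - table$distance_pre
  }
  attr(table, "missing_baseline") <- table$id[is.na(table$distance_pre)]
  table
}

# Two-sided Grubbs critical value for the most extreme deviation in a
# normal sample of size n at significance alpha.
grubbs_critical <- function(n, alpha) {
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Screen out statistically extreme subjects per arm
#'
#' Within each arm independently, subjects whose screening value is
#' statistically extreme are removed before the endpoint comparisons. Two
#' modes: `"grubbs"` applies the Grubbs test iteratively at significance
#' `alpha` (stopping when the most extreme value is no longer significant);
#' `"fixed"` removes exactly `k` most-extreme subjects per arm (largest
#' standardized deviation, recomputed after each removal).
#'
#' @param table A [trial_table()] (after [baseline_subtract()] if the
#'   screening endpoint is a change).
#' @param endpoint Column screened, or `"change_mean"` for each subject's
#'   mean baseline-subtracted change across available follow-ups.
#' @param alpha Grubbs significance level, in (0, 1).
#' @param mode `"grubbs"` or `"fixed"`.
#' @param k Removals per arm in fixed mode.
#' @return The table with extreme subjects removed; removals appended to the
#'   `exclusions` attribute with the Grubbs statistic at removal time.
#' @export
exclude_outliers <- function(table, endpoint = "change_mean", alpha = 0.05,
                             mode = c("grubbs", "fixed"), k = 5) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  vals <- screening_values(table, endpoint)
  log <- attr(table, "exclusions")
  drop_ids <- character()
  for (a in unique(table$arm)) {
    in_arm <- table$arm == a & !is.na(vals)
    if (sum(in_arm) < 3) next
    ids <- table$id[in_arm]; x <- vals[in_arm]
    repeat {
      n <- length(x)
      if (n < 3) break
      s <- stats::sd(x)
      if (s == 0) break
      g <- abs(x - mean(x)) / s
      i <- which.max(g)
      stop_now <- if (mode == "grubbs") g[i] <= grubbs_critical(n, alpha)
                  else length(drop_ids[drop_ids %in% table$id[table$arm == a]]) >= k
      if (stop_now) break
      log <- rbind(log, data.frame(id = ids[i], arm = a,
                                   reason = paste0(mode, " outlier on ",
                                                   endpoint),
                                   statistic = g[i]))
      drop_ids <- c(drop_ids, ids[i])
      ids <- ids[-i]; x <- x[-i]
    }
  }
  out <- table[!(table$id %in% drop_ids), , drop = FALSE]
  out <- structure(as.data.frame(out),
                   class = c("trial_table", "data.frame"),
                   exclusions = log,
                   missing_baseline = attr(table, "missing_baseline"))
  out
}

# Per-subject screening values for outlier exclusion.
screening_values <- function(table, endpoint) {
  if (endpoint == "change_mean") {
    if (!"change_2wk" %in% names(table)) table <- baseline_subtract(table)
    rowMeans(table[, c("change_2wk", "change_3mo", "change_9mo")],
             na.rm = TRUE)
  } else {
    if (!endpoint %in% names(table) && grepl("^change_", endpoint))
      table <- baseline_subtract(table)
    if (!endpoint %in% names(table)) stop("unknown endpoint: ", endpoint)
    table[[endpoint]]
  }
}

#' Two-sample t-test (closed form, raw samples or printed summaries)
#'
#' Computes the independent two-sample t-test from first principles so that
#' it can run equally from raw samples or from published mean / SD / n
#' summaries. Both the pooled-variance (Student) and the unpooled
#' (Welch-Satterthwaite) variants are available.
#'
#' Degenerate samples with zero pooled standard error follow the convention
#' p = 1 when the means are equal (no evidence of a difference), p = 0
#' otherwise, with a warning.
#'
#' @param x,y Raw numeric samples, each of length >= 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param endpoint Label carried into the result.
#' @return An object of class `group_comparison`: per-arm n/mean/sd, the
#'   test name, t statistic, degrees of freedom and two-sided p.
#' @examples
#' ttest_independent(c(1, 2, 3), c(4, 5, 6), variant = "pooled")  # p ~ 0.021
#' @export
ttest_independent <- function(x, y, variant = c("welch", "pooled"),
                              endpoint = NA_character_) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least two values")
  ttest_from_summary(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y),
                     variant = variant, endpoint = endpoint)
}

#' @rdname ttest_independent
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Summary statistics per arm.
#' @export
ttest_from_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                               variant = c("welch", "pooled"),
                               endpoint = NA_character_) {
  variant <- match.arg(variant)
  stopifnot(n_x >= 2, n_y >= 2, sd_x >= 0, sd_y >= 0)
  if (variant == "pooled") {
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2)
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
    df <- n_x + n_y - 2
  } else {
    vx <- sd_x^2 / n_x; vy <- sd_y^2 / n_y
    se <- sqrt(vx + vy)
    df <- if (se > 0) (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
          else n_x + n_y - 2
  }
  if (se == 0) {
    warning("zero variance in both samples; p set by convention")
    t <- 0
    p <- if (mean_x == mean_y) 1 else 0
    if (mean_x != mean_y) t <- sign(mean_x - mean_y) * Inf
  } else {
    t <- (mean_x - mean_y) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(endpoint = endpoint,
                 test = paste0("t (", variant, ")"),
                 n = c(n_x, n_y), mean = c(mean_x, mean_y),
                 sd = c(sd_x, sd_y),
                 statistic = t, df = df, p = p),
            class = "group_comparison")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison used for the subgroup analyses. The U statistic uses
#' mid-ranks for ties. The p-value is exact when the combined sample size is
#' at most 20 and there are no ties, otherwise a normal approximation with
#' tie and continuity corrections is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param endpoint Label carried into the result.
#' @return A `group_comparison` with the U statistic (for `x` relative to
#'   `y`) and the two-sided p.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, endpoint = NA_character_) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2) <= 20 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  structure(list(endpoint = endpoint,
                 test = if (exact) "Mann-Whitney U (exact)"
                        else "Mann-Whitney U (normal approx.)",
                 n = c(n1, n2), mean = c(mean(x), mean(y)),
                 sd = c(stats::sd(x), stats::sd(y)),
                 statistic = u, df = NA_real_, p = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d)\n",
              x$endpoint %||% "comparison",
              x$mean[1], x$sd[1], x$n[1], x$mean[2], x$sd[2], x$n[2]))
  cat(sprintf("  %s: statistic = %.4g, p = %.4g\n", x$test, x$statistic, x$p))
  invisible(x)
}
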