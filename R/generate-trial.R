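#' Published endpoint summaries used as simulation defaults
#'
#' Per-arm mean and SD of the session distance (mm) at baseline and of the
#' baseline-subtracted changes at the three follow-ups, with 44 analyzed
#' subjects per arm, for the anti-adhesion (`"AA+"`) and control (`"AA-"`)
#' arms of the thyroidectomy trial the measurement system was built for.
#' These are the default effect parameters of [generate_trial()].
#'
#' @return Nested list with components `AA+` and `AA-`, each holding
#'   `pre = c(mean, sd)` and `chg`, a list over `"2wk"`, `"3mo"`, `"9mo"`;
#'   plus `n_per_arm`.
#' @export
default_arm_params <- function() {
  list(`AA+` = list(pre = c(3.92, 1.19),
                    chg = list(`2wk` = c(2.96, 2.10),
                               `3mo` = c(1.80, 1.52),
                               `9mo` = c(1.45, 1.66))),
       `AA-` = list(pre = c(4.10, 1.38),
                    chg = list(`2wk` = c(2.04, 1.85),
                               `3mo` = c(1.10, 1.55),
                               `9mo` = c(0.58, 1.50))),
       n_per_arm = 44)
}

#' Published endpoint summary table of the reference trial
#'
#' Mean and SD of the session distance per arm (anti-adhesion vs control,
#' 44 analyzed subjects each) at each timepoint, both as actual distances
#' and as baseline-subtracted changes, as reported for the thyroidectomy
#' trial the measurement system was developed on. Useful for
#' summary-statistic reproduction with [ttest_from_summary()].
#'
#' @return Data.frame with columns `endpoint`, `type`, `mean_aa`, `sd_aa`,
#'   `mean_ctrl`, `sd_ctrl`, `n_per_arm`, `reported_p`.
#' @export
published_endpoint_summaries <- function() {
  data.frame(
    endpoint = c("pre", "2wk", "3mo", "9mo", "chg_2wk", "chg_3mo", "chg_9mo"),
    type = rep(c("actual", "baseline-subtracted"), c(4, 3)),
    mean_aa   = c(3.92, 6.87, 5.71, 5.41, 2.96, 1.80, 1.45),
    sd_aa     = c(1.19, 2.07, 1.96, 2.04, 2.10, 1.52, 1.66),
    mean_ctrl = c(4.10, 6.14, 5.20, 4.69, 2.04, 1.10, 0.58),
    sd_ctrl   = c(1.38, 1.84, 1.65, 1.72, 1.85, 1.55, 1.50),
    n_per_arm = 44,
    reported_p = c(0.512, 0.087, 0.189, 0.084, 0.035, 0.037, 0.013))
}

#' Generate a synthetic randomized trial table
#'
#' Draws per-subject baseline distances and baseline-subtracted changes from
#' normal distributions (one set of mean/SD parameters per arm), builds the
#' follow-up distances as baseline + change, and samples covariates: sex
#' (36% male, as observed), age from a normal (48, 9.5) truncated to the
#' 20-65 eligibility window, and height from a normal (160, 7) truncated to
#' 140-185 cm. Arms are exactly balanced.
#'
#' Follow-up distances are floored at zero (skin cannot move a negative
#' distance); with the default parameters the floor is hit in well under 1%
#' of draws.
#'
#' @param n_per_arm Subjects per arm (>= 2).
#' @param effect Arm parameters shaped like [default_arm_params()].
#' @param seed Integer RNG seed.
#' @return A [trial_table()].
#' @export
generate_trial <- function(n_per_arm = default_arm_params()$n_per_arm,
                           effect = default_arm_params(), seed = 1L) {
  if (!is.numeric(n_per_arm) || n_per_arm < 2)
    stop("n_per_arm must be at least 2")
  arms <- setdiff(names(effect), "n_per_arm")
  stopifnot(length(arms) == 2)
  with_seed(seed, {
    rows <- lapply(arms, function(a) {
      p <- effect[[a]]
      pre <- stats::rnorm(n_per_arm, p$pre[1], p$pre[2])
      pre <- pmax(pre, 0)
      chg <- lapply(p$chg, function(ms)
        stats::rnorm(n_per_arm, ms[1], ms[2]))
      data.frame(id = sprintf("A%d_%03d", match(a, arms), seq_len(n_per_arm)),
                 arm = a,
                 sex = sample(c("M", "F"), n_per_arm, replace = TRUE,
                              prob = c(0.36, 0.64)),
                 age_years = round(rnorm_trunc(n_per_arm, 48, 9.5, 20, 65)),
                 height_cm = round(rnorm_trunc(n_per_arm, 160, 7, 140, 185), 1),
                 distance_pre = pre,
                 distance_2wk = pmax(pre + chg[["2wk"]], 0),
                 distance_3mo = pmax(pre + chg[["3mo"]], 0),
                 distance_9mo = pmax(pre + chg[["9mo"]], 0))
    })
    trial_table(do.call(rbind, rows))
  })
}

# Truncated normal by resampling out-of-range draws.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Write / read a trial table as CSV
#'
#' @param table A [trial_table()].
#' @param path CSV path.
#' @param validate Passed to [trial_table()] on read.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   a `trial_table`.
#' @export
write_trial_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path, validate = TRUE) {
  trial_table(utils::read.csv(path), validate = validate)
}
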