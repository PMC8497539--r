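make_table <- function(n = 10, seed = 3, arm_shift = 0) {
  with_seed_helper(seed, {
    arms <- rep(c("AA+", "AA-"), each = n)
    pre <- runif(2 * n, 3, 5)
    data.frame(id = sprintf("S%03d", 1:(2 * n)), arm = arms,
               sex = sample(c("M", "F"), 2 * n, TRUE),
               age_years = sample(20:65, 2 * n, TRUE),
               height_cm = round(runif(2 * n, 150, 175)),
               distance_pre = pre,
               distance_2wk = pre + 2 + arm_shift * (arms == "AA+"),
               distance_3mo = pre + 1.5,
               distance_9mo = pre + 1)
  })
}

test_that("baseline subtraction gives follow-up minus baseline, negatives allowed", {
  df <- make_table(n = 3)
  df$distance_pre[1] <- 4.1; df$distance_2wk[1] <- 6.14
  df$distance_pre[2] <- 5; df$distance_9mo[2] <- 4
  df$distance_pre[3] <- df$distance_3mo[3]
  tt <- baseline_subtract(trial_table(df))
  expect_equal(tt$change_2wk[1], 2.04)
  expect_equal(tt$change_9mo[2], -1)
  expect_equal(tt$change_3mo[3], 0)
  # missing baseline flagged and excluded from change endpoints
  df$distance_pre[4] <- NA
  tt2 <- baseline_subtract(trial_table(df))
  expect_true(df$id[4] %in% attr(tt2, "missing_baseline"))
  expect_true(is.na(tt2$change_2wk[4]))
})

test_that("grubbs screening removes an injected extreme and spares clean arms", {
  df <- make_table(n = 25, seed = 5)
  tt <- baseline_subtract(trial_table(df))
  # inject a subject 6 SD beyond the arm mean of the screening endpoint
  v <- tt$change_2wk[tt$arm == "AA+"]
  bump <- mean(v) + 6 * sd(tt$change_2wk)
  victim <- which(tt$arm == "AA+")[1]
  tt$distance_2wk[victim] <- tt$distance_pre[victim] + bump
  tt$distance_3mo[victim] <- tt$distance_pre[victim] + bump
  tt$distance_9mo[victim] <- tt$distance_pre[victim] + bump
  tt <- baseline_subtract(tt)
  out <- exclude_outliers(tt, endpoint = "change_mean", alpha = 0.05)
  expect_false(tt$id[victim] %in% out$id)
  expect_true(tt$id[victim] %in% attr(out, "exclusions")$id)
  # an all-equal arm yields no exclusions
  df2 <- make_table(n = 10)
  df2$distance_2wk <- df2$distance_pre + 2
  out2 <- exclude_outliers(baseline_subtract(trial_table(df2)),
                           endpoint = "change_2wk")
  expect_equal(nrow(attr(out2, "exclusions")), 0)
  expect_error(exclude_outliers(tt, alpha = 1.2), "alpha")
})

test_that("fixed-count screening turns 49 per arm into 44 analyzed", {
  df <- make_table(n = 49, seed = 9)
  # add heterogeneous changes so extremes exist
  df$distance_2wk <- df$distance_pre + rnorm(98, 2, 1.5)
  tt <- baseline_subtract(trial_table(df))
  out <- exclude_outliers(tt, endpoint = "change_2wk", mode = "fixed", k = 5)
  expect_equal(sum(out$arm == "AA+"), 44)
  expect_equal(sum(out$arm == "AA-"), 44)
  expect_equal(nrow(attr(out, "exclusions")), 10)
})

test_that("the pooled t-test matches its closed form and stats::t.test", {
  res <- ttest_independent(c(1, 2, 3), c(4, 5, 6), variant = "pooled")
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.021312, tolerance = 1e-4)
  # cross-check both variants against stats::t.test on random samples
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5)
    rp <- ttest_independent(x, y, "pooled")
    ro <- t.test(x, y, var.equal = TRUE)
    expect_equal(rp$p, ro$p.value, tolerance = 1e-12)
    expect_equal(rp$statistic, unname(ro$statistic), tolerance = 1e-12)
    rw <- ttest_independent(x, y, "welch")
    ow <- t.test(x, y)
    expect_equal(rw$p, ow$p.value, tolerance = 1e-12)
    expect_equal(rw$df, unname(ow$parameter), tolerance = 1e-9)
  }
  # identical samples: no evidence of a difference
  expect_equal(ttest_independent(c(1, 2, 3), c(1, 2, 3), "pooled")$p, 1)
  # zero variance in both arms
  expect_warning(r0 <- ttest_from_summary(2, 0, 5, 2, 0, 5), "convention")
  expect_equal(r0$p, 1)
  expect_warning(r1 <- ttest_from_summary(2, 0, 5, 3, 0, 5), "convention")
  expect_equal(r1$p, 0)
})

test_that("summary-input t-tests equal raw-sample t-tests with those summaries", {
  set.seed(17)
  for (i in 1:8) {
    x <- rnorm(sample(5:30, 1), 2, 1.5); y <- rnorm(sample(5:30, 1), 1, 2)
    for (v in c("pooled", "welch")) {
      raw <- ttest_independent(x, y, v)
      summ <- ttest_from_summary(mean(x), sd(x), length(x),
                                 mean(y), sd(y), length(y), v)
      expect_equal(summ$p, raw$p, tolerance = 1e-12)
      expect_equal(summ$statistic, raw$statistic, tolerance = 1e-12)
    }
  }
})

test_that("published 9-month change summaries reproduce a significant difference", {
  r <- ttest_from_summary(1.45, 1.66, 44, 0.58, 1.50, 44, "pooled")
  expect_lt(r$p, 0.05)
  expect_equal(r$p, 0.013, tolerance = 0.15)
})

test_that("Mann-Whitney U handles the hand-checkable cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  # identical multisets: U = n^2 / 2 by symmetry
  r2 <- mann_whitney_u(c(1, 2, 5), c(1, 2, 5))
  expect_equal(r2$statistic, 4.5)
  r3 <- mann_whitney_u(1, 2)
  expect_equal(r3$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("the exact Mann-Whitney branch matches full enumeration", {
  set.seed(23)
  for (n1 in 1:5) for (n2 in 1:(10 - n1)) {
    x <- sample(100, n1); y <- sample(200, n2) + 0.5  # no ties by construction
    r <- mann_whitney_u(x, y)
    expect_equal(r$p, enumerate_mw_p(x, y), tolerance = 1e-12,
                 label = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("mean of differences equals difference of means on complete tables", {
  tt <- baseline_subtract(generate_trial(n_per_arm = 30, seed = 2))
  for (a in c("AA+", "AA-")) for (tp in c("2wk", "3mo", "9mo")) {
    sel <- tt$arm == a
    expect_equal(mean(tt[[paste0("change_", tp)]][sel]),
                 mean(tt[[paste0("distance_", tp)]][sel]) -
                   mean(tt$distance_pre[sel]),
                 tolerance = 1e-12)
  }
})

test_that("run_trial_analysis produces the full endpoint and subgroup layout", {
  tt <- generate_trial(n_per_arm = 30, seed = 4)
  rep <- run_trial_analysis(tt, outlier_mode = "none")
  expect_s3_class(rep, "trial_report")
  expect_equal(nrow(rep$endpoints), 7)
  expect_equal(sum(rep$endpoints$type == "baseline-subtracted"), 3)
  expect_true(all(rep$endpoints$p >= 0 & rep$endpoints$p <= 1))
  # strata partition: age dichotomized at 50, height at 160
  n_young <- sum(tt$age_years < 50 & tt$arm == "AA+")
  sub <- rep$subgroups
  row <- sub[sub$stratum_var == "age" & sub$stratum == "20-49" &
               sub$endpoint == "distance_pre", ]
  expect_equal(row$n_1, n_young)
  n_tall <- sum(tt$height_cm >= 160 & tt$arm == "AA-")
  row2 <- sub[sub$stratum_var == "height" & sub$stratum == ">160 cm" &
                sub$endpoint == "distance_pre", ]
  expect_equal(row2$n_2, n_tall)
  expect_true(all(grepl("Mann-Whitney", sub$test[!is.na(sub$p)])))
  # single arm is rejected
  expect_error(run_trial_analysis(as.data.frame(tt)[tt$arm == "AA+", ]),
               "two arms")
  # an empty stratum is reported as not testable, not an error
  tt$sex <- "F"
  rep2 <- run_trial_analysis(tt, outlier_mode = "none")
  male <- rep2$subgroups[rep2$subgroups$stratum == "M", ]
  expect_true(all(is.na(male$p)))
  expect_true(all(male$test == "not testable"))
})

test_that("tests record which subjects entered them", {
  tt <- generate_trial(n_per_arm = 10, seed = 6)
  df <- as.data.frame(tt)
  df$distance_9mo[1] <- NA
  rep <- run_trial_analysis(trial_table(df), outlier_mode = "none")
  expect_false(df$id[1] %in% rep$test_subjects[["change_9mo"]])
  expect_true(df$id[1] %in% rep$test_subjects[["distance_pre"]])
})
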