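#' Run the full two-arm endpoint analysis
#'
#' Reproduces the structure of the trial's result tables: per-timepoint arm
#' summaries and independent t-tests for the raw ("actual") distances and
#' for the baseline-subtracted changes, plus subgroup tables (sex, age
#' dichotomized at `strata$age_years`, height at `strata$height_cm`) in
#' which arms are compared by Mann-Whitney U tests. Outlier screening is
#' applied per arm before testing; every test records the ids of the
#' subjects that entered it.
#'
#' @param table A [trial_table()].
#' @param ttest_variant `"welch"` or `"pooled"`.
#' @param outlier_mode `"grubbs"`, `"fixed"`, or `"none"`.
#' @param outlier_alpha Grubbs significance level.
#' @param outlier_k Removals per arm in fixed mode.
#' @param outlier_endpoint Screening endpoint (see [exclude_outliers()]).
#' @param strata List with dichotomization boundaries `age_years` (default
#'   50: strata 20-49 vs 50-69) and `height_cm` (default 160).
#' @param p_adjust `"none"` (default, matching per-endpoint reporting) or
#'   `"holm"` applied within each results table.
#' @return An object of class `trial_report`: data.frames `endpoints` and
#'   `subgroups`, the exclusion log, the analyzed table, and per-test
#'   subject ids.
#' @export
run_trial_analysis <- function(table,
                               ttest_variant = c("welch", "pooled"),
                               outlier_mode = c("grubbs", "fixed", "none"),
                               outlier_alpha = 0.05, outlier_k = 5,
                               outlier_endpoint = "change_mean",
                               strata = list(age_years = 50, height_cm = 160),
                               p_adjust = c("none", "holm")) {
  ttest_variant <- match.arg(ttest_variant)
  outlier_mode <- match.arg(outlier_mode)
  p_adjust <- match.arg(p_adjust)
  if (!inherits(table, "trial_table")) table <- trial_table(table)
  arms <- unique(table$arm)
  arms <- if ("AA+" %in% arms) c("AA+", setdiff(arms, "AA+")) else sort(arms)

  table <- baseline_subtract(table)
  if (outlier_mode != "none")
    table <- exclude_outliers(table, endpoint = outlier_endpoint,
                              alpha = outlier_alpha, mode = outlier_mode,
                              k = outlier_k)

  endpoints <- c(paste0("distance_", TIMEPOINTS),
                 paste0("change_", c("2wk", "3mo", "9mo")))
  subjects <- list()
  rows <- lapply(endpoints, function(ep) {
    x <- table[[ep]][table$arm == arms[1]]
    y <- table[[ep]][table$arm == arms[2]]
    ids <- c(table$id[table$arm == arms[1] & !is.na(table[[ep]])],
             table$id[table$arm == arms[2] & !is.na(table[[ep]])])
    subjects[[ep]] <<- ids
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(endpoint = ep,
                        type = if (grepl("^change", ep)) "baseline-subtracted"
                               else "actual",
                        n_1 = length(x), mean_1 = mean(x), sd_1 = sd(x),
                        n_2 = length(y), mean_2 = mean(y), sd_2 = sd(y),
                        test = "not testable", statistic = NA_real_,
                        p = NA_real_))
    }
    res <- ttest_independent(x, y, variant = ttest_variant, endpoint = ep)
    data.frame(endpoint = ep,
               type = if (grepl("^change", ep)) "baseline-subtracted"
                      else "actual",
               n_1 = res$n[1], mean_1 = res$mean[1], sd_1 = res$sd[1],
               n_2 = res$n[2], mean_2 = res$mean[2], sd_2 = res$sd[2],
               test = res$test, statistic = res$statistic, p = res$p)
  })
  endpoints_df <- do.call(rbind, rows)

  strata_def <- list(
    sex = list(M = table$sex == "M", F = table$sex == "F"),
    age = stats::setNames(
      list(table$age_years < strata$age_years,
           table$age_years >= strata$age_years),
      c(sprintf("20-%d", strata$age_years - 1),
        sprintf("%d-69", strata$age_years))),
    height = stats::setNames(
      list(table$height_cm < strata$height_cm,
           table$height_cm >= strata$height_cm),
      c(sprintf("<%g cm", strata$height_cm),
        sprintf(">%g cm", strata$height_cm))))
  sub_endpoints <- c("distance_pre", paste0("change_", c("2wk", "3mo", "9mo")))
  sub_rows <- list()
  for (sv in names(strata_def)) for (lv in names(strata_def[[sv]])) {
    sel <- strata_def[[sv]][[lv]] & !is.na(strata_def[[sv]][[lv]])
    for (ep in sub_endpoints) {
      x <- table[[ep]][sel & table$arm == arms[1]]
      y <- table[[ep]][sel & table$arm == arms[2]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) == 0 || length(y) == 0) {
        sub_rows[[length(sub_rows) + 1]] <-
          data.frame(stratum_var = sv, stratum = lv, endpoint = ep,
                     n_1 = length(x), mean_1 = NA_real_, sd_1 = NA_real_,
                     n_2 = length(y), mean_2 = NA_real_, sd_2 = NA_real_,
                     test = "not testable", statistic = NA_real_,
                     p = NA_real_)
        next
      }
      res <- mann_whitney_u(x, y, endpoint = ep)
      subjects[[paste(sv, lv, ep, sep = ":")]] <-
        table$id[sel & !is.na(table[[ep]])]
      sub_rows[[length(sub_rows) + 1]] <-
        data.frame(stratum_var = sv, stratum = lv, endpoint = ep,
                   n_1 = res$n[1], mean_1 = res$mean[1], sd_1 = res$sd[1],
                   n_2 = res$n[2], mean_2 = res$mean[2], sd_2 = res$sd[2],
                   test = res$test, statistic = res$statistic, p = res$p)
    }
  }
  subgroups_df <- do.call(rbind, sub_rows)

  if (p_adjust == "holm") {
    endpoints_df$p_adj <- stats::p.adjust(endpoints_df$p, "holm")
    subgroups_df$p_adj <- stats::p.adjust(subgroups_df$p, "holm")
  }

  structure(list(arms = arms, endpoints = endpoints_df,
                 subgroups = subgroups_df,
                 exclusions = attr(table, "exclusions"),
                 analyzed = table, test_subjects = subjects,
                 settings = list(ttest_variant = ttest_variant,
                                 outlier_mode = outlier_mode,
                                 outlier_alpha = outlier_alpha,
                                 outlier_k = outlier_k,
                                 outlier_endpoint = outlier_endpoint,
                                 strata = strata, p_adjust = p_adjust)),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, digits = 3, ...) {
  cat(sprintf("trial report: %s (n=%d) vs %s (n=%d), %d excluded\n",
              x$arms[1], sum(x$analyzed$arm == x$arms[1]),
              x$arms[2], sum(x$analyzed$arm == x$arms[2]),
              nrow(x$exclusions)))
  cat("\nEndpoints:\n")
  print(cbind(x$endpoints[, c("endpoint", "type")],
              round(x$endpoints[, c("mean_1", "sd_1", "mean_2", "sd_2",
                                    "p")], digits)),
        row.names = FALSE)
  cat("\nSubgroups (Mann-Whitney):\n")
  print(cbind(x$subgroups[, c("stratum_var", "stratum", "endpoint",
                              "n_1", "n_2")],
              p = round(x$subgroups$p, digits)), row.names = FALSE)
  invisible(x)
}

#' Write a trial report to disk
#'
#' Writes `endpoints.csv`, `subgroups.csv`, `exclusions.csv` and a
#' `report.json` bundling everything, into `dir`.
#'
#' @param report A `trial_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_trial_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$endpoints, file.path(dir, "endpoints.csv"),
                   row.names = FALSE)
  utils::write.csv(report$subgroups, file.path(dir, "subgroups.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(arms = report$arms, endpoints = report$endpoints,
         subgroups = report$subgroups, exclusions = report$exclusions,
         settings = report$settings),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
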