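#' Build the paired-accuracy and group-comparison report
#'
#' Consumes tidy morphometry results (one row per specimen, modality, ROI
#' and parameter) and emits, per ROI, the table-style accuracy report: for
#' pooled data (ALL) and each group, ex vivo and in vivo mean +/- SD, mean
#' paired difference, mean per-specimen percent difference, the paired
#' t-test p-value with a significance star at p < 0.05, agreement regression
#' (slope, intercept, R^2), Bland-Altman limits (+/- 2 SD) and Lilliefors
#' normality of the differences. A group-comparison table (SHAM vs DMM per
#' modality) is attached. No multiple-testing correction is applied
#' (per-parameter p < 0.05).
#'
#' @param results Data frame with columns `specimen`, `group`, `modality`,
#'   `roi`, `parameter`, `value` (modalities `ex_vivo` and `in_vivo`).
#' @param rois ROI labels to report (default: all present).
#' @param mc_replicates,seed Monte-Carlo settings for the normality test.
#' @param var_equal Pooled-variance group test when `TRUE`.
#' @return An `accuracy_report`: list with `tables` (per ROI, rows =
#'   parameter x cohort), `group_comparison`, and `bland_altman` summary.
#' @export
build_report <- function(results, rois = NULL, mc_replicates = 2000L,
                         seed = 1L, var_equal = TRUE) {
  need <- c("specimen", "group", "modality", "roi", "parameter", "value")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  if (is.null(rois)) rois <- unique(results$roi)

  tables <- list()
  ba_rows <- list()
  gc_rows <- list()
  for (r in rois) {
    sub <- results[results$roi == r, ]
    rows <- list()
    for (par in unique(sub$parameter)) {
      ss <- sub[sub$parameter == par, ]
      wide <- merge(
        ss[ss$modality == "ex_vivo", c("specimen", "group", "value")],
        ss[ss$modality == "in_vivo", c("specimen", "value")],
        by = "specimen", suffixes = c("_ex", "_in"))
      if (nrow(wide) < nrow(ss) / 2)
        stop("missing modality for some specimens: ", par, " / ", r)
      cohorts <- c(list(ALL = wide),
                   split(wide, wide$group))
      for (cn in names(cohorts)) {
        w <- cohorts[[cn]]
        if (nrow(w) < 3) next
        pa <- paired_accuracy(w$value_ex, w$value_in)
        reg <- if (sd(w$value_ex) > 0)
          linear_regression(w$value_ex, w$value_in)
        else list(slope = NA, intercept = NA, r2 = NA, p = NA)
        ba <- bland_altman(w$value_ex, w$value_in)
        nt <- if (!pa$degenerate && nrow(w) >= 4)
          normality_test(w$value_in - w$value_ex,
                         replicates = mc_replicates, seed = seed)
        else list(statistic = NA, p = NA)
        rows[[length(rows) + 1]] <- data.frame(
          roi = r, parameter = par, cohort = cn, n = pa$n,
          ex_mean = mean(w$value_ex), ex_sd = sd(w$value_ex),
          in_mean = mean(w$value_in), in_sd = sd(w$value_in),
          diff_mean = pa$diff_mean, diff_sd = pa$diff_sd,
          pdiff_mean = pa$pdiff_mean, pdiff_sd = pa$pdiff_sd,
          paired_p = pa$p,
          significant = !is.na(pa$p) & pa$p < 0.05,
          slope = reg$slope, intercept = reg$intercept, r2 = reg$r2,
          regression_p = reg$p,
          ba_mean = ba$mean_diff, ba_lower = ba$lower, ba_upper = ba$upper,
          normality_p = nt$p, stringsAsFactors = FALSE)
        if (cn == "ALL")
          ba_rows[[length(ba_rows) + 1]] <- data.frame(
            roi = r, parameter = par, mean_diff = ba$mean_diff,
            lower = ba$lower, upper = ba$upper,
            n_outside = ba$n_outside, stringsAsFactors = FALSE)
      }
      # between-group contrast per modality
      groups <- unique(wide$group)
      if (length(groups) == 2) {
        for (mod in c("ex", "in")) {
          v <- wide[[paste0("value_", mod)]]
          ga <- v[wide$group == groups[1]]
          gb <- v[wide$group == groups[2]]
          if (length(ga) >= 2 && length(gb) >= 2 &&
              (sd(ga) > 0 || sd(gb) > 0)) {
            gc <- group_compare(ga, gb, var_equal = var_equal)
            gc_rows[[length(gc_rows) + 1]] <- data.frame(
              roi = r, parameter = par,
              modality = if (mod == "ex") "ex_vivo" else "in_vivo",
              group_a = groups[1], group_b = groups[2],
              mean_a = gc$mean_a, sd_a = gc$sd_a,
              mean_b = gc$mean_b, sd_b = gc$sd_b,
              percent_diff = gc$percent_diff, p = gc$p,
              significant = gc$p < 0.05, stringsAsFactors = FALSE)
          }
        }
      }
    }
    tables[[r]] <- do.call(rbind, rows)
  }
  structure(list(tables = tables,
                 group_comparison = if (length(gc_rows))
                   do.call(rbind, gc_rows) else NULL,
                 bland_altman = if (length(ba_rows))
                   do.call(rbind, ba_rows) else NULL,
                 footer = "No multiple-testing correction applied; per-parameter p < 0.05."),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 3, ...) {
  for (r in names(x$tables)) {
    cat("== ROI:", r, "==\n")
    t <- x$tables[[r]]
    show <- t[, c("parameter", "cohort", "ex_mean", "ex_sd", "in_mean",
                  "in_sd", "diff_mean", "pdiff_mean", "paired_p", "r2")]
    show$star <- ifelse(t$significant, "*", "")
    print(format(show, digits = digits), row.names = FALSE)
    cat("\n")
  }
  if (!is.null(x$group_comparison)) {
    cat("== Group comparison ==\n")
    print(format(x$group_comparison[, c("roi", "parameter", "modality",
                                        "percent_diff", "p", "significant")],
                 digits = digits), row.names = FALSE)
  }
  cat(x$footer, "\n")
  invisible(x)
}

#' Write an accuracy report to CSV files
#'
#' One CSV per ROI table mirroring the report column order, plus the
#' Bland-Altman summary and group-comparison tables.
#'
#' @param report An `accuracy_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in names(report$tables)) {
    p <- file.path(dir, paste0("report_", gsub("[^a-z-]", "_", r), ".csv"))
    write.csv(report$tables[[r]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$bland_altman)) {
    p <- file.path(dir, "bland_altman.csv")
    write.csv(report$bland_altman, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$group_comparison)) {
    p <- file.path(dir, "group_comparison.csv")
    write.csv(report$group_comparison, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Bland-Altman plot
#'
#' Differences against means with the mean difference and +/- 2 SD limits.
#'
#' @param ex,iv Paired numeric vectors.
#' @param parameter Axis label.
#' @return Invisibly, the [bland_altman()] summary.
#' @export
plot_bland_altman <- function(ex, iv, parameter = "parameter") {
  ba <- bland_altman(ex, iv)
  m <- (ex + iv) / 2
  graphics::plot(m, iv - ex, xlab = paste("mean of methods:", parameter),
                 ylab = "in vivo - ex vivo", pch = 19)
  graphics::abline(h = c(ba$mean_diff, ba$lower, ba$upper),
                   lty = c(1, 2, 2))
  invisible(ba)
}
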