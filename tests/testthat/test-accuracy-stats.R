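test_that("paired accuracy reproduces hand arithmetic and the t oracle", {
  pa <- paired_accuracy(c(10, 20, 30), c(9, 22, 30))
  expect_equal(pa$diff_mean, mean(c(-1, 2, 0)))
  expect_equal(pa$pdiff_mean, mean(c(-10, 10, 0)))

  # percent difference is the mean of per-specimen ratios, not the ratio of
  # means: the two conventions must disagree on skewed data
  ex <- c(10, 100, 1000)
  iv <- c(5, 110, 1100)
  pa2 <- paired_accuracy(ex, iv)
  ratio_of_means <- 100 * (mean(iv) - mean(ex)) / mean(ex)
  expect_equal(pa2$pdiff_mean, mean(100 * (iv - ex) / ex))
  expect_gt(abs(pa2$pdiff_mean - ratio_of_means), 1)

  # closed-form t cross-check against the reference implementation
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(8, 50, 5)
    b <- a + rnorm(8, 1, 2)
    pa3 <- paired_accuracy(a, b)
    tt <- t.test(b, a, paired = TRUE)
    expect_equal(pa3$p, tt$p.value, tolerance = 1e-9)
    expect_equal(pa3$t, unname(tt$statistic), tolerance = 1e-9)
  }

  # identical pairs are flagged degenerate rather than given a p-value
  pad <- paired_accuracy(c(1, 2, 3), c(1, 2, 3))
  expect_true(pad$degenerate)
  expect_true(is.na(pad$p))

  expect_error(paired_accuracy(1:4, 1:3), "equal length")
  expect_error(paired_accuracy(1:2, 3:4), "at least 3")
})

test_that("paired t on shifted data equals one-sample t on the shift", {
  set.seed(8)
  x <- rnorm(10, 20, 3)
  d <- rnorm(10, 1, 0.5)
  pa <- paired_accuracy(x, x + d)
  one <- t.test(d)
  expect_equal(pa$p, one$p.value, tolerance = 1e-12)
})

test_that("regression recovers exact lines and is affine invariant", {
  x <- c(1, 2, 3, 5, 8)
  # an exact line triggers stats' perfect-fit warning by construction
  fit <- suppressWarnings(linear_regression(x, 2 * x + 1))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1)

  set.seed(12)
  xx <- rnorm(30)
  yy <- rnorm(30)     # independent: R^2 near zero
  expect_lt(linear_regression(xx, yy)$r2, 0.2)

  y2 <- 1.3 * xx + rnorm(30, 0, 0.4)
  r2a <- linear_regression(xx, y2)$r2
  r2b <- linear_regression(10 * xx - 4, 0.2 * y2 + 7)$r2
  expect_equal(r2a, r2b, tolerance = 1e-12)
  expect_error(linear_regression(rep(1, 5), 1:5), "zero variance")
})

test_that("Bland-Altman limits are the mean difference plus/minus 2 SD", {
  # differences with mean -5.3 and SD 2.4 give limits (-10.1, -0.5)
  d <- c(-5.3, -5.3 - 2.4, -5.3 + 2.4)
  stopifnot(abs(mean(d) + 5.3) < 1e-9, abs(sd(d) - 2.4) < 1e-9)
  ba <- bland_altman(rep(0, 3), d)
  expect_equal(ba$mean_diff, -5.3, tolerance = 1e-9)
  expect_equal(ba$lower, -10.1, tolerance = 1e-9)
  expect_equal(ba$upper, -0.5, tolerance = 1e-9)

  bac <- bland_altman(c(1, 2, 3), c(3, 4, 5))
  expect_equal(bac$lower, bac$upper)
  expect_equal(bac$mean_diff, 2)

  # at least 75% of points inside +/- 2 SD on any sample (Chebyshev)
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(40)
    b <- a + rexp(40) - 0.3
    ba2 <- bland_altman(a, b)
    expect_gte(1 - ba2$n_outside / 40, 0.75)
  }
})

test_that("Lilliefors statistic and tail behavior are sound", {
  set.seed(21)
  x <- rexp(100)
  nt <- normality_test(x, replicates = 2000, seed = 5)
  expect_lt(nt$p, 0.01)
  expect_gte(nt$statistic, 0)

  y <- rnorm(100)
  nty <- normality_test(y, replicates = 2000, seed = 5)
  expect_gt(nty$p, 0.01)

  # statistic agrees with the independent reference implementation
  if (requireNamespace("nortest", quietly = TRUE)) {
    expect_equal(nt$statistic, unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
  expect_error(normality_test(c(1, 1, 1, 1), seed = 1), "zero variance")
  expect_error(normality_test(c(1, 2, 3), seed = 1), "at least 4")
})

test_that("two-sample comparison matches t.test and is exchange-symmetric", {
  set.seed(14)
  a <- rnorm(8, 10, 2)
  b <- rnorm(8, 12, 2)
  gc <- group_compare(a, b)
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(gc$p, tt$p.value, tolerance = 1e-12)
  expect_equal(group_compare(b, a)$p, gc$p, tolerance = 1e-12)
  expect_equal(group_compare(a, a)$percent_diff, 0)

  gw <- group_compare(a, b, var_equal = FALSE)
  expect_equal(gw$p, t.test(b, a)$p.value, tolerance = 1e-12)
  expect_error(group_compare(rep(1, 3), rep(1, 3)), "degenerate")
})

test_that("a 2-SD shift at n = 8 is detected in most replicates", {
  hits <- 0
  set.seed(600)
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    a <- rnorm(8)
    b <- rnorm(8, mean = 2)
    hits <- hits + (group_compare(a, b)$p < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("the report reproduces identities and injected bias", {
  set.seed(50)
  n <- 8
  truth <- rnorm(2 * n, 37, 5)
  df <- expand.grid(specimen = sprintf("s%02d", 1:(2 * n)),
                    modality = c("ex_vivo", "in_vivo"),
                    stringsAsFactors = FALSE)
  df$group <- rep(rep(c("SHAM", "DMM"), each = n), 2)
  df$roi <- "trabecular-whole"
  df$parameter <- "BV/TV"
  df$value <- ifelse(df$modality == "ex_vivo", truth[match(df$specimen,
                                                           unique(df$specimen))],
                     0.85 * truth[match(df$specimen, unique(df$specimen))] +
                       rnorm(2 * n, 0, 0.3))

  rep <- build_report(df, mc_replicates = 500, seed = 2)
  tab <- rep$tables[["trabecular-whole"]]
  all_row <- tab[tab$cohort == "ALL", ]
  # linearity: diff column equals the difference of its own mean columns
  expect_equal(all_row$diff_mean, all_row$in_mean - all_row$ex_mean,
               tolerance = 1e-12)
  # injected -15% multiplicative bias is recovered with significance
  expect_lt(abs(all_row$pdiff_mean - (-15)), 2)
  expect_lt(all_row$paired_p, 0.05)
  expect_true(all_row$significant)
  # Bland-Altman limits symmetric about the mean difference
  expect_equal(all_row$ba_upper - all_row$ba_mean,
               all_row$ba_mean - all_row$ba_lower, tolerance = 1e-12)

  # identical modalities: zero differences and no stars
  df0 <- df
  df0$value[df0$modality == "in_vivo"] <-
    df0$value[df0$modality == "ex_vivo"]
  rep0 <- suppressWarnings(build_report(df0, mc_replicates = 200, seed = 2))
  t0 <- rep0$tables[["trabecular-whole"]]
  expect_true(all(t0$diff_mean == 0))
  expect_true(all(!t0$significant))
})

test_that("report CSVs round-trip through write_report", {
  df <- data.frame(
    specimen = rep(sprintf("s%d", 1:6), 2),
    group = rep(rep(c("SHAM", "DMM"), each = 3), 2),
    modality = rep(c("ex_vivo", "in_vivo"), each = 6),
    roi = "trabecular-whole", parameter = "Tb.Th",
    value = c(60:65, 62:67) + round(sin(1:12), 2), stringsAsFactors = FALSE)
  rep <- build_report(df, mc_replicates = 200, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "bland_altman.csv")))
  back <- read.csv(list.files(dir, "report_", full.names = TRUE)[1])
  expect_equal(back$diff_mean, rep$tables[[1]]$diff_mean, tolerance = 1e-9)
})
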