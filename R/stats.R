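#' Paired accuracy statistics between two modalities
#'
#' For specimen-matched measurements: mean and SD of the paired differences
#' (in - ex), mean and SD of the per-specimen percent differences
#' `100 * (in - ex) / ex` (the mean of ratios, not the ratio of means), and
#' the two-sided paired t-test p-value.
#'
#' @param ex,iv Numeric vectors matched by specimen (ex vivo reference and
#'   in vivo measurement).
#' @return List with `diff_mean`, `diff_sd`, `pdiff_mean`, `pdiff_sd`, `p`,
#'   `t`, `df`, `n` and `degenerate` (TRUE when the differences have zero
#'   variance, where the t statistic is undefined).
#' @export
paired_accuracy <- function(ex, iv) {
  if (length(ex) != length(iv)) stop("paired vectors must have equal length")
  n <- length(ex)
  if (n < 3) stop("need at least 3 pairs")
  d <- iv - ex
  pdiff <- 100 * d / ex
  out <- list(diff_mean = mean(d), diff_sd = sd(d),
              pdiff_mean = mean(pdiff), pdiff_sd = sd(pdiff), n = n,
              df = n - 1, degenerate = sd(d) == 0)
  if (out$degenerate) {
    out$t <- NA_real_
    out$p <- NA_real_
  } else {
    out$t <- mean(d) / (sd(d) / sqrt(n))
    out$p <- 2 * pt(-abs(out$t), df = n - 1)
  }
  out
}

#' Ordinary least-squares agreement regression
#'
#' @param x,y Numeric vectors (n >= 3); `x` must not be constant.
#' @return List with `slope`, `intercept`, `r2` (squared Pearson
#'   correlation) and two-sided slope `p`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = s$r.squared, p = unname(s$coefficients[2, 4]))
}

#' Bland-Altman agreement limits
#'
#' Mean paired difference and limits of agreement at exactly +/- 2 SD of
#' the differences (the reporting convention adopted here, rather than
#' 1.96 SD).
#'
#' @param ex,iv Paired numeric vectors.
#' @return List with `mean_diff`, `lower`, `upper`, `sd_diff` and
#'   `n_outside` (points beyond the limits).
#' @export
bland_altman <- function(ex, iv) {
  if (length(ex) != length(iv)) stop("paired vectors must have equal length")
  if (length(ex) < 3) stop("need at least 3 pairs")
  d <- iv - ex
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, lower = m - 2 * s, upper = m + 2 * s, sd_diff = s,
       n_outside = sum(d < m - 2 * s | d > m + 2 * s))
}

# cache of Monte-Carlo null distributions of the Lilliefors statistic,
# keyed by (n, replicates, seed)
.lillie_cache <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  cdf <- pnorm(z)
  max(seq_len(n) / n - cdf, cdf - (seq_len(n) - 1) / n)
}

#' Lilliefors normality test with Monte-Carlo null
#'
#' The statistic is the Kolmogorov-Smirnov supremum distance between the
#' empirical CDF and the normal CDF with estimated mean and SD; because the
#' parameters are estimated, the null distribution is obtained by seeded
#' Monte-Carlo simulation of normal samples of the same size.
#'
#' @param x Numeric sample (n >= 4) with positive variance.
#' @param replicates Monte-Carlo replicates for the null.
#' @param seed Seed for the null simulation.
#' @return List with `statistic` and `p` (Monte-Carlo p-value
#'   `(1 + #\{D0 >= D\}) / (replicates + 1)`).
#' @export
normality_test <- function(x, replicates = 10000L, seed = 1L) {
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (sd(x) == 0) stop("zero variance sample")
  D <- lilliefors_stat(x)
  key <- paste(n, replicates, seed, sep = "_")
  null <- .lillie_cache[[key]]
  if (is.null(null)) {
    null <- with_seed(seed, {
      m <- matrix(rnorm(replicates * n), nrow = replicates)
      apply(m, 1, lilliefors_stat)
    })
    .lillie_cache[[key]] <- null
  }
  list(statistic = D, p = (1 + sum(null >= D)) / (replicates + 1))
}

#' Two-sample group comparison
#'
#' Two-sided two-sample t-test (pooled variance by default, Welch
#' optionally) and the percent group difference
#' `100 * (mean(B) - mean(A)) / mean(A)`.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @param var_equal Pooled-variance test when `TRUE` (default), Welch
#'   otherwise.
#' @return List with `p`, `t`, `df`, `percent_diff`, `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`.
#' @export
group_compare <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 observations per group")
  if (sd(group_a) == 0 && sd(group_b) == 0)
    stop("degenerate: both groups have zero variance")
  tt <- stats::t.test(group_b, group_a, var.equal = var_equal)
  list(p = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter),
       percent_diff = 100 * (mean(group_b) - mean(group_a)) / mean(group_a),
       mean_a = mean(group_a), mean_b = mean(group_b),
       sd_a = sd(group_a), sd_b = sd(group_b))
}
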