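# Estimation statistics: effect sizes (Cohen's d, AUROC), BCa bootstrap
# confidence intervals, one-tailed rank tests, Kruskal-Wallis,
# Benjamini-Hochberg FDR, and 2x2 chi-square with continuity correction.

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_p` where `s_p` pools the two n-1 variances
#' by their degrees of freedom.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return The effect size; errors on zero pooled SD unless the means
#'   are equal (then 0).
#' @export
cohen_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("samples must have at least 2 observations")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(0)
    stop("zero pooled SD with unequal means: Cohen's d undefined")
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `U / (n_cases * n_controls)` with midranks, so ties count 0.5; the
#' probability that a random case scores above a random control.
#'
#' @param cases,controls Nonempty numeric samples.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(cases, controls) {
  n1 <- length(cases); n2 <- length(controls)
  if (n1 == 0L || n2 == 0L) stop("samples must be nonempty")
  r <- rank(c(cases, controls))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' BCa bootstrap confidence interval for a two-sample statistic
#'
#' Bias-corrected and accelerated percentile interval.  The bias
#' correction `z0` comes from the fraction of bootstrap replicates below
#' the point estimate; the acceleration `a` from the jackknife skewness
#' of the statistic over the concatenated leave-one-out samples (each
#' observation of either group deleted in turn).  Bootstrap resampling
#' draws with replacement within each group independently.
#'
#' @param statistic Function of two samples, e.g. [cohen_d()] or
#'   [auroc()].
#' @param x,y The two samples.
#' @param n_bootstrap Number of bootstrap resamples (>= 100; the study
#'   convention is 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param force_z0,force_accel Optional overrides for the bias
#'   correction and acceleration (used to demonstrate the reduction to
#'   the plain percentile interval when both are 0).
#' @return Numeric `c(low, high)`, with attributes `z0`, `accel`, and
#'   `estimate`.  A degenerate bootstrap distribution collapses the
#'   interval to that value with a warning.
#' @export
bca_ci <- function(statistic, x, y, n_bootstrap = 5000L, level = 0.95,
                   seed = 1L, force_z0 = NULL, force_accel = NULL) {
  if (n_bootstrap < 100L) stop("n_bootstrap must be at least 100")
  theta <- statistic(x, y)
  boot <- with_seed(derive_seed(seed, 7L),
    vapply(seq_len(n_bootstrap), function(b)
      statistic(x[sample.int(length(x), replace = TRUE)],
                y[sample.int(length(y), replace = TRUE)]),
      numeric(1)))
  if (max(boot) == min(boot)) {
    warning("degenerate bootstrap distribution; interval collapsed")
    out <- c(boot[1L], boot[1L])
    attributes(out) <- list(z0 = 0, accel = 0, estimate = theta)
    return(out)
  }
  z0 <- force_z0 %||% qnorm((sum(boot < theta) + 0.5 * sum(boot == theta)) /
                              n_bootstrap)
  if (!is.finite(z0)) z0 <- 0
  accel <- force_accel %||% {
    jack <- c(
      vapply(seq_along(x), function(i) statistic(x[-i], y), numeric(1)),
      vapply(seq_along(y), function(i) statistic(x, y[-i]), numeric(1))
    )
    dev <- mean(jack) - jack
    denom <- 6 * sum(dev^2)^1.5
    if (denom == 0) 0 else sum(dev^3) / denom
  }
  alpha <- (1 - level) / 2
  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + zq) / (1 - accel * (z0 + zq)))
  out <- unname(quantile(boot, adj, type = 7))
  attributes(out) <- list(z0 = z0, accel = accel, estimate = theta)
  out
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Midranks for ties.  For combined sample sizes up to 10 the p-value is
#' computed by exhaustive enumeration of all group assignments of the
#' pooled ranks (ties at the observed statistic counted fully); above
#' that a normal approximation with tie-corrected variance is used.
#'
#' @param x,y Nonempty numeric samples.
#' @param direction `"greater"` tests x stochastically above y;
#'   `"less"` the reverse.
#' @return List with `statistic` (rank sum of `x`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_one_tailed <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("samples must be nonempty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  n <- nx + ny
  if (n <= 10L) {
    sets <- combn(n, nx)
    Wnull <- colSums(matrix(r[sets], nrow = nx))
    p <- if (direction == "greater") mean(Wnull >= W) else mean(Wnull <= W)
    return(list(statistic = W, p_value = p, method = "exact"))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0)   # every observation tied: no evidence either way
    return(list(statistic = W, p_value = 1, method = "normal"))
  z <- (W - mu) / sqrt(sigma2)
  p <- if (direction == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
  list(statistic = W, p_value = p, method = "normal")
}

#' Kruskal-Wallis test
#'
#' H statistic on midranks with tie correction and a chi-square p-value
#' on k - 1 degrees of freedom.
#'
#' @param samples List of 2 or more nonempty numeric vectors.
#' @return List with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2L || any(lengths(samples) == 0L))
    stop("need at least 2 nonempty groups")
  pooled <- unlist(samples, use.names = FALSE)
  n <- length(pooled)
  if (n < 5L) stop("need at least 5 observations in total")
  if (length(unique(pooled)) == 1L)
    return(list(statistic = 0, df = length(samples) - 1L, p_value = 1))
  r <- rank(pooled)
  g <- rep(seq_along(samples), lengths(samples))
  Rj <- tapply(r, g, sum)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / lengths(samples)) - 3 * (n + 1)
  ties <- table(r)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  df <- length(samples) - 1L
  list(statistic = H, df = df, p_value = pchisq(H, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' 2x2 chi-square test with continuity correction
#'
#' Pearson chi-square on a 2x2 contingency table with Yates continuity
#' correction: `sum(max(|O - E| - 0.5, 0)^2 / E)` on 1 degree of
#' freedom.  The correction is clamped at 0 when `|O - E| <= 0.5`.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param continuity_correction Apply the Yates correction (default
#'   `TRUE`).
#' @return List with `statistic`, `df = 1`, `p_value`.
#' @export
chi_square_2x2 <- function(table, continuity_correction = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("table must be 2x2")
  if (any(table < 0) || sum(table) == 0) stop("invalid table counts")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  E <- outer(rs, cs) / sum(table)
  dev <- abs(table - E)
  if (continuity_correction) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat, df = 1L, p_value = pchisq(stat, 1L, lower.tail = FALSE))
}

#' Pairwise estimation contrast
#'
#' Gardner-Altman style summary of a two-group comparison: Cohen's d and
#' AUROC with 95% BCa bootstrap confidence intervals, plus the one-tailed
#' rank-sum p-value.
#'
#' @param x,y Numeric samples (x is the group hypothesized higher under
#'   `direction = "greater"`).
#' @param direction Tail of the rank-sum test.
#' @param n_bootstrap Bootstrap resamples for both intervals.
#' @param seed Integer seed.
#' @return An `estimation_result`: list with `cohen_d`, `cohen_d_ci`,
#'   `auroc`, `auroc_ci`, `p_value`, `n_bootstrap`, `seed`.
#' @export
estimate_contrast <- function(x, y, direction = c("greater", "less"),
                              n_bootstrap = 5000L, seed = 1L) {
  direction <- match.arg(direction)
  structure(list(
    cohen_d = cohen_d(x, y),
    cohen_d_ci = bca_ci(cohen_d, x, y, n_bootstrap, seed = seed),
    auroc = auroc(x, y),
    auroc_ci = bca_ci(auroc, x, y, n_bootstrap, seed = derive_seed(seed, 8L)),
    p_value = rank_sum_one_tailed(x, y, direction)$p_value,
    direction = direction, n_bootstrap = n_bootstrap, seed = seed,
    n_x = length(x), n_y = length(y)
  ), class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(paste0("<estimation_result> d = %.3f [%.3f, %.3f], ",
                     "AUROC = %.3f [%.3f, %.3f], one-tailed p = %.4g\n"),
              x$cohen_d, x$cohen_d_ci[1], x$cohen_d_ci[2],
              x$auroc, x$auroc_ci[1], x$auroc_ci[2], x$p_value))
  invisible(x)
}

#' Demographics table statistics
#'
#' Chi-square tests (with continuity correction) comparing the two
#' patient groups on the binary manifest variables sex, side,
#' hippocampal sclerosis and surgical outcome, mirroring the usual
#' cohort-description table.
#'
#' @param manifest Cohort manifest data frame with columns `group` plus
#'   any of `sex`, `side`, `hs`, `outcome`.
#' @return Data frame with one row per testable variable: `variable`,
#'   `chi_square`, `p_value`.
#' @export
demographics_table <- function(manifest) {
  pats <- manifest[manifest$group %in% c("FBTCS+", "FBTCS-"), , drop = FALSE]
  vars <- intersect(c("sex", "side", "hs", "outcome"), names(pats))
  rows <- lapply(vars, function(v) {
    tab <- table(pats$group, pats[[v]])
    if (!all(dim(tab) == 2L)) return(NULL)
    res <- chi_square_2x2(tab)
    data.frame(variable = v, chi_square = res$statistic,
               p_value = res$p_value)
  })
  do.call(rbind, rows)
}
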