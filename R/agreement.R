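# Method-comparison statistics: Pearson correlation, Lin's concordance
# correlation coefficient, Bland-Altman limits of agreement, proportional-
# bias regression, paired and two-sample t contrasts, and BCa bootstrap
# confidence intervals.
#
# Direction convention: differences are method A minus method B throughout
# (x - y), matching the usual "reference minus candidate" reading of a
# Bland-Altman plot.

.check_paired <- function(x, y, min_n = 3L) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("need at least %d paired observations", min_n), call. = FALSE)
  invisible(length(x))
}

#' Lin's concordance correlation coefficient
#'
#' `r_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moment convention — Lin's original definition.  Equals the Pearson
#' correlation exactly when the two methods share mean and variance, and is
#' attenuated towards zero by any location or scale shift
#' (`|r_c| <= |r|`).
#'
#' @param x,y Paired measurements (length >= 3, no missing values).
#' @return The concordance correlation coefficient.
#' @examples
#' lin_ccc(1:3, 1:3)        # 1
#' lin_ccc(1:3, 1:3 + 1)    # 4/7
#' @export
lin_ccc <- function(x, y) {
  n <- .check_paired(x, y)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0)
    stop("CCC undefined: both variances zero and means equal", call. = FALSE)
  2 * sxy / den
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y` (method A minus method B) summarised by the mean
#' bias, the sample SD of the differences (1/(n-1)), and the 95% limits of
#' agreement `mean(d) +/- 1.96 sd(d)`.  The returned `data` holds the
#' plotting pairs (per-pair mean vs difference).
#'
#' @param x,y Paired measurements (length >= 2, no missing values).
#' @return List with `mean_diff`, `sd_diff`, `loa` (length-2 vector), and
#'   `data` (data frame with columns `mean`, `diff`).
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 2, 2))$loa  # -1.96, 1.96
#' @export
bland_altman <- function(x, y) {
  .check_paired(x, y, min_n = 2L)
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  list(mean_diff = md, sd_diff = sdd,
       loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
       data = data.frame(mean = (x + y) / 2, diff = d))
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated bootstrap interval of a statistic:
#' the bias constant is `z0 = qnorm(#\{theta*_b < theta_hat\} / B)`, the
#' acceleration `a` comes from the jackknife skewness
#' `a = sum((tbar - t_i)^3) / (6 (sum((tbar - t_i)^2))^1.5)`, and the
#' interval endpoints are order statistics of the bootstrap distribution at
#' the adjusted percentiles (index `floor((B + 1) p)` clamped to `[1, B]`;
#' never extrapolated).  Rows of a matrix or data frame are resampled
#' jointly, so paired structures stay intact; `strata` switches to
#' stratified resampling (e.g. the two arms of a two-sample contrast).
#'
#' @param data Vector, matrix, or data frame of observations (rows).
#' @param statistic Function mapping a resampled `data` to a single number.
#' @param n_resamples Number of bootstrap resamples (default 3000).
#' @param alpha Two-sided miss probability (default 0.05 for a 95% CI).
#' @param seed RNG seed for the resampling (optional but recommended).
#' @param strata Optional factor of length `nrow(data)`; resampling is then
#'   done independently within each stratum.
#' @return List of class `bca_ci`: `estimate`, `ci` (length-2 vector), `z0`,
#'   `a`, `n_resamples`, `alpha`, `degenerate` (TRUE when all bootstrap
#'   statistics coincide, in which case the interval is the point estimate
#'   and a warning is raised).
#' @export
bca_ci <- function(data, statistic, n_resamples = 3000, alpha = 0.05,
                   seed = NULL, strata = NULL) {
  n <- NROW(data)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  check_scalar(n_resamples, "n_resamples", 1, integer = TRUE)
  check_scalar(alpha, "alpha", 0, 1, strict_lo = TRUE, strict_hi = TRUE)
  take <- if (is.null(dim(data))) function(i) data[i]
          else function(i) data[i, , drop = FALSE]
  theta_hat <- statistic(data)
  if (!is.numeric(theta_hat) || length(theta_hat) != 1L || !is.finite(theta_hat))
    stop("`statistic` must return a single finite number", call. = FALSE)
  B <- as.integer(n_resamples)
  if (!is.null(strata) && length(strata) != n)
    stop("`strata` must have one entry per observation", call. = FALSE)

  out <- with_seed(seed, {
    if (is.null(strata)) {
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    } else {
      strata <- as.factor(strata)
      idx <- matrix(0L, nrow = n, ncol = B)
      for (lev in levels(strata)) {
        rows <- which(strata == lev)
        idx[rows, ] <- matrix(rows[sample.int(length(rows), length(rows) * B,
                                              replace = TRUE)],
                              nrow = length(rows))
      }
    }
    theta_star <- vapply(seq_len(B), function(b) statistic(take(idx[, b])),
                         numeric(1))
    theta_star
  })
  theta_star <- out
  # a statistic may be undefined (NA) on degenerate resamples, e.g. a
  # correlation when a resample repeats one row; such replicates are dropped
  ok <- is.finite(theta_star)
  if (!all(ok)) {
    if (sum(ok) < 2L)
      stop("statistic undefined on nearly all bootstrap resamples",
           call. = FALSE)
    theta_star <- theta_star[ok]
    B <- length(theta_star)
  }

  if (max(theta_star) == min(theta_star)) {
    warning("all bootstrap statistics identical: degenerate (point) interval")
    return(structure(list(estimate = theta_hat,
                          ci = c(lower = theta_hat, upper = theta_hat),
                          z0 = 0, a = 0, n_resamples = B, alpha = alpha,
                          degenerate = TRUE),
                     class = "bca_ci"))
  }

  prop <- sum(theta_star < theta_hat) / B
  if (prop == 0 || prop == 1) {
    warning("estimate outside the bootstrap distribution; ",
            "bias correction clamped")
    prop <- clip(prop, 1 / (B + 1), B / (B + 1))
  }
  z0 <- stats::qnorm(prop)

  jack <- vapply(seq_len(n), function(i) statistic(take(-i)), numeric(1))
  if (anyNA(jack)) {
    a <- 0
  } else {
    djack <- mean(jack) - jack
    denom <- sum(djack^2)^1.5
    a <- if (denom == 0) 0 else sum(djack^3) / (6 * denom)
  }

  zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  s <- sort(theta_star)
  ix <- clip(floor((B + 1) * adj), 1, B)
  structure(list(estimate = theta_hat,
                 ci = c(lower = s[ix[1]], upper = s[ix[2]]),
                 z0 = z0, a = a, n_resamples = B, alpha = alpha,
                 degenerate = FALSE),
            class = "bca_ci")
}

#' @export
print.bca_ci <- function(x, ...) {
  cat(sprintf("BCa %d%% CI: [%.6g, %.6g]  (estimate %.6g, B = %d%s)\n",
              round(100 * (1 - x$alpha)), x$ci[1], x$ci[2], x$estimate,
              x$n_resamples, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Proportional-bias regression
#'
#' Ordinary least-squares slope of the inter-method difference `x - y` on
#' the paired mean `(x + y) / 2`.  Significance is judged by the BCa
#' bootstrap CI of the slope excluding zero (not the OLS t-test), matching
#' the bootstrap-CI convention used for the other agreement statistics.
#'
#' @param x,y Paired measurements (length >= 3).
#' @param n_resamples,seed,alpha Passed to [bca_ci()].
#' @return List with `slope`, `intercept`, `ci` (BCa interval of the slope),
#'   and `proportional_bias` (logical: CI excludes zero).
#' @examples
#' pb <- proportional_bias(c(1, 2, 3, 4), c(0, 0, 0, 0), seed = 1)
#' pb$slope  # 2: difference = x, mean = x / 2
#' @export
proportional_bias <- function(x, y, n_resamples = 3000, seed = NULL,
                              alpha = 0.05) {
  .check_paired(x, y)
  m <- (x + y) / 2
  if (stats::sd(m) == 0)
    stop("degenerate regressor: paired means are constant", call. = FALSE)
  # slope as cov/var rather than a QR fit: an exactly constant difference
  # then yields an exact zero instead of O(1e-16) numerical noise that a
  # bootstrap CI would mistake for proportional bias
  ols_slope <- function(d) {
    if (stats::sd(d$m) == 0) return(0)
    stats::cov(d$dd, d$m) / stats::var(d$m)
  }
  dat <- data.frame(m = m, dd = x - y)
  slope <- ols_slope(dat)
  ci <- bca_ci(dat, ols_slope,
               n_resamples = n_resamples, seed = seed, alpha = alpha)
  list(slope = slope,
       intercept = mean(dat$dd) - slope * mean(m),
       ci = ci$ci,
       proportional_bias = ci$ci[1] > 0 || ci$ci[2] < 0)
}

#' Paired t-test of the mean inter-method difference
#'
#' Classical paired Student's t-test of `x - y` against zero.
#'
#' @param x,y Paired measurements (length >= 2).
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  .check_paired(x, y, min_n = 2L)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("paired t-test undefined: differences have zero variance",
         call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Two-sample contrast of a measurement between two groups
#'
#' Classical two-sample Student's t-test (pooled variance) plus the BCa
#' bootstrap CI of the difference in group means (stratified resampling
#' within groups) — the layout used for dichotomous covariates such as
#' birth status.
#'
#' @param values Numeric measurements.
#' @param group Two-level factor (or coercible) of the same length.
#' @param n_resamples,seed,alpha Passed to [bca_ci()].
#' @return List with `means` (named group means), `mean_diff` (first level
#'   minus second), `t`, `df`, `p`, and `ci` (BCa interval of the mean
#'   difference).
#' @export
two_sample_t <- function(values, group, n_resamples = 3000, seed = NULL,
                         alpha = 0.05) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("`group` must have exactly two levels",
                                 call. = FALSE)
  if (length(values) != length(group) || anyNA(values))
    stop("`values` must match `group` with no missing values", call. = FALSE)
  if (min(table(group)) < 2L)
    stop("need at least 2 observations per group", call. = FALSE)
  tt <- stats::t.test(values ~ group, var.equal = TRUE)
  means <- tapply(values, group, mean)
  stat <- function(d) {
    mm <- tapply(d$v, d$g, mean)
    unname(mm[1] - mm[2])
  }
  ci <- bca_ci(data.frame(v = values, g = group), stat,
               n_resamples = n_resamples, seed = seed, alpha = alpha,
               strata = group)
  list(means = means, mean_diff = unname(means[1] - means[2]),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       ci = ci$ci)
}

#' Full method-agreement analysis of two paired measurement series
#'
#' Computes the complete agreement ledger for one metric measured by two
#' methods on the same samples: Pearson r with BCa CI, paired t-test for
#' systematic bias, Lin's concordance correlation coefficient, Bland-Altman
#' mean bias and 95% limits of agreement, and the proportional-bias
#' regression slope with BCa CI.
#'
#' @param x Method-A values (e.g. laser diffraction).
#' @param y Method-B values (e.g. image-based morphometry), same samples.
#' @param labels Length-2 character vector naming the methods.
#' @param n_resamples Bootstrap resamples for the BCa intervals
#'   (default 3000).
#' @param seed RNG seed for the bootstrap.
#' @param alpha Two-sided miss probability of the intervals (default 0.05).
#' @return An object of class `method_agreement` with components `n`, `r`,
#'   `r_ci`, `t`, `t_p`, `ccc`, `mean_diff`, `sd_diff`, `loa`, `slope`,
#'   `slope_ci`, `proportional_bias_flag`, `labels`, and `data`.
#' @examples
#' pm <- generate_paired(paired_sim_spec(30, slope = 1.1, noise_sd = 0.5,
#'                                       seed = 7))
#' fit <- method_agreement(pm$x, pm$y, seed = 7, n_resamples = 500)
#' print(fit)
#' @export
method_agreement <- function(x, y, labels = c("A", "B"), n_resamples = 3000,
                             seed = NULL, alpha = 0.05) {
  .check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  dat <- data.frame(x = x, y = y)
  r <- stats::cor(x, y)
  r_ci <- bca_ci(dat, function(d) {
    if (stats::sd(d$x) == 0 || stats::sd(d$y) == 0) return(NA_real_)
    stats::cor(d$x, d$y)
  }, n_resamples = n_resamples,
  seed = if (is.null(seed)) NULL else seed, alpha = alpha)
  # a zero-variance difference (e.g. a method compared with itself) leaves
  # the t-test undefined but the rest of the ledger intact
  tt <- tryCatch(paired_t(x, y),
                 error = function(e) list(t = NA_real_, df = NA_real_,
                                          p = NA_real_,
                                          mean_diff = mean(x - y)))
  ba <- bland_altman(x, y)
  pb <- proportional_bias(x, y, n_resamples = n_resamples,
                          seed = if (is.null(seed)) NULL else seed + 1L,
                          alpha = alpha)
  structure(list(n = length(x), r = r, r_ci = r_ci$ci,
                 t = tt$t, t_p = tt$p,
                 ccc = lin_ccc(x, y),
                 mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                 loa = ba$loa,
                 slope = pb$slope, slope_ci = pb$ci,
                 proportional_bias_flag = pb$proportional_bias,
                 labels = labels, alpha = alpha,
                 n_resamples = n_resamples, data = dat),
            class = "method_agreement")
}

#' @export
print.method_agreement <- function(x, ...) {
  cat(sprintf("Method agreement (%s vs %s), n = %d\n",
              x$labels[1], x$labels[2], x$n))
  cat(sprintf("  Pearson r      %.3f  [%.3f, %.3f] BCa %d%%\n",
              x$r, x$r_ci[1], x$r_ci[2], round(100 * (1 - x$alpha))))
  cat(sprintf("  CCC (r_c)      %.3f\n", x$ccc))
  cat(sprintf("  Paired t       t = %.3f, p = %.4g\n", x$t, x$t_p))
  cat(sprintf("  Mean bias      %.4g (SD %.4g)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  95%% LoA        [%.4g, %.4g]\n", x$loa[1], x$loa[2]))
  cat(sprintf("  Prop. bias B   %.3f  [%.3f, %.3f]%s\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              if (x$proportional_bias_flag) "  *CI excludes 0*" else ""))
  invisible(x)
}

#' @export
summary.method_agreement <- function(object, ...) {
  data.frame(n = object$n, r = object$r,
             r_ci_lower = object$r_ci[1], r_ci_upper = object$r_ci[2],
             t = object$t, t_p = object$t_p, ccc = object$ccc,
             mean_diff = object$mean_diff, sd_diff = object$sd_diff,
             loa_lower = object$loa[1], loa_upper = object$loa[2],
             slope = object$slope,
             slope_ci_lower = object$slope_ci[1],
             slope_ci_upper = object$slope_ci[2],
             proportional_bias = object$proportional_bias_flag,
             row.names = NULL)
}

#' Bland-Altman and concordance plots for a method-agreement fit
#'
#' Left panel: Bland-Altman plot (difference A - B against paired mean) with
#' the mean bias (solid) and 95% limits of agreement (dashed).  Right panel:
#' concordance plot of A against B with the identity line (solid) and the
#' least-squares line of best fit (dotted).
#'
#' @param x A `method_agreement` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.method_agreement <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  m <- (x$data$x + x$data$y) / 2
  d <- x$data$x - x$data$y
  graphics::plot(m, d, xlab = sprintf("mean of %s and %s", x$labels[1], x$labels[2]),
                 ylab = sprintf("difference (%s - %s)", x$labels[1], x$labels[2]),
                 main = "Bland-Altman",
                 ylim = range(c(d, x$loa)), ...)
  graphics::abline(h = x$mean_diff, lwd = 2)
  graphics::abline(h = x$loa, lty = 2)
  graphics::plot(x$data$y, x$data$x, xlab = x$labels[2], ylab = x$labels[1],
                 main = sprintf("Concordance (CCC = %.3f)", x$ccc), ...)
  graphics::abline(0, 1, lwd = 2)
  graphics::abline(stats::lm(x$data$x ~ x$data$y), lty = 3)
  invisible(x)
}
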