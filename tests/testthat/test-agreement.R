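# Method-comparison statistics: closed-form examples, attenuation and
# symmetry properties, BCa behaviour against the boot package, and
# parameter recovery on simulated paired data.

test_that("Lin's CCC matches hand computations with 1/n moments", {
  x <- c(1, 2, 3)
  expect_equal(lin_ccc(x, x), 1)
  expect_equal(lin_ccc(x, x + 1), 4 / 7)  # (4/3)/(2/3 + 2/3 + 1)
  z <- c(-1, 0, 1)
  expect_equal(lin_ccc(z, -z), -1)        # anti-concordance limit
  expect_error(lin_ccc(rep(2, 5), rep(2, 5)), "undefined")
})

test_that("CCC is attenuated relative to Pearson, with equality at matched moments", {
  set.seed(51)
  for (rep in 1:30) {
    x <- stats::rnorm(20); y <- 0.8 * x + stats::rnorm(20, 1, 0.5)
    expect_lte(abs(lin_ccc(x, y)), abs(stats::cor(x, y)) + 1e-12)
  }
  x <- stats::rnorm(40)
  y <- sample(x)  # same mean and variance exactly
  expect_equal(lin_ccc(x, y), stats::cor(x, y) * (length(x) - 1) / length(x) /
                 ((length(x) - 1) / length(x)))
})

test_that("Pearson correlation on the worked three-point example", {
  expect_equal(stats::cor(c(0, 1, 2), c(0, 1, 4)), 4 / sqrt(2 * 78 / 9))
})

test_that("Bland-Altman statistics match hand computations", {
  out <- bland_altman(c(1, 2, 3), c(2, 2, 2))
  expect_equal(out$mean_diff, 0)
  expect_equal(out$sd_diff, 1)
  expect_equal(unname(out$loa), c(-1.96, 1.96))
  same <- bland_altman(1:5, 1:5)
  expect_equal(c(same$mean_diff, same$sd_diff, unname(same$loa)), rep(0, 4))
  shift <- bland_altman(1:5, 1:5 - 3)
  expect_equal(shift$mean_diff, 3); expect_equal(shift$sd_diff, 0)
})

test_that("swapping the methods negates the bias and reflects the limits", {
  set.seed(52)
  x <- stats::rlnorm(15, log(8), 0.3); y <- x + stats::rnorm(15, 0.5, 0.4)
  a <- bland_altman(x, y); b <- bland_altman(y, x)
  expect_equal(b$mean_diff, -a$mean_diff)
  expect_equal(unname(b$loa), -rev(unname(a$loa)))
})

test_that("proportional-bias slope has its algebraic values", {
  # constant difference: slope 0
  x <- c(1, 2, 3, 4, 5)
  pb0 <- suppressWarnings(proportional_bias(x, x - 2, n_resamples = 200, seed = 1))
  expect_equal(pb0$slope, 0)
  expect_false(pb0$proportional_bias)
  # y = 0: difference = x, mean = x / 2, slope exactly 2 in every resample
  expect_warning(
    pb2 <- proportional_bias(x, rep(0, 5), n_resamples = 200, seed = 1),
    "degenerate")
  expect_equal(pb2$slope, 2)
  expect_error(proportional_bias(rep(1, 4), rep(1, 4)), "degenerate")
})

test_that("a true proportional bias is detected on simulated pairs", {
  pm <- generate_paired(paired_sim_spec(100, slope = 1.5, intercept = 0,
                                        noise_sd = 0.5, seed = 53))
  pb <- proportional_bias(pm$x, pm$y, n_resamples = 1000, seed = 53)
  # y = 1.5 x: difference x - y = -0.5 x, mean = 1.25 x -> slope -0.4
  expect_equal(pb$slope, -0.4, tolerance = 0.05)
  expect_true(pb$proportional_bias)
})

test_that("BCa intervals degenerate to a point on constant statistics", {
  expect_warning(ci <- bca_ci(rep(5, 10), mean, n_resamples = 100, seed = 1),
                 "degenerate")
  expect_true(ci$degenerate)
  expect_equal(unname(ci$ci), c(5, 5))
})

test_that("BCa is deterministic given a seed and reduces to percentile when symmetric", {
  x <- seq(-2, 2, length.out = 30)
  a <- bca_ci(x, mean, n_resamples = 2000, seed = 9)
  b <- bca_ci(x, mean, n_resamples = 2000, seed = 9)
  expect_identical(a$ci, b$ci)
  expect_lt(abs(a$z0), 0.1)
  expect_lt(abs(a$a), 0.05)
  # with z0 ~ a ~ 0 the interval sits near the normal-theory one
  theta_sd <- stats::sd(x) / sqrt(30)
  expect_lt(abs(a$ci[1] - (mean(x) - 1.96 * theta_sd)), 0.15)
  expect_lt(abs(a$ci[2] - (mean(x) + 1.96 * theta_sd)), 0.15)
})

test_that("BCa endpoints agree with boot::boot.ci on skewed data", {
  skip_if_not_installed("boot")
  set.seed(99)
  x <- stats::rexp(25)
  mine <- bca_ci(x, mean, n_resamples = 8000, seed = 7)
  set.seed(7)
  bo <- boot::boot(x, function(d, i) mean(d[i]), R = 8000)
  bci <- boot::boot.ci(bo, type = "bca")
  expect_equal(unname(mine$ci), bci$bca[4:5], tolerance = 0.08)
  expect_equal(mine$estimate, mean(x))
})

test_that("paired rows are resampled jointly", {
  # a perfectly correlated pair keeps r = 1 in every joint resample, so the
  # bootstrap distribution of r collapses to 1 (up to float wobble); row-
  # independent resampling would scatter r well below 1
  d <- data.frame(x = 1:20, y = 2 * (1:20))
  ci <- suppressWarnings(bca_ci(d, function(dd) stats::cor(dd$x, dd$y),
                                n_resamples = 200, seed = 3))
  expect_equal(unname(ci$ci), c(1, 1), tolerance = 1e-9)
})

test_that("paired t-test errors on zero-variance differences", {
  expect_error(paired_t(1:5, 1:5), "zero variance")
  expect_error(paired_t(1:4, 1:4 - 1), "zero variance")
  out <- paired_t(c(1, 2, 3, 5), c(0, 1, 2, 2))
  ref <- stats::t.test(c(1, 2, 3, 5), c(0, 1, 2, 2), paired = TRUE)
  expect_equal(out$p, ref$p.value)
})

test_that("two-sample contrasts report group means and a covering BCa CI", {
  set.seed(54)
  v <- c(stats::rnorm(30, 0, 0.5), stats::rnorm(30, 1, 0.5))
  g <- rep(c("a", "b"), each = 30)
  out <- two_sample_t(v, g, n_resamples = 800, seed = 4)
  expect_equal(as.vector(out$means), c(mean(v[1:30]), mean(v[31:60])))
  expect_equal(out$mean_diff, mean(v[1:30]) - mean(v[31:60]))
  expect_true(out$ci[2] < 0)  # true difference -1: CI excludes 0
  expect_error(two_sample_t(v, rep("a", 60)), "two levels")
})

test_that("r and CCC are invariant to a common affine rescaling", {
  set.seed(55)
  x <- stats::rlnorm(20, log(6), 0.4); y <- x + stats::rnorm(20, 0.3, 0.5)
  expect_equal(lin_ccc(2 * x + 1, 2 * y + 1), lin_ccc(x, y))
  expect_equal(stats::cor(2 * x + 1, 2 * y + 1), stats::cor(x, y))
  a <- bland_altman(x, y); b <- bland_altman(2 * x, 2 * y)
  expect_equal(b$mean_diff, 2 * a$mean_diff)
  expect_equal(unname(b$loa), 2 * unname(a$loa))
})

test_that("the full agreement object is internally consistent", {
  pm <- generate_paired(paired_sim_spec(30, slope = 1.1, intercept = 0.5,
                                        noise_sd = 0.8, seed = 56))
  fit <- method_agreement(pm$x, pm$y, labels = c("LD", "IBMA"),
                          n_resamples = 500, seed = 56)
  expect_s3_class(fit, "method_agreement")
  expect_lte(abs(fit$ccc), abs(fit$r))
  expect_true(fit$loa[1] <= fit$mean_diff && fit$mean_diff <= fit$loa[2])
  expect_equal(fit$ccc, lin_ccc(pm$x, pm$y))
  s <- summary(fit)
  expect_equal(s$r, fit$r)
  expect_output(print(fit), "Pearson r")
  # identical reruns under the same seed
  fit2 <- method_agreement(pm$x, pm$y, labels = c("LD", "IBMA"),
                           n_resamples = 500, seed = 56)
  expect_identical(summary(fit), summary(fit2))
})
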