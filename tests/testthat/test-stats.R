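test_that("density estimates integrate to 1 and use the Silverman bandwidth", {
  set.seed(11)
  x <- rlnorm(500, 4, 0.3)
  de <- estimate_density(x)
  integral <- sum(diff(de$grid) * (head(de$density, -1) + tail(de$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  # bandwidth equals the closed-form Silverman rule of thumb
  silverman <- 0.9 * min(sd(x), IQR(x) / 1.34) * length(x)^(-1 / 5)
  expect_equal(de$bandwidth, silverman, tolerance = 1e-12)
  expect_error(estimate_density(c(1)), "at least 2")
  expect_error(estimate_density(c(2, 2, 2)), "zero spread")
})

test_that("density of a symmetric sample is symmetric about its centre", {
  set.seed(21)
  half <- rlnorm(2000, 2, 0.4)
  x <- c(10 + half, 10 - half) # mirror-symmetric around 10
  de <- estimate_density(x)
  left <- de$density[de$grid < 10]
  right <- rev(de$density[de$grid > 10])
  m <- min(length(left), length(right))
  expect_lt(max(abs(left[seq_len(m)] - right[seq_len(m)])), 0.02 * max(de$density))
})

test_that("KDE converges to the standard normal density", {
  set.seed(5)
  de <- estimate_density(rnorm(1e5))
  expect_lt(max(abs(de$density - dnorm(de$grid))), 0.01)
})

test_that("KS statistic matches hand-derived and reference values", {
  expect_equal(ks_statistic(c(1, 5, 9), c(1, 5, 9)), 0)
  expect_equal(ks_statistic(c(1, 2, 3), c(10, 11)), 1) # disjoint supports
  expect_equal(ks_statistic(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)
  # against stats::ks.test on tied and untied random data
  set.seed(33)
  for (i in 1:5) {
    a <- sample(1:20, 30, replace = TRUE)
    b <- sample(5:25, 40, replace = TRUE)
    expect_equal(ks_statistic(a, b),
                 unname(suppressWarnings(ks.test(a, b))$statistic))
  }
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
})

test_that("permutation KS: identical samples give D = 0 and p = 1", {
  x <- rnorm(30)
  res <- permutation_ks_test(x, x, m = 200, seed = 3)
  expect_equal(res$d_observed, 0)
  expect_equal(res$p_value, 1)
})

test_that("the Phipson-Smyth estimator never returns zero", {
  # complete separation: no permutation reaches the observed D on this draw
  res <- permutation_ks_test(1:50, 101:150, m = 10000, seed = 4)
  expect_equal(res$d_observed, 1)
  expect_equal(res$n_exceed, 0L)
  expect_equal(res$p_value, 1 / 10001)
  expect_gt(res$p_value, 0)
  # p = (b + 1) / (m + 1) exactly
  res2 <- permutation_ks_test(rnorm(40), rnorm(40, 0.5), m = 999, seed = 5)
  expect_equal(res2$p_value, (res2$n_exceed + 1) / 1000)
  expect_error(permutation_ks_test(1:3, 4:6, m = 0), "m")
})

test_that("permutation p agrees with the asymptotic two-sample KS p under the null", {
  set.seed(77)
  a <- rnorm(200)
  b <- rnorm(200)
  res <- permutation_ks_test(a, b, m = 10000, seed = 78)
  asym <- suppressWarnings(ks.test(a, b))$p.value
  expect_lt(abs(res$p_value - asym), 0.02)
})

test_that("D is exchangeable in the pooled input order and reproducible", {
  set.seed(9)
  a <- rnorm(25)
  b <- rnorm(35, 1)
  r1 <- permutation_ks_test(a, b, m = 500, seed = 10)
  r2 <- permutation_ks_test(rev(a), sample(b), m = 500, seed = 10)
  expect_equal(r1$d_observed, r2$d_observed)
  expect_equal(r1$p_value, r2$p_value)
  r3 <- permutation_ks_test(a, b, m = 500, seed = 10)
  expect_identical(r1, r3)
})

test_that("effects model recovers a planted tissue effect", {
  set.seed(14)
  n <- 24
  df <- data.frame(tissue = rep(c("VAT", "SCAT"), each = n / 2),
                   sex = rep(c("F", "M"), n / 2),
                   body_weight = runif(n, 700, 1200))
  df$mean_diameter <- 10 + 17 * (df$tissue == "VAT") + rnorm(n, 0, 0.1)
  em <- fit_effects_model(df, "mean_diameter")
  co <- em$coefficients
  est <- co$estimate[startsWith(co$term, "tissue")]
  expect_equal(abs(est), 17, tolerance = 0.5 / 17)
  expect_lt(term_p_value(em, "tissue"), 1e-6)
})

test_that("zero-noise exact linear response fits exactly", {
  df <- data.frame(tissue = rep(c("VAT", "SCAT"), 6),
                   sex = rep(c("F", "M"), each = 6),
                   body_weight = seq(700, 1250, length.out = 12))
  df$mean_diameter <- 5 + 2 * (df$tissue == "VAT") + 0.01 * df$body_weight
  em <- fit_effects_model(df, "mean_diameter")
  expect_lt(max(abs(residuals(em$fit))), 1e-10)
  expect_lt(term_p_value(em, "tissue"), 1e-12)
  expect_lt(term_p_value(em, "body_weight"), 1e-12)
})

test_that("effects model errors name the offending term or column", {
  df <- data.frame(tissue = "VAT", sex = c("F", "M"), body_weight = c(1, 2),
                   mean_diameter = c(1, 2))
  expect_error(fit_effects_model(df), "tissue")
  df2 <- data.frame(tissue = c("VAT", "SCAT"), sex = c("F", "M"),
                    mean_diameter = c(1, 2))
  expect_error(fit_effects_model(df2), "body_weight")
})
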