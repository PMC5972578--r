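# Fixed-effects gradient fits, log transform, lack-of-fit and group
# comparison.

test_that("an exact line is recovered with r2 = 1", {
  f <- fit_gradient(data.frame(distance_um = c(0, 100, 200),
                               response = c(1, 2, 3)))
  expect_equal(f$slope, 0.01)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_equal(unname(coef(f)), c(1, 0.01))
  expect_equal(predict(f, 50), 1.5)
  expect_equal(residuals(f), rep(0, 3), tolerance = 1e-12)
})

test_that("OLS estimates equal the closed-form expressions", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- stats::runif(n, 0, 500)
    y <- 2 - 0.004 * x + stats::rnorm(n, 0, 0.5)
    f <- fit_gradient(data.frame(distance_um = x, response = y))
    expect_equal(f$slope, ols_slope(x, y), tolerance = 1e-12)
    expect_equal(f$intercept, ols_intercept(x, y), tolerance = 1e-12)
  }
})

test_that("degenerate designs are rejected and constants give slope 0", {
  expect_error(fit_gradient(data.frame(distance_um = 1:2, response = 1:2)),
               "at least 3")
  expect_error(fit_gradient(data.frame(distance_um = rep(5, 4),
                                       response = 1:4)), "degenerate")
  f <- fit_gradient(data.frame(distance_um = c(1, 2, 3, 4),
                               response = rep(7, 4)))
  expect_equal(f$slope, 0)
})

test_that("log transform and back-transform round-trip", {
  b <- data.frame(area_um2 = c(1, exp(1), 5), distance_um = c(10, 20, 30))
  obs <- log_transform_areas(b)
  expect_equal(obs$response, c(0, 1, log(5)))
  set.seed(8)
  x <- stats::rlnorm(50, 2, 1)
  expect_equal(exp(log_transform_areas(
    data.frame(area_um2 = x, distance_um = seq_along(x)))$response),
    x, tolerance = 1e-12)
  expect_error(log_transform_areas(
    data.frame(area_um2 = c(1, 0), distance_um = c(1, 2))), "non-positive")
})

test_that("quadratic lack-of-fit F matches the nested-model formula", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    x <- stats::runif(n, 0, 300)
    y <- 1 + 0.01 * x + 2e-5 * x^2 + stats::rnorm(n, 0, 0.3)
    f <- quadratic_check(fit_gradient(data.frame(distance_um = x,
                                                 response = y)))
    lin <- stats::lm(y ~ x); quad <- stats::lm(y ~ x + I(x^2))
    rss1 <- sum(residuals(lin)^2); rss2 <- sum(residuals(quad)^2)
    Fwant <- ((rss1 - rss2) / 1) / (rss2 / (n - 3))
    expect_equal(f$quad_F, Fwant, tolerance = 1e-10)
    expect_equal(f$quad_p, stats::pf(Fwant, 1, n - 3, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("noise-free linear data give F = 0, p = 1; curvature is detected", {
  f <- quadratic_check(fit_gradient(
    data.frame(distance_um = c(0, 10, 20, 30, 40),
               response = 2 + 0.1 * c(0, 10, 20, 30, 40))))
  expect_equal(f$quad_F, 0)
  expect_equal(f$quad_p, 1)
  set.seed(77)
  x <- stats::runif(50, 0, 100)
  y <- 1 + 0.02 * x + 5e-4 * x^2 + stats::rnorm(50, 0, 0.05)
  f2 <- quadratic_check(fit_gradient(data.frame(distance_um = x,
                                                response = y)))
  expect_lt(f2$quad_p, 0.01)
  expect_error(quadratic_check(fit_gradient(
    data.frame(distance_um = c(1, 2, 3), response = c(1, 2, 3)))),
    "at least 4")
})

test_that("identical fits difference to zero; single group is rejected", {
  f <- fit_gradient(data.frame(distance_um = c(0, 1, 2, 4),
                               response = c(1, 1.5, 2.2, 4.1)),
                    group = "a")
  tab <- compare_groups(list(f, f))
  expect_equal(tab$slope_diff, 0)
  expect_equal(tab$z, 0)
  expect_error(compare_groups(list(f)), "2 groups")
})

test_that("slope-difference estimates cover the programmed difference", {
  delta <- 0.02
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    x <- seq(0, 100, length.out = 15)
    ya <- 1 + 0.01 * x + stats::rnorm(15, 0, 0.4)
    yb <- 1 + (0.01 + delta) * x + stats::rnorm(15, 0, 0.4)
    fa <- fit_gradient(data.frame(distance_um = x, response = ya), "a")
    fb <- fit_gradient(data.frame(distance_um = x, response = yb), "b")
    tab <- compare_groups(list(fa, fb))
    if (abs((tab$slope_a - tab$slope_b) + delta) <= 2 * tab$diff_se)
      hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.90)
})
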