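rlaplace <- function(n, scale = 1) stats::rexp(n, 1 / scale) - stats::rexp(n, 1 / scale)

test_that("spearman matches hand values and the base-R cross-check", {
  expect_equal(spearman(1:3, c(10, 20, 30))$r, 1.0)
  expect_equal(spearman(1:4, c(1, 3, 2, 4))$r, 0.8)  # 1 - 6*2/(4*15)
  expect_equal(spearman(1:3, c(30, 20, 10))$r, -1.0)
  withr::with_seed(42, {
    x <- rnorm(60); y <- x + rnorm(60)
  })
  ours <- spearman(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  # t-approximation p agrees with the AS89-backed reference to ~1e-3 here
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-2)
})

test_that("spearman is invariant under strictly monotone transforms and drops NA pairwise", {
  withr::with_seed(7, {
    x <- rlnorm(40); y <- x + rnorm(40)
  })
  base <- spearman(x, y)$r
  expect_equal(spearman(log(x), y)$r, base)
  expect_equal(spearman(x, exp(y / 4))$r, base)
  xm <- c(x, NA, 5); ym <- c(y, 3, NA)
  expect_equal(spearman(xm, ym)$r, base)
  expect_identical(spearman(xm, ym)$n, 40L)
  # constant vector: undefined, flagged
  flag <- spearman(rep(1, 10), rnorm(10))
  expect_false(flag$defined)
  expect_true(is.na(flag$r))
})

test_that("rank regression recovers noise-free linear data exactly", {
  withr::with_seed(1, x <- rnorm(50))
  fit <- rank_regression(matrix(x, dimnames = list(NULL, "x")), 1 + 2 * x)
  expect_equal(unname(fit$coefficients), 2.0, tolerance = 1e-6)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-6)
  expect_equal(fit$dispersion_full, 0, tolerance = 1e-9)
  # two covariates, noise-free
  withr::with_seed(2, X <- matrix(rnorm(120), ncol = 2))
  y2 <- 0.5 - 1.5 * X[, 1] + 3 * X[, 2]
  fit2 <- rank_regression(X, y2)
  expect_equal(unname(fit2$coefficients), c(-1.5, 3), tolerance = 1e-4)
})

test_that("rank regression under Laplace noise recovers the slope within 0.1", {
  withr::with_seed(11, {
    x <- rnorm(500)
    y <- 1 + 2 * x + rlaplace(500)
  })
  fit <- rank_regression(matrix(x, dimnames = list(NULL, "x")), y)
  expect_equal(unname(fit$coefficients), 2.0, tolerance = 0.05)
  expect_lt(abs(unname(fit$coefficients) - 2.0), 0.1)
  expect_lt(fit$p_values[["x"]], 1e-6)
})

test_that("the fitted dispersion is minimal against grid perturbations and the null", {
  withr::with_seed(5, {
    X <- matrix(rnorm(200), ncol = 2)
    y <- 1 + X[, 1] - 0.5 * X[, 2] + rnorm(100)
  })
  fit <- rank_regression(X, y)
  b <- unname(fit$coefficients)
  disp <- function(bb) aasupply:::jaeckel_dispersion(y - X %*% bb)
  for (d1 in c(-0.1, 0, 0.1)) {
    for (d2 in c(-0.1, 0, 0.1)) {
      expect_gte(disp(b + c(d1, d2)) + 1e-9, fit$dispersion_full)
    }
  }
  expect_lte(fit$dispersion_full, fit$dispersion_null)
  expect_true(fit$total_r >= 0 && fit$total_r <= 1)
})

test_that("total R is near zero when the response is independent noise", {
  withr::with_seed(19, {
    X <- matrix(rnorm(4000), ncol = 2)
    y <- rnorm(2000)
  })
  fit <- rank_regression(X, y)
  expect_lt(fit$total_r, 0.1)
  expect_gt(min(fit$p_values), 0.01)
})

test_that("rank slope sign agrees with spearman on monotone data", {
  withr::with_seed(23, {
    x <- rnorm(80)
    for (slope in c(-3, -0.2, 0.4, 2)) {
      y <- slope * x + rnorm(80, sd = 0.3)
      fit <- rank_regression(matrix(x, dimnames = list(NULL, "x")), y)
      expect_identical(sign(unname(fit$coefficients)), sign(spearman(x, y)$r))
    }
  })
})

test_that("the rank estimator resists gross outliers better than least squares", {
  wins <- withr::with_seed(31, {
    vapply(1:25, function(i) {
      n <- 150
      x <- rnorm(n)
      y <- 1 + 2 * x + rnorm(n)
      bad <- sample(n, n %/% 10)
      y[bad] <- y[bad] + 50
      rkfit <- rank_regression(matrix(x, dimnames = list(NULL, "x")), y)
      ols <- stats::coef(stats::lm(y ~ x))[["x"]]
      abs(unname(rkfit$coefficients) - 2) < abs(ols - 2)
    }, logical(1))
  })
  expect_gte(mean(wins), 0.9)
})

test_that("KSM tau estimate is near the theoretical value for normal errors", {
  # for N(0, sigma): tau = sigma * sqrt(pi/3)
  withr::with_seed(13, e <- rnorm(800, sd = 2))
  tau <- aasupply:::ksm_tau(e, p = 1)
  expect_equal(tau, 2 * sqrt(pi / 3), tolerance = 0.15)
})

test_that("wilcoxon: enumeration is exact, matching base R on tie-free samples", {
  expect_equal(wilcoxon_ranksum_one_sided(c(1, 2), c(3, 4), "x_less")$p_value,
               1 / 6, tolerance = 1e-12)
  withr::with_seed(3, {
    for (rep in 1:10) {
      n_x <- sample(2:6, 1); n_y <- sample(2:6, 1)
      x <- rnorm(n_x); y <- rnorm(n_y)
      for (alt in c("x_less", "x_greater")) {
        ours <- wilcoxon_ranksum_one_sided(x, y, alt)
        ref <- stats::wilcox.test(x, y, alternative =
                                    if (alt == "x_less") "less" else "greater",
                                  exact = TRUE)
        expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("wilcoxon: identical samples give p >= 0.5 on either side", {
  x <- c(1, 2, 3)
  expect_gte(wilcoxon_ranksum_one_sided(x, x, "x_less")$p_value, 0.5)
  expect_gte(wilcoxon_ranksum_one_sided(x, x, "x_greater")$p_value, 0.5)
  big <- rep(c(1, 2), 10)
  expect_gte(wilcoxon_ranksum_one_sided(big, big, "x_less")$p_value, 0.5)
})

test_that("normal approximation tracks enumeration and base R, including ties", {
  withr::with_seed(8, {
    x <- rnorm(6); y <- rnorm(6) + 0.5
  })
  exact <- wilcoxon_ranksum_one_sided(x, y, "x_less")
  approx <- wilcoxon_ranksum_one_sided(x, y, "x_less", exact_max = 0L)
  expect_identical(exact$method, "exact enumeration")
  expect_identical(approx$method, "normal approximation")
  expect_equal(approx$p_value, exact$p_value, tolerance = 0.01)
  # tie correction cross-checked against base R at larger n
  withr::with_seed(9, {
    xt <- sample(1:5, 30, replace = TRUE)
    yt <- sample(2:6, 25, replace = TRUE)
  })
  ours <- wilcoxon_ranksum_one_sided(xt, yt, "x_less")
  ref <- suppressWarnings(stats::wilcox.test(xt, yt, alternative = "less",
                                             exact = FALSE, correct = TRUE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("wilcoxon is antisymmetric under swapping groups and alternative", {
  withr::with_seed(14, {
    x <- rnorm(20); y <- rnorm(15) + 0.3
  })
  p1 <- wilcoxon_ranksum_one_sided(x, y, "x_less")$p_value
  p2 <- wilcoxon_ranksum_one_sided(y, x, "x_greater")$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  p3 <- wilcoxon_ranksum_one_sided(x[1:5], y[1:4], "x_less")$p_value
  p4 <- wilcoxon_ranksum_one_sided(y[1:4], x[1:5], "x_greater")$p_value
  expect_equal(p3, p4, tolerance = 1e-12)
})
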