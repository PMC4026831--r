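# Cohort statistics against closed-form and simulation oracles.

df2 <- function(x, y) data.frame(v = c(x, y),
                                 g = rep(c("a", "b"), c(length(x), length(y))))

test_that("two-group comparison matches the pooled-t closed form", {
  r0 <- compare_groups(df2(1:3, 1:3), "v", "g")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r <- compare_groups(df2(1:3, 2:4), "v", "g")
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.2878, tolerance = 1e-3)
  expect_equal(r$summaries$mean, c(2, 3))
  expect_error(compare_groups(df2(1, 2:4), "v", "g"), "at least 2")
  # swapping group labels flips the sign and preserves p
  d <- df2(c(1.2, 3.1, 2.2, 4.0), c(2.5, 3.3, 5.1))
  d2 <- d; d2$g <- ifelse(d$g == "a", "b", "a")
  ra <- compare_groups(d, "v", "g"); rb <- compare_groups(d2, "v", "g")
  expect_equal(ra$statistic, -rb$statistic)
  expect_equal(ra$p_value, rb$p_value)
})

test_that("pooled-t p agrees with a permutation oracle", {
  set.seed(19)
  x <- rnorm(12, 0, 1); y <- rnorm(10, 0.8, 1)
  p_t <- compare_groups(df2(x, y), "v", "g")$p_value
  v <- c(x, y); nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  perm <- replicate(4000, {
    s <- sample(length(v), nx)
    abs(mean(v[s]) - mean(v[-s]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_t - p_perm), 0.04)
})

test_that("welch and mann-whitney variants run and return valid p-values", {
  d <- df2(rnorm(8), rnorm(9, 1, 3))
  for (m in c("welch_t", "mann_whitney")) {
    r <- compare_groups(d, "v", "g", method = m)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("ANOVA F matches the sums-of-squares oracle and Bonferroni is by definition", {
  # three identical groups: F = 0, p = 1, all adjusted pairwise p = 1
  d0 <- data.frame(v = rep(c(1, 2, 3), 3), g = rep(c("x", "y", "z"), each = 3))
  r0 <- anova_bonferroni(d0, "v", "g")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_true(all(r0$pairwise$p_adjusted == 1))

  set.seed(5)
  d <- data.frame(v = rnorm(36, rep(c(1, 1.5, 2, 2.5, 3, 3.5), each = 6), 0.6),
                  g = rep(letters[1:6], each = 6))
  r <- anova_bonferroni(d, "v", "g")
  # between/within mean-square oracle
  gm <- mean(d$v)
  ssb <- sum(tapply(d$v, d$g, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(d$v, d$g, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / 5) / (ssw / 30)
  expect_equal(r$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(r$df, c(5, 30))
  expect_true(all(r$pairwise$p_adjusted ==
                    pmin(1, r$pairwise$p_raw * nrow(r$pairwise))))
  expect_true(all(r$pairwise$p_adjusted >= r$pairwise$p_raw))
  expect_error(anova_bonferroni(d[1:11, ], "v", "g"), "at least")
})

test_that("chi-square matches the expected-count oracle", {
  r0 <- proportion_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # gender-style 2x2: 12/4 vs 8/6
  r <- proportion_test(matrix(c(12, 8, 4, 6), 2))
  expect_equal(r$statistic, 1.0714, tolerance = 1e-4)
  expect_equal(r$df, 1)
  set.seed(9)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 12) + 1, 2)
    r <- proportion_test(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(r$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
  }
  expect_error(proportion_test(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("regression matches the normal-equations oracle and screens predictors", {
  set.seed(13)
  n <- 60
  d <- data.frame(age = rnorm(n, 50, 12), sex = sample(c("m", "f"), n, TRUE),
                  noisevar = rnorm(n))
  d$ecv <- 0.2 + 0.001 * d$age + rnorm(n, 0, 0.01)
  r <- regress_ecv(d, "ecv", c("age", "sex", "noisevar"), multivariate = TRUE)
  expect_true(all(abs(r$univariate$R) <= 1))
  expect_true("age" %in% r$entered)
  expect_false("noisevar" %in% r$entered)
  # multivariate coefficients equal the closed-form OLS solution
  X <- cbind(1, as.matrix(d[, r$entered, drop = FALSE]))
  beta <- solve(t(X) %*% X, t(X) %*% d$ecv)
  expect_equal(unname(r$coefficients[, 1]), unname(drop(beta)), tolerance = 1e-10)

  # exact linear response: R = 1, p ~ 0
  d$lin <- 2 * d$age
  ru <- regress_ecv(d, "lin", "age")
  expect_equal(ru$univariate$R, 1, tolerance = 1e-12)
  expect_lt(ru$univariate$p_value, 1e-12)
})

test_that("an independent predictor shows |R| < 0.05 at n = 1e4", {
  set.seed(29)
  d <- data.frame(x = rnorm(1e4), y = rnorm(1e4))
  expect_lt(abs(regress_ecv(d, "y", "x")$univariate$R), 0.05)
})
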