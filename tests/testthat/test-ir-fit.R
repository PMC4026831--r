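# Magnitude inversion-recovery fitting: exact round trips, polarity
# restoration against a brute-force nls oracle, scale invariance,
# Look-Locker correction, and noise behaviour.

scheme <- build_scheme_335(1000)
tis <- scheme$effective_tis

test_that("noiseless fits recover the generating parameters exactly", {
  cases <- list(c(1.0, 1.95, 850), c(0.8, 1.5, 1200), c(2.0, 4.0, 300),
                c(1.0, 2.0, 1711.1))
  for (p in cases) {
    y <- molli_signal(p[1], p[2], p[3], tis)
    f <- fit_ir_magnitude(y, tis)
    expect_true(f$valid)
    expect_equal(f$a, p[1], tolerance = 1e-6)
    expect_equal(f$b, p[2], tolerance = 1e-6)
    expect_equal(f$t1_star, p[3], tolerance = 1e-6)
  }
})

test_that("polarity restoration finds the brute-force global optimum", {
  # a=1, b=2, T1*=800: null at 800 ln 2 = 554 ms, i.e. between the 3rd and
  # 4th TI in ascending order -> polarity index 3
  y <- molli_signal(1, 2, 800, tis)
  f <- fit_ir_magnitude(y, tis)
  expect_identical(f$polarity_index, 3L)
  expect_equal(f$t1_star, 800, tolerance = 1e-6)
  expect_equal(look_locker_correct(f), 800, tolerance = 1e-5)

  # independent oracle: exhaustive polarity search, each candidate fitted
  # with nls on the signed data
  ord <- order(tis)
  brute <- sapply(0:5, function(p) {
    ys <- y[ord]
    if (p > 0) ys[seq_len(p)] <- -ys[seq_len(p)]
    fit <- tryCatch(suppressWarnings(
      nls(ys ~ a - b * exp(-tis[ord] / t1s),
          start = list(a = 1.1, b = 1.9, t1s = 700),
          control = nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) Inf else sum(residuals(fit)^2)
  })
  expect_identical(which.min(brute) - 1L, f$polarity_index)
})

test_that("fitted T1 is invariant to positive rescaling of the signal", {
  set.seed(11)
  y <- rician(molli_signal(1, 1.9, 1100, tis), 0.02)
  f1 <- fit_ir_magnitude(y, tis)
  f2 <- fit_ir_magnitude(7.3 * y, tis)
  expect_equal(f2$a / f1$a, 7.3, tolerance = 1e-6)
  expect_equal(f2$b / f1$b, 7.3, tolerance = 1e-6)
  expect_equal(f2$t1_star, f1$t1_star, tolerance = 1e-7)
  expect_equal(look_locker_correct(f2), look_locker_correct(f1),
               tolerance = 1e-6)
})

test_that("Look-Locker correction follows T1 = T1* (b/a - 1)", {
  expect_equal(look_locker_correct(list(a = 1, b = 2, t1_star = 800)), 800)
  expect_equal(look_locker_correct(list(a = 1, b = 1.8, t1_star = 900)), 720)
  # b = 2a is the identity case
  expect_equal(look_locker_correct(list(a = 1.4, b = 2.8, t1_star = 640)), 640)
  # degenerate b <= a: flagged invalid (NA), not an error
  expect_true(is.na(look_locker_correct(list(a = 2, b = 2, t1_star = 500))))
})

test_that("degenerate signals give an invalid flag, not an error", {
  f <- fit_ir_magnitude(rep(3, 11), tis)
  expect_false(f$valid)
})

test_that("median recovered T1 is within 2% at SNR 50 and bias shrinks with SNR", {
  t1_true <- 1000
  b_over_a <- 1.9
  t1_star <- t1_true / (b_over_a - 1)
  clean <- molli_signal(1, b_over_a, t1_star, tis)
  run_snr <- function(snr, n) {
    set.seed(1000 + snr)
    S <- t(replicate(n, rician(clean, 1 / snr)))
    r <- cmrfibrosis:::.ir_fit_batch(S, tis)
    r$t1[r$valid]
  }
  t1_50 <- run_snr(50, 1000)
  expect_lt(abs(median(t1_50) - t1_true) / t1_true, 0.02)
  bias <- sapply(c(20, 50, 100), function(s) abs(mean(run_snr(s, 400)) - t1_true))
  expect_true(all(diff(bias) < 0))
})
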