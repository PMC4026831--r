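# LGE signal-intensity threshold segmentation.

mk_image <- function(px, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  lge_image(px, mask)
}

test_that("locate_core_max_si returns the ROI maximum and validates the ROI", {
  px <- matrix(0, 5, 5)
  px[2, 2] <- 10; px[2, 3] <- 50; px[3, 2] <- 100
  img <- mk_image(px)
  roi <- matrix(FALSE, 5, 5); roi[2:3, 2:3] <- TRUE
  expect_equal(locate_core_max_si(img, roi), 100)
  # uniform ROI returns the common value
  expect_equal(locate_core_max_si(mk_image(matrix(7, 4, 4)),
                                  matrix(TRUE, 4, 4)), 7)
  expect_error(locate_core_max_si(img, matrix(FALSE, 5, 5)), "empty")
  m <- matrix(TRUE, 5, 5); m[1, 1] <- FALSE
  out <- matrix(FALSE, 5, 5); out[1, 1] <- TRUE
  expect_error(locate_core_max_si(mk_image(px, m), out), "within")
})

test_that("classification applies the 20%/50% rule with FWHM boundary semantics", {
  px <- matrix(c(10, 19.999, 20, 35, 49.999, 50, 80, 100, 0), 3, 3)
  em <- classify_enhancement(mk_image(px), max_si = 100)
  cls <- em$classes
  expect_equal(cls[px < 20], rep(1L, sum(px < 20)))
  expect_equal(cls[px >= 20 & px < 50], rep(2L, sum(px >= 20 & px < 50)))
  expect_equal(cls[px >= 50], rep(3L, sum(px >= 50)))
  expect_error(classify_enhancement(mk_image(px), max_si = 0), "max_si")
})

test_that("classes partition the mask, scale-invariantly, matching a brute-force oracle", {
  set.seed(17)
  for (i in 1:10) {
    px <- matrix(runif(400, 0, 3), 20, 20)
    mask <- matrix(runif(400) > 0.3, 20, 20)
    if (!any(mask)) next
    img <- lge_image(px, mask)
    max_si <- runif(1, 0.5, 3)
    em <- classify_enhancement(img, max_si)
    # partition property
    counts <- table(factor(em$classes[mask], levels = 1:3))
    expect_equal(sum(counts), sum(mask))
    expect_true(all(em$classes[!mask] == 0L))
    # brute-force per-pixel oracle
    oracle <- ifelse(px / max_si < 0.2, 1L, ifelse(px / max_si < 0.5, 2L, 3L))
    oracle[!mask] <- 0L
    expect_identical(em$classes, oracle)
    # scale invariance
    em2 <- classify_enhancement(lge_image(px * 3.7, mask), max_si * 3.7)
    expect_identical(em2$classes, em$classes)
    # monotone thresholds: raising max SI never upgrades a class
    em3 <- classify_enhancement(img, max_si * 1.5)
    expect_true(all(em3$classes[mask] <= em$classes[mask]))
  }
})

test_that("extract_roi returns the largest 8-connected component above min_area", {
  mask <- matrix(TRUE, 20, 20)
  px <- matrix(0, 20, 20)
  px[2:11, 2:11] <- 100   # 100-pixel enhanced block
  px[15:19, 14:19] <- 100 # 30-pixel block, disconnected
  em <- classify_enhancement(lge_image(px, mask), 100)
  roi <- extract_roi(em, "enhanced", min_area = 10)
  expect_equal(sum(roi), 100)
  expect_true(all(which(roi) %in% which(px == 100)))
  # min_area above every component -> empty, reported as absent
  expect_equal(sum(extract_roi(em, "enhanced", min_area = 500)), 0)
  # diagonal connectivity joins components (8-connectedness)
  px2 <- matrix(0, 5, 5); px2[1, 1] <- 100; px2[2, 2] <- 100
  em2 <- classify_enhancement(lge_image(px2, matrix(TRUE, 5, 5)), 100)
  expect_equal(sum(extract_roi(em2, "enhanced")), 2)
})

test_that("threshold transfer reuses the reference max SI on the target slice", {
  px <- matrix(1, 8, 8); px[3:4, 3:4] <- 10
  img <- mk_image(px)
  core <- matrix(FALSE, 8, 8); core[3:4, 3:4] <- TRUE
  # self-transfer equals direct classification
  em_direct <- classify_enhancement(img, locate_core_max_si(img, core))
  em_self <- transfer_threshold(img, core, img)
  expect_identical(em_self$classes, em_direct$classes)
  # a quiet target slice is all non-enhanced
  quiet <- mk_image(matrix(1, 8, 8))
  em_q <- transfer_threshold(img, core, quiet)
  expect_true(all(em_q$classes[quiet$myo_mask] == 1L))
})

test_that("phantom classification agrees with ground-truth classes at SNR 50", {
  s <- tiny_subject(lesion = TRUE, snr = 50, seed = 6)
  em <- classify_enhancement(s$lge$image,
                             locate_core_max_si(s$lge$image, auto_core_roi(s)))
  myo <- s$masks$myocardium
  truth <- c(`1` = 1L, `2` = 2L, `3` = 3L)[as.character(s$masks$region[myo])]
  expect_gt(mean(em$classes[myo] == truth), 0.95)
  # lesion-core peak: measured max SI within noise of the clean core signal
  clean <- abs(1 - 2 * exp(-s$lge$ti_null / s$gt$t1_lge))
  expect_lt(abs(em$max_si - max(clean[s$masks$region == 3L])), 6 / s$snr)
})
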