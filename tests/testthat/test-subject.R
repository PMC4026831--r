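# Synthetic subject generation: determinism, ground-truth invariants and the
# LGE rendering model.

test_that("generation is a pure function of the seed", {
  s1 <- tiny_subject(snr = 50, seed = 99)
  s2 <- tiny_subject(snr = 50, seed = 99)
  expect_identical(s1$molli$pre$frames, s2$molli$pre$frames)
  expect_identical(s1$molli$post20$frames, s2$molli$post20$frames)
  expect_identical(s1$lge$image$pixels, s2$lge$image$pixels)
  s3 <- tiny_subject(snr = 50, seed = 100)
  expect_false(identical(s1$molli$pre$frames, s3$molli$pre$frames))
})

test_that("ground-truth ECV is lambda (1 - Hct) per region and LGE+ iff lesioned", {
  tm <- tissue_model(lambda_remote = 0.5, hematocrit = 0.48)
  s <- generate_subject(tiny_geometry(), tm, seed = 1, snr = Inf)
  expect_equal(s$gt$ecv$remote, 0.26)
  expect_false(s$lge_positive)
  expect_null(s$gt$ecv$core)

  sl <- tiny_subject(lesion = TRUE, ecv = 0.27, hct = 0.4, snr = Inf)
  expect_true(sl$lge_positive)
  expect_equal(sl$gt$ecv$core, 0.45)
  expect_equal(sl$gt$ecv$border, 0.35)
  expect_equal(sl$gt$ecv$remote, 0.27)
})

test_that("ground-truth R1 courses are collinear with slope lambda by construction", {
  s <- tiny_subject(ecv = 0.3, hct = 0.45, snr = Inf)
  lam <- s$tissue$lambda_remote
  myo_px <- which(s$masks$region == 1L)[1]
  r1_myo <- sapply(s$gt$t1, function(t1) 1000 / t1[myo_px])
  fit <- fit_partition_coefficient(r1_myo, s$gt$blood_r1)
  expect_equal(fit$lambda, lam, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("LGE nulling: remote myocardium at zero, lesion bright, closed-form pixels", {
  s <- tiny_subject(lesion = TRUE, snr = Inf, seed = 2)
  img <- s$lge$image$pixels
  remote <- s$masks$region == 1L
  core <- s$masks$region == 3L
  t1_remote <- median(s$gt$t1_lge[remote])
  expect_equal(s$lge$ti_null, t1_remote * log(2), tolerance = 1e-9)
  expect_lt(max(img[remote]), 1e-9)
  expect_gt(mean(img[core]), mean(img[remote]))
  # every body pixel matches |1 - 2 exp(-TI/T1)| exactly
  body <- is.finite(s$gt$t1_lge)
  expect_equal(img[body],
               abs(1 - 2 * exp(-s$lge$ti_null / s$gt$t1_lge[body])),
               tolerance = 1e-12)
  # explicit nulling TI for a uniform-lambda subject
  lge2 <- render_lge_image(s, ti_null = t1_remote * log(2), noise_sd = 0)
  expect_lt(max(lge2$image$pixels[remote]), 1e-9)
  expect_error(render_lge_image(s, ti_null = -10), "ti_null")
})

test_that("geometry rejects impossible lesions and hypertrophy", {
  expect_error(phantom_geometry(lesion_sectors = data.frame(
    start_deg = 0, end_deg = 40, inner_frac = 0.9, outer_frac = 0.4,
    class = "core")), "within the myocardium")
  expect_error(phantom_geometry(endo_radius = 30, epi_radius = 25), "epi_radius")
  expect_error(phantom_geometry(grid_size = 48, pixel_spacing = 1,
                                epi_radius = 30), "fit")
})
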