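# Contrast kinetics: blood R1 course and equilibrium tissue R1.

test_that("pre-contrast blood R1 equals 1000/T1 and the washout matches the closed form", {
  tm <- tissue_model(native_t1_blood = 1540, relaxivity_r1 = 4.0,
                     washout_amplitudes = c(2.0, 1.0),
                     washout_rates = c(0.3, 0.02))
  r1 <- simulate_blood_r1_course(tm, c(0, 8, 20))
  expect_equal(as.numeric(r1)[1], 1000 / 1540)
  expect_equal(as.numeric(r1)[1], 0.6494, tolerance = 1e-4)
  # independent evaluation of the stated closed form
  cb <- function(t) 2.0 * exp(-0.3 * t) + 1.0 * exp(-0.02 * t)
  expect_equal(as.numeric(r1)[2], 1000 / 1540 + 4.0 * cb(8), tolerance = 1e-12)
  expect_equal(as.numeric(r1)[3], 1000 / 1540 + 4.0 * cb(20), tolerance = 1e-12)
})

test_that("post-contrast blood R1 is strictly decreasing for any valid tissue model", {
  set.seed(4)
  for (i in 1:20) {
    tm <- tissue_model(native_t1_blood = runif(1, 1300, 1800),
                       relaxivity_r1 = runif(1, 3, 5),
                       washout_amplitudes = runif(2, 0.5, 3),
                       washout_rates = sort(runif(2, 0.01, 0.5), decreasing = TRUE))
    r1 <- as.numeric(simulate_blood_r1_course(tm, c(0, 4, 8, 12, 20, 30)))
    expect_true(all(diff(r1[-1]) < 0))
  }
})

test_that("negative times and invalid parameters are rejected", {
  tm <- tissue_model()
  expect_error(simulate_blood_r1_course(tm, c(-1, 8)), "non-negative")
  expect_error(tissue_model(hematocrit = 1.2), "hematocrit")
  expect_error(tissue_model(lambda_remote = 0), "partition")
  expect_error(tissue_model(lambda_remote = 1.3), "partition")
  expect_error(tissue_model(lambda_remote = 0.6, lambda_core = 0.5), ">=")
})

test_that("tissue R1 scales the blood R1 change by lambda", {
  tm <- tissue_model()
  blood <- structure(c(0.65, 2.65, 1.85), times = c(0, 8, 20),
                     class = "r1_course")
  # identity case
  myo1 <- derive_tissue_r1(blood, 1.0, 1000)
  expect_equal(as.numeric(myo1) - 1.0, as.numeric(blood) - 0.65)
  # lambda = 0.5 halves the deltas
  myo <- derive_tissue_r1(blood, 0.5, 1000)
  expect_equal(as.numeric(myo), 1.0 + 0.5 * c(0, 2.0, 1.2))
  # lambda = 0 is outside the contract
  expect_error(derive_tissue_r1(blood, 0, 1000), "partition")
  # course without the pre-contrast point is rejected
  bad <- structure(c(2.65, 1.85), times = c(8, 20), class = "r1_course")
  expect_error(derive_tissue_r1(bad, 0.5, 1000), "pre-contrast")
})
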