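# AHA six-segment division, wall thickness, hypertrophy, LV mass.

circle_contour <- function(r, n = 360, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = centre[1] + r * cos(th), y = centre[2] + r * sin(th))
}

test_that("a symmetric annulus divides into six near-equal segments that partition it", {
  ras <- rasterize_phantom(tiny_geometry())
  segs <- divide_aha6(ras$myocardium, rv_insertion_angle = 90)
  n_total <- sum(ras$myocardium)
  counts <- tabulate(segs$labels[segs$labels > 0], 6)
  expect_equal(sum(counts), n_total)             # partition
  expect_true(all(abs(counts - n_total / 6) <= 0.01 * n_total))
  # every myocardial pixel is labelled, nothing outside is
  expect_true(all((segs$labels > 0) == ras$myocardium))
})

test_that("rotating the RV insertion by 60 degrees shifts labels by one position", {
  ras <- rasterize_phantom(tiny_geometry())
  a <- divide_aha6(ras$myocardium, rv_insertion_angle = 90)
  b <- divide_aha6(ras$myocardium, rv_insertion_angle = 150)
  ma <- segment_masks(a); mb <- segment_masks(b)
  for (k in 1:6) {
    # segment k measured from the rotated anchor equals segment k+1 from the
    # original anchor
    expect_identical(mb[[cmrfibrosis:::AHA6_LABELS[k]]],
                     ma[[cmrfibrosis:::AHA6_LABELS[(k %% 6) + 1]]])
  }
})

test_that("segment assignment equals a per-pixel angle-binning oracle on random annuli", {
  set.seed(41)
  for (i in 1:5) {
    g <- phantom_geometry(grid_size = 40, pixel_spacing = 2,
                          endo_radius = runif(1, 8, 14),
                          epi_radius = runif(1, 20, 26))
    ras <- rasterize_phantom(g)
    rv <- runif(1, 0, 360)
    segs <- divide_aha6(ras$myocardium, rv_insertion_angle = rv)
    idx <- which(ras$myocardium, arr.ind = TRUE)
    ctr <- colMeans(idx)
    th <- (atan2(idx[, 1] - ctr[1], idx[, 2] - ctr[2]) * 180 / pi) %% 360
    oracle <- 1L + (floor(((th - rv) %% 360) / 60) %% 6L)
    expect_equal(segs$labels[cbind(idx[, 1], idx[, 2])], oracle)
  }
})

test_that("degenerate (non-annular) masks are rejected", {
  expect_error(divide_aha6(matrix(FALSE, 10, 10), 0), "degenerate")
  disk <- matrix(TRUE, 11, 11)   # no cavity
  expect_error(divide_aha6(disk, 0), "degenerate")
})

test_that("wall thickness matches analytic geometry", {
  # circular annulus: 10 mm in every segment
  ct <- lv_contours(circle_contour(25), circle_contour(35), rv_insertion_angle = 90)
  wt <- wall_thickness(ct)
  expect_equal(as.numeric(wt), rep(10, 6), tolerance = 1e-6)
  expect_equal(attr(wt, "max"), 10, tolerance = 1e-6)

  # septal epicardial bulge to 41 mm -> 16 mm in that segment only
  g <- tiny_geometry(thick_sectors = data.frame(
    start_deg = 90, end_deg = 150, epi_radius = 41), rv_insertion_angle = 90)
  wt2 <- wall_thickness(phantom_contours(g))
  expect_equal(unname(wt2["anteroseptal"]), 16, tolerance = 0.05)
  expect_equal(unname(wt2["inferior"]), 10, tolerance = 1e-6)

  # elliptical borders: radial-distance oracle within 2%
  th <- seq(0, 2 * pi, length.out = 360)[-360]
  r_of <- function(a, b) a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  endo <- cbind(30 * cos(th), 24 * sin(th))
  epi <- cbind(40 * cos(th), 34 * sin(th))
  ct3 <- lv_contours(endo, epi, rv_insertion_angle = 0)
  wt3 <- wall_thickness(ct3)
  seg_oracle <- sapply(0:5, function(k) {
    deg <- (th * 180 / pi) %% 360
    sel <- deg >= 60 * k & deg < 60 * (k + 1)
    mean((r_of(40, 34) - r_of(30, 24))[sel])
  })
  expect_equal(as.numeric(wt3), seg_oracle, tolerance = 0.02)

  # crossing contours rejected at construction
  expect_error(lv_contours(circle_contour(25), circle_contour(24), 0), "enclose")
})

test_that("hypertrophy threshold is inclusive at 15 mm", {
  expect_true(classify_hypertrophic(18))
  expect_false(classify_hypertrophic(14.9))
  expect_true(classify_hypertrophic(15.0))
  expect_error(classify_hypertrophic(-2), "positive")
})

test_that("LV mass matches the analytic cylinder and is rigid-motion invariant", {
  ct <- lv_contours(circle_contour(25), circle_contour(35),
                    rv_insertion_angle = 0, slice_thickness = 10, slice_gap = 0)
  m <- lv_mass_indexed(ct, bsa = 2.0)
  expect_equal(m$volume_ml, pi * (35^2 - 25^2) * 10 / 1000, tolerance = 1e-3)
  expect_equal(m$mass_g, 19.79, tolerance = 1e-2)
  expect_equal(m$indexed_g_m2, 9.90, tolerance = 1e-2)

  # translation + rotation leave the mass unchanged
  rot <- function(p, deg, dxy) {
    a <- deg * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    sweep(p %*% R, 2, dxy, `+`)
  }
  ct2 <- lv_contours(rot(circle_contour(25), 33, c(12, -7)),
                     rot(circle_contour(35), 33, c(12, -7)),
                     rv_insertion_angle = 0, slice_thickness = 10)
  expect_equal(lv_mass_indexed(ct2, 2)$mass_g, m$mass_g, tolerance = 1e-9)

  # two stacked slices of known volume within 1%
  slices <- list(ct, lv_contours(circle_contour(24), circle_contour(33),
                                 rv_insertion_angle = 0, slice_thickness = 10))
  v_true <- (pi * (35^2 - 25^2) * 10 + pi * (33^2 - 24^2) * 10) / 1000
  expect_equal(lv_mass_indexed(slices, 2)$volume_ml, v_true, tolerance = 0.01)
})
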