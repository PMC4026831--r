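# AHA six-segment mid-ventricular analysis: segment division, wall thickness,
# hypertrophy classification and BSA-indexed LV mass.

# Mid-cavity AHA segment names in counter-clockwise order starting at the
# anterior RV insertion (the septum is traversed first).
AHA6_LABELS <- c("anteroseptal", "inferoseptal", "inferior",
                 "inferolateral", "anterolateral", "anterior")

.segment_index <- function(theta, rv_insertion_angle) {
  1L + (floor(deg_mod(theta - rv_insertion_angle) / 60) %% 6L)
}

#' Construct left-ventricular contours
#'
#' Closed endocardial and epicardial contours of one short-axis slice, in mm
#' coordinates. The epicardial contour must strictly enclose the endocardial
#' contour (checked radially about the endocardial centroid).
#'
#' @param endo,epi Two-column matrices (`x`, `y`) of contour points, mm.
#' @param rv_insertion_angle Angle (deg) of the anterior RV insertion about
#'   the cavity centroid.
#' @param slice_thickness,slice_gap Slice geometry, mm.
#' @return Object of class `lv_contours`.
#' @export
lv_contours <- function(endo, epi, rv_insertion_angle,
                        slice_thickness = 8, slice_gap = 0) {
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  abort_if(ncol(endo) != 2L || ncol(epi) != 2L || nrow(endo) < 8L || nrow(epi) < 8L,
           "contours must be two-column point matrices with >= 8 points")
  check_number(slice_thickness, "slice_thickness", lower = 0, open_lower = TRUE)
  check_number(slice_gap, "slice_gap", lower = 0)
  ctr <- colMeans(endo)
  r_endo <- .radial_profile(endo, ctr)
  r_epi <- .radial_profile(epi, ctr)
  abort_if(any(r_epi <= r_endo),
           "epicardial contour must strictly enclose the endocardial contour")
  structure(list(endo = endo, epi = epi, centroid = ctr,
                 rv_insertion_angle = deg_mod(rv_insertion_angle),
                 slice_thickness = slice_thickness, slice_gap = slice_gap),
            class = "lv_contours")
}

# Radius (mm) of a star-shaped contour at 1-degree ray angles about `ctr`.
.radial_profile <- function(points, ctr, theta_out = 0:359) {
  dx <- points[, 1] - ctr[1]; dy <- points[, 2] - ctr[2]
  ang <- deg_mod(atan2(dy, dx) * 180 / pi)
  r <- sqrt(dx^2 + dy^2)
  o <- order(ang)
  ang <- ang[o]; r <- r[o]
  # wrap for periodic interpolation
  ang_w <- c(ang[length(ang)] - 360, ang, ang[1] + 360)
  r_w <- c(r[length(r)], r, r[1])
  stats::approx(ang_w, r_w, xout = theta_out, rule = 2)$y
}

#' Divide a myocardial mask into the six AHA mid-cavity segments
#'
#' Assigns every myocardial pixel to one of six contiguous 60-degree angular
#' sectors measured counter-clockwise from the anterior RV insertion, labelled
#' (in traversal order, septum first): anteroseptal, inferoseptal, inferior,
#' inferolateral, anterolateral, anterior.
#'
#' @param mask Logical annular myocardial mask.
#' @param rv_insertion_angle Anchor angle in degrees.
#' @param centroid Cavity centre as `(row, col)` pixel coordinates; defaults
#'   to the centroid of the mask pixels.
#' @return Object of class `segment_set`: `labels` (integer matrix, 0 outside,
#'   1..6 by segment), `segment_names`, `rv_insertion_angle`, `centroid`.
#' @export
divide_aha6 <- function(mask, rv_insertion_angle, centroid = NULL) {
  abort_if(!is.logical(mask) || !is.matrix(mask), "'mask' must be a logical matrix")
  idx <- which(mask, arr.ind = TRUE)
  abort_if(nrow(idx) < 6L, "degenerate mask: too few myocardial pixels")
  if (is.null(centroid)) centroid <- colMeans(idx)
  cr <- round(centroid)
  abort_if(cr[1] >= 1 && cr[1] <= nrow(mask) && cr[2] >= 1 && cr[2] <= ncol(mask) &&
             mask[cr[1], cr[2]],
           "degenerate mask: centroid lies inside the myocardium (no annulus)")
  theta <- deg_mod(atan2(idx[, 1] - centroid[1], idx[, 2] - centroid[2]) * 180 / pi)
  seg <- .segment_index(theta, rv_insertion_angle)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[cbind(idx[, 1], idx[, 2])] <- seg
  structure(list(labels = labels, segment_names = AHA6_LABELS,
                 rv_insertion_angle = deg_mod(rv_insertion_angle),
                 centroid = centroid),
            class = "segment_set")
}

#' Per-segment pixel masks from a segment set
#'
#' @param segments A [divide_aha6()] result.
#' @return Named list of six logical matrices.
#' @export
segment_masks <- function(segments) {
  stopifnot(inherits(segments, "segment_set"))
  out <- lapply(seq_along(AHA6_LABELS), function(k) segments$labels == k)
  names(out) <- segments$segment_names
  out
}

#' Per-segment wall thickness from LV contours
#'
#' Measures the radial epicardium-endocardium distance along rays (1-degree
#' steps) from the cavity centroid and averages it within each AHA segment's
#' sector. The maximum single-ray thickness is attached as attribute `"max"`.
#'
#' @param contours An [lv_contours()] object.
#' @param segment Optional segment name(s) to return; default all six.
#' @return Named numeric vector of mean thickness (mm) per segment.
#' @examples
#' # circular annulus, endo 25 mm / epi 35 mm -> 10 mm everywhere
#' @export
wall_thickness <- function(contours, segment = NULL) {
  stopifnot(inherits(contours, "lv_contours"))
  theta <- 0:359
  thick <- .radial_profile(contours$epi, contours$centroid, theta) -
    .radial_profile(contours$endo, contours$centroid, theta)
  abort_if(any(thick <= 0), "crossing contours: non-positive wall thickness")
  seg <- .segment_index(theta, contours$rv_insertion_angle)
  out <- vapply(1:6, function(k) mean(thick[seg == k]), numeric(1))
  names(out) <- AHA6_LABELS
  if (!is.null(segment)) {
    abort_if(!all(segment %in% AHA6_LABELS), "unknown segment name")
    out <- out[segment]
  }
  attr(out, "max") <- max(thick)
  out
}

#' Classify hypertrophic segments
#'
#' A segment is hypertrophic when its wall thickness is at or above the
#' threshold (>= 15 mm by convention for hypertrophic cardiomyopathy).
#'
#' @param thickness Wall thickness in mm (vector allowed).
#' @param threshold Threshold in mm, inclusive.
#' @return Logical flag(s).
#' @export
classify_hypertrophic <- function(thickness, threshold = 15) {
  abort_if(any(!is.finite(thickness)) || any(thickness <= 0),
           "thickness must be positive")
  thickness >= threshold
}

.polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(seq_len(nrow(p))[-1], 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' BSA-indexed left-ventricular mass from contours
#'
#' Slice myocardial volume is (epicardial area - endocardial area) times the
#' slice thickness plus gap; mass uses the standard myocardial density of
#' 1.05 g/mL and is indexed to body surface area.
#'
#' @param contours An [lv_contours()] object or a list of them (one per slice).
#' @param bsa Body surface area in m^2.
#' @return List of class `lv_mass`: `volume_ml`, `mass_g`, `indexed_g_m2`.
#' @examples
#' # endo r=25, epi r=35, 10 mm slice: volume 18.85 mL, mass 19.79 g
#' @export
lv_mass_indexed <- function(contours, bsa) {
  check_number(bsa, "bsa", lower = 0, open_lower = TRUE)
  if (inherits(contours, "lv_contours")) contours <- list(contours)
  vol_mm3 <- 0
  for (sl in contours) {
    stopifnot(inherits(sl, "lv_contours"))
    a <- .polygon_area(sl$epi) - .polygon_area(sl$endo)
    abort_if(a <= 0, "non-positive myocardial slice area")
    vol_mm3 <- vol_mm3 + a * (sl$slice_thickness + sl$slice_gap)
  }
  mass_g <- vol_mm3 * 1.05e-3   # 1.05 g/mL
  structure(list(volume_ml = vol_mm3 / 1000, mass_g = mass_g,
                 indexed_g_m2 = mass_g / bsa), class = "lv_mass")
}
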