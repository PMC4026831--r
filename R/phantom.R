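# Short-axis phantom geometry and rasterisation.
#
# The phantom is a mid-ventricular short-axis slice: an annular myocardium
# (endocardial radius .. epicardial radius) around a circular blood pool.
# The epicardial radius may be raised over angular sectors to create
# hypertrophic wall segments, and lesion sectors (core / border tissue
# classes) can be placed inside the wall. Angles are measured
# counter-clockwise in image coordinates, in degrees [0, 360).

#' Construct a phantom geometry
#'
#' @param grid_size Image size in pixels (square grid).
#' @param pixel_spacing Pixel size in mm.
#' @param endo_radius Endocardial radius, mm.
#' @param epi_radius Baseline epicardial radius, mm (> `endo_radius`).
#' @param rv_insertion_angle Angle (deg) of the anterior right-ventricular
#'   insertion point, the anchor of the AHA segmentation.
#' @param thick_sectors Optional data.frame `start_deg`, `end_deg`,
#'   `epi_radius`: angular sectors whose epicardial radius is raised
#'   (hypertrophy). Arcs are `[start, end)` CCW and may wrap through 0.
#' @param lesion_sectors Optional data.frame `start_deg`, `end_deg`,
#'   `inner_frac`, `outer_frac`, `class` (`"core"` or `"border"`): annular
#'   sectors of focal fibrosis, radially positioned as fractions of the local
#'   wall thickness (0 = endocardium, 1 = epicardium).
#' @param blood_margin Erosion (mm) between endocardium and the blood-pool
#'   mask, excluding partial-volume boundary pixels.
#' @return Object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid_size = 96, pixel_spacing = 1.2,
                             endo_radius = 25, epi_radius = 35,
                             rv_insertion_angle = 90,
                             thick_sectors = NULL, lesion_sectors = NULL,
                             blood_margin = 3) {
  check_number(grid_size, "grid_size", lower = 16)
  check_number(pixel_spacing, "pixel_spacing", lower = 0, open_lower = TRUE)
  check_number(endo_radius, "endo_radius", lower = 0, open_lower = TRUE)
  check_number(epi_radius, "epi_radius", lower = endo_radius, open_lower = TRUE)
  if (!is.null(thick_sectors)) {
    stopifnot(is.data.frame(thick_sectors),
              all(c("start_deg", "end_deg", "epi_radius") %in% names(thick_sectors)))
    abort_if(any(thick_sectors$epi_radius <= endo_radius),
             "thickened epicardial radius must exceed the endocardial radius")
  }
  if (!is.null(lesion_sectors)) {
    stopifnot(is.data.frame(lesion_sectors),
              all(c("start_deg", "end_deg", "inner_frac", "outer_frac", "class")
                  %in% names(lesion_sectors)))
    abort_if(any(lesion_sectors$inner_frac < 0 | lesion_sectors$outer_frac > 1 |
                   lesion_sectors$inner_frac >= lesion_sectors$outer_frac),
             "lesion sectors must lie within the myocardium (0 <= inner_frac < outer_frac <= 1)")
    abort_if(!all(lesion_sectors$class %in% c("core", "border")),
             "lesion class must be 'core' or 'border'")
  }
  max_r <- max(epi_radius, thick_sectors$epi_radius %||% 0)
  abort_if(max_r >= grid_size * pixel_spacing / 2,
           "epicardium does not fit on the grid")
  structure(list(grid_size = as.integer(grid_size),
                 pixel_spacing = pixel_spacing,
                 endo_radius = endo_radius, epi_radius = epi_radius,
                 rv_insertion_angle = deg_mod(rv_insertion_angle),
                 thick_sectors = thick_sectors,
                 lesion_sectors = lesion_sectors,
                 blood_margin = blood_margin),
            class = "phantom_geometry")
}

# Per-pixel polar coordinates (mm, deg) about the grid centre.
.pixel_polar <- function(geometry) {
  n <- geometry$grid_size
  c0 <- (n + 1) / 2
  xs <- ((seq_len(n)) - c0) * geometry$pixel_spacing
  x <- matrix(xs, n, n, byrow = TRUE)   # column offset
  y <- matrix(xs, n, n)                 # row offset
  list(r = sqrt(x^2 + y^2), theta = deg_mod(atan2(y, x) * 180 / pi))
}

# Local epicardial radius (mm) at angles theta (deg).
.epi_radius_at <- function(geometry, theta) {
  r <- rep(geometry$epi_radius, length(theta))
  ts <- geometry$thick_sectors
  if (!is.null(ts)) {
    for (i in seq_len(nrow(ts))) {
      hit <- angle_in_arc(theta, ts$start_deg[i], ts$end_deg[i])
      r[hit] <- ts$epi_radius[i]
    }
  }
  r
}

#' Rasterise phantom masks and tissue-region labels
#'
#' @param geometry A [phantom_geometry()].
#' @return List: `myocardium` and `blood` logical matrices, `region` integer
#'   matrix (0 background, 1 remote myocardium, 2 lesion border, 3 lesion
#'   core, 4 blood pool), `polar` (per-pixel radius/angle).
#' @export
rasterize_phantom <- function(geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  pp <- .pixel_polar(geometry)
  epi <- matrix(.epi_radius_at(geometry, as.vector(pp$theta)),
                geometry$grid_size, geometry$grid_size)
  myo <- pp$r >= geometry$endo_radius & pp$r < epi
  blood <- pp$r <= geometry$endo_radius - geometry$blood_margin
  region <- matrix(0L, geometry$grid_size, geometry$grid_size)
  region[myo] <- 1L
  ls <- geometry$lesion_sectors
  if (!is.null(ls)) {
    wall <- epi - geometry$endo_radius
    for (i in seq_len(nrow(ls))) {
      hit <- myo &
        angle_in_arc(pp$theta, ls$start_deg[i], ls$end_deg[i]) &
        pp$r >= geometry$endo_radius + ls$inner_frac[i] * wall &
        pp$r <  geometry$endo_radius + ls$outer_frac[i] * wall
      region[hit] <- if (ls$class[i] == "core") 3L else 2L
    }
  }
  region[blood] <- 4L
  list(myocardium = myo, blood = blood, region = region, polar = pp)
}

#' Extract endocardial/epicardial contours from a phantom geometry
#'
#' Samples both borders at 1-degree steps, yielding the analytic contours the
#' generator emits in place of manual delineation.
#'
#' @param geometry A [phantom_geometry()].
#' @param slice_thickness,slice_gap Slice geometry in mm.
#' @return An [lv_contours()] object.
#' @export
phantom_contours <- function(geometry, slice_thickness = 8, slice_gap = 0) {
  theta <- 0:359
  rad <- theta * pi / 180
  endo <- cbind(x = geometry$endo_radius * cos(rad),
                y = geometry$endo_radius * sin(rad))
  r_epi <- .epi_radius_at(geometry, theta)
  epi <- cbind(x = r_epi * cos(rad), y = r_epi * sin(rad))
  lv_contours(endo, epi, rv_insertion_angle = geometry$rv_insertion_angle,
              slice_thickness = slice_thickness, slice_gap = slice_gap)
}
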