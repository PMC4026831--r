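# Plain-text serialization of image stacks and subject bundles.
#
# Stacks are written as whitespace-separated text with a '#dims nr nc nz'
# header (gzip-compressed when the path ends in .gz), plus a JSON sidecar for
# everything that is not a pixel: inversion times, time points, hematocrit,
# ground truth. A standard volumetric container (NIfTI) would be preferable,
# but no NIfTI reader is available in the target R environment; the layout
# (per-subject stacks + sidecar + cohort.csv) is unchanged.

#' Write a matrix or 3-D array as a text image stack
#'
#' @param x Numeric matrix or 3-D array.
#' @param path Output path; `.gz` suffix enables gzip compression.
#' @export
write_image_txt <- function(x, path) {
  d <- dim(x)
  abort_if(is.null(d) || !length(d) %in% c(2L, 3L), "'x' must be a matrix or 3-D array")
  if (length(d) == 2L) d <- c(d, 1L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#dims %d %d %d", d[1], d[2], d[3]), con)
  arr <- array(x, d)
  for (k in seq_len(d[3]))
    utils::write.table(arr[, , k], con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a text image stack written by [write_image_txt()]
#'
#' @param path Input path.
#' @return Matrix (single frame) or 3-D array.
#' @export
read_image_txt <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 1L)
  abort_if(!startsWith(hdr, "#dims "), "not an image stack: missing #dims header")
  d <- as.integer(strsplit(trimws(sub("#dims", "", hdr)), "\\s+")[[1]])
  vals <- scan(con, what = numeric(), quiet = TRUE)
  abort_if(length(vals) != prod(d), "corrupt image stack: size mismatch")
  arr <- array(NA_real_, d)
  per <- d[1] * d[2]
  for (k in seq_len(d[3]))
    arr[, , k] <- matrix(vals[((k - 1) * per + 1):(k * per)], d[1], d[2],
                         byrow = TRUE)
  if (d[3] == 1L) arr[, , 1] else arr
}

#' Write a synthetic subject to disk as a bundle
#'
#' Emits `<id>_molli_<tp>.tsv.gz` (one stack per time point),
#' `<id>_lge.tsv.gz`, `<id>_masks.tsv.gz` (layers: myocardium, blood pool,
#' region labels) and the `<id>_truth.json` sidecar.
#'
#' @param subject A [generate_subject()] result.
#' @param dir Output directory (created if missing).
#' @return The sidecar path, invisibly.
#' @export
write_subject_bundle <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- subject$subject_id
  tps <- names(subject$molli)
  for (tp in tps)
    write_image_txt(subject$molli[[tp]]$frames,
                    file.path(dir, sprintf("%s_molli_%s.tsv.gz", id, tp)))
  write_image_txt(subject$lge$image$pixels,
                  file.path(dir, sprintf("%s_lge.tsv.gz", id)))
  masks <- array(0, c(dim(subject$masks$region), 3L))
  masks[, , 1] <- subject$masks$myocardium
  masks[, , 2] <- subject$masks$blood
  masks[, , 3] <- subject$masks$region
  write_image_txt(masks, file.path(dir, sprintf("%s_masks.tsv.gz", id)))
  sidecar <- list(
    subject_id = id, group = subject$group,
    lge_positive = subject$lge_positive, hct = subject$hct,
    snr = subject$snr, covariates = subject$covariates,
    time_points = subject$gt$times, lge_time = subject$gt$lge_time,
    effective_tis = lapply(subject$molli, `[[`, "effective_tis"),
    rr_interval = subject$scheme$rr_interval,
    ti_null = subject$lge$ti_null,
    pixel_spacing = subject$geometry$pixel_spacing,
    rv_insertion_angle = subject$geometry$rv_insertion_angle,
    endo_radius = subject$geometry$endo_radius,
    epi_radius = subject$geometry$epi_radius,
    thick_sectors = subject$geometry$thick_sectors,
    lesion_sectors = subject$geometry$lesion_sectors,
    ground_truth = subject$gt$ecv)
  path <- file.path(dir, sprintf("%s_truth.json", id))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a subject bundle written by [write_subject_bundle()]
#'
#' Reconstructs the fields [analyze_subject()] needs (images, masks, contours
#' re-derived from the recorded geometry, hematocrit). Ground truth travels
#' in `$gt$ecv` for comparison only.
#'
#' @param dir Bundle directory.
#' @param id Subject identifier.
#' @return A `synthetic_subject`-compatible object.
#' @export
read_subject_bundle <- function(dir, id) {
  sc <- jsonlite::read_json(file.path(dir, sprintf("%s_truth.json", id)),
                            simplifyVector = TRUE)
  masks <- read_image_txt(file.path(dir, sprintf("%s_masks.tsv.gz", id)))
  myo <- masks[, , 1] > 0.5
  as_df <- function(x) if (is.null(x) || !length(x) ||
                           (is.data.frame(x) && !nrow(x))) NULL else as.data.frame(x)
  geom <- phantom_geometry(grid_size = nrow(myo),
                           pixel_spacing = sc$pixel_spacing,
                           endo_radius = sc$endo_radius,
                           epi_radius = sc$epi_radius,
                           rv_insertion_angle = sc$rv_insertion_angle,
                           thick_sectors = as_df(sc$thick_sectors),
                           lesion_sectors = as_df(sc$lesion_sectors))
  tps <- names(sc$effective_tis)
  molli <- lapply(tps, function(tp) {
    frames <- read_image_txt(file.path(dir, sprintf("%s_molli_%s.tsv.gz", id, tp)))
    molli_series(frames, sc$effective_tis[[tp]], time_point = tp,
                 rr_interval = sc$rr_interval)
  })
  names(molli) <- tps
  lge_px <- read_image_txt(file.path(dir, sprintf("%s_lge.tsv.gz", id)))
  structure(list(
    subject_id = sc$subject_id, group = sc$group,
    lge_positive = isTRUE(sc$lge_positive), hct = sc$hct, snr = sc$snr,
    covariates = sc$covariates, geometry = geom,
    masks = list(myocardium = myo, blood = masks[, , 2] > 0.5,
                 region = matrix(as.integer(round(masks[, , 3])),
                                 nrow(myo), ncol(myo))),
    gt = list(times = sc$time_points, lge_time = sc$lge_time, ecv = sc$ground_truth),
    molli = molli,
    lge = list(image = lge_image(lge_px, myo, sc$pixel_spacing),
               ti_null = sc$ti_null, time_min = sc$lge_time),
    contours = phantom_contours(geom)
  ), class = "synthetic_subject")
}
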