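# Synthetic subject: ground-truth tissue maps rendered into MOLLI and LGE
# magnitude images with Rician noise.

# Rician magnitude noise: Gaussian noise on two quadrature channels.
.add_rician <- function(signal, sd) {
  if (sd <= 0) return(signal)
  n1 <- stats::rnorm(length(signal), 0, sd)
  n2 <- stats::rnorm(length(signal), 0, sd)
  matrix(sqrt((signal + n1)^2 + n2^2), nrow(signal), ncol(signal))
}

# Render one MOLLI series from a ground-truth T1 map (ms, NA = background).
# The apparent T1* follows from the inversion factor b/a:
# T1* = T1 / (b/a - 1), so Look-Locker correction of a fit recovers T1.
.render_molli <- function(t1_map, scheme, time_point, inversion_factor = 1.9,
                          noise_sd = 0) {
  t1_star <- t1_map / (inversion_factor - 1)
  nr <- nrow(t1_map); nc <- ncol(t1_map)
  frames <- array(0, c(nr, nc, scheme$n_images))
  body <- is.finite(t1_star)
  for (k in seq_len(scheme$n_images)) {
    f <- matrix(0, nr, nc)
    f[body] <- abs(1 - inversion_factor *
                     exp(-scheme$effective_tis[k] / t1_star[body]))
    frames[, , k] <- .add_rician(f, noise_sd)
  }
  molli_series(frames, scheme$effective_tis, time_point = time_point,
               rr_interval = scheme$rr_interval)
}

#' Render the LGE magnitude image of a synthetic subject
#'
#' Inversion-recovery LGE signal `|1 - 2 exp(-TI / T1_post)|` evaluated on
#' the ground-truth post-contrast T1 at the LGE time point, plus Rician
#' noise. When `ti_null` is omitted it is chosen to null remote myocardium
#' (`TI = T1_remote * ln 2`, the operator's nulling), so remote signal sits
#' at the noise floor while shorter-T1 fibrotic tissue is bright.
#'
#' @param subject A [generate_subject()] result.
#' @param ti_null Inversion time in ms (> 0), or `NULL` for automatic
#'   nulling of remote myocardium.
#' @param noise_sd Rician channel noise SD on the unit-signal scale;
#'   defaults to the subject's rendering noise (`1/snr`).
#' @return List: `image` (an [lge_image()]), `ti_null`, `time_min`.
#' @export
render_lge_image <- function(subject, ti_null = NULL, noise_sd = NULL) {
  stopifnot(inherits(subject, "synthetic_subject"))
  t1 <- subject$gt$t1_lge
  if (is.null(ti_null)) {
    remote <- t1[subject$masks$region == 1L]
    ti_null <- stats::median(remote) * log(2)
  }
  check_number(ti_null, "ti_null", lower = 0, open_lower = TRUE)
  if (is.null(noise_sd)) noise_sd <- if (subject$snr > 0) 1 / subject$snr else 0
  nr <- nrow(t1); nc <- ncol(t1)
  sig <- matrix(0, nr, nc)
  body <- is.finite(t1)
  sig[body] <- abs(1 - 2 * exp(-ti_null / t1[body]))
  sig <- .add_rician(sig, noise_sd)
  list(image = lge_image(sig, subject$masks$myocardium,
                         subject$geometry$pixel_spacing),
       ti_null = ti_null, time_min = subject$gt$lge_time)
}

#' Generate one synthetic subject
#'
#' Builds the ground-truth tissue maps (per-pixel partition coefficient and
#' T1 at every acquisition time), renders the MOLLI series at the three time
#' points and the LGE image, and packages masks, contours and covariates.
#' Deterministic given `seed`.
#'
#' @param geometry A [phantom_geometry()].
#' @param tissue A [tissue_model()].
#' @param seed Integer seed for the rendering noise.
#' @param covariates Optional list (age, sex, bsa, sbp, dbp, ...).
#' @param subject_id Identifier string.
#' @param group Group label: `"control"`, `"HCM"` or `"hypertensive_HCM"`.
#' @param scheme MOLLI sampling scheme ([build_scheme_335()]).
#' @param snr Signal-to-noise ratio at the equilibrium signal (Rician channel
#'   SD = 1/snr); `Inf` or 0 disables noise.
#' @param time_points MOLLI acquisition times in minutes (pre = 0).
#' @param lge_time LGE acquisition time in minutes.
#' @param inversion_factor Rendered `b/a` ratio (2 = perfect inversion).
#' @param segment_lambda Optional named vector of per-AHA-segment remote
#'   partition coefficients (overrides `tissue$lambda_remote` per segment).
#' @param motion_shifts Optional list (named by time-point label) of
#'   `nframes x 2` integer matrices: in-plane translation injected per frame
#'   before noise, emulating respiratory motion.
#' @return Object of class `synthetic_subject`.
#' @export
generate_subject <- function(geometry, tissue, seed, covariates = list(),
                             subject_id = "S01", group = "control",
                             scheme = build_scheme_335(1000), snr = 50,
                             time_points = c(0, 8, 20), lge_time = 10,
                             inversion_factor = 1.9, segment_lambda = NULL,
                             motion_shifts = NULL) {
  stopifnot(inherits(geometry, "phantom_geometry"), inherits(tissue, "tissue_model"))
  abort_if(time_points[1] != 0 || length(time_points) != 3L,
           "time_points must be (0, post1, post2) minutes")
  ras <- rasterize_phantom(geometry)
  lge_positive <- !is.null(geometry$lesion_sectors)
  if (lge_positive)
    abort_if(!any(ras$region == 3L),
             "lesion sectors rasterised to zero core pixels (outside myocardium?)")

  # per-pixel partition coefficient
  lam <- matrix(NA_real_, geometry$grid_size, geometry$grid_size)
  myo <- ras$myocardium
  if (is.null(segment_lambda)) {
    lam[myo] <- tissue$lambda_remote
  } else {
    abort_if(!all(AHA6_LABELS %in% names(segment_lambda)),
             "segment_lambda must name all six AHA segments")
    seg_idx <- .segment_index(ras$polar$theta, geometry$rv_insertion_angle)
    for (k in 1:6) lam[myo & seg_idx == k] <- segment_lambda[[AHA6_LABELS[k]]]
  }
  if (!is.null(tissue$lambda_border)) lam[ras$region == 2L] <- tissue$lambda_border
  if (!is.null(tissue$lambda_core)) lam[ras$region == 3L] <- tissue$lambda_core

  # ground-truth T1 per acquisition time (myocardium + whole cavity as blood)
  all_times <- c(time_points, lge_time)
  blood_r1 <- simulate_blood_r1_course(tissue, all_times)
  d_blood <- as.numeric(blood_r1) - as.numeric(blood_r1)[1]
  cavity <- ras$polar$r < geometry$endo_radius
  t1_at <- function(i) {
    r1 <- matrix(NA_real_, geometry$grid_size, geometry$grid_size)
    r1[myo] <- 1000 / tissue$native_t1_myo + lam[myo] * d_blood[i]
    r1[cavity] <- as.numeric(blood_r1)[i]
    1000 / r1
  }
  t1_gt <- lapply(seq_along(time_points), t1_at)
  tp_labels <- c("pre", paste0("post", time_points[-1]))
  names(t1_gt) <- tp_labels
  t1_lge <- t1_at(length(all_times))

  hct <- tissue$hematocrit
  ecv_regions <- list(remote = tissue$lambda_remote * (1 - hct))
  if (!is.null(segment_lambda))
    ecv_regions$segments <- segment_lambda[AHA6_LABELS] * (1 - hct)
  if (!is.null(tissue$lambda_border))
    ecv_regions$border <- tissue$lambda_border * (1 - hct)
  if (!is.null(tissue$lambda_core))
    ecv_regions$core <- tissue$lambda_core * (1 - hct)

  noise_sd <- if (is.finite(snr) && snr > 0) 1 / snr else 0
  subject <- structure(list(
    subject_id = subject_id, group = group, lge_positive = lge_positive,
    geometry = geometry, tissue = tissue, covariates = covariates,
    hct = hct, snr = snr, scheme = scheme,
    masks = list(myocardium = myo, blood = ras$blood, cavity = cavity,
                 region = ras$region),
    gt = list(times = time_points, lge_time = lge_time,
              blood_r1 = as.numeric(blood_r1)[seq_along(time_points)],
              t1 = t1_gt, t1_lge = t1_lge, lambda_map = lam,
              ecv = ecv_regions),
    contours = phantom_contours(geometry)
  ), class = "synthetic_subject")

  with_seed(seed, {
    subject$molli <- lapply(seq_along(time_points), function(i) {
      s <- .render_molli(t1_gt[[i]], scheme, tp_labels[i],
                         inversion_factor = inversion_factor, noise_sd = 0)
      ms <- motion_shifts[[tp_labels[i]]]
      if (!is.null(ms)) {
        for (k in seq_len(dim(s$frames)[3])) {
          if (any(ms[k, ] != 0))
            s$frames[, , k] <- .shift_matrix(s$frames[, , k], ms[k, 1], ms[k, 2])
        }
      }
      if (noise_sd > 0) {
        for (k in seq_len(dim(s$frames)[3]))
          s$frames[, , k] <- .add_rician(s$frames[, , k], noise_sd)
      }
      s
    })
    names(subject$molli) <- tp_labels
    subject$lge <- render_lge_image(subject)
  })
  subject
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("Synthetic subject %s [%s]%s: Hct %.2f, remote ECV %.3f, SNR %g\n",
              x$subject_id, x$group,
              if (x$lge_positive) " LGE+" else "", x$hct,
              x$gt$ecv$remote, x$snr))
  invisible(x)
}

#' Automatic lesion-core ROI
#'
#' A small (default 3x3 pixel) square ROI centred on the lesion-core
#' centroid, emulating the operator's manually drawn "small ROI in the core
#' of the region with focal fibrosis". Synthetic-mode stand-in; real data
#' takes a user-supplied ROI.
#'
#' @param subject A LGE-positive [generate_subject()] result.
#' @param size ROI edge length in pixels (odd).
#' @return Logical matrix ROI (intersected with the core region).
#' @export
auto_core_roi <- function(subject, size = 3L) {
  stopifnot(inherits(subject, "synthetic_subject"))
  core <- which(subject$masks$region == 3L, arr.ind = TRUE)
  abort_if(nrow(core) == 0L, "subject has no lesion core")
  ctr <- round(colMeans(core))
  h <- (size - 1L) %/% 2L
  roi <- matrix(FALSE, nrow(subject$masks$region), ncol(subject$masks$region))
  rs <- pmax(1L, ctr[1] - h):pmin(nrow(roi), ctr[1] + h)
  cs <- pmax(1L, ctr[2] - h):pmin(ncol(roi), ctr[2] + h)
  roi[rs, cs] <- TRUE
  hit <- roi & subject$masks$region == 3L
  if (!any(hit)) {
    # centroid fell outside the (possibly non-convex) core: snap to the
    # core pixel closest to it
    d <- (core[, 1] - ctr[1])^2 + (core[, 2] - ctr[2])^2
    hit[core[which.min(d), 1], core[which.min(d), 2]] <- TRUE
  }
  hit
}
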