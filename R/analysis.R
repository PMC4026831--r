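# End-to-end analysis of one rendered subject and of whole cohorts:
# registration -> T1 mapping -> LGE classification -> partition coefficient /
# ECV -> AHA segmental values. This is the measurement route; it consumes
# only the rendered images, the delineation masks, the contours and the
# hematocrit -- never the ground-truth tissue parameters.

#' Analyse one subject through the full measurement pipeline
#'
#' @param subject A [generate_subject()] result (or an equivalent bundle with
#'   `molli`, `lge`, `masks`, `contours`, `hct`, `geometry`).
#' @param register Run in-plane rigid registration before fitting.
#' @param thresholds LGE class thresholds (fractions of max SI).
#' @param min_roi_area Minimum connected-component area (pixels) for a class
#'   ROI.
#' @param average ROI averaging mode for [ecv_for_roi()].
#' @param t1_range Plausibility gate for [compute_t1_map()].
#' @param wt_threshold Hypertrophy wall-thickness threshold, mm.
#' @return List: `ecv` (global `ecv_result`, measured in non-enhanced
#'   myocardium for LGE-positive subjects, whole myocardium otherwise),
#'   `ecv_classes` (per enhancement class, LGE-positive only), `ecv_segments`
#'   (named numeric, six AHA segments), `wall_thickness`, `hypertrophic`,
#'   `max_wt`, `t1_maps`, `enhancement` (mask or NULL), `shifts`,
#'   `valid_fraction`.
#' @export
analyze_subject <- function(subject, register = TRUE,
                            thresholds = c(0.20, 0.50), min_roi_area = 9L,
                            average = c("t1", "r1"), t1_range = c(100, 4000),
                            wt_threshold = 15) {
  average <- match.arg(average)
  series <- subject$molli
  shifts <- NULL
  if (register) {
    series <- lapply(series, register_frames)
    shifts <- lapply(series, attr, "shifts")
  }
  fit_mask <- subject$masks$myocardium | subject$masks$blood
  t1_maps <- lapply(series, compute_t1_map, mask = fit_mask, t1_range = t1_range)
  myo <- subject$masks$myocardium
  blood <- subject$masks$blood
  valid_fraction <- mean(vapply(t1_maps, function(m) mean(m$valid[myo]), numeric(1)))

  enh <- NULL
  ecv_classes <- NULL
  global_roi <- myo
  if (isTRUE(subject$lge_positive)) {
    core_roi <- auto_core_roi(subject)
    max_si <- locate_core_max_si(subject$lge$image, core_roi)
    enh <- classify_enhancement(subject$lge$image, max_si, thresholds)
    rois <- lapply(c(enhanced = "enhanced", intermediate = "intermediate",
                     non_enhanced = "non_enhanced"),
                   function(cl) extract_roi(enh, cl, min_area = min_roi_area))
    ecv_classes <- lapply(rois, function(r) {
      if (!any(r)) return(NULL)
      ecv_for_roi(t1_maps, r, blood, subject$hct, average = average)
    })
    if (any(rois$non_enhanced)) global_roi <- rois$non_enhanced
  }
  ecv_global <- ecv_for_roi(t1_maps, global_roi, blood, subject$hct,
                            average = average)

  segs <- divide_aha6(myo, subject$geometry$rv_insertion_angle)
  smasks <- segment_masks(segs)
  ecv_segments <- vapply(smasks, function(m) {
    tryCatch(ecv_for_roi(t1_maps, m, blood, subject$hct, average = average)$ecv,
             error = function(e) NA_real_)
  }, numeric(1))
  wt <- wall_thickness(subject$contours)
  list(ecv = ecv_global, ecv_classes = ecv_classes,
       ecv_segments = ecv_segments, wall_thickness = wt,
       hypertrophic = classify_hypertrophic(wt, wt_threshold),
       max_wt = attr(wt, "max"), t1_maps = t1_maps, enhancement = enh,
       shifts = shifts, valid_fraction = valid_fraction)
}

#' Analyse a whole cohort
#'
#' Runs [analyze_subject()] on every subject; a failure in one subject is
#' recorded and skipped, not fatal (failed subjects keep their row with NA
#' measurements).
#'
#' @param cohort A [generate_cohort()] result.
#' @param ... Passed to [analyze_subject()].
#' @return Data frame: one row per subject joining the generator covariates
#'   with the measured global ECV (`ecv`), fit diagnostics, per-class ECV
#'   (`ecv_enhanced`, `ecv_intermediate`, `ecv_non_enhanced`), per-segment
#'   ECV and wall thickness columns, and hypertrophy flags. Failures are
#'   listed in attribute `"failures"`.
#' @export
analyze_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  failures <- character(0)
  rows <- lapply(cohort$subjects, function(subj) {
    base <- cohort$table[cohort$table$subject_id == subj$subject_id, , drop = FALSE]
    res <- tryCatch(analyze_subject(subj, ...), error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", subj$subject_id, conditionMessage(e)))
      NULL
    })
    m <- list(ecv = NA_real_, lambda = NA_real_, r_squared = NA_real_,
              ecv_enhanced = NA_real_, ecv_intermediate = NA_real_,
              ecv_non_enhanced = NA_real_, valid_fraction = NA_real_)
    segv <- stats::setNames(rep(NA_real_, 6), paste0("ecv_seg_", AHA6_LABELS))
    wtv <- stats::setNames(rep(NA_real_, 6), paste0("wt_", AHA6_LABELS))
    hyp <- stats::setNames(rep(NA, 6), paste0("hypertrophic_", AHA6_LABELS))
    if (!is.null(res)) {
      m$ecv <- res$ecv$ecv; m$lambda <- res$ecv$lambda
      m$r_squared <- res$ecv$r_squared
      m$valid_fraction <- res$valid_fraction
      for (cl in c("enhanced", "intermediate", "non_enhanced")) {
        e <- res$ecv_classes[[cl]]
        if (!is.null(e)) m[[paste0("ecv_", cl)]] <- e$ecv
      }
      segv[] <- unname(res$ecv_segments[AHA6_LABELS])
      wtv[] <- unname(res$wall_thickness[AHA6_LABELS])
      hyp[] <- unname(res$hypertrophic[AHA6_LABELS])
    }
    cbind(base, as.data.frame(m), as.data.frame(as.list(segv)),
          as.data.frame(as.list(wtv)), as.data.frame(as.list(hyp)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
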