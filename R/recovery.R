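# Parameter-recovery experiments: cohorts whose ground-truth ECV is pinned to
# reference values, pushed through the full measurement pipeline
# (render -> register -> fit T1 -> classify LGE -> ECV -> segments). These
# back the package's acceptance checks and are the natural smoke tests for a
# new installation.

#' Control-cohort ECV recovery
#'
#' Generates `n` control subjects whose ground-truth remote ECV equals
#' `ecv_target` exactly (per-subject lambda is derived from the drawn
#' hematocrit), runs the full pipeline, and summarises the recovered
#' whole-myocardium ECV.
#'
#' @param seed Integer seed.
#' @param n Number of control subjects.
#' @param ecv_target Ground-truth ECV fraction.
#' @param ... Overrides passed to [cohort_config()].
#' @return List: `mean_ecv`, `sd_ecv`, `results` (per-subject table),
#'   `ecv_target`, `n`.
#' @export
recover_control_cohort <- function(seed, n = 14L, ecv_target = 0.26, ...) {
  cfg <- cohort_config(n_hcm = 0L, n_control = n, n_lge_positive = 0L,
                       ecv_control = c(mean = ecv_target, sd = 0), ...)
  res <- analyze_cohort(generate_cohort(cfg, seed))
  list(mean_ecv = mean(res$ecv), sd_ecv = stats::sd(res$ecv), results = res,
       ecv_target = ecv_target, n = n)
}

#' LGE-positive three-class ECV recovery
#'
#' Generates `n` LGE-positive subjects with a three-class lesion whose core /
#' border / remote ground-truth ECVs are pinned to `lesion_ecv`, classifies
#' the rendered LGE image with the 20%/50% thresholds anchored on the lesion
#' core, and recovers per-class ECV.
#'
#' @param seed Integer seed.
#' @param n Number of LGE-positive subjects.
#' @param lesion_ecv Named `c(core, border, remote)` ground-truth ECV.
#' @param ... Overrides passed to [cohort_config()].
#' @return List: `mean_ecv` (named: enhanced, intermediate, non_enhanced),
#'   `ordering_ok` (enhanced > intermediate > non-enhanced in every
#'   subject), `results`.
#' @export
recover_lge_cohort <- function(seed, n = 9L,
                               lesion_ecv = c(core = 0.45, border = 0.35,
                                              remote = 0.27), ...) {
  cfg <- cohort_config(n_hcm = n, n_control = 0L, n_lge_positive = n,
                       lesion_ecv = lesion_ecv, ...)
  res <- analyze_cohort(generate_cohort(cfg, seed))
  cls <- c("ecv_enhanced", "ecv_intermediate", "ecv_non_enhanced")
  means <- vapply(cls, function(cl) mean(res[[cl]]), numeric(1))
  names(means) <- sub("^ecv_", "", cls)
  ordering <- all(res$ecv_enhanced > res$ecv_intermediate &
                    res$ecv_intermediate > res$ecv_non_enhanced)
  list(mean_ecv = means, ordering_ok = ordering, results = res,
       lesion_ecv = lesion_ecv, n = n)
}

# Reference per-segment ECV of healthy controls (septal segments highest).
CONTROL_SEGMENT_ECV <- c(inferoseptal = 0.28, anteroseptal = 0.28,
                         anterior = 0.25, anterolateral = 0.25,
                         inferolateral = 0.26, inferior = 0.27)

#' Segmental ECV recovery in controls
#'
#' Generates `n` control subjects whose per-AHA-segment ground-truth ECV is
#' pinned to `segment_ecv` and recovers the per-segment ECV through the AHA
#' six-segment division.
#'
#' @param seed Integer seed.
#' @param n Number of subjects.
#' @param segment_ecv Named length-6 vector of ground-truth segment ECV.
#' @param ... Overrides passed to [cohort_config()].
#' @return List: `mean_ecv` (named per segment), `results`.
#' @export
recover_segmental_cohort <- function(seed, n = 14L,
                                     segment_ecv = CONTROL_SEGMENT_ECV, ...) {
  cfg <- cohort_config(n_hcm = 0L, n_control = n, n_lge_positive = 0L,
                       segment_ecv = segment_ecv, ...)
  res <- analyze_cohort(generate_cohort(cfg, seed))
  means <- vapply(AHA6_LABELS, function(s) mean(res[[paste0("ecv_seg_", s)]]),
                  numeric(1))
  list(mean_ecv = means, results = res, segment_ecv = segment_ecv, n = n)
}

#' Hypertrophic-segment ECV recovery in an HCM cohort
#'
#' Generates one HCM subject per entry of `schedule`, thickening that AHA
#' segment (epicardial bulge) past the 15 mm wall-thickness threshold and
#' pinning its ground-truth ECV to `ecv_hypertrophic` while the remaining
#' segments carry `ecv_remote`. The pipeline measures wall thickness from
#' the contours, flags hypertrophic segments and recovers their ECV.
#'
#' @param seed Integer seed.
#' @param schedule Segment name per subject (default: 3 inferoseptal,
#'   3 anteroseptal, 2 anterior -- eight hypertrophic segments).
#' @param ecv_hypertrophic,ecv_remote Ground-truth ECV inside / outside the
#'   thickened segment.
#' @param epi_radius Epicardial radius (mm) of the thickened sector.
#' @param wt_threshold Hypertrophy threshold in mm.
#' @param ... Overrides passed to [cohort_config()].
#' @return List: `mean_ecv` (over segments flagged hypertrophic),
#'   `n_hypertrophic_segments`, `results`.
#' @export
recover_hypertrophic_cohort <- function(seed,
                                        schedule = rep(c("inferoseptal",
                                                         "anteroseptal",
                                                         "anterior"),
                                                       c(3, 3, 2)),
                                        ecv_hypertrophic = 0.29,
                                        ecv_remote = 0.26,
                                        epi_radius = 41, wt_threshold = 15,
                                        ...) {
  n <- length(schedule)
  cfg <- cohort_config(n_hcm = n, n_control = 0L, n_lge_positive = 0L,
                       ecv_hcm = c(mean = ecv_remote, sd = 0),
                       hypertrophy = list(schedule = schedule,
                                          epi_radius = epi_radius,
                                          ecv = ecv_hypertrophic), ...)
  res <- analyze_cohort(generate_cohort(cfg, seed))
  vals <- unlist(lapply(AHA6_LABELS, function(s) {
    hyp <- res[[paste0("hypertrophic_", s)]]
    res[[paste0("ecv_seg_", s)]][hyp %in% TRUE]
  }))
  list(mean_ecv = mean(vals), n_hypertrophic_segments = length(vals),
       results = res, ecv_hypertrophic = ecv_hypertrophic)
}
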