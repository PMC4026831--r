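# Cohort configuration and generation.

#' Cohort configuration
#'
#' Describes a synthetic cohort: group sizes, the distributions of the
#' ground-truth ECV targets, hematocrit and clinical covariates, lesion and
#' hypertrophy design, phantom geometry, MOLLI scheme and noise level.
#' Per-subject partition coefficients are derived from the drawn ECV target
#' and hematocrit as `lambda = ECV / (1 - Hct)`, so ground-truth ECV is
#' controlled exactly.
#'
#' Defaults emulate a representative HCM imaging cohort: 16 HCM / 14
#' controls, 9 LGE-positive HCM; group ECV 0.26; lesion core/border/remote
#' ECV 0.45 / 0.35 / 0.27; hematocrit 0.45 +- 0.04 (HCM) and 0.42 +- 0.02
#' (controls).
#'
#' @param n_hcm,n_control Group sizes.
#' @param n_lge_positive Number of HCM subjects with a focal lesion (must not
#'   exceed `n_hcm`).
#' @param ecv_hcm,ecv_control `c(mean, sd)` of the per-subject remote-ECV
#'   target per group.
#' @param lesion_ecv Named `c(core, border, remote)` ECV of LGE-positive
#'   subjects' lesion core, border rim and remote myocardium.
#' @param segment_ecv Optional named length-6 vector of per-AHA-segment ECV
#'   targets (overrides the group remote ECV; applied to every subject).
#' @param hypertrophy Optional list `schedule` (segment name per HCM subject,
#'   recycled/truncated to HCM count; `NA` entries mean no hypertrophy),
#'   `epi_radius` (mm, thickened sector), `ecv` (ECV inside the thickened
#'   segment).
#' @param hct_hcm,hct_control `c(mean, sd)` of hematocrit per group.
#' @param hct_bounds Truncation bounds for the hematocrit draw.
#' @param covariates List of `c(mean, sd)` entries `age_hcm`, `age_control`,
#'   `bsa_hcm`, `bsa_control`, `sbp`, `dbp` and scalars `male_frac_hcm`,
#'   `male_frac_control`.
#' @param geometry Baseline [phantom_geometry()] (lesion/thickening sectors
#'   are added per subject).
#' @param scheme MOLLI scheme.
#' @param snr Rendering SNR.
#' @param time_points,lge_time Acquisition times in minutes.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_hcm = 16L, n_control = 14L, n_lge_positive = 9L,
                          ecv_hcm = c(mean = 0.26, sd = 0.03),
                          ecv_control = c(mean = 0.26, sd = 0.02),
                          lesion_ecv = c(core = 0.45, border = 0.35, remote = 0.27),
                          segment_ecv = NULL,
                          hypertrophy = NULL,
                          hct_hcm = c(mean = 0.45, sd = 0.04),
                          hct_control = c(mean = 0.42, sd = 0.02),
                          hct_bounds = c(0.2, 0.6),
                          covariates = list(
                            age_hcm = c(47, 14), age_control = c(48, 15),
                            bsa_hcm = c(2.0, 0.17), bsa_control = c(1.9, 0.19),
                            sbp = c(132, 12), dbp = c(75, 11),
                            male_frac_hcm = 12 / 16, male_frac_control = 8 / 14),
                          geometry = phantom_geometry(),
                          scheme = build_scheme_335(1000),
                          snr = 50, time_points = c(0, 8, 20), lge_time = 10) {
  abort_if(n_hcm < 0 || n_control < 0 || n_lge_positive < 0,
           "group sizes must be non-negative")
  abort_if(n_lge_positive > n_hcm,
           "n_lge_positive (%d) cannot exceed n_hcm (%d)", n_lge_positive, n_hcm)
  abort_if(hct_hcm[["mean"]] <= hct_bounds[1] || hct_hcm[["mean"]] >= hct_bounds[2] ||
             hct_control[["mean"]] <= hct_bounds[1] || hct_control[["mean"]] >= hct_bounds[2],
           "hematocrit means must lie inside hct_bounds")
  if (!is.null(segment_ecv))
    abort_if(!all(AHA6_LABELS %in% names(segment_ecv)),
             "segment_ecv must name all six AHA segments")
  if (!is.null(hypertrophy)) {
    abort_if(is.null(hypertrophy$schedule),
             "hypertrophy$schedule (segment name per HCM subject) is required")
    abort_if(!all(stats::na.omit(hypertrophy$schedule) %in% AHA6_LABELS),
             "unknown segment in hypertrophy schedule")
    hypertrophy$epi_radius <- hypertrophy$epi_radius %||% 41
    hypertrophy$ecv <- hypertrophy$ecv %||% 0.29
  }
  structure(list(n_hcm = as.integer(n_hcm), n_control = as.integer(n_control),
                 n_lge_positive = as.integer(n_lge_positive),
                 ecv_hcm = ecv_hcm, ecv_control = ecv_control,
                 lesion_ecv = lesion_ecv, segment_ecv = segment_ecv,
                 hypertrophy = hypertrophy,
                 hct_hcm = hct_hcm, hct_control = hct_control,
                 hct_bounds = hct_bounds, covariates = covariates,
                 geometry = geometry, scheme = scheme, snr = snr,
                 time_points = time_points, lge_time = lge_time),
            class = "cohort_config")
}

# Lesion sector layout: a 40-degree transmural core flanked by two 20-degree
# border rims, placed over the septum (relative to the RV insertion), with
# thin remote rims towards both surfaces (radial span 15-85% of the wall).
.lesion_sectors <- function(rv) {
  data.frame(
    start_deg = deg_mod(c(rv + 35, rv + 15, rv + 75)),
    end_deg = deg_mod(c(rv + 75, rv + 35, rv + 95)),
    inner_frac = 0.15, outer_frac = 0.85,
    class = c("core", "border", "border"),
    stringsAsFactors = FALSE)
}

# Angular arc of AHA segment `name` for a given RV insertion angle.
.segment_arc <- function(name, rv) {
  k <- match(name, AHA6_LABELS) - 1L
  c(start = deg_mod(rv + 60 * k), end = deg_mod(rv + 60 * (k + 1L)))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject parameters from the configured distributions and renders
#' every subject ([generate_subject()]). Requested group and LGE-positive
#' counts are honoured exactly; the whole cohort is a pure function of
#' `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List of class `synthetic_cohort`: `subjects` (list) and `table`
#'   (one data.frame row per subject: id, group, LGE status, ground-truth
#'   ECV, hematocrit, covariates, indexed LV mass, maximal wall thickness).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_hcm + config$n_control
  groups <- rep(c("HCM", "control"), c(config$n_hcm, config$n_control))
  lge_flags <- rep(FALSE, n)
  if (config$n_lge_positive > 0) lge_flags[seq_len(config$n_lge_positive)] <- TRUE

  params <- with_seed(seed, {
    draw2 <- function(ms, n) {
      m <- if ("mean" %in% names(ms)) ms[["mean"]] else ms[1]
      s <- if ("sd" %in% names(ms)) ms[["sd"]] else ms[2]
      stats::rnorm(n, m, s)
    }
    is_hcm <- groups == "HCM"
    hct <- numeric(n)
    hct[is_hcm] <- rnorm_trunc(sum(is_hcm), config$hct_hcm[["mean"]],
                               config$hct_hcm[["sd"]],
                               config$hct_bounds[1], config$hct_bounds[2])
    hct[!is_hcm] <- rnorm_trunc(sum(!is_hcm), config$hct_control[["mean"]],
                                config$hct_control[["sd"]],
                                config$hct_bounds[1], config$hct_bounds[2])
    ecv <- numeric(n)
    ecv[is_hcm] <- rnorm_trunc(sum(is_hcm), config$ecv_hcm[["mean"]],
                               config$ecv_hcm[["sd"]], 0.05, 0.9)
    ecv[!is_hcm] <- rnorm_trunc(sum(!is_hcm), config$ecv_control[["mean"]],
                                config$ecv_control[["sd"]], 0.05, 0.9)
    cv <- config$covariates
    age <- ifelse(is_hcm, stats::rnorm(n, cv$age_hcm[1], cv$age_hcm[2]),
                  stats::rnorm(n, cv$age_control[1], cv$age_control[2]))
    male <- stats::rbinom(n, 1, ifelse(is_hcm, cv$male_frac_hcm,
                                       cv$male_frac_control)) == 1
    bsa <- ifelse(is_hcm, stats::rnorm(n, cv$bsa_hcm[1], cv$bsa_hcm[2]),
                  stats::rnorm(n, cv$bsa_control[1], cv$bsa_control[2]))
    bsa <- pmax(bsa, 1.2)
    sbp <- draw2(cv$sbp, n); dbp <- draw2(cv$dbp, n)
    list(hct = hct, ecv = ecv, age = pmax(age, 18), male = male, bsa = bsa,
         sbp = sbp, dbp = dbp)
  })

  subjects <- vector("list", n)
  rows <- vector("list", n)
  hcm_counter <- 0L
  for (i in seq_len(n)) {
    hct <- params$hct[i]
    ecv_target <- params$ecv[i]
    lam_of <- function(e) e / (1 - hct)
    geom <- config$geometry
    rv <- geom$rv_insertion_angle
    lam_core <- lam_border <- NULL
    if (lge_flags[i]) {
      ecv_target <- config$lesion_ecv[["remote"]] %||% ecv_target
      lam_core <- lam_of(config$lesion_ecv[["core"]])
      lam_border <- lam_of(config$lesion_ecv[["border"]])
      geom$lesion_sectors <- .lesion_sectors(rv)
    }
    segment_lambda <- NULL
    if (!is.null(config$segment_ecv))
      segment_lambda <- vapply(config$segment_ecv[AHA6_LABELS], lam_of, numeric(1))
    if (groups[i] == "HCM") hcm_counter <- hcm_counter + 1L
    hyp_seg <- NA_character_
    if (!is.null(config$hypertrophy) && groups[i] == "HCM" &&
        hcm_counter <= length(config$hypertrophy$schedule))
      hyp_seg <- config$hypertrophy$schedule[hcm_counter]
    if (!is.na(hyp_seg)) {
      arc <- .segment_arc(hyp_seg, rv)
      geom$thick_sectors <- data.frame(start_deg = arc[["start"]],
                                       end_deg = arc[["end"]],
                                       epi_radius = config$hypertrophy$epi_radius)
      if (is.null(segment_lambda))
        segment_lambda <- stats::setNames(rep(lam_of(ecv_target), 6), AHA6_LABELS)
      segment_lambda[[hyp_seg]] <- lam_of(config$hypertrophy$ecv)
    }
    geom <- do.call(phantom_geometry, unclass(geom))  # re-validate per-subject edits
    tissue <- tissue_model(lambda_remote = lam_of(ecv_target),
                           lambda_core = lam_core, lambda_border = lam_border,
                           hematocrit = hct)
    id <- sprintf("%s%02d", ifelse(groups[i] == "HCM", "H", "C"),
                  ifelse(groups[i] == "HCM", hcm_counter, i - config$n_hcm))
    covs <- list(age = params$age[i], sex = ifelse(params$male[i], "m", "f"),
                 bsa = params$bsa[i], sbp = params$sbp[i], dbp = params$dbp[i])
    subj <- generate_subject(geom, tissue, seed = derive_seed(seed, i),
                             covariates = covs, subject_id = id,
                             group = groups[i], scheme = config$scheme,
                             snr = config$snr, time_points = config$time_points,
                             lge_time = config$lge_time,
                             segment_lambda = segment_lambda)
    wt <- wall_thickness(subj$contours)
    mass <- lv_mass_indexed(subj$contours, covs$bsa)
    subjects[[i]] <- subj
    rows[[i]] <- data.frame(
      subject_id = id, group = groups[i], lge_positive = lge_flags[i],
      ecv_true = ecv_target, hct = hct, age = covs$age, sex = covs$sex,
      bsa = covs$bsa, sbp = covs$sbp, dbp = covs$dbp,
      lv_mass_indexed = mass$indexed_g_m2, max_wt = attr(wt, "max"),
      stringsAsFactors = FALSE)
  }
  table <- if (n > 0) do.call(rbind, rows) else
    data.frame(subject_id = character(), group = character(),
               lge_positive = logical(), ecv_true = numeric(),
               hct = numeric(), age = numeric(), sex = character(),
               bsa = numeric(), sbp = numeric(), dbp = numeric(),
               lv_mass_indexed = numeric(), max_wt = numeric(),
               stringsAsFactors = FALSE)
  structure(list(subjects = subjects, table = table, config = config,
                 seed = seed), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d HCM / %d control, %d LGE+), seed %s\n",
              nrow(x$table), sum(x$table$group == "HCM"),
              sum(x$table$group == "control"), sum(x$table$lge_positive),
              format(x$seed)))
  invisible(x)
}
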