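# Partition-coefficient and extracellular-volume-fraction estimation.

#' Relaxation rate from T1
#'
#' `R1 = 1000 / T1` (T1 in ms, R1 in s^-1).
#'
#' @param t1 T1 in ms (> 0), vectorised.
#' @return R1 in s^-1.
#' @export
r1_from_t1 <- function(t1) {
  abort_if(any(!is.finite(t1)) || any(t1 <= 0), "T1 must be positive (ms)")
  1000 / t1
}

#' Contrast partition coefficient by R1-R1 regression
#'
#' Ordinary least-squares regression (with intercept) of myocardial R1 on
#' blood-pool R1 across the acquisition time points. Under dynamic
#' equilibrium the relation is linear and the slope is the partition
#' coefficient lambda; the R-squared serves as an equilibrium diagnostic.
#'
#' @param r1_myo,r1_blood Paired R1 samples, s^-1 (typically three time
#'   points: pre, ~8 min, ~20 min). At least two samples with distinct blood
#'   R1 are required.
#' @return Object of class `partition_fit`: `lambda` (slope), `intercept`,
#'   `r_squared`, `n_points`.
#' @examples
#' fit_partition_coefficient(c(0.8, 1.5, 2.5), c(0.6, 2.0, 4.0))  # lambda 0.5
#' @export
fit_partition_coefficient <- function(r1_myo, r1_blood) {
  abort_if(length(r1_myo) != length(r1_blood), "paired samples required")
  abort_if(length(r1_myo) < 2L, "at least two time points required")
  abort_if(any(!is.finite(r1_myo)) || any(!is.finite(r1_blood)) ||
             any(r1_myo <= 0) || any(r1_blood <= 0), "R1 values must be positive")
  abort_if(stats::sd(r1_blood) == 0,
           "degenerate regression: blood R1 identical at all time points")
  fit <- stats::lm(r1_myo ~ r1_blood)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((r1_myo - mean(r1_myo))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(lambda = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = max(0, min(1, r2)),
                 n_points = length(r1_myo)),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("Partition fit: lambda=%.4f intercept=%.4f R^2=%.5f (n=%d)\n",
              x$lambda, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Hematocrit-corrected extracellular volume fraction
#'
#' `ECV = lambda * (1 - hematocrit)`: the partition coefficient rescaled from
#' the blood to the plasma distribution volume. Results outside (0, 1) are
#' flagged invalid.
#'
#' @param fit A [fit_partition_coefficient()] result, or a single lambda.
#' @param hematocrit Blood cell volume fraction, in (0, 1).
#' @return Object of class `ecv_result`: `ecv`, `lambda`, `intercept`,
#'   `r_squared`, `hematocrit`, `valid`.
#' @examples
#' compute_ecv(0.5, 0.48)$ecv  # 0.26
#' @export
compute_ecv <- function(fit, hematocrit) {
  check_number(hematocrit, "hematocrit", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  if (inherits(fit, "partition_fit")) {
    lambda <- fit$lambda; intercept <- fit$intercept; r2 <- fit$r_squared
  } else {
    lambda <- fit; intercept <- NA_real_; r2 <- NA_real_
  }
  check_number(lambda, "lambda")
  ecv <- lambda * (1 - hematocrit)
  structure(list(ecv = ecv, lambda = lambda, intercept = intercept,
                 r_squared = r2, hematocrit = hematocrit,
                 valid = is.finite(ecv) && ecv > 0 && ecv < 1),
            class = "ecv_result")
}

#' @export
print.ecv_result <- function(x, ...) {
  cat(sprintf("ECV = %.4f (lambda %.4f, Hct %.3f%s)\n", x$ecv, x$lambda,
              x$hematocrit, if (x$valid) "" else ", INVALID"))
  invisible(x)
}

#' ROI-level ECV from three T1 maps
#'
#' The primary ROI-level product: per time point the ROI-mean T1 (valid
#' pixels only) is converted to R1 for the myocardial ROI and the blood-pool
#' ROI, the partition coefficient is fitted across time points, and the
#' hematocrit correction is applied. Set `average = "r1"` to average
#' per-pixel R1 instead of T1 first.
#'
#' @param t1_maps List of three [compute_t1_map()] results (pre, post8,
#'   post20 in any order; all time points distinct).
#' @param roi Logical myocardial ROI.
#' @param blood_roi Logical blood-pool ROI.
#' @param hematocrit Hematocrit fraction.
#' @param average `"t1"` (ROI-mean T1 first, default) or `"r1"`.
#' @return An `ecv_result` (see [compute_ecv()]); the fit R-squared is
#'   carried along as an equilibrium diagnostic.
#' @export
ecv_for_roi <- function(t1_maps, roi, blood_roi, hematocrit,
                        average = c("t1", "r1")) {
  average <- match.arg(average)
  abort_if(length(t1_maps) < 2L, "at least two T1 maps required")
  roi_r1 <- function(map, mask) {
    sel <- mask & map$valid
    abort_if(!any(sel), "ROI has no valid pixels at time point '%s'", map$time_point)
    if (average == "t1") r1_from_t1(mean(map$t1[sel])) else mean(r1_from_t1(map$t1[sel]))
  }
  r1m <- vapply(t1_maps, roi_r1, numeric(1), mask = roi)
  r1b <- vapply(t1_maps, roi_r1, numeric(1), mask = blood_roi)
  fit <- fit_partition_coefficient(r1m, r1b)
  compute_ecv(fit, hematocrit)
}
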