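# Tissue relaxation / contrast-kinetics model for the synthetic cohort.

#' Construct a tissue model
#'
#' Ground-truth relaxation and contrast-kinetics parameters for one synthetic
#' subject. Blood gadolinium concentration after a bolus follows a
#' bi-exponential washout (fast mixing + slow renal clearance compartment);
#' at dynamic equilibrium the myocardial R1 change is the blood R1 change
#' scaled by the partition coefficient lambda, and the extracellular volume
#' fraction is `ECV = lambda * (1 - hematocrit)`.
#'
#' @param native_t1_myo Native (pre-contrast) myocardial T1, ms.
#' @param native_t1_blood Native blood T1, ms.
#' @param lambda_remote Partition coefficient of remote myocardium, in (0, 1.2].
#' @param lambda_core,lambda_border Optional lesion core / border partition
#'   coefficients; must be >= `lambda_remote` when given.
#' @param hematocrit Blood cell volume fraction, in (0, 1).
#' @param relaxivity_r1 Contrast agent R1 relaxivity, s^-1 mM^-1 (typical
#'   extracellular gadolinium agents at 1.5 T: ~4).
#' @param dose Contrast dose, mmol/kg (bolus).
#' @param washout_amplitudes Two compartment amplitudes (mM) of the blood
#'   concentration decay.
#' @param washout_rates Two decay constants, min^-1 (fast, slow).
#' @return Object of class `tissue_model`.
#' @export
tissue_model <- function(native_t1_myo = 1000, native_t1_blood = 1540,
                         lambda_remote = 0.45, lambda_core = NULL,
                         lambda_border = NULL, hematocrit = 0.42,
                         relaxivity_r1 = 4.0, dose = 0.2,
                         washout_amplitudes = c(2.0, 1.0),
                         washout_rates = c(0.3, 0.02)) {
  check_number(native_t1_myo, "native_t1_myo", lower = 0, open_lower = TRUE)
  check_number(native_t1_blood, "native_t1_blood", lower = 0, open_lower = TRUE)
  check_number(hematocrit, "hematocrit", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(relaxivity_r1, "relaxivity_r1", lower = 0, open_lower = TRUE)
  check_number(dose, "dose", lower = 0, open_lower = TRUE)
  .check_lambda(lambda_remote)
  for (lam in c(lambda_core, lambda_border)) {
    .check_lambda(lam)
    abort_if(lam < lambda_remote,
             "lesion partition coefficient (%g) must be >= remote (%g)",
             lam, lambda_remote)
  }
  abort_if(length(washout_amplitudes) != 2L || any(washout_amplitudes < 0),
           "'washout_amplitudes' must be two non-negative values (mM)")
  abort_if(length(washout_rates) != 2L || any(washout_rates <= 0),
           "'washout_rates' must be two positive decay constants (min^-1)")
  structure(list(native_t1_myo = native_t1_myo,
                 native_t1_blood = native_t1_blood,
                 lambda_remote = lambda_remote,
                 lambda_core = lambda_core,
                 lambda_border = lambda_border,
                 hematocrit = hematocrit,
                 relaxivity_r1 = relaxivity_r1,
                 dose = dose,
                 washout_amplitudes = washout_amplitudes,
                 washout_rates = washout_rates),
            class = "tissue_model")
}

.check_lambda <- function(lambda) {
  abort_if(!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
             lambda <= 0 || lambda > 1.2,
           "partition coefficient must lie in (0, 1.2], got %s",
           paste(lambda, collapse = ","))
}

#' Blood-pool R1 time course after a contrast bolus
#'
#' `R1_blood(t) = 1000 / native_t1_blood + relaxivity_r1 * C_blood(t)`, with
#' `C_blood(0) = 0` (pre-contrast) and, for `t > 0`,
#' `C_blood(t) = A1 exp(-k1 t) + A2 exp(-k2 t)` (bi-exponential washout). The
#' post-contrast course is strictly decreasing, consistent with sampling at
#' dynamic equilibrium well after the bolus.
#'
#' @param tissue A [tissue_model()].
#' @param times Minutes after injection; `0` means pre-contrast. Must be
#'   non-negative.
#' @return Object of class `r1_course`: numeric R1 values (s^-1) with the
#'   sampling times attached as attribute `"times"`.
#' @examples
#' tm <- tissue_model()
#' simulate_blood_r1_course(tm, c(0, 8, 20))
#' @export
simulate_blood_r1_course <- function(tissue, times) {
  stopifnot(inherits(tissue, "tissue_model"))
  abort_if(any(!is.finite(times)) || any(times < 0),
           "times must be non-negative minutes")
  conc <- ifelse(times == 0, 0,
                 tissue$washout_amplitudes[1] * exp(-tissue$washout_rates[1] * times) +
                 tissue$washout_amplitudes[2] * exp(-tissue$washout_rates[2] * times))
  r1 <- 1000 / tissue$native_t1_blood + tissue$relaxivity_r1 * conc
  structure(r1, times = times, class = "r1_course")
}

#' Myocardial R1 course at dynamic equilibrium
#'
#' At dynamic equilibrium the gadolinium-induced myocardial R1 change is
#' proportional to the blood change: `dR1_myo(t) = lambda * dR1_blood(t)`,
#' with the pre-contrast myocardial R1 equal to `1000 / native_t1_myo`.
#'
#' @param blood_r1_course An [simulate_blood_r1_course()] result whose first
#'   sample is the pre-contrast point (time 0).
#' @param lambda_true Partition coefficient, in (0, 1.2].
#' @param native_t1_myo Native myocardial T1, ms.
#' @return Myocardial R1 per time, s^-1 (same `"times"` attribute).
#' @export
derive_tissue_r1 <- function(blood_r1_course, lambda_true, native_t1_myo) {
  .check_lambda(lambda_true)
  check_number(native_t1_myo, "native_t1_myo", lower = 0, open_lower = TRUE)
  times <- attr(blood_r1_course, "times")
  abort_if(is.null(times) || times[1] != 0,
           "blood R1 course must include the pre-contrast point (time 0) first")
  delta <- as.numeric(blood_r1_course) - as.numeric(blood_r1_course)[1]
  structure(1000 / native_t1_myo + lambda_true * delta,
            times = times, class = "r1_course")
}
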