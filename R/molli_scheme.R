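#' Build a MOLLI 3(3)3(3)5 sampling scheme
#'
#' The modified Look-Locker inversion recovery (MOLLI) scheme acquires eleven
#' single-shot images over seventeen heart beats: three inversion blocks yield
#' 3, 3 and 5 images respectively, separated by two 3-beat recovery pauses.
#' Within a block, readout j (j = 0, 1, ...) occurs at an effective inversion
#' time of `base_ti + j * rr_interval` because images are acquired on
#' successive cardiac cycles.
#'
#' @param rr_interval R-R interval in ms (one cardiac cycle).
#' @param base_tis Three base inversion times in ms, one per inversion block;
#'   must be positive, strictly increasing and all shorter than `rr_interval`.
#' @return An object of class `molli_scheme` with elements `rr_interval`,
#'   `base_tis`, `readout_counts` (3, 3, 5), `recovery_beats` (3, 3),
#'   `effective_tis` (11 values, block order), `n_images` and `beats_spanned`.
#' @examples
#' s <- build_scheme_335(1000)
#' s$n_images        # 11
#' s$beats_spanned   # 17
#' @export
build_scheme_335 <- function(rr_interval, base_tis = c(100, 180, 260)) {
  check_number(rr_interval, "rr_interval", lower = 0, open_lower = TRUE)
  abort_if(length(base_tis) != 3L || any(!is.finite(base_tis)),
           "'base_tis' must be three finite inversion times (ms)")
  abort_if(any(base_tis <= 0), "base inversion times must be positive")
  abort_if(any(diff(base_tis) <= 0), "base inversion times must be increasing")
  abort_if(any(base_tis >= rr_interval),
           "base inversion times must be shorter than the R-R interval (readouts would collide)")
  counts <- c(3L, 3L, 5L)
  recovery <- c(3L, 3L)
  tis <- unlist(lapply(seq_along(counts), function(k) {
    base_tis[k] + (seq_len(counts[k]) - 1L) * rr_interval
  }))
  structure(list(
    rr_interval = rr_interval,
    base_tis = base_tis,
    readout_counts = counts,
    recovery_beats = recovery,
    effective_tis = tis,
    n_images = length(tis),
    beats_spanned = sum(counts) + sum(recovery)
  ), class = "molli_scheme")
}

#' @export
print.molli_scheme <- function(x, ...) {
  cat(sprintf("MOLLI 3(3)3(3)5 scheme: %d images / %d beats, RR = %g ms\n",
              x$n_images, x$beats_spanned, x$rr_interval))
  cat("effective TIs (ms):", paste(round(x$effective_tis, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Magnitude inversion-recovery signal model
#'
#' Three-parameter apparent-relaxation model for magnitude-reconstructed MOLLI
#' data: `s(TI) = |a - b * exp(-TI / t1_star)|`, where `t1_star` is the
#' apparent (Look-Locker shortened) relaxation time.
#'
#' @param a Equilibrium signal amplitude (arbitrary units, > 0 for physical
#'   signals).
#' @param b Inversion amplitude (same units; `b = 2a` for a perfect inversion
#'   with full recovery).
#' @param t1_star Apparent relaxation time in ms (> 0).
#' @param effective_tis Effective inversion times in ms.
#' @return Magnitude signal, one value per TI.
#' @export
molli_signal <- function(a, b, t1_star, effective_tis) {
  check_number(t1_star, "t1_star", lower = 0, open_lower = TRUE)
  abs(a - b * exp(-effective_tis / t1_star))
}
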