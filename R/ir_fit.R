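# Three-parameter magnitude inversion-recovery fitting.
#
# Model: s(TI) = | a - b * exp(-TI / T1*) |, sampled at the 11 MOLLI effective
# inversion times. Magnitude reconstruction destroys the sign of the early
# samples, so the fit restores polarity by exhaustive search over the number p
# of earliest-TI samples to negate (p = 0..5), keeping the candidate with the
# smallest residual (ties broken towards smaller p).
#
# For fixed T1* the model is linear in (a, b), so the nonlinear problem is
# profiled down to one dimension: a log-spaced T1* grid brackets the optimum
# and a golden-section style interval search refines it. Everything is
# vectorised across pixels, which is what makes whole-map fitting feasible in
# pure R.

# Profiled residual sum of squares for per-pixel t1_star values.
# Y: npix x n signed signals (TI-ascending column order); precomputed row sums
# sy, syy avoid recomputation inside the interval search.
.ir_profile_rss <- function(Y, tis, t1_star, sy, syy) {
  n <- length(tis)
  npix <- nrow(Y)
  E <- exp(-matrix(tis, npix, n, byrow = TRUE) / t1_star)
  sx <- rowSums(E)
  sxx <- rowSums(E * E)
  sxy <- rowSums(Y * E)
  den <- sxx - sx * sx / n
  den[den < 1e-12] <- NA_real_
  b <- (sx * sy / n - sxy) / den
  a <- (sy + b * sx) / n
  rss <- syy - 2 * a * sy + 2 * b * sxy + n * a * a - 2 * a * b * sx + b * b * sxx
  rss[!is.finite(rss)] <- Inf
  list(rss = pmax(rss, 0), a = a, b = b)
}

# Same profile but with a single shared t1_star evaluated for all pixels
# (grid stage): x is a length-n vector, so the sums collapse to cheap
# matrix-vector products.
.ir_profile_rss_shared <- function(Y, tis, t1_star, sy, syy) {
  n <- length(tis)
  x <- exp(-tis / t1_star)
  sx <- sum(x)
  sxx <- sum(x * x)
  sxy <- as.numeric(Y %*% x)
  den <- sxx - sx * sx / n
  if (den < 1e-12) {
    return(list(rss = rep(Inf, nrow(Y)), a = rep(NA_real_, nrow(Y)),
                b = rep(NA_real_, nrow(Y))))
  }
  b <- (sx * sy / n - sxy) / den
  a <- (sy + b * sx) / n
  rss <- syy - 2 * a * sy + 2 * b * sxy + n * a * a - 2 * a * b * sx + b * b * sxx
  rss[!is.finite(rss)] <- Inf
  list(rss = pmax(rss, 0), a = a, b = b)
}

# Batch magnitude IR fit. signals: npix x n matrix (rows = curves), tis in ms.
# Returns per-pixel vectors. Internal engine shared by fit_ir_magnitude() and
# compute_t1_map().
.ir_fit_batch <- function(signals, tis,
                          t1_grid = exp(seq(log(60), log(6000), length.out = 45)),
                          max_polarity = 5L, refine_iter = 45L) {
  stopifnot(is.matrix(signals))
  n <- length(tis)
  abort_if(ncol(signals) != n, "signal columns (%d) must match TIs (%d)",
           ncol(signals), n)
  abort_if(n < 4L, "at least 4 samples are required")
  abort_if(anyDuplicated(tis) > 0L, "inversion times must be distinct")
  ord <- order(tis)
  tis_s <- tis[ord]
  Y0 <- signals[, ord, drop = FALSE]
  npix <- nrow(Y0)
  n_pol <- min(max_polarity, n - 1L) + 1L   # candidates p = 0..max_polarity

  grid_rss <- array(Inf, c(npix, n_pol))
  grid_idx <- array(1L, c(npix, n_pol))
  sy_list <- vector("list", n_pol)
  syy_list <- vector("list", n_pol)
  for (p in seq_len(n_pol)) {
    sgn <- rep(1, n)
    if (p > 1L) sgn[seq_len(p - 1L)] <- -1
    Yp <- sweep(Y0, 2L, sgn, `*`)
    sy <- rowSums(Yp)
    syy <- rowSums(Yp * Yp)
    sy_list[[p]] <- sy
    syy_list[[p]] <- syy
    best <- rep(Inf, npix)
    bidx <- rep(1L, npix)
    for (g in seq_along(t1_grid)) {
      pr <- .ir_profile_rss_shared(Yp, tis_s, t1_grid[g], sy, syy)
      upd <- pr$rss < best
      best[upd] <- pr$rss[upd]
      bidx[upd] <- g
    }
    grid_rss[, p] <- best
    grid_idx[, p] <- bidx
  }

  # Refine the two best polarity candidates per pixel.
  rank1 <- max.col(-grid_rss, ties.method = "first")
  tmp <- grid_rss
  tmp[cbind(seq_len(npix), rank1)] <- Inf
  rank2 <- max.col(-tmp, ties.method = "first")

  refine_one <- function(p_vec) {
    # golden-section search on log(t1_star), per pixel, polarity p_vec[i]
    sgnmat <- 1 - 2 * outer(p_vec - 1L, seq_len(n), `>=`)
    Yp <- Y0 * sgnmat
    sy <- rowSums(Yp)
    syy <- rowSums(Yp * Yp)
    gi <- grid_idx[cbind(seq_len(npix), p_vec)]
    lo <- log(t1_grid[pmax(gi - 1L, 1L)])
    hi <- log(t1_grid[pmin(gi + 1L, length(t1_grid))])
    gr <- (sqrt(5) - 1) / 2
    for (it in seq_len(refine_iter)) {
      m1 <- hi - gr * (hi - lo)
      m2 <- lo + gr * (hi - lo)
      f1 <- .ir_profile_rss(Yp, tis_s, exp(m1), sy, syy)$rss
      f2 <- .ir_profile_rss(Yp, tis_s, exp(m2), sy, syy)$rss
      left <- f1 <= f2
      hi <- ifelse(left, m2, hi)
      lo <- ifelse(left, lo, m1)
    }
    t1s <- exp((lo + hi) / 2)
    pr <- .ir_profile_rss(Yp, tis_s, t1s, sy, syy)
    list(t1_star = t1s, rss = pr$rss, a = pr$a, b = pr$b)
  }

  r1 <- refine_one(rank1)
  r2 <- refine_one(rank2)

  # Choose smaller refined RSS; ties (within numerical noise) go to the
  # smaller polarity index.
  pick2 <- r2$rss < r1$rss - 1e-12 |
    (abs(r2$rss - r1$rss) <= 1e-12 & rank2 < rank1)
  sel <- function(x1, x2) ifelse(pick2, x2, x1)
  a <- sel(r1$a, r2$a)
  b <- sel(r1$b, r2$b)
  t1_star <- sel(r1$t1_star, r2$t1_star)
  rss <- sel(r1$rss, r2$rss)
  polarity <- as.integer(sel(rank1, rank2)) - 1L

  valid <- is.finite(a) & is.finite(b) & is.finite(t1_star) &
    a > 0 & b > a
  t1 <- ifelse(valid, t1_star * (b / a - 1), NA_real_)
  list(a = a, b = b, t1_star = t1_star, t1 = t1,
       residual_rms = sqrt(rss / n), polarity_index = polarity,
       valid = valid)
}

#' Fit a three-parameter magnitude inversion-recovery curve
#'
#' Fits `s(TI) = |a - b exp(-TI/T1*)|` to one sampled MOLLI curve with
#' exhaustive polarity restoration (the `p` earliest-TI magnitude samples are
#' restored to negative, `p = 0..5`; the candidate with minimal residual wins,
#' ties towards smaller `p`). The apparent `T1*` is converted to T1 with the
#' Look-Locker correction `T1 = T1* (b/a - 1)`.
#'
#' @param signal Magnitude samples (>= 4 values).
#' @param effective_tis Effective inversion times in ms, same length as
#'   `signal`, distinct.
#' @return An object of class `ir_fit`: `a`, `b`, `t1_star`, `t1`,
#'   `residual_rms`, `polarity_index`, `valid`. Non-physical solutions
#'   (`b <= a`, which would give T1 <= 0) are flagged invalid, not raised as
#'   errors.
#' @examples
#' s <- build_scheme_335(1000)
#' y <- molli_signal(1, 1.95, 850, s$effective_tis)
#' fit_ir_magnitude(y, s$effective_tis)$t1_star
#' @export
fit_ir_magnitude <- function(signal, effective_tis) {
  abort_if(length(signal) != length(effective_tis),
           "signal and effective_tis must have equal length")
  r <- .ir_fit_batch(matrix(signal, nrow = 1L), effective_tis)
  structure(lapply(r, `[`, 1L), class = "ir_fit")
}

#' @export
print.ir_fit <- function(x, ...) {
  cat(sprintf("IR fit: a=%.4g b=%.4g T1*=%.1f ms T1=%.1f ms (polarity %d, %s)\n",
              x$a, x$b, x$t1_star, x$t1, x$polarity_index,
              if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

#' Look-Locker correction of an apparent T1
#'
#' Converts the apparent relaxation time of a Look-Locker readout train to the
#' true T1: `T1 = T1* (b/a - 1)`. When `b = 2a` (complete inversion, full
#' recovery) the correction is the identity.
#'
#' @param fit An `ir_fit` object, or a list/vector with elements `a`, `b`,
#'   `t1_star`.
#' @return Corrected T1 in ms; `NA` when `b <= a` or `a <= 0` (non-physical
#'   fit, flagged invalid rather than raised).
#' @export
look_locker_correct <- function(fit) {
  a <- fit[["a"]]; b <- fit[["b"]]; t1s <- fit[["t1_star"]]
  abort_if(is.null(a) || is.null(b) || is.null(t1s),
           "'fit' must carry elements a, b and t1_star")
  ifelse(is.finite(a) & is.finite(b) & a > 0 & b > a, t1s * (b / a - 1),
         NA_real_)
}
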