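# MOLLI series container, frame registration and per-pixel T1 mapping.

#' Construct a MOLLI series
#'
#' One breath-hold MOLLI acquisition: a stack of magnitude frames with their
#' per-frame effective inversion times.
#'
#' @param frames 3-D numeric array `nx x ny x nframes` of magnitude images.
#' @param effective_tis Effective inversion times in ms, one per frame,
#'   strictly positive.
#' @param time_point One of `"pre"`, `"post8"`, `"post20"` (acquisition time
#'   point relative to contrast injection).
#' @param rr_interval R-R interval in ms.
#' @return Object of class `molli_series`.
#' @export
molli_series <- function(frames, effective_tis,
                         time_point = c("pre", "post8", "post20"),
                         rr_interval = NA_real_) {
  time_point <- match.arg(time_point)
  abort_if(length(dim(frames)) != 3L, "'frames' must be a 3-D array")
  abort_if(dim(frames)[3] != length(effective_tis),
           "number of frames (%d) must match number of TIs (%d)",
           dim(frames)[3], length(effective_tis))
  abort_if(any(effective_tis <= 0), "effective TIs must be strictly positive")
  structure(list(frames = frames, effective_tis = effective_tis,
                 time_point = time_point, rr_interval = rr_interval),
            class = "molli_series")
}

#' @export
print.molli_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("MOLLI series [%s]: %d x %d, %d frames, TIs %g-%g ms\n",
              x$time_point, d[1], d[2], d[3],
              min(x$effective_tis), max(x$effective_tis)))
  invisible(x)
}

# Integer translation of a matrix, zero fill outside.
.shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Rigid in-plane registration of MOLLI frames
#'
#' Aligns every frame to a reference frame (by default the one with the
#' longest inversion time, which has the most recovered, anatomy-like
#' contrast) by exhaustive integer-translation search maximising the absolute
#' Pearson correlation over the overlapping region. Absolute correlation is
#' used because early-TI inversion-recovery frames have inverted contrast at
#' the correct alignment. Stands in for the manual respiratory-motion
#' correction an observer would perform.
#'
#' @param series A [molli_series()].
#' @param max_shift Search radius in pixels per axis.
#' @return The registered series; the applied corrections are attached as
#'   attribute `"shifts"` (`nframes x 2` matrix of row/col corrections). A
#'   motion-free series returns all-zero shifts.
#' @export
register_frames <- function(series, max_shift = 4L) {
  stopifnot(inherits(series, "molli_series"))
  ref_idx <- which.max(series$effective_tis)
  ref <- series$frames[, , ref_idx]
  nfr <- dim(series$frames)[3]
  offsets <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
  offsets <- offsets[order(abs(offsets$dr) + abs(offsets$dc)), ]  # prefer small shifts
  shifts <- matrix(0L, nfr, 2, dimnames = list(NULL, c("row", "col")))
  out <- series
  nr <- nrow(ref); nc <- ncol(ref)
  for (k in seq_len(nfr)) {
    if (k == ref_idx) next
    fr <- series$frames[, , k]
    best <- -Inf; bdr <- 0L; bdc <- 0L
    for (o in seq_len(nrow(offsets))) {
      dr <- offsets$dr[o]; dc <- offsets$dc[o]
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      a <- ref[rs, cs]
      b <- fr[rs - dr, cs - dc]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      sim <- abs(stats::cor(as.vector(a), as.vector(b)))
      if (sim > best + 1e-12) { best <- sim; bdr <- dr; bdc <- dc }
    }
    shifts[k, ] <- c(bdr, bdc)
    if (bdr != 0L || bdc != 0L)
      out$frames[, , k] <- .shift_matrix(fr, bdr, bdc)
  }
  attr(out, "shifts") <- shifts
  out
}

#' Per-pixel T1 map from a MOLLI series
#'
#' Runs the magnitude inversion-recovery fit ([fit_ir_magnitude()] model) on
#' every pixel inside `mask`, applies the Look-Locker correction, and gates
#' the result to the physiologically plausible range: valid pixels satisfy
#' `t1_range[1] < T1 < t1_range[2]` (default 100-4000 ms), which excludes
#' air/fat fit failures without touching physiologic myocardial or blood
#' values. Degenerate pixels (e.g. constant signal) are marked invalid, never
#' raised as errors.
#'
#' @param series A [molli_series()] (registered beforehand if needed).
#' @param mask Logical matrix of pixels to fit (non-empty).
#' @param t1_range Plausibility gate in ms.
#' @return Object of class `t1_map`: `t1` (matrix, NA outside mask/invalid),
#'   `valid` (logical matrix), `residual_rms` (matrix), `time_point`.
#' @export
compute_t1_map <- function(series, mask, t1_range = c(100, 4000)) {
  stopifnot(inherits(series, "molli_series"))
  d <- dim(series$frames)
  abort_if(!is.logical(mask) || !all(dim(mask) == d[1:2]),
           "'mask' must be a logical matrix matching the frame size")
  idx <- which(mask)
  abort_if(length(idx) == 0L, "empty mask")
  nfr <- d[3]
  S <- matrix(0, length(idx), nfr)
  for (k in seq_len(nfr)) S[, k] <- series$frames[, , k][idx]
  fit <- .ir_fit_batch(S, series$effective_tis)
  ok <- fit$valid & is.finite(fit$t1) &
    fit$t1 > t1_range[1] & fit$t1 < t1_range[2]
  t1 <- matrix(NA_real_, d[1], d[2])
  t1[idx] <- ifelse(ok, fit$t1, NA_real_)
  valid <- matrix(FALSE, d[1], d[2])
  valid[idx] <- ok
  res <- matrix(NA_real_, d[1], d[2])
  res[idx] <- fit$residual_rms
  structure(list(t1 = t1, valid = valid, residual_rms = res,
                 time_point = series$time_point),
            class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  v <- x$t1[x$valid]
  cat(sprintf("T1 map [%s]: %d valid pixels, median T1 %.0f ms\n",
              x$time_point, sum(x$valid), stats::median(v)))
  invisible(x)
}
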