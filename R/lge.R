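# Late gadolinium enhancement signal-intensity threshold segmentation.
#
# The classifier anchors on the maximum signal intensity (max SI) inside a
# small operator-placed ROI in the core of focal fibrosis, then partitions
# the myocardium into three classes: non-enhanced (SI < 20% of max SI),
# intermediate (20-50%), and enhanced (SI >= 50%, the full-width-half-maximum
# convention, which includes the half-maximum itself).

LGE_CLASSES <- c(outside = 0L, non_enhanced = 1L, intermediate = 2L,
                 enhanced = 3L)

#' Construct an LGE image
#'
#' @param pixels Non-negative magnitude image (matrix).
#' @param myo_mask Logical myocardial mask, non-empty, same size.
#' @param pixel_spacing Pixel size, mm.
#' @return Object of class `lge_image`.
#' @export
lge_image <- function(pixels, myo_mask, pixel_spacing = 1) {
  abort_if(!is.matrix(pixels) || any(pixels < 0, na.rm = TRUE),
           "'pixels' must be a non-negative magnitude image")
  abort_if(!is.logical(myo_mask) || !all(dim(myo_mask) == dim(pixels)),
           "'myo_mask' must be a logical matrix matching the image")
  abort_if(!any(myo_mask), "myocardial mask is empty")
  structure(list(pixels = pixels, myo_mask = myo_mask,
                 pixel_spacing = pixel_spacing), class = "lge_image")
}

#' Maximum signal intensity within a core ROI
#'
#' The reference intensity for threshold classification: the maximum pixel
#' value inside a small ROI placed in the core of the focal-fibrosis region.
#'
#' @param image An [lge_image()].
#' @param core_roi Logical mask (same size) or pixel index vector; must lie
#'   within the myocardial mask and contain at least one pixel.
#' @return Maximum SI (single number).
#' @export
locate_core_max_si <- function(image, core_roi) {
  stopifnot(inherits(image, "lge_image"))
  idx <- if (is.logical(core_roi)) which(core_roi) else as.integer(core_roi)
  abort_if(length(idx) == 0L, "core ROI is empty")
  abort_if(!all(image$myo_mask[idx]), "core ROI must lie within the myocardial mask")
  max(image$pixels[idx])
}

#' Three-class enhancement mask from SI thresholds
#'
#' Classifies every myocardial pixel by its signal relative to `max_si`:
#' `SI/max_si < 0.20` non-enhanced, `[0.20, 0.50)` intermediate, `>= 0.50`
#' enhanced (FWHM convention). Pixels outside the myocardial mask are class
#' `outside`. The three classes always partition the myocardial mask.
#'
#' @param image An [lge_image()].
#' @param max_si Reference maximum SI (> 0), from [locate_core_max_si()].
#' @param thresholds Fractions of `max_si` separating the classes.
#' @return Object of class `enhancement_mask`: `classes` (integer matrix with
#'   codes 0 outside / 1 non-enhanced / 2 intermediate / 3 enhanced),
#'   `max_si`, `thresholds`, `myo_mask`.
#' @export
classify_enhancement <- function(image, max_si, thresholds = c(0.20, 0.50)) {
  stopifnot(inherits(image, "lge_image"))
  check_number(max_si, "max_si", lower = 0, open_lower = TRUE)
  abort_if(length(thresholds) != 2L || any(diff(thresholds) <= 0),
           "'thresholds' must be two increasing fractions")
  rel <- image$pixels / max_si
  cls <- matrix(LGE_CLASSES[["outside"]], nrow(rel), ncol(rel))
  m <- image$myo_mask
  cls[m] <- LGE_CLASSES[["non_enhanced"]]
  cls[m & rel >= thresholds[1]] <- LGE_CLASSES[["intermediate"]]
  cls[m & rel >= thresholds[2]] <- LGE_CLASSES[["enhanced"]]
  structure(list(classes = cls, max_si = max_si, thresholds = thresholds,
                 myo_mask = m), class = "enhancement_mask")
}

#' @export
print.enhancement_mask <- function(x, ...) {
  n <- table(factor(x$classes[x$myo_mask], levels = 1:3,
                    labels = names(LGE_CLASSES)[2:4]))
  cat(sprintf("Enhancement mask (max SI %.4g): %s\n", x$max_si,
              paste(names(n), n, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Transfer a reference-slice threshold to a target slice
#'
#' When focal fibrosis is visible on a different slice than the slice of
#' interest, the max SI measured on the reference slice sets the thresholds
#' for the target slice (both slices must share intensity normalisation).
#'
#' @param reference_image,target_image [lge_image()] objects.
#' @param reference_core_roi Core ROI on the reference slice.
#' @param thresholds Class thresholds, fractions of max SI.
#' @return [classify_enhancement()] result for the target slice.
#' @export
transfer_threshold <- function(reference_image, reference_core_roi,
                               target_image, thresholds = c(0.20, 0.50)) {
  max_si <- locate_core_max_si(reference_image, reference_core_roi)
  classify_enhancement(target_image, max_si, thresholds)
}

# 8-connected component labelling of a logical matrix (iterative flood fill).
.connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  cur <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

#' Largest connected region of an enhancement class
#'
#' Returns the largest 8-connected component of the requested class with at
#' least `min_area` pixels, emulating the selection of a maximal contiguous
#' ROI. An empty result (no component large enough) is returned as an empty
#' mask, not an error.
#'
#' @param mask An [classify_enhancement()] result.
#' @param target_class `"non_enhanced"`, `"intermediate"` or `"enhanced"`.
#' @param min_area Minimum component area in pixels.
#' @return Logical matrix selecting the component (all-FALSE when absent).
#' @export
extract_roi <- function(mask, target_class, min_area = 1L) {
  stopifnot(inherits(mask, "enhancement_mask"))
  abort_if(!target_class %in% names(LGE_CLASSES)[-1], "unknown target class")
  sel <- mask$classes == LGE_CLASSES[[target_class]]
  if (!any(sel)) return(sel)
  lab <- .connected_components(sel)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  if (sizes[best] < min_area) return(matrix(FALSE, nrow(sel), ncol(sel)))
  lab == best
}
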