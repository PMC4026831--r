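# Shared fixtures: a down-scaled phantom (48 px grid, 2 mm pixels) that keeps
# per-subject fitting under a second while preserving the anatomy, and small
# constructors used across test files.

tiny_geometry <- function(...) {
  phantom_geometry(grid_size = 48, pixel_spacing = 2, ...)
}

tiny_config <- function(...) {
  cohort_config(geometry = tiny_geometry(), ...)
}

tiny_subject <- function(ecv = 0.26, hct = 0.42, snr = Inf, seed = 1,
                         lesion = FALSE, lesion_ecv = c(core = 0.45,
                                                        border = 0.35), ...) {
  lam <- function(e) e / (1 - hct)
  geom <- if (lesion)
    tiny_geometry(lesion_sectors = cmrfibrosis:::.lesion_sectors(90))
  else tiny_geometry()
  tissue <- tissue_model(
    lambda_remote = lam(ecv),
    lambda_core = if (lesion) lam(lesion_ecv[["core"]]) else NULL,
    lambda_border = if (lesion) lam(lesion_ecv[["border"]]) else NULL,
    hematocrit = hct)
  generate_subject(geom, tissue, seed = seed, snr = snr, ...)
}

# Rician magnitude sampler on a clean signal vector.
rician <- function(s, sd) sqrt((s + rnorm(length(s), 0, sd))^2 +
                                 rnorm(length(s), 0, sd)^2)
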