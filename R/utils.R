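# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           "'%s' must be a single finite number", name)
  lo_bad <- if (open_lower) x <= lower else x < lower
  hi_bad <- if (open_upper) x >= upper else x > upper
  abort_if(lo_bad || hi_bad, "'%s' = %g is outside the allowed range %s%g, %g%s",
           name, x, if (open_lower) "(" else "[", lower, upper,
           if (open_upper) ")" else "]")
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-subject sub-seed kept below 2^31.
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
}

# Truncated-normal sampler by rejection (bounds far from the mean, so cheap).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

deg_mod <- function(x) ((x %% 360) + 360) %% 360

# Does angle theta (deg) fall in the arc [start, end) measured CCW, wrapping?
angle_in_arc <- function(theta, start, end) {
  theta <- deg_mod(theta); start <- deg_mod(start); end <- deg_mod(end)
  if (start <= end) theta >= start & theta < end
  else theta >= start | theta < end
}
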