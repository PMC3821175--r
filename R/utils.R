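# Internal helpers shared across modules.

# mean +/- SEM with n; SEM is NA (flagged) for n = 1
.mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  list(mean = if (n > 0) mean(x) else NA_real_,
       sem  = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n    = n)
}

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# index of the time grid sample nearest to t (ms)
.t_index <- function(trace, t_ms) {
  idx <- round((t_ms - trace$time_ms[1]) * trace$fs_khz) + 1L
  .assert(idx >= 1L && idx <= length(trace$time_ms),
          "time %.3f ms is outside the recorded sweep", t_ms)
  as.integer(idx)
}
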