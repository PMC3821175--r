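#' Biexponential decomposition of cumulative evoked charge
#'
#' Fits the two-component charge model
#' \deqn{Q(t) = A_{fast}\,(1 - e^{-(t-t_0)/\tau_{fast}}) +
#'              A_{slow}\,(1 - e^{-(t-t_0)/\tau_{slow}})}
#' to a cumulative charge trace by nonlinear least squares
#' (Levenberg–Marquardt, `minpack.lm`), with constraints
#' \eqn{A \ge 0} and \eqn{0.1\,\mathrm{ms} \le \tau_{fast} <
#' \tau_{slow} \le 500\,\mathrm{ms}}, from eight deterministic
#' log-spaced \eqn{(\tau_{fast}, \tau_{slow})} starts; the
#' best-residual converged start wins.
#'
#' The slow amplitude coefficient is not used directly. Following the
#' subtraction rule, the effective slow charge is
#' `a_slow_eff = q50 - a_fast`, so `a_fast + a_slow_eff = q50` holds
#' exactly, and the fast fraction is `f_fast = a_fast / q50` (values
#' outside `[0, 1]` are clipped and flagged).
#'
#' @param x a [sweep_trace()] (the charge curve is computed with
#'   [cumulative_charge()]), or the list returned by
#'   [cumulative_charge()], or a numeric vector of cumulative charge
#'   (pC) with `time_ms` supplied.
#' @param time_ms time grid in ms relative to stimulus (needed only
#'   for the numeric-vector method).
#' @param t0 stimulus time (ms), for the `sweep_trace` method; default
#'   the trace's `t0_ms` marker.
#' @param duration_ms integration window (ms) for the `sweep_trace`
#'   method.
#' @param tau_bounds length-2 limits on both time constants (ms).
#' @param ... passed between methods.
#'
#' @return An object of class `charge_decomp` with elements `q50`,
#'   `a_fast`, `tau_fast`, `tau_slow`, `a_slow_eff`, `f_fast`,
#'   `b_slow_coef` (the raw slow coefficient), `residual_norm`,
#'   `converged`, `flags` (character), and the fitted data. Methods:
#'   [coef()], [predict()], [fitted()], [residuals()], `print`,
#'   `summary`, `plot`.
#' @examples
#' tr <- sim_evoked_trace(q_total = 1, f_fast = 0.77, tau_fast = 5.29,
#'                        tau_slow = 40.3, noise_sd = 0, seed = 1)
#' fit <- fit_charge_decomposition(tr)
#' coef(fit)
#' @export
fit_charge_decomposition <- function(x, ...) {
  UseMethod("fit_charge_decomposition")
}

#' @rdname fit_charge_decomposition
#' @export
fit_charge_decomposition.sweep_trace <- function(x, t0 = x$markers$t0_ms,
                                                 duration_ms = 50, ...) {
  .assert(!is.null(t0), "t0 missing: supply it or set the t0_ms marker")
  cc <- cumulative_charge(x, t0, duration_ms)
  fit_charge_decomposition(cc$q_pC, time_ms = cc$time_ms, ...)
}

#' @rdname fit_charge_decomposition
#' @export
fit_charge_decomposition.list <- function(x, ...) {
  fit_charge_decomposition(x$q_pC, time_ms = x$time_ms, ...)
}

#' @rdname fit_charge_decomposition
#' @export
fit_charge_decomposition.default <- function(x, time_ms,
                                             tau_bounds = c(0.1, 500), ...) {
  q <- as.numeric(x)
  .assert(length(q) == length(time_ms), "charge/time length mismatch")
  .assert(length(q) >= 20, "need at least 20 samples to fit")
  s <- time_ms - time_ms[1]
  q50 <- q[length(q)]
  .assert(q50 > 0, "total charge must be positive to decompose")

  model <- function(p, s)
    p[1] * (1 - exp(-s / p[3])) + p[2] * (1 - exp(-s / p[4]))

  # 8 deterministic log-spaced (tau_fast, tau_slow) starts
  starts <- expand.grid(tf = c(0.5, 2, 8, 30), ratio = c(8, 40))
  best <- NULL
  flags <- character(0)
  df <- data.frame(s = s, q = q)
  for (k in seq_len(nrow(starts))) {
    st <- list(af = q50 / 2, bs = q50 / 2, tf = starts$tf[k],
               ts = min(starts$tf[k] * starts$ratio[k], tau_bounds[2]))
    fit <- tryCatch(
      minpack.lm::nlsLM(q ~ af * (1 - exp(-s / tf)) + bs * (1 - exp(-s / ts)),
                        data = df, start = st,
                        lower = c(0, 0, tau_bounds[1], tau_bounds[1]),
                        upper = c(Inf, Inf, tau_bounds[2], tau_bounds[2]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::residuals(fit)^2))
    if (is.null(best) || rn < best$rn - 1e-12) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    flags <- c(flags, "no_convergence")
    out <- list(q50 = q50, a_fast = NA_real_, tau_fast = NA_real_,
                tau_slow = NA_real_, a_slow_eff = NA_real_,
                f_fast = NA_real_, b_slow_coef = NA_real_,
                residual_norm = NA_real_, converged = FALSE,
                flags = flags, time_ms = time_ms, q_pC = q)
    class(out) <- "charge_decomp"
    return(out)
  }

  p <- stats::coef(best$fit)
  af <- p[["af"]]; bs <- p[["bs"]]; tf <- p[["tf"]]; ts <- p[["ts"]]
  if (tf > ts) { tmp <- tf; tf <- ts; ts <- tmp
                 tmp <- af; af <- bs; bs <- tmp }
  if (af < 1e-6 * q50 && bs > 0) {
    # effectively single-component: the populated term is the fast one
    af <- bs; tf <- ts
    bs <- 0; ts <- tau_bounds[2]
    flags <- c(flags, "single_component")
  } else if (bs < 1e-6 * q50) {
    flags <- c(flags, "single_component")
  }
  if (abs(tf - ts) < 1e-4 * ts) {
    # indistinguishable time constants: merge into one fast component
    af <- af + bs
    bs <- 0; ts <- tau_bounds[2]
    flags <- c(flags, "tau_collision")
  }
  at_bound <- abs(c(tf, ts) - tau_bounds[1]) < 1e-9 |
              abs(c(tf, ts) - tau_bounds[2]) < 1e-9
  if (any(at_bound)) flags <- c(flags, "tau_at_bound")

  a_slow_eff <- q50 - af            # the subtraction rule
  f_fast <- af / q50
  if (f_fast < 0 || f_fast > 1) {
    flags <- c(flags, "f_fast_clipped")
    f_fast <- min(max(f_fast, 0), 1)
  }
  out <- list(q50 = q50, a_fast = af, tau_fast = tf, tau_slow = ts,
              a_slow_eff = a_slow_eff, f_fast = f_fast, b_slow_coef = bs,
              residual_norm = best$rn, converged = TRUE, flags = flags,
              time_ms = time_ms, q_pC = q, nls = best$fit)
  class(out) <- "charge_decomp"
  out
}

#' @export
coef.charge_decomp <- function(object, ...) {
  c(q50 = object$q50, a_fast = object$a_fast,
    a_slow_eff = object$a_slow_eff, tau_fast = object$tau_fast,
    tau_slow = object$tau_slow, f_fast = object$f_fast)
}

#' @export
predict.charge_decomp <- function(object, time_ms = object$time_ms, ...) {
  s <- time_ms - object$time_ms[1]
  out <- object$a_fast * (1 - exp(-s / object$tau_fast))
  if (object$b_slow_coef > 0)
    out <- out + object$b_slow_coef * (1 - exp(-s / object$tau_slow))
  out
}

#' @export
fitted.charge_decomp <- function(object, ...) predict(object)

#' @export
residuals.charge_decomp <- function(object, ...)
  object$q_pC - predict(object)

#' @export
print.charge_decomp <- function(x, ...) {
  cat("Biexponential charge decomposition\n")
  if (!x$converged) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  q50       %8.4g pC\n", x$q50))
  cat(sprintf("  a_fast    %8.4g pC  (f_fast = %.1f%%)\n",
              x$a_fast, 100 * x$f_fast))
  cat(sprintf("  a_slow    %8.4g pC  (q50 - a_fast)\n", x$a_slow_eff))
  cat(sprintf("  tau_fast  %8.4g ms\n", x$tau_fast))
  cat(sprintf("  tau_slow  %8.4g ms\n", x$tau_slow))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.charge_decomp <- function(object, ...) {
  print(object)
  if (object$converged) {
    cat(sprintf("  residual norm %.4g pC over %d samples\n",
                object$residual_norm, length(object$q_pC)))
    se <- tryCatch(sqrt(diag(stats::vcov(object$nls))),
                   error = function(e) NULL)
    if (!is.null(se))
      cat(sprintf("  approx. SE: a_fast %.3g, b_slow %.3g, tau_fast %.3g, tau_slow %.3g\n",
                  se[["af"]], se[["bs"]], se[["tf"]], se[["ts"]]))
  }
  invisible(object)
}

#' @export
plot.charge_decomp <- function(x, ...) {
  plot(x$time_ms, x$q_pC, type = "l", col = "grey40",
       xlab = "time after stimulus (ms)", ylab = "cumulative charge (pC)",
       ...)
  if (x$converged) {
    lines(x$time_ms, predict(x), col = "red", lwd = 2)
    s <- x$time_ms - x$time_ms[1]
    lines(x$time_ms, x$a_fast * (1 - exp(-s / x$tau_fast)),
          col = "blue", lty = 2)
    lines(x$time_ms, x$b_slow_coef * (1 - exp(-s / x$tau_slow)),
          col = "darkgreen", lty = 2)
    legend("bottomright", bty = "n",
           legend = c("data", "fit", "fast", "slow"),
           col = c("grey40", "red", "blue", "darkgreen"),
           lty = c(1, 1, 2, 2))
  }
  invisible(x)
}
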