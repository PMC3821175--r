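#' Baseline subtraction
#'
#' Subtracts the mean current of a pre-event window from the whole
#' sweep, compensating for basal activity before a stimulus or
#' application.
#'
#' @param trace a [sweep_trace()].
#' @param pre_window_ms length-2 vector `(start, stop)` in ms; must lie
#'   within the record and contain at least one sample.
#' @return the baseline-subtracted [sweep_trace()].
#' @export
baseline_subtract <- function(trace, pre_window_ms) {
  stopifnot(inherits(trace, "sweep_trace"))
  .assert(length(pre_window_ms) == 2 && pre_window_ms[2] > pre_window_ms[1],
          "pre_window_ms must be (start, stop) with stop > start")
  sel <- trace$time_ms >= pre_window_ms[1] & trace$time_ms <= pre_window_ms[2]
  .assert(any(sel), "empty baseline window")
  trace$current_pA <- trace$current_pA - mean(trace$current_pA[sel])
  trace
}

#' Blank the stimulus artifact
#'
#' Replaces the samples in `[t0, t0 + width_ms]` by linear
#' interpolation between the window edges, removing the brief square
#' stimulus artifact before integration.
#'
#' @param trace a [sweep_trace()].
#' @param t0 stimulus time (ms).
#' @param width_ms blanking width after `t0`; default 0.7 ms.
#' @return the artifact-blanked [sweep_trace()].
#' @export
blank_artifact <- function(trace, t0, width_ms = 0.7) {
  stopifnot(inherits(trace, "sweep_trace"))
  i0 <- .t_index(trace, t0)
  i1 <- .t_index(trace, t0 + width_ms)
  if (i1 > i0 + 1L) {
    idx <- (i0 + 1L):(i1 - 1L)
    trace$current_pA[idx] <- stats::approx(
      x = trace$time_ms[c(i0, i1)], y = trace$current_pA[c(i0, i1)],
      xout = trace$time_ms[idx])$y
  }
  trace
}

#' Peak amplitude of an evoked response
#'
#' Maximum inward (negative) deflection within `[t0, t0 + search_ms]`
#' of a baseline-subtracted sweep, reported as a positive magnitude
#' with its latency from `t0`.
#'
#' @param trace baseline-subtracted [sweep_trace()].
#' @param t0 stimulus time (ms).
#' @param search_ms search window length (ms).
#' @return list with `amplitude_pA` (magnitude) and `latency_ms`.
#' @export
peak_amplitude <- function(trace, t0, search_ms = 50) {
  i0 <- .t_index(trace, t0)
  i1 <- .t_index(trace, t0 + search_ms)
  .assert(i1 >= i0, "empty search window")
  seg <- trace$current_pA[i0:i1]
  k <- which.min(seg)
  list(amplitude_pA = max(0, -seg[k]),
       latency_ms = trace$time_ms[i0 + k - 1L] - t0)
}

#' Cumulative charge transfer
#'
#' Trapezoidal integral of the negated current (inward current counts
#' positive charge) from `t0`, in pC (pA x s).
#'
#' @param trace baseline-subtracted [sweep_trace()].
#' @param t0 integration start (ms).
#' @param duration_ms integration length (ms); default 50.
#' @return list with `time_ms` (relative to `t0`), `q_pC` (cumulative
#'   curve) and `q_total` — the charge at `t0 + duration_ms`.
#' @export
cumulative_charge <- function(trace, t0, duration_ms = 50) {
  i0 <- .t_index(trace, t0)
  i1 <- .t_index(trace, t0 + duration_ms)
  .assert(i1 > i0, "integration window must span at least one interval")
  t_rel <- trace$time_ms[i0:i1] - t0
  q <- pracma::cumtrapz(t_rel, -trace$current_pA[i0:i1]) / 1000  # pA ms -> pC
  q <- as.numeric(q)
  list(time_ms = t_rel, q_pC = q, q_total = q[length(q)])
}

#' Charge per analysis window
#'
#' Trapezoid integrals of the negated current over half-open windows
#' `[start, stop)` relative to `t0` (e.g. 0--20 and 25--50 ms).
#'
#' @param trace baseline-subtracted [sweep_trace()].
#' @param t0 reference time (ms).
#' @param windows list of length-2 vectors `(start, stop)` in ms;
#'   windows must not overlap and must lie within the record.
#' @return named numeric vector of charges (pC), names `start-stop`.
#' @export
windowed_charge <- function(trace, t0, windows = list(c(0, 20), c(25, 50))) {
  .assert(length(windows) >= 1, "need at least one window")
  w <- do.call(rbind, windows)
  .assert(all(w[, 2] > w[, 1]), "each window needs stop > start")
  ord <- order(w[, 1])
  if (nrow(w) > 1)
    .assert(all(w[ord[-1], 1] >= w[ord[-nrow(w)], 2]),
            "windows must not overlap")
  out <- vapply(windows, function(win) {
    i0 <- .t_index(trace, t0 + win[1])
    i1 <- .t_index(trace, t0 + win[2])
    pracma::trapz(trace$time_ms[i0:i1], -trace$current_pA[i0:i1]) / 1000
  }, 0)
  names(out) <- vapply(windows, function(win)
    sprintf("%g-%g", win[1], win[2]), "")
  out
}

#' Sucrose-evoked charge transfer
#'
#' Baseline-compensated charge during the first 1 s and first 5 s of a
#' hypertonic sucrose application — the readily-releasable-pool
#' readout. Baseline is the mean current over `baseline_ms` before
#' application onset. Windows extending past the record are integrated
#' to the end and flagged censored.
#'
#' @param trace a [sweep_trace()] (raw; compensation is internal).
#' @param app_start application onset (ms).
#' @param windows_s integration windows from onset, in seconds.
#' @param baseline_ms length of the pre-application baseline (ms).
#' @return list with `q_pC` (named per window), `censored` (logical per
#'   window), `baseline_pA`.
#' @export
sucrose_charges <- function(trace, app_start, windows_s = c(1, 5),
                            baseline_ms = 500) {
  .assert(app_start - baseline_ms >= trace$time_ms[1],
          "baseline window precedes the record")
  bl <- baseline_subtract(trace, c(app_start - baseline_ms, app_start))
  t_end <- bl$time_ms[length(bl$time_ms)]
  q <- censored <- numeric(0)
  for (w in windows_s) {
    stop_ms <- app_start + w * 1000
    cens <- stop_ms > t_end
    stop_ms <- min(stop_ms, t_end)
    i0 <- .t_index(bl, app_start); i1 <- .t_index(bl, stop_ms)
    q <- c(q, pracma::trapz(bl$time_ms[i0:i1], -bl$current_pA[i0:i1]) / 1000)
    censored <- c(censored, cens)
  }
  names(q) <- sprintf("q_%gs", windows_s)
  list(q_pC = q, censored = as.logical(censored),
       baseline_pA = mean(trace$current_pA[trace$time_ms >=
                            app_start - baseline_ms &
                            trace$time_ms <= app_start]))
}

#' Evoked/sucrose release-probability proxy
#'
#' Ratio of the genotype mean evoked charge (50 ms window) to the
#' genotype mean sucrose charge (5 s window). A genotype-level scalar:
#' means are taken across animals first, so no SEM is attached.
#'
#' @param mean_eepsc_q50 mean evoked charge (pC), `> 0`.
#' @param mean_sucrose_q5s mean sucrose charge (pC), `> 0`.
#' @return the dimensionless ratio.
#' @export
release_ratio <- function(mean_eepsc_q50, mean_sucrose_q5s) {
  .assert(.is_number(mean_eepsc_q50) && mean_eepsc_q50 > 0,
          "mean eEPSC charge must be a positive number")
  .assert(.is_number(mean_sucrose_q5s) && mean_sucrose_q5s > 0,
          "mean sucrose charge must be a positive number")
  mean_eepsc_q50 / mean_sucrose_q5s
}

#' 90--10% decay time
#'
#' Time between the decay-phase crossings of 90% and 10% of peak
#' current magnitude, with linear interpolation between samples — a
#' desynchronization metric dominated by the slow release phase.
#'
#' @param trace baseline-subtracted [sweep_trace()] with an inward
#'   (negative) response.
#' @param t0 stimulus time (ms).
#' @param search_ms peak search window after `t0` (ms).
#' @param smooth_ms optional moving-average width (ms); default no
#'   smoothing.
#' @return list with `decay_ms`, crossing times `t90_ms`, `t10_ms`
#'   (absolute), and `censored` — `TRUE` when the trace never decays to
#'   10% within the record (then `decay_ms` is the time to the record
#'   end, a lower bound).
#' @export
decay_time_90_10 <- function(trace, t0, search_ms = 50, smooth_ms = NULL) {
  cur <- trace$current_pA
  if (!is.null(smooth_ms) && smooth_ms > 0) {
    w <- max(1L, round(smooth_ms * trace$fs_khz))
    cur <- as.numeric(stats::filter(cur, rep(1 / w, w), sides = 2))
    cur[is.na(cur)] <- trace$current_pA[is.na(cur)]
  }
  i0 <- .t_index(trace, t0)
  i1 <- .t_index(trace, min(t0 + search_ms,
                            trace$time_ms[length(trace$time_ms)]))
  ipk <- i0 - 1L + which.min(cur[i0:i1])
  peak <- -cur[ipk]
  .assert(peak > 0, "no inward peak found after t0")

  cross_after <- function(start, level) {
    # first time after `start` where magnitude falls below `level`
    mag <- -cur[start:length(cur)]
    k <- which(mag <= level)[1]
    if (is.na(k)) return(NA_real_)
    if (k == 1L) return(trace$time_ms[start])
    i_hi <- start + k - 2L; i_lo <- start + k - 1L
    stats::approx(x = -cur[c(i_hi, i_lo)],
                  y = trace$time_ms[c(i_hi, i_lo)], xout = level)$y
  }
  t90 <- cross_after(ipk, 0.9 * peak)
  t10 <- cross_after(ipk, 0.1 * peak)
  censored <- is.na(t10)
  if (censored) t10 <- trace$time_ms[length(trace$time_ms)]
  list(decay_ms = t10 - t90, t90_ms = t90, t10_ms = t10,
       censored = censored)
}
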