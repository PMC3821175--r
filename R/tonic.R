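#' Detect miniature/tonic EPSC events
#'
#' Derivative-threshold detector: the current is boxcar-smoothed, a
#' lagged difference (over roughly one rise time) is computed, and
#' candidate events are local minima of that difference trace lying
#' below `-threshold_sd * SD`, where SD is the robust baseline SD of
#' the difference trace (median absolute deviation x 1.4826). Using
#' minima rather than threshold crossings lets closely spaced events
#' register separately. Candidates below `min_amp_pA`, or within
#' `refractory_ms` of a larger event, are dropped. Per-event amplitude
#' is the local pre-event baseline (median of the 2 ms before onset)
#' minus the post-onset peak.
#'
#' @param trace a baseline-subtracted or detrended [sweep_trace()]
#'   with inward (negative) events.
#' @param threshold_sd detection threshold in robust SD units.
#' @param min_amp_pA minimum accepted amplitude (pA).
#' @param refractory_ms events closer than this keep only the larger.
#' @param smooth_ms boxcar smoothing width (ms).
#' @param diff_lag_ms lag of the difference operator (ms), matched to
#'   the event rise time.
#' @param peak_window_ms window after onset searched for the peak (ms).
#'
#' @return An `event_list`: list with `time_ms` (onsets, strictly
#'   increasing), `amplitude_pA` (> 0), `duration_s`, `frequency_hz`
#'   (= count / duration), and `config` — a snapshot of every
#'   detection parameter.
#' @examples
#' tr <- sim_tonic_trace(rate = 10, duration = 5, seed = 3)
#' ev <- detect_events(tr)
#' ev$frequency_hz
#' @export
detect_events <- function(trace, threshold_sd = 4, min_amp_pA = 10,
                          refractory_ms = 2, smooth_ms = 0.5,
                          diff_lag_ms = 1, peak_window_ms = 5) {
  stopifnot(inherits(trace, "sweep_trace"))
  cur <- trace$current_pA
  .assert(all(is.finite(cur)), "trace contains non-finite samples")
  fs <- trace$fs_khz
  n <- length(cur)

  w <- max(1L, round(smooth_ms * fs))
  sm <- as.numeric(stats::filter(cur, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- cur[is.na(sm)]
  lag <- max(1L, round(diff_lag_ms * fs))
  d <- c(rep(0, lag), sm[(lag + 1):n] - sm[1:(n - lag)])

  sd_r <- stats::mad(d, constant = 1.4826)
  if (sd_r == 0) sd_r <- stats::sd(d)
  thr <- -threshold_sd * sd_r
  below <- d < thr
  dm <- c(0, diff(d))
  onsets <- which(below & c(dm[-1] >= 0, TRUE) & c(TRUE, dm[-n] < 0))
  if (!length(onsets))
    return(.event_list(numeric(0), numeric(0), trace,
                       threshold_sd, min_amp_pA, refractory_ms,
                       smooth_ms, diff_lag_ms, peak_window_ms))

  # amplitude: local pre-onset baseline minus post-onset trough
  pre <- max(1L, round(2 * fs))
  pk_w <- max(1L, round(peak_window_ms * fs))
  amps <- t_on <- numeric(length(onsets))
  for (k in seq_along(onsets)) {
    i <- onsets[k]
    base <- stats::median(sm[max(1L, i - pre):max(1L, i - 1L)])
    seg <- sm[i:min(n, i + pk_w)]
    amps[k] <- base - min(seg)
    # the difference-trace minimum trails the onset by about half a lag
    t_on[k] <- trace$time_ms[i] - diff_lag_ms / 2
  }
  keep <- amps >= min_amp_pA
  t_on <- t_on[keep]; amps <- amps[keep]

  # refractory: among events closer than refractory_ms, keep the larger
  if (length(t_on) > 1) {
    keep <- rep(TRUE, length(t_on))
    ord <- order(amps, decreasing = TRUE)
    for (k in ord) {
      if (!keep[k]) next
      close <- which(keep & abs(t_on - t_on[k]) < refractory_ms)
      close <- setdiff(close, k)
      keep[close[amps[close] <= amps[k]]] <- FALSE
    }
    t_on <- t_on[keep]; amps <- amps[keep]
  }
  ord <- order(t_on)
  .event_list(t_on[ord], amps[ord], trace, threshold_sd, min_amp_pA,
              refractory_ms, smooth_ms, diff_lag_ms, peak_window_ms)
}

#' Construct an event list
#'
#' Container for detected (or known ground-truth) synaptic events.
#' Normally produced by [detect_events()]; constructing one directly
#' is useful for feeding generator ground truth into
#' [event_summary()] or [cali_timecourse()].
#'
#' @param time_ms event onset times (ms), strictly increasing.
#' @param duration_s trace duration (s), `> 0`.
#' @param amplitude_pA event amplitudes (pA, positive magnitudes).
#' @param decay_ms optional per-event decay times (ms).
#' @param config detection parameter snapshot (list).
#' @return object of class `event_list`; `frequency_hz` is
#'   `length(time_ms) / duration_s`.
#' @export
event_list <- function(time_ms, duration_s,
                       amplitude_pA = rep(NA_real_, length(time_ms)),
                       decay_ms = rep(NA_real_, length(time_ms)),
                       config = list()) {
  .assert(duration_s > 0, "duration must be positive")
  .assert(!is.unsorted(time_ms, strictly = TRUE) || length(time_ms) < 2,
          "event times must be strictly increasing")
  .assert(all(is.na(amplitude_pA) | amplitude_pA > 0),
          "amplitudes must be positive")
  structure(list(time_ms = as.numeric(time_ms),
                 amplitude_pA = as.numeric(amplitude_pA),
                 decay_ms = as.numeric(decay_ms),
                 duration_s = duration_s,
                 frequency_hz = length(time_ms) / duration_s,
                 config = config),
            class = "event_list")
}

.event_list <- function(time_ms, amplitude_pA, trace, threshold_sd,
                        min_amp_pA, refractory_ms, smooth_ms,
                        diff_lag_ms, peak_window_ms) {
  event_list(time_ms, duration_s = diff(range(trace$time_ms)) / 1000,
             amplitude_pA = amplitude_pA,
             config = list(threshold_sd = threshold_sd,
                           min_amp_pA = min_amp_pA,
                           refractory_ms = refractory_ms,
                           smooth_ms = smooth_ms,
                           diff_lag_ms = diff_lag_ms,
                           peak_window_ms = peak_window_ms))
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("event_list: %d events in %.3g s (%.2f Hz)\n",
              length(x$time_ms), x$duration_s, x$frequency_hz))
  invisible(x)
}

#' Single-exponential decay time of one event
#'
#' Fits `I(t) = A exp(-t / tau)` to the current decay after the event
#' peak; returns tau in ms (NA, flagged, on failure). The fit starts
#' `skip_ms` after the peak so the blunt top — where the rising phase
#' still contributes — does not bias the time constant.
#'
#' @param trace the [sweep_trace()] the event came from.
#' @param event_time_ms event onset time (ms).
#' @param fit_window_ms decay-fit window after the peak (ms).
#' @param peak_window_ms window after onset searched for the peak (ms).
#' @param skip_ms gap between the peak and the start of the fit (ms).
#' @return list with `tau_ms` (NA on failure) and `ok`.
#' @export
event_decay_time <- function(trace, event_time_ms, fit_window_ms = 15,
                             peak_window_ms = 5, skip_ms = 1) {
  fs <- trace$fs_khz
  i_on <- .t_index(trace, event_time_ms)
  n <- length(trace$current_pA)
  seg_end <- min(n, i_on + round(peak_window_ms * fs))
  ipk <- i_on - 1L + which.min(trace$current_pA[i_on:seg_end])
  i0 <- min(n, ipk + round(skip_ms * fs))
  iend <- min(n, ipk + round(fit_window_ms * fs))
  t <- trace$time_ms[i0:iend] - trace$time_ms[i0]
  y <- -trace$current_pA[i0:iend]
  if (length(t) < 5 || y[1] <= 0) return(list(tau_ms = NA_real_, ok = FALSE))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / tau),
                      data = data.frame(t = t, y = y),
                      start = list(a = y[1], tau = 3),
                      lower = c(0, 0.1), upper = c(Inf, 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(tau_ms = NA_real_, ok = FALSE))
  list(tau_ms = stats::coef(fit)[["tau"]], ok = TRUE)
}

#' Attach per-event decay times to an event list
#'
#' @param events an `event_list` from [detect_events()].
#' @param trace the source [sweep_trace()].
#' @inheritParams event_decay_time
#' @return the `event_list` with its `decay_ms` field filled (NA where
#'   the per-event fit failed; such events are excluded from means).
#' @export
measure_decays <- function(events, trace, fit_window_ms = 15) {
  events$decay_ms <- vapply(events$time_ms, function(t)
    event_decay_time(trace, t, fit_window_ms)$tau_ms, 0)
  events
}

#' Summary statistics of a detected event list
#'
#' @param events an `event_list`.
#' @return list with `frequency_hz`, `n`, and mean +/- SEM of
#'   amplitude and decay (NA-flagged when undefined, e.g. no events or
#'   a single event).
#' @export
event_summary <- function(events) {
  .assert(events$duration_s > 0, "duration must be positive")
  amp <- .mean_sem(events$amplitude_pA)
  dec <- .mean_sem(events$decay_ms)
  list(frequency_hz = events$frequency_hz, n = length(events$time_ms),
       amp_mean_pA = amp$mean, amp_sem_pA = amp$sem,
       decay_mean_ms = dec$mean, decay_sem_ms = dec$sem)
}

#' Event-frequency time course around an illumination epoch
#'
#' Bins event frequency across the record and normalizes the
#' frequency in the bin starting at `light_on + span_s` to the mean
#' pre-illumination frequency — the readout used for
#' chromophore-assisted light inactivation (CALI) experiments, where
#' `span_s` is the illumination duration (default 2 min).
#'
#' @param events an `event_list` (or [detect_events()] output).
#' @param trace the source [sweep_trace()] (defines the record extent).
#' @param light_on_ms illumination onset (ms).
#' @param span_s illumination span (s); default 120.
#' @param bin_s bin width (s).
#' @return A `cali_timecourse`: list with `bin_start_s`, `freq_hz`
#'   per bin, `pre_mean_hz`, `normalized_post`, and the markers.
#' @export
cali_timecourse <- function(events, trace, light_on_ms, span_s = 120,
                            bin_s = 30) {
  t0 <- trace$time_ms[1]; t1 <- trace$time_ms[length(trace$time_ms)]
  .assert(light_on_ms > t0 && light_on_ms < t1,
          "light_on must lie within the record")
  ev_s <- events$time_ms / 1000
  edges <- seq(t0 / 1000, t1 / 1000 + bin_s, by = bin_s)
  counts <- graphics::hist(ev_s, breaks = edges, plot = FALSE)$counts
  freq <- counts / bin_s

  pre_mask <- ev_s < light_on_ms / 1000
  pre_dur <- (light_on_ms - t0) / 1000
  .assert(pre_dur > 0, "pre-light segment is empty")
  pre_mean <- sum(pre_mask) / pre_dur
  .assert(pre_mean > 0, "zero pre-light frequency: cannot normalize")

  post_start <- light_on_ms / 1000 + span_s
  post_bin <- sum(ev_s >= post_start & ev_s < post_start + bin_s) / bin_s
  structure(list(bin_start_s = edges[-length(edges)], freq_hz = freq,
                 bin_s = bin_s, light_on_s = light_on_ms / 1000,
                 span_s = span_s, pre_mean_hz = pre_mean,
                 normalized_post = post_bin / pre_mean),
            class = "cali_timecourse")
}

#' @export
print.cali_timecourse <- function(x, ...) {
  cat(sprintf(paste0("cali_timecourse: pre %.2f Hz; post (%g s after",
                     " light on) %.2f x pre\n"),
              x$pre_mean_hz, x$span_s, x$normalized_post))
  invisible(x)
}

#' Write detected events as CSV
#'
#' Columns: `time_ms`, `amp_pA`, `decay_ms`.
#' @param events an `event_list`.
#' @param path CSV file path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(data.frame(time_ms = events$time_ms,
                              amp_pA = events$amplitude_pA,
                              decay_ms = events$decay_ms),
                   path, row.names = FALSE)
  invisible(path)
}
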