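# In-code fixtures and independent oracles shared across tests.

# independent trapezoid rule (oracle; deliberately not pracma)
trapz_oracle <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# a pure single-exponential inward current, peak 1 pA at t0
pure_exp_trace <- function(tau_ms, t0 = 10, fs = 10, duration_ms = 400) {
  t <- seq(0, duration_ms, by = 1 / fs)
  cur <- -ifelse(t >= t0, exp(-(t - t0) / tau_ms), 0)
  sweep_trace(t, cur, fs, markers = list(t0_ms = t0))
}

# noiseless biexponential cumulative charge on a time grid (ms)
biexp_q <- function(s, a_fast, b_slow, tau_fast, tau_slow) {
  a_fast * (1 - exp(-s / tau_fast)) + b_slow * (1 - exp(-s / tau_slow))
}

# event-matching precision/recall against ground truth
match_events <- function(detected_ms, truth_ms, tol_ms = 3) {
  prec <- if (length(detected_ms))
    mean(vapply(detected_ms, function(t) any(abs(truth_ms - t) < tol_ms),
                TRUE)) else NA_real_
  rec <- if (length(truth_ms))
    mean(vapply(truth_ms, function(t) any(abs(detected_ms - t) < tol_ms),
                TRUE)) else NA_real_
  list(precision = prec, recall = rec)
}

# ground-truth events of a simulated tonic trace as an event_list
truth_events <- function(trace) {
  gt <- trace$ground_truth
  ord <- order(gt$event_times_ms)
  event_list(gt$event_times_ms[ord], duration_s = gt$duration,
             amplitude_pA = gt$amplitudes_pA[ord])
}
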