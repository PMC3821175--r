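#' Simulate an evoked EPSC sweep with known biexponential kinetics
#'
#' Generates the current corresponding to a two-component cumulative
#' charge curve
#' \deqn{Q(t) = A_{fast}(1 - e^{-(t-t_0)/\tau_{fast}}) +
#'              B_{slow}(1 - e^{-(t-t_0)/\tau_{slow}})}
#' with \eqn{A_{fast} = f_{fast} \cdot q_{total}} and \eqn{B_{slow}}
#' chosen so that the charge transferred in the 50 ms integration window
#' equals `q_total` exactly. The simulated current is the (negative,
#' inward) time derivative of Q, optionally low-pass filtered with a
#' first-order rise, on a Gaussian-noise baseline.
#'
#' @param t0 stimulus time (ms).
#' @param q_total total transferred charge over the 50 ms window (pC).
#' @param f_fast fast fraction of `q_total` (0--1).
#' @param tau_fast,tau_slow fast and slow time constants (ms);
#'   `tau_fast < tau_slow` required.
#' @param rise_tau optional first-order rise filter constant (ms);
#'   `NULL` (default) for an instantaneous-onset current.
#' @param noise_sd baseline current noise SD (pA), `>= 0`.
#' @param fs sampling rate (kHz).
#' @param duration_ms record length (ms).
#' @param window_ms integration window defining `q_total` (ms).
#' @param seed integer seed; all randomness in the call flows from it.
#'
#' @return A [sweep_trace()] with marker `t0_ms` and a `ground_truth`
#'   list holding every generating parameter plus the realized
#'   `a_fast`/`b_slow` amplitudes (pC).
#' @examples
#' tr <- sim_evoked_trace(t0 = 10, q_total = 1.5, f_fast = 0.77,
#'                        tau_fast = 5.29, tau_slow = 40.3, seed = 1)
#' tr$ground_truth$a_fast
#' @export
sim_evoked_trace <- function(t0 = 10, q_total = 1.5, f_fast = 0.77,
                             tau_fast = 5.29, tau_slow = 40.3,
                             rise_tau = NULL, noise_sd = 5,
                             fs = 10, duration_ms = 100,
                             window_ms = 50, seed = 1) {
  .assert(tau_fast < tau_slow, "tau_fast must be smaller than tau_slow")
  .assert(f_fast >= 0 && f_fast <= 1, "f_fast must lie in [0, 1]")
  .assert(q_total >= 0, "q_total must be non-negative")
  .assert(noise_sd >= 0, "noise_sd must be non-negative")
  .assert(fs > 0, "fs must be positive")
  .assert(t0 + window_ms <= duration_ms,
          "integration window extends past the record")

  a_fast <- f_fast * q_total
  # slow amplitude normalized so Q(t0 + window) = q_total exactly
  b_slow <- (q_total - a_fast * (1 - exp(-window_ms / tau_fast))) /
    (1 - exp(-window_ms / tau_slow))

  time_ms <- seq(0, duration_ms, by = 1 / fs)
  s <- pmax(time_ms - t0, 0)
  on <- time_ms >= t0
  # dQ/dt in pC/ms = nA; current in pA, inward negative
  i_pa <- -1000 * on * (a_fast / tau_fast * exp(-s / tau_fast) +
                          b_slow / tau_slow * exp(-s / tau_slow))
  if (!is.null(rise_tau)) {
    .assert(rise_tau > 0, "rise_tau must be positive")
    # first-order recursion y[k] = a y[k-1] + (1-a) x[k]; DC gain 1
    a <- exp(-1 / (fs * rise_tau))
    i_pa <- as.numeric(stats::filter(i_pa * (1 - a), a, method = "recursive"))
  }
  set.seed(seed)
  i_pa <- i_pa + stats::rnorm(length(i_pa), 0, noise_sd)

  sweep_trace(time_ms, i_pa, fs_khz = fs, markers = list(t0_ms = t0),
              ground_truth = list(t0 = t0, q_total = q_total,
                                  f_fast = f_fast, tau_fast = tau_fast,
                                  tau_slow = tau_slow, rise_tau = rise_tau,
                                  noise_sd = noise_sd, a_fast = a_fast,
                                  b_slow = b_slow, window_ms = window_ms,
                                  seed = seed))
}

# difference-of-exponentials quantal waveform, unit peak amplitude
.quantal_kernel <- function(fs, decay_tau, rise_tau, n_tail = 8) {
  len <- max(2L, ceiling(fs * (rise_tau + n_tail * decay_tau)))
  t <- seq_len(len) / fs
  w <- exp(-t / decay_tau) - exp(-t / rise_tau)
  w / max(w)
}

#' Simulate a tonic (miniature) EPSC sweep
#'
#' Superimposes difference-of-exponential quantal currents at Poisson
#' event times on a Gaussian-noise baseline. An optional `rate_profile`
#' multiplies the base rate as a function of time (used to emulate
#' illumination time courses); events are drawn by thinning.
#'
#' @param rate mean event rate (Hz), `>= 0`.
#' @param duration trace duration (s).
#' @param amp_mean,amp_cv quantal amplitude mean (pA) and coefficient of
#'   variation; amplitudes are gamma-distributed (positive by
#'   construction), constant when `amp_cv = 0`.
#' @param decay_tau,rise_tau quantal decay and rise constants (ms).
#' @param noise_sd baseline noise SD (pA).
#' @param fs sampling rate (kHz).
#' @param rate_profile optional function of time in seconds returning a
#'   non-negative rate multiplier (values above 1 are allowed).
#' @param seed integer seed.
#'
#' @return A [sweep_trace()] whose `ground_truth` holds the event times
#'   (ms), amplitudes (pA) and generating parameters.
#' @examples
#' tr <- sim_tonic_trace(rate = 20, duration = 5, seed = 2)
#' length(tr$ground_truth$event_times_ms)
#' @export
sim_tonic_trace <- function(rate = 25, duration = 60, amp_mean = 25,
                            amp_cv = 0.3, decay_tau = 3, rise_tau = 0.5,
                            noise_sd = 2.5, fs = 10,
                            rate_profile = NULL, seed = 1) {
  .assert(rate >= 0, "rate must be non-negative")
  .assert(duration > 0, "duration must be positive")
  .assert(amp_cv >= 0, "amp_cv must be non-negative")
  .assert(rise_tau < decay_tau, "rise_tau must be smaller than decay_tau")
  .assert(noise_sd >= 0, "noise_sd must be non-negative")

  set.seed(seed)
  n_samp <- floor(duration * 1000 * fs) + 1L
  time_ms <- (seq_len(n_samp) - 1L) / fs

  # homogeneous candidates at the base rate, thinned by rate_profile;
  # exact ties (possible at the RNG's granularity) are re-drawn so
  # event times are strictly increasing
  draw_times <- function(n) {
    ev <- stats::runif(n, 0, duration)
    while (anyDuplicated(ev) > 0)
      ev[duplicated(ev)] <- stats::runif(sum(duplicated(ev)), 0, duration)
    sort(ev)
  }
  n_ev <- stats::rpois(1, rate * duration)
  ev_s <- draw_times(n_ev)
  if (!is.null(rate_profile) && length(ev_s)) {
    mult <- vapply(ev_s, rate_profile, 0)
    .assert(all(mult >= 0), "rate_profile must be non-negative")
    mmax <- max(mult, 1)
    if (mmax > 1) {  # re-draw candidates at the elevated ceiling
      n_ev <- stats::rpois(1, rate * mmax * duration)
      ev_s <- draw_times(n_ev)
      mult <- vapply(ev_s, rate_profile, 0) / mmax
    }
    ev_s <- ev_s[stats::runif(length(ev_s)) < mult]
  }
  ev_ms <- ev_s * 1000
  amps <- if (amp_cv == 0) rep(amp_mean, length(ev_ms)) else
    stats::rgamma(length(ev_ms), shape = 1 / amp_cv^2,
                  scale = amp_mean * amp_cv^2)

  i_pa <- stats::rnorm(n_samp, 0, noise_sd)
  kern <- .quantal_kernel(fs, decay_tau, rise_tau)
  for (k in seq_along(ev_ms)) {
    i0 <- floor(ev_ms[k] * fs) + 1L
    idx <- i0 + seq_along(kern) - 1L
    keep <- idx <= n_samp
    i_pa[idx[keep]] <- i_pa[idx[keep]] - amps[k] * kern[keep]
  }

  sweep_trace(time_ms, i_pa, fs_khz = fs,
              ground_truth = list(event_times_ms = ev_ms,
                                  amplitudes_pA = amps,
                                  rate = rate, duration = duration,
                                  amp_mean = amp_mean, amp_cv = amp_cv,
                                  decay_tau = decay_tau, rise_tau = rise_tau,
                                  noise_sd = noise_sd, seed = seed))
}

#' Simulate a dual-channel fluorescence line profile
#'
#' Places `n_puncta` Gaussian puncta along a line for channel 1; each
#' has a channel-2 partner with probability `coloc_prob`, displaced by a
#' draw from Normal(`offset_mean_nm`, `offset_sd_nm`). Unpartnered
#' channel-2 puncta appear in place of missing partners at independent
#' positions, so both channels carry comparable punctum counts.
#'
#' @param length_nm profile length (nm).
#' @param pixel_nm grid spacing (nm); default 100.
#' @param n_puncta number of channel-1 puncta; their centers are spaced
#'   at least `3 * punctum_sigma_nm` apart (error if they cannot fit).
#' @param punctum_sigma_nm Gaussian punctum SD (nm).
#' @param punctum_amp_range length-2 amplitude range (AFU).
#' @param offset_mean_nm,offset_sd_nm channel-2 displacement
#'   distribution (nm).
#' @param baseline constant background (AFU).
#' @param noise_sd additive intensity noise SD (AFU).
#' @param coloc_prob probability a channel-1 punctum has a channel-2
#'   partner.
#' @param animal_id label carried into the output.
#' @param seed integer seed.
#'
#' @return A `line_profile_pair`: list with `animal_id`, `position_nm`,
#'   `ch1`, `ch2`, `pixel_nm` and a `ground_truth` list of punctum
#'   positions, partner offsets and parameters.
#' @export
sim_profile_pair <- function(length_nm = 20000, pixel_nm = 100,
                             n_puncta = 10, punctum_sigma_nm = 200,
                             punctum_amp_range = c(80, 150),
                             offset_mean_nm = 0, offset_sd_nm = 0,
                             baseline = 5, noise_sd = 2,
                             coloc_prob = 1, animal_id = "a1", seed = 1) {
  .assert(pixel_nm > 0, "pixel_nm must be positive")
  .assert(length_nm >= 10 * pixel_nm, "profile must span at least 10 pixels")
  .assert(punctum_sigma_nm > 0, "punctum_sigma_nm must be positive")
  .assert(coloc_prob >= 0 && coloc_prob <= 1, "coloc_prob must be in [0, 1]")
  min_gap <- 3 * punctum_sigma_nm
  margin <- 3 * punctum_sigma_nm
  .assert(n_puncta * min_gap <= length_nm - 2 * margin,
          "%d puncta at >= %g nm spacing do not fit in %g nm",
          n_puncta, min_gap, length_nm)

  set.seed(seed)
  # sequential rejection placement with minimum spacing
  centers <- numeric(0)
  while (length(centers) < n_puncta) {
    cand <- stats::runif(1, margin, length_nm - margin)
    if (!length(centers) || min(abs(cand - centers)) >= min_gap)
      centers <- c(centers, cand)
  }
  centers <- sort(centers)
  amps1 <- stats::runif(n_puncta, punctum_amp_range[1], punctum_amp_range[2])
  partnered <- stats::runif(n_puncta) < coloc_prob
  offsets <- stats::rnorm(n_puncta, offset_mean_nm, offset_sd_nm)
  ch2_centers <- ifelse(partnered, centers + offsets,
                        stats::runif(n_puncta, margin, length_nm - margin))
  amps2 <- stats::runif(n_puncta, punctum_amp_range[1], punctum_amp_range[2])

  pos <- seq(0, length_nm, by = pixel_nm)
  gauss_sum <- function(cent, amp) {
    y <- numeric(length(pos))
    for (k in seq_along(cent))
      y <- y + amp[k] * exp(-(pos - cent[k])^2 / (2 * punctum_sigma_nm^2))
    y
  }
  ch1 <- pmax(baseline + gauss_sum(centers, amps1) +
                stats::rnorm(length(pos), 0, noise_sd), 0)
  ch2 <- pmax(baseline + gauss_sum(ch2_centers, amps2) +
                stats::rnorm(length(pos), 0, noise_sd), 0)

  line_profile_pair(position_nm = pos, ch1 = ch1, ch2 = ch2,
                    animal_id = animal_id,
                    ground_truth = list(ch1_centers_nm = centers,
                                        ch2_centers_nm = ch2_centers,
                                        partnered = partnered,
                                        offsets_nm = offsets[partnered],
                                        coloc_prob = coloc_prob,
                                        offset_mean_nm = offset_mean_nm,
                                        offset_sd_nm = offset_sd_nm,
                                        pixel_nm = pixel_nm, seed = seed))
}

#' Simulate a docked-vesicle EM dataset
#'
#' Draws per-profile vesicle counts from a Poisson distribution and
#' vesicle distances (nm, from the dense-projection edge along the
#' membrane) from a two-component mixture: a proximal exponential and a
#' distal Gaussian, both truncated at zero.
#'
#' @param n_synapses number of synapses (each a contiguous set of serial
#'   profiles containing a dense projection).
#' @param profiles_per_synapse mean of the (zero-truncated Poisson)
#'   profiles-per-synapse distribution.
#' @param vesicles_per_profile mean docked vesicles per profile.
#' @param mixture list with `weights` (length 2, sums to 1),
#'   `proximal_scale` (exponential scale, nm), `distal_mean`,
#'   `distal_sd` (Gaussian component, nm).
#' @param animal label carried into the output.
#' @param seed integer seed.
#'
#' @return An `em_dataset`: data frame with columns `animal`,
#'   `synapse_id`, `profile_id`, `distance_nm` (one row per vesicle;
#'   vesicle-free profiles appear with `distance_nm = NA` so the profile
#'   census is preserved), carrying the generating mixture as attribute
#'   `ground_truth`.
#' @export
sim_em_dataset <- function(n_synapses = 20, profiles_per_synapse = 6,
                           vesicles_per_profile = 4,
                           mixture = list(weights = c(0.7, 0.3),
                                          proximal_scale = 150,
                                          distal_mean = 500,
                                          distal_sd = 50),
                           animal = "wt1", seed = 1) {
  .assert(n_synapses >= 1, "need at least one synapse")
  .assert(profiles_per_synapse >= 1, "profiles_per_synapse must be >= 1")
  .assert(abs(sum(mixture$weights) - 1) < 1e-9, "mixture weights must sum to 1")

  set.seed(seed)
  rows <- vector("list", n_synapses)
  for (s in seq_len(n_synapses)) {
    n_prof <- max(1L, stats::rpois(1, profiles_per_synapse))
    prof_rows <- vector("list", n_prof)
    for (p in seq_len(n_prof)) {
      n_ves <- stats::rpois(1, vesicles_per_profile)
      if (n_ves == 0) {
        d <- NA_real_
      } else {
        comp <- stats::runif(n_ves) < mixture$weights[1]
        d <- ifelse(comp,
                    stats::rexp(n_ves, rate = 1 / mixture$proximal_scale),
                    abs(stats::rnorm(n_ves, mixture$distal_mean,
                                     mixture$distal_sd)))
      }
      prof_rows[[p]] <- data.frame(animal = animal,
                                   synapse_id = sprintf("s%03d", s),
                                   profile_id = sprintf("s%03d_p%02d", s, p),
                                   distance_nm = d)
    }
    rows[[s]] <- do.call(rbind, prof_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- c(mixture,
                                 list(n_synapses = n_synapses,
                                      profiles_per_synapse = profiles_per_synapse,
                                      vesicles_per_profile = vesicles_per_profile,
                                      seed = seed))
  class(out) <- c("em_dataset", "data.frame")
  out
}

#' Read / write docked-vesicle tables as CSV
#'
#' Columns: `animal`, `synapse_id`, `profile_id`, `distance_nm`
#' (NA rows mark vesicle-free profiles).
#'
#' @param dataset an `em_dataset` data frame.
#' @param path CSV file path.
#' @return `read_em_csv` returns an `em_dataset`.
#' @export
write_em_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_em_csv
#' @export
read_em_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("animal", "synapse_id", "profile_id", "distance_nm")
              %in% names(df)), "missing EM dataset columns")
  class(df) <- c("em_dataset", "data.frame")
  df
}
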