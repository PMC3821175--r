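# Evoked-EPSC analysis: baseline handling, charge integration, the
# biexponential decomposition, decay times, sucrose charges.

test_that("baseline subtraction removes constant and noisy offsets", {
  t <- seq(0, 100, by = 0.1)
  tr <- sweep_trace(t, rep(-10, length(t)), 10)
  bl <- baseline_subtract(tr, c(0, 20))
  expect_true(all(bl$current_pA == 0))

  # step response referenced to its own baseline
  cur <- ifelse(t >= 50, -105, -5)
  bl <- baseline_subtract(sweep_trace(t, cur, 10), c(0, 40))
  expect_equal(bl$current_pA[t >= 50][1], -100)

  # post-subtraction pre-window mean is zero to numerical precision,
  # well inside the noise_sd / sqrt(n) CLT bound
  set.seed(11)
  t <- seq(0, 600, by = 0.1)
  tr <- sweep_trace(t, rnorm(length(t), -20, 5), 10)
  bl <- baseline_subtract(tr, c(0, 500))
  expect_lt(abs(mean(bl$current_pA[t <= 500])), 5 / sqrt(5000))
  expect_lt(abs(mean(bl$current_pA[t <= 500])), 1e-9)
  expect_error(baseline_subtract(tr, c(700, 800)), "outside|empty")
})

test_that("peak amplitude reports inward magnitude and short latency", {
  tr <- sim_evoked_trace(t0 = 10, q_total = 1.5, f_fast = 0.77,
                         noise_sd = 0, seed = 1)
  pk <- peak_amplitude(tr, 10)
  gt <- tr$ground_truth
  i_expect <- 1000 * (gt$a_fast / gt$tau_fast + gt$b_slow / gt$tau_slow)
  expect_equal(pk$amplitude_pA, i_expect, tolerance = 1e-6)
  expect_lt(pk$latency_ms, 2)

  flat <- sweep_trace(seq(0, 100, by = 0.1), numeric(1001), 10)
  pk <- peak_amplitude(flat, 10)
  expect_equal(pk$amplitude_pA, 0)
})

test_that("cumulative and windowed charges match closed forms", {
  t <- seq(0, 100, by = 0.1)
  tr <- sweep_trace(t, rep(-100, length(t)), 10)
  cc <- cumulative_charge(tr, 10, 50)
  expect_equal(cc$q_total, 5, tolerance = 1e-12)  # 100 pA x 0.05 s

  wq <- windowed_charge(tr, 10, list(c(0, 20), c(25, 50)))
  expect_equal(unname(wq), c(2, 2.5), tolerance = 1e-12)

  zero <- sweep_trace(t, numeric(length(t)), 10)
  expect_true(all(cumulative_charge(zero, 10)$q_pC == 0))

  # additivity over contiguous windows equals q50
  tr2 <- sim_evoked_trace(q_total = 1.5, noise_sd = 0, seed = 1)
  q50 <- cumulative_charge(tr2, 10, 50)$q_total
  parts <- windowed_charge(tr2, 10, list(c(0, 20), c(20, 35), c(35, 50)))
  expect_equal(sum(parts), q50, tolerance = 1e-9)

  # analytic oracle for the biexponential window split
  gt <- tr2$ground_truth
  Q <- function(s) biexp_q(s, gt$a_fast, gt$b_slow, gt$tau_fast, gt$tau_slow)
  wq <- windowed_charge(tr2, 10, list(c(0, 20), c(25, 50)))
  expect_equal(unname(wq[1]), Q(20), tolerance = 1e-4)
  expect_equal(unname(wq[2]), Q(50) - Q(25), tolerance = 1e-4)

  expect_error(windowed_charge(tr2, 10, list(c(0, 20), c(15, 30))),
               "overlap")
  expect_error(cumulative_charge(tr2, 80, 50), "outside")
})

test_that("noiseless decomposition recovers kinetics to <1% across a grid", {
  for (tf in c(2, 5, 10)) for (ts in c(30, 40, 80))
    for (f in c(0.3, 0.5, 0.77, 0.9)) {
      tr <- sim_evoked_trace(t0 = 5, q_total = 1.5, f_fast = f,
                             tau_fast = tf, tau_slow = ts,
                             noise_sd = 0, fs = 10, duration_ms = 60,
                             seed = 1)
      fit <- fit_charge_decomposition(tr, t0 = 5)
      expect_true(fit$converged)
      expect_equal(fit$tau_fast, tf, tolerance = 0.01)
      expect_equal(fit$tau_slow, ts, tolerance = 0.01)
      expect_equal(fit$a_fast, f * 1.5, tolerance = 0.01)
    }
})

test_that("a_fast + a_slow_eff equals q50 exactly, noisy fits included", {
  for (s in 1:5) {
    tr <- sim_evoked_trace(q_total = 1.5, noise_sd = 10, seed = s)
    bl <- baseline_subtract(tr, c(0, 9))
    fit <- fit_charge_decomposition(bl, t0 = 10)
    expect_identical(fit$a_fast + fit$a_slow_eff, fit$q50)
  }
})

test_that("the pure-fast limit yields f_fast at 1 and the right tau", {
  s <- seq(0, 50, by = 0.05)
  fit <- fit_charge_decomposition(1 - exp(-s / 5), time_ms = s)
  expect_equal(fit$tau_fast, 5, tolerance = 0.01)
  expect_gt(fit$f_fast, 0.999)
})

test_that("noisy replicates recover kinetics within 10% in the median", {
  fits <- lapply(1:60, function(s) {
    tr <- sim_evoked_trace(t0 = 5, q_total = 1.5, f_fast = 0.75,
                           tau_fast = 5, tau_slow = 40,
                           noise_sd = 1000 * 1.5 * 0.75 / 5 / 20,  # SNR 20
                           duration_ms = 60, seed = s)
    bl <- baseline_subtract(tr, c(0, 4.5))
    fit_charge_decomposition(bl, t0 = 5)
  })
  expect_lt(abs(median(vapply(fits, `[[`, 0, "tau_fast")) - 5) / 5, 0.1)
  expect_lt(abs(median(vapply(fits, `[[`, 0, "tau_slow")) - 40) / 40, 0.1)
  expect_lt(abs(median(vapply(fits, `[[`, 0, "f_fast")) - 0.75) / 0.75, 0.1)
})

test_that("decomposition methods behave like a fitted model object", {
  tr <- sim_evoked_trace(q_total = 1.5, noise_sd = 0, seed = 1)
  fit <- fit_charge_decomposition(tr)
  expect_named(coef(fit), c("q50", "a_fast", "a_slow_eff", "tau_fast",
                            "tau_slow", "f_fast"))
  expect_equal(length(residuals(fit)), length(fit$q_pC))
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_equal(predict(fit), fitted(fit))
  expect_output(print(fit), "tau_fast")
})

test_that("90-10% decay time matches the biexponential root-finding oracle", {
  tr <- sim_evoked_trace(t0 = 10, q_total = 1, f_fast = 0.7721,
                         tau_fast = 5.29, tau_slow = 40.3,
                         noise_sd = 0, duration_ms = 400, seed = 1)
  gt <- tr$ground_truth
  cur <- function(s) gt$a_fast / gt$tau_fast * exp(-s / gt$tau_fast) +
    gt$b_slow / gt$tau_slow * exp(-s / gt$tau_slow)
  pk <- cur(0)
  t90 <- uniroot(function(s) cur(s) - 0.9 * pk, c(0, 400))$root
  t10 <- uniroot(function(s) cur(s) - 0.1 * pk, c(0, 400))$root
  d <- decay_time_90_10(tr, 10)
  expect_false(d$censored)
  expect_equal(d$decay_ms, t10 - t90, tolerance = 0.01)

  # censoring when the trace never reaches 10% of peak
  short <- sim_evoked_trace(t0 = 10, q_total = 1, f_fast = 0.2,
                            tau_fast = 5, tau_slow = 80, noise_sd = 0,
                            duration_ms = 60, seed = 1)
  expect_true(decay_time_90_10(short, 10)$censored)
})

test_that("sucrose charges are baseline-compensated window integrals", {
  t <- seq(0, 8000, by = 0.5)
  cur <- ifelse(t > 1000, -25, -5)  # -20 pA response on -5 pA basal
  tr <- sweep_trace(t, cur, 2, markers = list(app_start_ms = 1000))
  sq <- sucrose_charges(tr, 1000)
  expect_equal(unname(sq$q_pC), c(20, 100), tolerance = 1e-3)
  expect_false(any(sq$censored))

  zero <- sweep_trace(t, rep(-5, length(t)), 2)
  sq0 <- sucrose_charges(zero, 1000)
  expect_equal(unname(sq0$q_pC), c(0, 0), tolerance = 1e-9)

  # exponential-decay response: closed-form integral oracle
  tau_s <- 2
  cur <- -ifelse(t > 1000, 40 * exp(-(t - 1000) / (tau_s * 1000)), 0)
  tr <- sweep_trace(t, cur, 2)
  sq <- sucrose_charges(tr, 1000)
  q_an <- function(w) 40 * tau_s * (1 - exp(-w / tau_s))  # pA s = pC
  expect_equal(unname(sq$q_pC), c(q_an(1), q_an(5)), tolerance = 1e-3)

  # a window extending past the record is censored, not an error
  sq <- sucrose_charges(tr, 5000, windows_s = c(1, 5))
  expect_true(sq$censored[2])
})

test_that("the release ratio is a plain ratio of genotype means", {
  expect_equal(release_ratio(25, 100), 0.25)
  expect_equal(release_ratio(10, 10), 1)
  expect_equal(release_ratio(12.5, 100), release_ratio(25, 100) / 2)
  expect_error(release_ratio(25, 0), "positive")
})
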