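# Build a clean fourier_fit for analytic-signal tests by fitting noiseless
# waveforms on the default merged grid.
fit_wave <- function(fun) {
  td <- default_times()
  grid <- build_frequency_grid(td)
  fit_fourier_robust(fun(td, grid$frequencies), td, grid)
}

test_that("analytic signal of a cosine is the complex exponential", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  f1 <- grid$frequencies[1]
  fit <- fit_wave(function(t, fr) cos(2 * pi * fr[1] * t))
  tt <- seq(min(td), max(td), by = 0.1)
  z <- analytic_signal(tt, fit)
  expect_equal(Re(z), cos(2 * pi * f1 * tt), tolerance = 1e-7)
  expect_equal(Im(z), sin(2 * pi * f1 * tt), tolerance = 1e-7)
  expect_equal(Mod(z), rep(1, length(tt)), tolerance = 1e-7)  # |z| constant
  ip <- instantaneous_phase_freq(tt, fit)
  expect_equal(hairwave:::circ_wrap(ip$phase - 2 * pi * f1 * tt),
               rep(0, length(tt)), tolerance = 1e-6)
})

test_that("a sine lags the cosine by a quarter cycle", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  f1 <- grid$frequencies[1]
  fit <- fit_wave(function(t, fr) sin(2 * pi * fr[1] * t))
  tt <- seq(min(td), max(td), by = 0.5)
  ip <- instantaneous_phase_freq(tt, fit)
  expect_equal(hairwave:::circ_wrap(ip$phase - (2 * pi * f1 * tt - pi / 2)),
               rep(0, length(tt)), tolerance = 1e-6)
})

test_that("instantaneous frequency is constant for one harmonic and matches
          a finite-difference oracle for two", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  f1 <- grid$frequencies[1]
  fit1 <- fit_wave(function(t, fr) cos(2 * pi * fr[1] * t))
  tt <- seq(min(td) + 1, max(td) - 1, by = 0.2)
  ip1 <- instantaneous_phase_freq(tt, fit1)
  expect_equal(ip1$omega, rep(2 * pi * f1, length(tt)), tolerance = 1e-6)
  # two harmonics: compare against dense finite differences of the unwrapped
  # phase (independent of the closed-form derivative path)
  fit2 <- fit_wave(function(t, fr)
    cos(2 * pi * fr[1] * t) + 0.4 * sin(2 * pi * fr[2] * t + 1))
  h <- 1e-5
  ipm <- instantaneous_phase_freq(tt - h, fit2)
  ipp <- instantaneous_phase_freq(tt + h, fit2)
  om_fd <- hairwave:::circ_wrap(ipp$phase - ipm$phase) / (2 * h)
  om <- instantaneous_phase_freq(tt, fit2)$omega
  expect_equal(om, om_fd, tolerance = 1e-5)
})

test_that("order parameters quantify coherence and two-cluster structure", {
  expect_equal(Mod(order_parameter(rep(1.3, 50))), 1)
  # two equal clusters exactly pi apart: Z1 cancels, Z2 saturates
  ph <- c(rep(0.4, 25), rep(0.4 + pi, 25))
  expect_equal(Mod(order_parameter(ph, 1)), 0, tolerance = 1e-12)
  expect_equal(Mod(order_parameter(ph, 2)), 1, tolerance = 1e-12)
  # asymmetric tight clusters: |Z1| = |2p - 1|
  for (p in c(0.3, 0.64, 0.9)) {
    n <- 200
    ph <- c(rep(0, round(p * n)), rep(pi, n - round(p * n)))
    expect_equal(Mod(order_parameter(ph)), abs(2 * round(p * n) / n - 1),
                 tolerance = 1e-12)
  }
})

test_that("the weighted cluster identity holds exactly at every time", {
  set.seed(6)
  phase <- matrix(runif(40 * 15, 0, 2 * pi), 40, 15)
  labels <- rep(1:2, c(15, 25))
  Z1 <- order_parameter(phase)
  zc1 <- order_parameter(phase[labels == 1, ])
  zc2 <- order_parameter(phase[labels == 2, ])
  expect_equal(Z1, (15 / 40) * zc1 + (25 / 40) * zc2, tolerance = 1e-12)
  # global rotation leaves the magnitudes unchanged
  for (m in 1:2) {
    expect_equal(Mod(order_parameter(phase + 1.234, m)),
                 Mod(order_parameter(phase, m)), tolerance = 1e-12)
  }
})

test_that("phase clustering recovers two von Mises groups a half-cycle apart", {
  period <- 31
  set.seed(17)
  acc <- replicate(5, {
    n1 <- 60; n2 <- 100
    kappa_sd <- 1 / sqrt(20)  # concentration ~ kappa = 20
    th <- c(rnorm(n1, 0, kappa_sd), rnorm(n2, pi, kappa_sd)) %% (2 * pi)
    shifts <- th * period / (2 * pi)
    cl <- cluster_by_phase(shifts, period)
    truth <- rep(1:2, c(n1, n2))
    max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  })
  expect_true(all(acc > 0.99))
  # recovered separation is about half the period
  th <- c(rnorm(80, 0.3, 0.1), rnorm(120, 0.3 + pi, 0.1)) %% (2 * pi)
  cl <- cluster_by_phase(th * period / (2 * pi), period)
  expect_equal(cl$separation_days, period / 2, tolerance = 0.06 * period)
  expect_equal(cl$separation_degrees, 180, tolerance = 12)
})

test_that("cluster 1 is the anagen-peaking (earlier) group", {
  period <- 31
  shifts <- c(rep(3, 10), rep(19, 14))  # maxima near t_ref+3 and t_ref+19
  cl <- cluster_by_phase(shifts, period, t_ref = 23)
  expect_equal(sum(cl$labels == 1), 10)
  expect_lt(cl$mean_peak_day[1], cl$mean_peak_day[2])
})

test_that("a unimodal phase distribution is flagged ambiguous", {
  set.seed(2)
  shifts <- (rnorm(50, 5, 0.4)) %% 31
  expect_warning(cl <- cluster_by_phase(shifts, 31), "ambiguous")
  expect_true(cl$ambiguous)
  expect_error(cluster_by_phase(1:3, 31), class = "hairwave_validation_error")
})

test_that("randomized phases destroy synchronization", {
  set.seed(99)
  # a perfectly synchronized large ensemble
  phase <- matrix(rep(seq(0, 2, length.out = 25), each = 4000), 4000, 25)
  r1 <- randomize_phases(phase, seed = 3)
  expect_lt(max(Mod(order_parameter(r1, 1))), 0.05)
  expect_lt(max(Mod(order_parameter(r1, 2))), 0.05)
  expect_identical(randomize_phases(phase, seed = 3), r1)
  expect_false(identical(randomize_phases(phase, seed = 4), r1))
})

test_that("oscillator ensembles expose phases on a dense grid", {
  fx <- integration_fixture()
  ens <- oscillator_ensemble(fx$scan)
  expect_s3_class(ens, "oscillator_ensemble")
  expect_identical(nrow(ens$phase), sum(fx$scan$table$is_lfo))
  expect_equal(diff(ens$t)[1], 0.25)
  expect_true(all(is.finite(ens$phase)))
  # FSD source is also available
  ens2 <- oscillator_ensemble(fx$scan, which_probes = ens$probe_ids[1:5],
                              component = "fsd")
  expect_identical(nrow(ens2$phase), 5L)
})
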