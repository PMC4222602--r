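test_that("frequency grid covers the hair-cycle period and avoids extremes", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  # longest admissible period lands near one full cycle
  expect_equal(max(grid$periods), 31.5, tolerance = 1e-9)
  # no frequency at or above a third of the minimum sampling rate
  min_dt <- min(diff(sort(unique(td))))
  expect_true(all(grid$frequencies < 1 / (3 * min_dt)))
  # design stays overdetermined
  expect_lt(2 * grid$L + 1, length(td))
  expect_true(all(diff(grid$frequencies) > 0))
})

test_that("grids with too few admissible frequencies are rejected", {
  expect_error(build_frequency_grid(c(0, 5, 10), ),
               class = "hairwave_grid_error")  # < 6 distinct times
  # span 10 d with 2-d spacing and a strict short-period cutoff
  expect_error(build_frequency_grid(seq(0, 10, by = 2),
                                    fundamental_factor = 1,
                                    max_freq_factor = 3),
               class = "hairwave_grid_error")
})

test_that("noiseless harmonic signals are recovered exactly", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  f1 <- grid$frequencies[1]
  y <- 5 + 2 * cos(2 * pi * f1 * td)
  fit <- fit_fourier_robust(y, td, grid)
  expect_equal(fit$a0, 5, tolerance = 1e-8)
  expect_equal(fit$a[1], 2, tolerance = 1e-8)
  expect_equal(fit$b[1], 0, tolerance = 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  expect_true(fit$converged)
})

test_that("a single gross outlier barely moves the robust coefficients", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  f1 <- grid$frequencies[1]
  clean <- 5 + 2 * cos(2 * pi * f1 * td) + 0.5 * sin(2 * pi * f1 * td)
  dirty <- clean
  dirty[7] <- dirty[7] + 10
  # independent oracle: ordinary least squares on the clean signal
  X <- cbind(1, cos(outer(td, 2 * pi * grid$frequencies)),
             sin(outer(td, 2 * pi * grid$frequencies)))
  beta_clean <- qr.coef(qr(X), clean)
  fit <- fit_fourier_robust(dirty, td, grid)
  expect_lt(max(abs(c(fit$a0, fit$a, fit$b) - beta_clean)), 0.05)
  expect_lt(fit$weights[7], 0.1)
})

test_that("robust fit agrees with MASS::rlm on contaminated data", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  set.seed(42)
  y <- 3 + 1.5 * cos(2 * pi * grid$frequencies[1] * td) + rnorm(length(td), 0, 0.2)
  y[4] <- y[4] + 6
  X <- cbind(1, cos(outer(td, 2 * pi * grid$frequencies)),
             sin(outer(td, 2 * pi * grid$frequencies)))
  ref <- MASS::rlm(X, y, psi = MASS::psi.bisquare, c = 4.685,
                   scale.est = "MAD", maxit = 200, acc = 1e-8)
  fit <- fit_fourier_robust(y, td, grid)
  expect_equal(unname(c(fit$a0, fit$a, fit$b)), unname(coef(ref)),
               tolerance = 5e-3)
})

test_that("constant signals yield an intercept-only fit", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  fit <- fit_fourier_robust(rep(4.2, length(td)), td, grid)
  expect_equal(fit$a0, 4.2, tolerance = 1e-10)
  expect_lt(max(abs(c(fit$a, fit$b))), 1e-10)
})

test_that("robust fit equals OLS exactly when every weight is one", {
  # Tukey weights equal 1 only at zero residual, so the exact-equality
  # regime is a perfectly representable signal
  td <- default_times()
  grid <- build_frequency_grid(td)
  y <- 2 + cos(2 * pi * grid$frequencies[1] * td) -
    0.7 * sin(2 * pi * grid$frequencies[2] * td)
  fit <- fit_fourier_robust(y, td, grid)
  expect_true(all(fit$weights == 1))
  X <- cbind(1, cos(outer(td, 2 * pi * grid$frequencies)),
             sin(outer(td, 2 * pi * grid$frequencies)))
  ols <- qr.coef(qr(X), y)
  expect_equal(unname(c(fit$a0, fit$a, fit$b)), unname(ols),
               tolerance = 1e-10)
})

test_that("power spectrum follows the stated formula", {
  fit <- structure(list(a = c(3, 0), b = c(4, 0), n = 20,
                        grid = list(frequencies = c(0.1, 0.2), L = 2)),
                   class = "fourier_fit")
  expect_equal(power_spectrum(fit), c(125, 0))
  fit0 <- fit; fit0$a <- c(0, 0); fit0$b <- c(0, 0)
  expect_equal(power_spectrum(fit0), c(0, 0))
  # equal coefficient power gives equal spectral power
  fit2 <- fit; fit2$a <- c(3, 5); fit2$b <- c(4, 0)
  S <- power_spectrum(fit2)
  expect_equal(S[1], S[2])
})

test_that("Fisher's g matches hand values and is scale invariant", {
  expect_equal(g_statistic(c(25, 0, 0)), 1.0)
  expect_equal(g_statistic(c(1, 1, 1, 1)), 0.25)
  expect_equal(g_statistic(c(3, 1)), 0.75)
  expect_error(g_statistic(c(0, 0)), class = "hairwave_statistic_error")
  set.seed(3)
  for (i in 1:25) {
    S <- rexp(5)
    expect_equal(g_statistic(S), g_statistic(S * runif(1, 0.01, 100)))
  }
})

test_that("principal component extracts frequency, amplitude and phase", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  mk <- function(a, b) {
    structure(list(a = a, b = b, n = length(td), grid = grid),
              class = "fourier_fit")
  }
  pc <- principal_component(mk(c(1, 0, 0, 0, 0), numeric(5)))
  expect_equal(pc$phase, 0)
  expect_equal(pc$frequency, grid$frequencies[1])
  pc2 <- principal_component(mk(numeric(5), c(1, 0, 0, 0, 0)))
  expect_equal(pc2$phase, pi / 2)
  # maximum of cos(2 pi f t - pi/2) falls at a quarter period
  expect_equal(phase_shift_days(pc2, 0), (1 / pc2$frequency) / 4)
  # dominant component wins among several harmonics
  pc3 <- principal_component(mk(c(0.2, 0.1, 2), c(0.1, 0, 1)))
  expect_equal(pc3$frequency, grid$frequencies[3])
  expect_equal(pc3$amplitude, sqrt(5))
  # spectral ties resolve to the lowest frequency
  pc4 <- principal_component(mk(c(1, 1, 0), c(0, 0, 0)))
  expect_equal(pc4$frequency, grid$frequencies[1])
})

test_that("phase shift is the time to the next maximum", {
  # maximum at day 33 seen from day 24 with a 31-day period
  ppc <- list(frequency = 1 / 31, phase = 2 * pi * 33 / 31)
  expect_equal(phase_shift_days(ppc, 24), 9)
  # maximum exactly at the reference day
  ppc0 <- list(frequency = 1 / 31, phase = 2 * pi * 24 / 31)
  expect_equal(phase_shift_days(ppc0, 24), 0)
  # two probes peaking at days 33 and 48: shifts differ by half the period
  pA <- list(frequency = 1 / 31, phase = 2 * pi * 33 / 31)
  pB <- list(frequency = 1 / 31, phase = 2 * pi * 48 / 31)
  d <- phase_shift_days(pB, 24) - phase_shift_days(pA, 24)
  expect_equal(d, 15)
  expect_equal(d, 31 / 2, tolerance = 0.04)
  # always within [0, period)
  set.seed(8)
  for (i in 1:30) {
    pp <- list(frequency = 1 / runif(1, 5, 40), phase = runif(1, -10, 10))
    s <- phase_shift_days(pp, runif(1, 0, 60))
    expect_true(s >= 0 && s < 1 / pp$frequency)
  }
})

test_that("undersized or rank-deficient designs are rejected", {
  td <- default_times()
  grid <- build_frequency_grid(td)
  expect_error(fit_fourier_robust(rnorm(grid$L * 2), td[seq_len(grid$L * 2)],
                                  grid),
               class = "hairwave_fit_error")
})
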