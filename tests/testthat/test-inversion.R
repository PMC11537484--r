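test_that("current-to-cGMP inverts the channel relation exactly", {
  mc <- model_for("mouse_cone", 80)
  G <- current_to_cgmp(new_trace(rep(80, 10), 1e-4, "pA"), mc$params)
  expect_equal(G$values, rep(20, 10), tolerance = 1e-12)
  # round trip and power-law arithmetic
  set.seed(5)
  I <- new_trace(runif(100, 20, 80), 1e-4, "pA")
  G2 <- current_to_cgmp(I, mc$params)
  expect_equal(mc$params$k * G2$values^mc$params$n, I$values, tolerance = 1e-12)
  half <- current_to_cgmp(new_trace(I$values / 2, 1e-4, "pA"), mc$params)
  expect_equal(half$values, G2$values * 2^(-1 / 3), tolerance = 1e-12)
  expect_error(current_to_cgmp(new_trace(c(1, 0), 1e-4, "pA"), mc$params),
               "positive")
})

test_that("calcium recovery matches its steady state and both solvers agree", {
  m <- model_for("primate_cone")
  # dark current in -> dark calcium out
  Cd <- current_to_calcium(new_trace(rep(m$dark$i_dark, 100), 1e-4, "pA"),
                           m$dark, m$params)
  expect_equal(Cd$values, rep(m$params$c_dark, 100), tolerance = 1e-6)
  # constant current -> q I / beta
  Cc <- current_to_calcium(new_trace(rep(100, 100), 1e-4, "pA"),
                           m$dark, m$params)
  expect_equal(Cc$values, rep(m$dark$q * 100 / m$params$beta, 100),
               tolerance = 1e-6)
  # time-domain vs frequency-domain on a periodic band-limited noise trace:
  # random sinusoids on FFT bin frequencies, oversampled so both solvers
  # resolve them; compare the tail, after the time-domain initial
  # condition has washed out at rate beta
  set.seed(8)
  n <- 65536; dt <- 5e-5
  t <- (seq_len(n) - 1) * dt
  I_vals <- rep(200, n)
  for (k in sample(2:12, 6)) {
    f_k <- k / (n * dt)
    I_vals <- I_vals + runif(1, 2, 8) * sin(2 * pi * f_k * t + runif(1, 0, 2 * pi))
  }
  I <- new_trace(I_vals, dt, "pA")
  c_ode <- current_to_calcium(I, m$dark, m$params, method = "ode")
  c_fft <- current_to_calcium(I, m$dark, m$params, method = "fft")
  tail_idx <- seq.int(n / 2, n)
  err <- c_ode$values[tail_idx] - c_fft$values[tail_idx]
  expect_lt(sqrt(mean(err^2)) / sd(c_ode$values[tail_idx]), 1e-6)
})

test_that("PDE recovery returns the dark activity and round-trips the simulation", {
  m <- model_for("primate_rod")
  n <- 500
  P <- pde_from_cgmp(new_trace(rep(m$dark$g_dark, n), 1e-3, "uM"),
                     new_trace(rep(m$params$c_dark, n), 1e-3, "uM"),
                     m$params, m$dark)
  expect_equal(P$values, rep(2.53 / 7.07, n), tolerance = 1e-9)
  s <- short_sim("mouse_rod")
  P2 <- pde_from_cgmp(s$st$G, s$st$C, s$params, s$dark, scheme = "matched")
  interior <- seq_len(length(P2$values) - 1L)
  err <- P2$values[interior] - s$st$P$values[interior]
  expect_lt(sqrt(mean(err^2)) / sd(s$st$P$values), 1e-9)
})

test_that("stimulus recovery from PDE is exact in the dark and shifts with +c", {
  m <- model_for("mouse_rod")
  n <- 1000
  dark_p <- new_trace(rep(m$dark$p_dark, n), 1e-3, "s^-1")
  s0 <- stimulus_from_pde(dark_p, m$params)
  expect_lt(max(abs(s0$values)), 1e-9)
  # adding a constant c to P raises the steady-state stimulus by phi*sigma*c/gamma
  cc <- 0.5
  s1 <- stimulus_from_pde(new_trace(dark_p$values + cc, 1e-3, "s^-1"), m$params)
  expect_equal(s1$values[500],
               m$params$phi * m$params$sigma * cc / m$params$gamma,
               tolerance = 1e-9)
})

test_that("inversion of noise-free simulated currents is exact for all four types", {
  for (ct in .cell_types) {
    s <- short_sim(ct)
    est <- invert_current(s$st$I, s$params, s$dark)
    expect_gt(fraction_variance(s$stim, est), 0.999)
    # interior samples (inside the differentiation support) match to rounding
    n <- length(est$values)
    interior <- seq_len(n - 3L)
    err <- est$values[interior] - s$stim$values[interior]
    expect_lt(sqrt(mean(err^2)) / sd(s$stim$values), 1e-6)
  }
})

test_that("a constant dark current inverts to zero stimulus", {
  m <- model_for("primate_cone")
  est <- invert_current(new_trace(rep(m$dark$i_dark, 2000), 1e-4, "pA"),
                        m$params, m$dark)
  expect_lt(max(abs(est$values)), 1e-6)
})

test_that("response noise degrades the regularized estimate monotonically", {
  # band limit plus power-spectrum matching, the procedure used for
  # estimates from measured (noisy) responses
  s <- short_sim("mouse_rod")
  settings <- inversion_settings(cell_type = "mouse_rod",
                                 match_power_spectrum = TRUE,
                                 reference_spectrum = s$stim)
  fv <- vapply(c(0, 0.05, 0.5, 2), function(nsd) {
    set.seed(31)
    noisy <- new_trace(s$st$I$values + rnorm(length(s$st$I$values), 0, nsd),
                       s$st$I$dt, "pA")
    fraction_variance(s$stim, invert_current(noisy, s$params, s$dark,
                                             settings = settings))
  }, numeric(1))
  clean_fv <- fraction_variance(s$stim, invert_current(s$st$I, s$params, s$dark))
  expect_true(all(diff(fv) < 0))
  expect_lt(fv[2], clean_fv)
  expect_gt(fv[2], 0.5)   # modest noise still recovers most in-band structure
})

test_that("power-spectrum matching reproduces the reference spectrum bin-wise", {
  s <- short_sim("mouse_cone")
  set.seed(17)
  noisy <- new_trace(s$st$I$values + rnorm(length(s$st$I$values), 0, 1),
                     s$st$I$dt, "pA")
  settings <- inversion_settings(cell_type = "mouse_cone",
                                 match_power_spectrum = TRUE,
                                 reference_spectrum = s$stim)
  est <- invert_current(noisy, s$params, s$dark, settings = settings)
  f <- photoclamp:::.fft_freqs(length(est$values), est$dt)
  in_band <- abs(f) <= 30
  expect_equal(Mod(fft(est$values))[in_band], Mod(fft(s$stim$values))[in_band],
               tolerance = 1e-8)
})

test_that("stimulus and residual spectra converge where the estimate degrades", {
  s <- short_sim("mouse_rod")
  set.seed(23)
  noisy <- new_trace(s$st$I$values + rnorm(length(s$st$I$values), 0, 0.5),
                     s$st$I$dt, "pA")
  est <- invert_current(noisy, s$params, s$dark,
                        settings = inversion_settings(cell_type = "mouse_rod"))
  rs <- residual_spectra(s$stim, est)
  low <- rs$freq <= 3
  expect_lt(mean(rs$residual_power[low]) / mean(rs$stimulus_power[low]), 0.5)
  expect_false(is.na(rs$convergence_frequency))
  # a cleaner response converges at a higher frequency
  noisy2 <- new_trace(s$st$I$values + rnorm(length(s$st$I$values), 0, 0.05),
                      s$st$I$dt, "pA")
  est2 <- invert_current(noisy2, s$params, s$dark,
                         settings = inversion_settings(cell_type = "mouse_rod"))
  rs2 <- residual_spectra(s$stim, est2)
  expect_gte(rs2$convergence_frequency, rs$convergence_frequency)
})

test_that("the central-difference scheme remains accurate on smooth currents", {
  m <- model_for("primate_cone")
  stim <- make_sinusoid_stimulus(22000, 0.8, freq = 2, duration = 2, dt = 1e-4)
  init <- steady_state(m$params, m$dark, stim$values[1])
  st <- simulate_cascade(m$params, m$dark, stim,
                         initial = init[c("R", "P", "G", "C")])
  est <- invert_current(st$I, m$params, m$dark,
                        settings = inversion_settings(derivative_scheme = "central"))
  keep <- seq.int(100, length(est$values) - 100)
  expect_gt(fraction_variance(stim$values[keep], est$values[keep]), 0.999)
})

test_that("spectral differentiation is exact for band-limited periodic signals", {
  n <- 1024; dt <- 1e-3
  t <- (seq_len(n) - 1) * dt
  f0 <- 8 / (n * dt)  # a bin frequency, so the signal is exactly periodic
  x <- sin(2 * pi * f0 * t)
  d <- photoclamp:::.deriv(x, dt, "spectral")
  expect_equal(d, 2 * pi * f0 * cos(2 * pi * f0 * t), tolerance = 1e-9)
})
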