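test_that("fraction of variance explained matches hand arithmetic", {
  expect_equal(fraction_variance(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  m <- c(2, 4, 6, 8)
  expect_equal(fraction_variance(m, rep(mean(m), 4)), 0)
  expect_equal(fraction_variance(c(0, 1, 2, 3), c(0, 1, 2, 2)), 0.8)
  expect_error(fraction_variance(rep(1, 4), c(0, 1, 2, 3)), "zero variance")
})

# Small shared fixture for the fitting tests: one mouse rod recording.
fit_fixture <- function(noise_sd = 0, seed = 5, dark_current = 20) {
  truth <- consensus_params("mouse_rod")
  dk <- dark_operating_point(truth, dark_current)
  stim <- make_variable_mean_noise(mean_levels = c(2, 15, 30), segment_dur = 2,
                                   contrast = 0.5, dt = 1e-3, seed = seed)
  rec <- make_synthetic_recording(stim, truth, dk, noise_sd = noise_sd,
                                  seed = seed)
  list(truth = truth,
       pairs = list(list(stimulus = rec$stimulus, response = rec$response)),
       dark_current = dark_current)
}

test_that("noise-free synthetic data are fit essentially perfectly", {
  fx <- fit_fixture()
  init <- photoclamp:::.update_params(fx$truth, c(12, 5.5, 2.4, 0.5),
                                      c("gamma", "sigma", "eta", "k_gc"), TRUE)
  fit <- fit_cell(fx$pairs, fx$dark_current, init = init, restarts = 1)
  expect_gt(fit$fraction_variance, 0.999)
  for (nm in c("gamma", "sigma", "eta", "k_gc"))
    expect_equal(fit$params[[nm]], fx$truth[[nm]], tolerance = 0.02)
  expect_identical(fit$params$phi, fit$params$sigma)
})

test_that("starting at the truth does not increase the objective", {
  fx <- fit_fixture(noise_sd = 0.1)
  mse_truth <- photoclamp:::.cell_mse(fx$truth, fx$dark_current, fx$pairs)
  fit <- fit_cell(fx$pairs, fx$dark_current, init = fx$truth, restarts = 0)
  expect_lte(fit$mse, mse_truth * (1 + 1e-9))
  expect_true(all(diff(fit$iterations$objective) <= 1e-12))
})

test_that("parameters are recovered within 10% at realistic noise", {
  fx0 <- fit_fixture()
  # noise at ~5% of response SD, comparable to good rod recordings
  clean_sd <- sd(make_synthetic_recording(fx0$pairs[[1]]$stimulus, fx0$truth,
                                          dark_operating_point(fx0$truth, 20),
                                          0, 5)$clean$values)
  fx <- fit_fixture(noise_sd = 0.05 * clean_sd)
  init <- photoclamp:::.update_params(fx$truth, c(5, 10, 1.2, 0.5),
                                      c("gamma", "sigma", "eta", "k_gc"), TRUE)
  fit <- fit_cell(fx$pairs, fx$dark_current, init = init, restarts = 1)
  for (nm in c("gamma", "sigma", "eta", "k_gc"))
    expect_equal(fit$params[[nm]], fx$truth[[nm]],
                 tolerance = 0.1 * fx$truth[[nm]])
  expect_gt(fit$fraction_variance, 0.9)
})

test_that("model output depends only on the slower of the two decay rates", {
  # raising the PDE decay rate well above the opsin decay rate leaves the
  # output nearly unchanged: the derived cyclase rate scales with 1/phi, so
  # every fixed point is invariant and only the (fast) PDE stage speeds up.
  # This is why the two rates are tied during fitting.
  fx <- fit_fixture(noise_sd = 0.1)
  p <- unclass(fx$truth)
  p$phi <- 12          # 57% above sigma = 7.66
  faster_pde <- do.call(cascade_params, p)
  resp_sd <- sd(fx$pairs[[1]]$response$values)
  mse_truth <- photoclamp:::.cell_mse(fx$truth, fx$dark_current, fx$pairs)
  mse_fast <- photoclamp:::.cell_mse(faster_pde, fx$dark_current, fx$pairs)
  # fit quality (fraction of variance terms) changes by < 1%
  expect_lt((mse_fast - mse_truth) / resp_sd^2, 0.01)
  # whereas raising sigma by the same amount changes the light-collecting
  # gain and degrades the fit badly
  p <- unclass(fx$truth)
  p$sigma <- 12
  faster_opsin <- do.call(cascade_params, p)
  expect_gt(photoclamp:::.cell_mse(faster_opsin, fx$dark_current, fx$pairs),
            10 * mse_truth)
})

test_that("a single-cell consensus fit reduces to the per-cell fit", {
  fx <- fit_fixture(noise_sd = 0.05)
  init <- photoclamp:::.update_params(fx$truth, c(10, 6, 2, 0.45),
                                      c("gamma", "sigma", "eta", "k_gc"), TRUE)
  single <- fit_cell(fx$pairs, fx$dark_current, init = init, restarts = 1)
  cons <- fit_consensus(list(list(pairs = fx$pairs,
                                  dark_current = fx$dark_current)),
                        init = init, restarts = 1)
  for (nm in c("sigma", "eta", "k_gc"))
    expect_equal(cons$params[[nm]], single$params[[nm]], tolerance = 0.02)
  expect_equal(cons$per_cell_gamma[1], single$params$gamma, tolerance = 0.02)
})

test_that("MSE-doubling ranges bracket the optimum with endpoints at 2x", {
  fx <- fit_fixture(noise_sd = 0.1)
  for (nm in c("sigma", "k_gc")) {
    sr <- sensitivity_range(fx$truth, fx$pairs, fx$dark_current, nm)
    expect_false(any(attr(sr, "open")))
    expect_lt(sr[["lower"]], fx$truth[[nm]])
    expect_gt(sr[["upper"]], fx$truth[[nm]])
    expect_equal(unname(attr(sr, "mse_at_bounds")),
                 rep(2 * attr(sr, "mse_opt"), 2),
                 tolerance = 0.01 * attr(sr, "mse_opt"))
  }
  # at the optimum the ratio is 1 by definition
  mse0 <- photoclamp:::.cell_mse(fx$truth, fx$dark_current, fx$pairs)
  expect_equal(mse0 / attr(sensitivity_range(fx$truth, fx$pairs,
                                             fx$dark_current, "sigma"),
                           "mse_opt"), 1)
})

test_that("unreachable doubling is flagged as an open bound", {
  # a parameter the model barely depends on: c_dark (K_GC compensates);
  # within a narrow search span the MSE cannot double
  fx <- fit_fixture(noise_sd = 0.1)
  sr <- sensitivity_range(fx$truth, fx$pairs, fx$dark_current, "c_dark",
                          search_span = c(0.99, 1.01))
  expect_true(all(attr(sr, "open")))
  expect_true(all(is.na(sr)))
})

test_that("the finite-difference Hessian recovers quadratic costs", {
  a <- c(1.5, 4, 9)
  h <- sloppy_hessian(function(th) sum(a * th^2), theta = rep(0, 3))
  expect_equal(diag(h$H), 2 * a, tolerance = 0.01)
  expect_equal(h$eigenvalues, sort(2 * a, decreasing = TRUE), tolerance = 0.01)
  # random positive-definite quadratic form
  set.seed(42)
  A <- crossprod(matrix(rnorm(16), 4))
  h2 <- sloppy_hessian(function(th) 0.5 * drop(t(th) %*% A %*% th),
                       theta = rep(0, 4), rel_step = 0.05)
  expect_equal(h2$H, A, tolerance = 0.01 * max(abs(A)))
  expect_lt(max(abs(h2$H - t(h2$H))), 1e-8 * max(abs(h2$H)))
  # gradient outer-product variant on a linear cost
  g <- c(2, -3)
  h3 <- sloppy_hessian(function(th) sum(g * th), theta = c(1, 1),
                       method = "grad_outer")
  expect_equal(h3$H, outer(g, g), tolerance = 1e-6)
})

test_that("the cascade cost function is minimal at the generating parameters", {
  fx <- fit_fixture(noise_sd = 0.1)
  free <- c("gamma", "sigma", "eta", "k_gc")
  cost <- cascade_cost_function(fx$pairs, fx$dark_current, fx$truth, free)
  th0 <- unlist(unclass(fx$truth)[free])
  h <- sloppy_hessian(cost, th0, rel_step = 0.02)
  expect_true(all(h$eigenvalues > 0))  # a local minimum: positive curvature
})
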