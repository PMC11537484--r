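test_that("a constant stimulus is its own clamp (nothing to linearize)", {
  m <- model_for("primate_cone")
  lf <- lfp_for("primate_cone", 22000, duration = 10)
  stim <- new_trace(rep(lf$mean_level, 5000), 1e-4, "R*/s")
  cr <- design_clamp(stim, m$params, m$dark, lf)
  expect_equal(cr$clipped_fraction, 0)
  expect_true(cr$feasible)
  keep <- seq_len(length(stim$values) - 3L)
  expect_lt(max(abs(cr$modified_stimulus$values[keep] - stim$values[keep])) /
              lf$mean_level, 0.02)
})

test_that("low-contrast stimuli are nearly unchanged by the clamp", {
  # rods: the fitted filter is an accurate small-signal model, so the
  # linear target is what the full model already does, and inversion
  # returns (nearly) the input stimulus
  m <- model_for("mouse_rod")
  lf <- lfp_for("mouse_rod", 25, duration = 30)
  stim <- make_sinusoid_stimulus(25, contrast = 0.05, freq = 0.5,
                                 duration = 6, dt = 1e-3)
  cr <- design_clamp(stim, m$params, m$dark, lf)
  keep <- seq.int(2000, length(stim$values) - 3L)
  err <- cr$modified_stimulus$values[keep] - stim$values[keep]
  expect_lt(sqrt(mean(err^2)) / sd(stim$values[keep]), 0.05)
})

test_that("feasible designs achieve their target to inversion tolerance", {
  m <- model_for("primate_cone")
  lf <- lfp_for("primate_cone", 22000, duration = 10)
  stim <- make_sinusoid_stimulus(22000, contrast = 1, freq = 2,
                                 duration = 2, dt = 1e-4)
  cr <- design_clamp(stim, m$params, m$dark, lf)
  expect_equal(cr$clipped_fraction, 0)
  expect_lt(var(cr$achieved_response$values - cr$target_response$values) /
              var(cr$target_response$values), 1e-3)
})

test_that("sinusoid clamps suppress increment/decrement asymmetry", {
  for (ct in c("primate_cone", "mouse_rod")) {
    m <- model_for(ct)
    is_cone <- grepl("cone", ct)
    mean_lvl <- if (is_cone) 22000 else 25
    freq <- if (is_cone) 2 else 0.5
    lf <- lfp_for(ct, mean_lvl, duration = if (is_cone) 10 else 30)
    stim <- make_sinusoid_stimulus(mean_lvl, contrast = 0.8, freq = freq,
                                   duration = 2 / freq + 2 / freq,
                                   dt = default_dt(ct))
    cr <- design_clamp(stim, m$params, m$dark, lf)
    init <- steady_state(m$params, m$dark, stim$values[1])
    orig <- simulate_cascade(m$params, m$dark, stim,
                             initial = init[c("R", "P", "G", "C")])
    asym <- function(resp) {
      # increment vs decrement amplitude around the cycle-mean current
      dev <- resp$values - mean(resp$values)
      abs(abs(min(dev)) - abs(max(dev))) / max(abs(dev))
    }
    skip_period <- round(1 / freq / stim$dt)
    trim <- function(tr) new_trace(tr$values[-seq_len(skip_period)], tr$dt, tr$units)
    expect_lt(asym(trim(cr$achieved_response)), 0.2 * asym(trim(orig$I)))
  }
})

test_that("step+flash with no step returns the original stimulus", {
  m <- model_for("primate_cone")
  lf <- lfp_for("primate_cone", 5000, duration = 10)
  sf <- design_step_flash_clamp(pre_level = 5000, step_level = 5000,
                                flash_strength = 50, params = m$params,
                                dark = m$dark, lfp = lf)
  # away from the flashes the modified stimulus sits at the pre level
  ft <- attr(sf, "flash_times")
  t <- trace_time(sf$modified_stimulus)
  quiet <- t < ft[1] - 0.05
  expect_lt(max(abs(sf$modified_stimulus$values[quiet] - 5000)) / 5000, 0.02)
})

test_that("the forward model adapts to a step but the modified stimulus negates it", {
  m <- model_for("mouse_cone")
  lf <- lfp_for("mouse_cone", 5000, duration = 10)
  sf <- design_step_flash_clamp(pre_level = 5000, step_level = 10000,
                                flash_strength = 50, params = m$params,
                                dark = m$dark, lfp = lf)
  ft <- attr(sf, "flash_times")
  orig <- simulate_cascade(m$params, m$dark, sf$original_stimulus,
                           initial = steady_state(m$params, m$dark, 5000))
  g_orig <- gain_ratio(orig$I, ft[1], ft[2])
  g_mod <- gain_ratio(sf$achieved_response, ft[1], ft[2])
  expect_lt(g_orig, 0.75)              # clear adaptation
  expect_equal(as.numeric(g_mod), 1, tolerance = 0.02)
})

test_that("kinetics clamp leaves scale=1 unchanged and reports speeding limits", {
  m <- model_for("primate_rod")
  lf <- lfp_for("primate_rod", 25, duration = 30)
  fl <- make_step_flash_stimulus(25, 25, 1, flash_times = 1, step_onset = 0,
                                 step_dur = 0, total_dur = 5, dt = 1e-3)
  k1 <- design_kinetics_clamp(fl, 1, m$params, m$dark, lf)
  expect_equal(attr(k1, "predicted_ttp_change"), 0)
  orig <- simulate_cascade(m$params, m$dark, fl,
                           initial = steady_state(m$params, m$dark, 25))
  ttp_orig <- time_to_peak(orig$I, onset = 1)
  ttp_k1 <- time_to_peak(k1$achieved_response, onset = 1)
  expect_lt(rel_err(ttp_k1, ttp_orig), 0.15)
  # moderate speeding stays feasible, with its clipping reported
  k08 <- design_kinetics_clamp(fl, 0.8, m$params, m$dark, lf)
  expect_true(k08$feasible)
  expect_gt(attr(k08, "clip_energy_fraction"), 0)
  expect_gte(min(k08$modified_stimulus$values), 0)
})

test_that("slowing clamps hit the predicted time-to-peak change", {
  m <- model_for("mouse_rod")
  lf <- lfp_for("mouse_rod", 25, duration = 30)
  fl <- make_step_flash_stimulus(25, 25, 1, flash_times = 1, step_onset = 0,
                                 step_dur = 0, total_dur = 5, dt = 1e-3)
  orig <- simulate_cascade(m$params, m$dark, fl,
                           initial = steady_state(m$params, m$dark, 25))
  ttp_orig <- time_to_peak(orig$I, onset = 1)
  kc <- design_kinetics_clamp(fl, 2, m$params, m$dark, lf)
  achieved <- time_to_peak(kc$achieved_response, onset = 1) - ttp_orig
  expect_lt(rel_err(achieved, attr(kc, "predicted_ttp_change")), 0.1)
})

test_that("targets that cross zero current are rejected as infeasible", {
  m <- model_for("mouse_cone")
  lf <- lfp_for("mouse_cone", 5000, duration = 10)
  expect_error(design_step_flash_clamp(pre_level = 5000, step_level = 60000,
                                       flash_strength = 50, params = m$params,
                                       dark = m$dark, lfp = lf),
               "infeasible")
})
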