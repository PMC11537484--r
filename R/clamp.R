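#' Light-adaptation clamp: force the cascade to a chosen response
#'
#' The clamp turns the exact inversion into a stimulus-design tool: pass
#' the original stimulus through the small-signal linear model to obtain a
#' "target" response free of adaptive nonlinearities, then invert the full
#' cascade on that target to find the stimulus that elicits it. A forward
#' simulation of the modified stimulus verifies the design. Negative
#' samples of the modified stimulus (targets no light can produce) are
#' clipped to zero and reported.
#'
#' @param original_stimulus Stimulus trace, R*/s (or numeric with \code{dt}).
#' @param params \code{"cascade_params"}.
#' @param dark \code{"dark_point"}.
#' @param lfp \code{"linear_filter"} fit at (or near) the stimulus mean;
#'   see [fit_linear_model()].
#' @param settings Optional \code{"inversion_settings"}.
#' @param dt Sample interval for bare numeric input.
#' @return Object of class \code{"clamp_result"}: \code{original_stimulus},
#'   \code{target_response}, \code{modified_stimulus} (clipped at zero),
#'   \code{achieved_response} (forward simulation of the clipped stimulus),
#'   \code{clipped_fraction}, and \code{feasible} (\code{FALSE} when the
#'   target current touches zero, which no light can produce).
#' @export
design_clamp <- function(original_stimulus, params, dark, lfp,
                         settings = NULL, dt = NULL) {
  stopifnot(inherits(params, "cascade_params"), inherits(dark, "dark_point"),
            inherits(lfp, "linear_filter"))
  stim <- as_trace(original_stimulus, dt = dt, units = "R*/s")
  baseline <- steady_state(params, dark, lfp$mean_level)[["I"]]
  target <- linear_response(lfp, stim, baseline)
  .finish_clamp(stim, target, params, dark, settings)
}

.finish_clamp <- function(stim, target, params, dark, settings,
                          declare_infeasible_on_negative_target = TRUE) {
  if (any(target$values <= 0)) {
    bad <- which(target$values <= 0)[1L]
    if (declare_infeasible_on_negative_target)
      stop("infeasible target: current reaches zero at t = ",
           (bad - 1) * target$dt, " s; no light stimulus can produce it")
  }
  modified <- invert_current(target, params, dark, settings = settings)
  v <- modified$values
  tol <- 1e-9 * max(abs(v), 1)
  clipped_fraction <- mean(v < -tol)
  clipped <- new_trace(pmax(v, 0), modified$dt, "R*/s")
  init <- attr(modified, "initial_state")
  achieved <- simulate_cascade(params, dark, clipped, initial = init)
  structure(list(original_stimulus = stim,
                 target_response = target,
                 modified_stimulus = clipped,
                 achieved_response = achieved$I,
                 clipped_fraction = clipped_fraction,
                 feasible = all(target$values > 0)),
            class = "clamp_result")
}

#' @export
print.clamp_result <- function(x, ...) {
  cat(sprintf("<clamp_result> %d samples, dt = %g s\n",
              length(x$original_stimulus$values), x$original_stimulus$dt))
  fid <- stats::var(x$achieved_response$values - x$target_response$values) /
    stats::var(x$target_response$values)
  cat(sprintf("  feasible = %s, clipped fraction = %.3g, achieved-vs-target variance ratio = %.3g\n",
              x$feasible, x$clipped_fraction, fid))
  invisible(x)
}

#' Step-plus-flash clamp: negate adaptation to a mean-intensity step
#'
#' Builds a step-plus-flash protocol (identical test flashes before and
#' during a step in mean intensity), computes the non-adapting linear
#' target with the filter fit at the pre-step mean, and inverts it. The
#' full model's response to the original stimulus shows a reduced flash
#' gain during the step; the modified stimulus restores equal flash
#' amplitudes.
#'
#' @param pre_level,step_level Mean intensities before and during the
#'   step, R*/s.
#' @param flash_strength Test flash strength, R*.
#' @param flash_times Flash onset times, s; default one flash mid-way
#'   through the pre-step period and one mid-way through the step.
#' @param params,dark,lfp,settings,dt As in [design_clamp()]; \code{lfp}
#'   should be fit at \code{pre_level}.
#' @param step_onset,step_dur,total_dur,flash_duration Protocol layout, s.
#' @return A \code{"clamp_result"} with attributes \code{"flash_times"},
#'   \code{"flash_duration"}, and \code{"step_window"}.
#' @export
design_step_flash_clamp <- function(pre_level, step_level, flash_strength,
                                    flash_times = NULL, params, dark, lfp,
                                    settings = NULL, step_onset = NULL,
                                    step_dur = NULL, total_dur = NULL,
                                    flash_duration = 0.01, dt = NULL) {
  stopifnot(inherits(params, "cascade_params"), inherits(dark, "dark_point"))
  if (pre_level < 0 || step_level < 0) stop("levels must be nonnegative")
  is_cone <- isTRUE(grepl("cone", params$cell_type))
  dt <- dt %||% .default_dt_for(params)
  step_onset <- step_onset %||% (if (is_cone) 1 else 4)
  step_dur <- step_dur %||% (if (is_cone) 1 else 4)
  total_dur <- total_dur %||% (step_onset + step_dur + (if (is_cone) 0.5 else 2))
  flash_times <- flash_times %||% c(step_onset / 2, step_onset + step_dur / 2)
  stim <- make_step_flash_stimulus(pre_level, step_level, flash_strength,
                                   flash_times, step_onset, step_dur,
                                   total_dur, flash_duration, dt)
  if (any(flash_times < 0) || any(flash_times + flash_duration > total_dur))
    stop("flash times fall outside the trace")
  baseline <- steady_state(params, dark, lfp$mean_level)[["I"]]
  target <- linear_response(lfp, stim, baseline)
  out <- .finish_clamp(stim, target, params, dark, settings)
  attr(out, "flash_times") <- flash_times
  attr(out, "flash_duration") <- flash_duration
  attr(out, "step_window") <- c(step_onset, step_onset + step_dur)
  out
}

#' Kinetics clamp: scale the speed of the flash response
#'
#' Generates a target flash response from the linear filter with both time
#' constants multiplied by \code{scale} (slowing for \code{scale > 1},
#' speeding for \code{scale < 1}) and inverts it. Speeding pushes the
#' required stimulus toward negative intensities (a brief increment must
#' be followed by a decrement below zero light), so clipping is reported
#' and designs that lose a substantial fraction of their modulation energy
#' to clipping are flagged infeasible, with the largest cleanly achievable
#' scale attached as a diagnostic.
#'
#' @param flash_stimulus Stimulus trace containing a flash on a constant
#'   background equal to \code{lfp$mean_level}.
#' @param scale Time-constant scale factor (> 0); 1 leaves kinetics
#'   unchanged.
#' @param params,dark,lfp,settings,dt As in [design_clamp()].
#' @param max_clip_energy Fraction of target modulation energy that may be
#'   clipped before the design is declared infeasible.
#' @return A \code{"clamp_result"} with attributes
#'   \code{"predicted_ttp_change"} (s, target-vs-unscaled-target change in
#'   time to peak) and, when infeasible, \code{"achievable_scale"}.
#' @export
design_kinetics_clamp <- function(flash_stimulus, scale, params, dark, lfp,
                                  settings = NULL, dt = NULL,
                                  max_clip_energy = 0.2) {
  stopifnot(inherits(lfp, "linear_filter"))
  if (scale <= 0) stop("`scale` must be positive")
  stim <- as_trace(flash_stimulus, dt = dt, units = "R*/s")
  lfp_scaled <- linear_filter_params(lfp$alpha, lfp$tau_r * scale,
                                     lfp$tau_d * scale, lfp$mean_level,
                                     lfp$cell_type)
  baseline <- steady_state(params, dark, lfp$mean_level)[["I"]]
  target <- linear_response(lfp_scaled, stim, baseline)
  target_ref <- linear_response(lfp, stim, baseline)
  onset <- .first_deviation_time(stim)
  predicted_change <- time_to_peak(target, onset = onset) -
    time_to_peak(target_ref, onset = onset)
  out <- .finish_clamp(stim, target, params, dark, settings)
  attr(out, "predicted_ttp_change") <- predicted_change
  attr(out, "onset") <- onset
  # energy lost to clipping, relative to the stimulus modulation
  raw <- invert_current(target, params, dark, settings = settings)
  dev <- raw$values - lfp$mean_level
  clip_loss <- sum(pmin(raw$values, 0)^2) / max(sum(dev^2), .Machine$double.eps)
  attr(out, "clip_energy_fraction") <- clip_loss
  if (clip_loss > max_clip_energy) {
    out$feasible <- FALSE
    attr(out, "achievable_scale") <- .achievable_scale(stim, params, dark, lfp,
                                                      baseline, settings,
                                                      max_clip_energy)
  }
  out
}

.first_deviation_time <- function(stim) {
  base <- stim$values[1L]
  idx <- which(abs(stim$values - base) > 1e-9 * max(abs(stim$values), 1))
  if (!length(idx)) stop("flash stimulus has no deviation from baseline")
  (idx[1L] - 1L) * stim$dt
}

# Bisect for the smallest speeding scale whose clipped energy stays within
# budget (diagnostic only).
.achievable_scale <- function(stim, params, dark, lfp, baseline, settings,
                              max_clip_energy) {
  loss_at <- function(s) {
    lf <- linear_filter_params(lfp$alpha, lfp$tau_r * s, lfp$tau_d * s,
                               lfp$mean_level, lfp$cell_type)
    tgt <- linear_response(lf, stim, baseline)
    if (any(tgt$values <= 0)) return(Inf)
    raw <- invert_current(tgt, params, dark, settings = settings)
    dev <- raw$values - lfp$mean_level
    sum(pmin(raw$values, 0)^2) / max(sum(dev^2), .Machine$double.eps)
  }
  best <- 1
  for (s in seq(0.95, 0.5, by = -0.05)) {
    if (loss_at(s) <= max_clip_energy) best <- s else break
  }
  best
}
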