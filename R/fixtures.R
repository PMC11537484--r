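#' Variable-mean noise stimulus
#'
#' The workhorse protocol for probing adaptation and dynamics together:
#' Gaussian noise whose mean steps periodically across levels spanning up
#' to 30-fold, with noise SD proportional to the local mean (fixed
#' contrast) and samples truncated at zero. Deterministic for a fixed
#' seed.
#'
#' @param mean_levels Segment means, R*/s (all positive). Defaults per
#'   receptor class span 30-fold: cones 1500-45000 R*/s, rods 1-30 R*/s.
#' @param segment_dur Duration of each mean segment, s (default 2 s cones,
#'   5 s rods).
#' @param contrast Noise SD as a fraction of the local mean (< 1).
#' @param dt Sample interval, s (default per receptor class).
#' @param seed RNG seed.
#' @param cell_type Supplies the defaults above.
#' @return Stimulus \code{"ptrace"} (R*/s) with attributes
#'   \code{"mean_levels"} and \code{"segment_dur"}.
#' @export
make_variable_mean_noise <- function(mean_levels = NULL, segment_dur = NULL,
                                     contrast = 0.5, dt = NULL, seed = 1,
                                     cell_type = NULL) {
  if (is.null(mean_levels) || is.null(segment_dur) || is.null(dt)) {
    if (is.null(cell_type))
      stop("supply `cell_type` or all of mean_levels, segment_dur and dt")
    is_cone <- grepl("cone", cell_type)
    mean_levels <- mean_levels %||%
      (if (is_cone) c(1500, 4500, 12000, 24000, 45000)
       else c(1, 3, 8, 15, 30))
    segment_dur <- segment_dur %||% (if (is_cone) 2 else 5)
    dt <- dt %||% default_dt(cell_type)
  }
  if (any(mean_levels <= 0)) stop("mean levels must be positive")
  if (contrast < 0 || contrast >= 1) stop("`contrast` must lie in [0, 1)")
  set.seed(seed)
  n_seg <- round(segment_dur / dt)
  values <- unlist(lapply(mean_levels, function(m)
    pmax(0, stats::rnorm(n_seg, m, contrast * m))), use.names = FALSE)
  out <- new_trace(values, dt, "R*/s")
  attr(out, "mean_levels") <- mean_levels
  attr(out, "segment_dur") <- segment_dur
  attr(out, "seed") <- seed
  out
}

#' Flash family stimulus
#'
#' A sequence of brief flashes doubling in strength (by default starting
#' at ~3 R*, six flashes), each delivered on a common background with
#' enough spacing for the response to recover.
#'
#' @param base_strength Weakest flash strength, R*.
#' @param n_flashes Number of flashes.
#' @param spacing_factor Strength ratio between successive flashes.
#' @param background Constant background, R*/s.
#' @param interval Time between flash onsets, s.
#' @param flash_duration Flash duration, s.
#' @param dt Sample interval, s.
#' @param pre_dur Lead-in before the first flash, s.
#' @return Stimulus \code{"ptrace"} with attribute \code{"annotations"}, a
#'   data frame of flash onsets (s) and strengths (R*).
#' @export
make_flash_family <- function(base_strength = 3, n_flashes = 6,
                              spacing_factor = 2, background = 0,
                              interval = 3, flash_duration = 0.01,
                              dt = 1e-3, pre_dur = 0.5) {
  if (n_flashes < 1) stop("need at least one flash")
  strengths <- base_strength * spacing_factor^(seq_len(n_flashes) - 1L)
  onsets <- pre_dur + (seq_len(n_flashes) - 1L) * interval
  total <- max(onsets) + interval
  values <- rep(background, round(total / dt))
  n_fl <- max(1L, round(flash_duration / dt))
  for (i in seq_len(n_flashes)) {
    i0 <- round(onsets[i] / dt) + 1L
    values[i0:(i0 + n_fl - 1L)] <- background + strengths[i] / flash_duration
  }
  out <- new_trace(values, dt, "R*/s")
  attr(out, "annotations") <- data.frame(onset = onsets, strength = strengths)
  out
}

#' Sinusoidal stimulus
#'
#' @param mean_level Mean intensity, R*/s.
#' @param contrast Modulation depth (1 = 100\%, minimum touches zero).
#' @param freq Frequency, Hz.
#' @param duration Duration, s.
#' @param dt Sample interval, s.
#' @return Stimulus \code{"ptrace"}.
#' @export
make_sinusoid_stimulus <- function(mean_level, contrast = 1, freq = 2,
                                   duration = 2, dt = 1e-4) {
  if (contrast < 0 || contrast > 1) stop("`contrast` must lie in [0, 1]")
  t <- seq(0, duration - dt, by = dt)
  new_trace(mean_level * (1 + contrast * sin(2 * pi * freq * t)), dt, "R*/s")
}

#' Step-plus-flash stimulus
#'
#' Identical test flashes delivered before and during a step in mean
#' intensity, the protocol used to probe adaptation-induced gain changes.
#'
#' @param pre_level,step_level Intensities before/during the step, R*/s.
#' @param flash_strength Flash strength, R*.
#' @param flash_times Flash onsets, s.
#' @param step_onset,step_dur Step timing, s.
#' @param total_dur Trace duration, s.
#' @param flash_duration Flash duration, s.
#' @param dt Sample interval, s.
#' @return Stimulus \code{"ptrace"}.
#' @export
make_step_flash_stimulus <- function(pre_level, step_level, flash_strength,
                                     flash_times, step_onset, step_dur,
                                     total_dur, flash_duration = 0.01,
                                     dt = 1e-4) {
  if (pre_level < 0 || step_level < 0 || flash_strength < 0)
    stop("levels and flash strength must be nonnegative")
  n <- round(total_dur / dt)
  values <- rep(pre_level, n)
  i_step <- round(step_onset / dt) + 1L
  i_step_end <- min(n, round((step_onset + step_dur) / dt))
  values[i_step:i_step_end] <- step_level
  n_fl <- max(1L, round(flash_duration / dt))
  for (tt in flash_times) {
    i0 <- round(tt / dt) + 1L
    if (i0 < 1L || i0 + n_fl - 1L > n) stop("flash at ", tt, " s falls outside the trace")
    values[i0:(i0 + n_fl - 1L)] <- values[i0:(i0 + n_fl - 1L)] +
      flash_strength / flash_duration
  }
  new_trace(values, dt, "R*/s")
}

#' Synthetic recording from the forward model
#'
#' Simulates the cascade's response to a stimulus from the equilibrated
#' state and adds white Gaussian current noise, producing a
#' stimulus/response pair with known ground-truth parameters — the fixture
#' used for parameter-recovery experiments.
#'
#' @param stimulus Stimulus \code{"ptrace"} (e.g. from
#'   [make_variable_mean_noise()]).
#' @param params Ground-truth \code{"cascade_params"}.
#' @param dark \code{"dark_point"}.
#' @param noise_sd Additive current noise SD, pA (>= 0).
#' @param seed RNG seed for the noise.
#' @return List with \code{stimulus}, \code{response} (\code{"ptrace"},
#'   pA), \code{clean} (noise-free response), \code{params},
#'   \code{dark_current}, \code{noise_sd}, \code{seed}.
#' @export
make_synthetic_recording <- function(stimulus, params, dark, noise_sd = 0,
                                     seed = 1) {
  stopifnot(inherits(stimulus, "ptrace"), inherits(params, "cascade_params"),
            inherits(dark, "dark_point"))
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  bg <- mean(stimulus$values[seq_len(min(length(stimulus$values),
                                         max(1L, round(0.5 / stimulus$dt))))])
  init <- steady_state(params, dark, bg)
  st <- simulate_cascade(params, dark, stimulus,
                         initial = init[c("R", "P", "G", "C")])
  clean <- st$I
  set.seed(seed)
  noisy <- clean$values +
    if (noise_sd > 0) stats::rnorm(length(clean$values), 0, noise_sd) else 0
  list(stimulus = stimulus,
       response = new_trace(noisy, stimulus$dt, "pA"),
       clean = clean,
       params = params,
       dark_current = dark$i_dark,
       noise_sd = noise_sd,
       seed = seed)
}
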