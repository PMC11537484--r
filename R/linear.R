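#' Small-signal linear filter parameters
#'
#' Parameterized impulse response of the photocurrent for low-contrast
#' stimuli around an adapting mean:
#' \deqn{L(t) = \alpha \frac{(t/\tau_R)^3}{1 + (t/\tau_R)^3} e^{-t/\tau_D}}
#' i.e. a cubed saturating rise with time constant \code{tau_r} multiplied
#' by an exponential decay with time constant \code{tau_d}. The filter is
#' zero at t = 0 and decays to zero; \code{alpha} maps stimulus deviations
#' (R*/s) to current (pA) after convolution. Filters are only valid near
#' the mean level they were fit at, because the gain and kinetics of the
#' cascade adapt with mean intensity.
#'
#' @param alpha Scale factor (> 0 for the standard sign convention, where
#'   light increments reduce the current magnitude).
#' @param tau_r Rising time constant (saturating front), s (> 0).
#' @param tau_d Decay time constant (exponential), s (> 0).
#' @param mean_level Adapting background the filter was fit at, R*/s.
#' @param cell_type Optional photoreceptor type tag.
#' @return Object of class \code{"linear_filter"}.
#' @export
linear_filter_params <- function(alpha, tau_r, tau_d, mean_level,
                                 cell_type = NA_character_) {
  if (!all(vapply(list(alpha, tau_r, tau_d, mean_level),
                  function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1L))))
    stop("alpha, tau_r, tau_d and mean_level must be single finite numbers")
  if (tau_r <= 0 || tau_d <= 0) stop("time constants must be positive")
  structure(list(alpha = alpha, tau_r = tau_r, tau_d = tau_d,
                 mean_level = mean_level, cell_type = cell_type),
            class = "linear_filter")
}

#' @export
print.linear_filter <- function(x, ...) {
  cat(sprintf(
    "<linear_filter> alpha = %.4g, tau_r = %.4g ms, tau_d = %.4g ms\n",
    x$alpha, 1e3 * x$tau_r, 1e3 * x$tau_d))
  cat(sprintf("  fit at mean = %g R*/s (%s)\n", x$mean_level,
              ifelse(is.na(x$cell_type), "custom", x$cell_type)))
  invisible(x)
}

#' Evaluate the linear filter
#'
#' @param lfp A \code{"linear_filter"}.
#' @param t Times, s (nonnegative).
#' @return Filter values at \code{t}.
#' @examples
#' lf <- linear_filter_params(1, 0.01, 0.01, mean_level = 0)
#' eval_filter(lf, 0.01)  # 0.5 * exp(-1)
#' @export
eval_filter <- function(lfp, t) {
  stopifnot(inherits(lfp, "linear_filter"))
  if (any(t < 0)) stop("filter is causal: `t` must be nonnegative")
  u <- (t / lfp$tau_r)^3
  lfp$alpha * u / (1 + u) * exp(-t / lfp$tau_d)
}

# Sampled kernel covering the filter's support (internal).
filter_kernel <- function(lfp, dt, t_max = NULL) {
  t_max <- t_max %||% (20 * max(lfp$tau_r, lfp$tau_d))
  eval_filter(lfp, seq(0, t_max, by = dt))
}

# Causal FFT convolution: returns the first length(x) samples of x * kern.
conv_causal <- function(x, kern) {
  n <- length(x); m <- length(kern)
  N <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, numeric(N - n)))
  K <- stats::fft(c(kern, numeric(N - m)))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(n)] / N
}

#' Linear-model response to a stimulus
#'
#' Convolves the fitted filter with the stimulus deviation from the
#' filter's mean level, signed so that light increments reduce the current
#' magnitude, and offsets by the baseline current at that mean. This is the
#' response the photoreceptor would produce if it had no nonlinearities —
#' the "target" used by the adaptation clamp.
#'
#' @param lfp A \code{"linear_filter"}.
#' @param stimulus \code{"ptrace"} in R*/s (or numeric with \code{dt}).
#' @param baseline_current Current at the mean level, pA (magnitude).
#' @param dt Sample interval for bare numeric stimuli.
#' @return \code{"ptrace"} in pA.
#' @export
linear_response <- function(lfp, stimulus, baseline_current, dt = NULL) {
  stopifnot(inherits(lfp, "linear_filter"))
  stim <- as_trace(stimulus, dt = dt, units = "R*/s")
  kern <- filter_kernel(lfp, stim$dt)
  dev <- stim$values - lfp$mean_level
  drive <- conv_causal(dev, kern) * stim$dt
  new_trace(baseline_current - drive, stim$dt, "pA")
}

#' Fit the linear filter to the full model's low-contrast response
#'
#' Drives the full cascade model with low-contrast Gaussian noise about a
#' mean light level, then least-squares fits the parameterized filter (see
#' [linear_filter_params()]) so that its convolution with the stimulus
#' deviation reproduces the model's baseline-subtracted response. In this
#' regime the cascade responds linearly, so the fitted filter is the
#' small-signal description of the model at that mean.
#'
#' The simplex search runs over \code{log(tau_r), log(tau_d)} with the
#' scale \code{alpha} profiled out in closed form at each step. The
#' simulation runs at the reference step; stimulus and response are
#' block-averaged to \code{fit_dt} before fitting (the filter has no power
#' at the frequencies this removes).
#'
#' @inheritParams simulate_cascade
#' @param mean_level Adapting mean, R*/s (> 0).
#' @param contrast RMS contrast of the fitting noise (0 < contrast <= 0.2).
#' @param duration Noise duration, s; defaults to 30 s for cones and 60 s
#'   for rods.
#' @param seed RNG seed for the fitting noise.
#' @param fit_dt Resolution at which the fit is performed, s.
#' @param kernel_dur Filter support used in the fit, s; defaults to 0.5 s
#'   for cones, 2 s for rods.
#' @return A \code{"linear_filter"} with attributes \code{"mse"} (residual
#'   mean squared error), \code{"fv"} (fraction of response variance
#'   explained), and \code{"convergence"} (from [stats::optim()]).
#' @export
fit_linear_model <- function(params, dark, mean_level, contrast = 0.05,
                             duration = NULL, seed = 1, dt = NULL,
                             fit_dt = 1e-3, kernel_dur = NULL) {
  stopifnot(inherits(params, "cascade_params"), inherits(dark, "dark_point"))
  if (contrast <= 0 || contrast > 0.2)
    stop("`contrast` must lie in (0, 0.2]: the filter is a small-signal model")
  if (mean_level <= 0) stop("`mean_level` must be positive")
  is_cone <- isTRUE(grepl("cone", params$cell_type))
  dt <- dt %||% .default_dt_for(params)
  duration <- duration %||% (if (is_cone) 30 else 60)
  kernel_dur <- kernel_dur %||% (if (is_cone) 0.5 else 2)

  set.seed(seed)
  n <- round(duration / dt)
  stim <- pmax(0, stats::rnorm(n, mean_level, contrast * mean_level))
  init <- steady_state(params, dark, mean_level)
  st <- simulate_cascade(params, dark, new_trace(stim, dt, "R*/s"),
                         initial = init[c("R", "P", "G", "C")])

  fac <- max(1L, round(fit_dt / dt))
  fit_dt <- fac * dt
  dev <- .block_mean(stim, fac) - mean(.block_mean(stim, fac))
  resp <- .block_mean(st$I$values, fac)
  resp <- resp - mean(resp)

  tau0 <- if (is_cone) c(0.02, 0.02) else c(0.15, 0.15)
  fit <- .fit_filter(dev, resp, fit_dt, kernel_dur, tau0)
  if (fit$convergence != 0)
    warning("filter fit did not fully converge (code ", fit$convergence,
            "); returning best parameters found (objective ", fit$mse, ")")
  out <- linear_filter_params(fit$alpha, fit$tau_r, fit$tau_d, mean_level,
                              params$cell_type)
  attr(out, "mse") <- fit$mse
  attr(out, "fv") <- fit$fv
  attr(out, "convergence") <- fit$convergence
  out
}

# Core least-squares machinery of the filter fit: given stimulus and
# response deviations, simplex over log time constants with the scale
# profiled out in closed form.
.fit_filter <- function(dev, resp, fit_dt, kernel_dur, tau0) {
  n_k <- round(kernel_dur / fit_dt)
  keep <- seq.int(n_k + 1L, length(dev))
  N <- stats::nextn(length(dev) + n_k, 2L)
  DEV <- stats::fft(c(dev, numeric(N - length(dev))))
  shape_for <- function(tau) {
    kern <- eval_filter(linear_filter_params(1, tau[1L], tau[2L], 0),
                        seq(0, kernel_dur, by = fit_dt))
    K <- stats::fft(c(kern, numeric(N - length(kern))))
    -Re(stats::fft(DEV * K, inverse = TRUE))[seq_along(dev)] / N * fit_dt
  }
  obj <- function(log_tau) {
    sh <- shape_for(exp(log_tau))[keep]
    a <- sum(sh * resp[keep]) / sum(sh * sh)
    mean((resp[keep] - a * sh)^2)
  }
  best <- stats::optim(log(tau0), obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 1000))
  # one restart from a perturbed optimum to escape a flat simplex
  again <- stats::optim(best$par + c(0.25, -0.25), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 1000))
  if (again$value < best$value) best <- again
  tau <- exp(best$par)
  sh <- shape_for(tau)[keep]
  alpha <- sum(sh * resp[keep]) / sum(sh * sh)
  list(alpha = alpha, tau_r = tau[1L], tau_d = tau[2L], mse = best$value,
       fv = 1 - best$value / mean(resp[keep]^2),
       convergence = best$convergence)
}

.block_mean <- function(x, fac) {
  if (fac == 1L) return(x)
  n <- (length(x) %/% fac) * fac
  colMeans(matrix(x[seq_len(n)], nrow = fac))
}
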