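#' Best-fitting sinusoid and normalized deviation
#'
#' Least-squares fit of \code{offset + a sin(2 pi f t) + b cos(2 pi f t)}
#' at a known frequency (closed form on the sin/cos/constant basis). The
#' reported MSE is the mean squared residual divided by the trace variance,
#' so it is independent of response contrast and baseline: 0 for an exact
#' sinusoid, approaching 1 when the trace shares nothing with the fit.
#'
#' @param trace Response trace (or numeric vector with \code{dt}).
#' @param freq Sinusoid frequency, Hz; the trace must span at least two
#'   periods.
#' @param dt Sample interval for bare numeric input.
#' @return List with \code{amplitude}, \code{phase} (radians), \code{offset},
#'   \code{mse} (variance-normalized), and \code{fitted} values.
#' @export
best_fit_sinusoid <- function(trace, freq, dt = NULL) {
  tr <- as_trace(trace, dt = dt)
  t <- trace_time(tr)
  if (max(t) < 2 / freq)
    stop("trace must span at least two periods of `freq`")
  X <- cbind(1, sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- stats::lm.fit(X, tr$values)$coefficients
  fitted <- drop(X %*% cf)
  res <- tr$values - fitted
  v <- mean((tr$values - mean(tr$values))^2)
  if (v == 0) stop("constant trace: normalized sinusoid MSE is undefined")
  list(amplitude = sqrt(cf[2L]^2 + cf[3L]^2),
       phase = atan2(cf[3L], cf[2L]),
       offset = unname(cf[1L]),
       mse = mean(res^2) / v,
       fitted = fitted)
}

#' Adaptation gain ratio from a step-plus-flash response
#'
#' Ratio of the flash-response amplitude during an adapting step to the
#' amplitude of the identical flash before the step. Each amplitude is the
#' peak absolute deviation from a local baseline taken just before the
#' flash, so the sustained step response cancels. A ratio of 1 means no
#' gain change; adaptation gives ratios below 1.
#'
#' @param response Response trace, pA (or numeric with \code{dt}).
#' @param flash_time_pre,flash_time_during Flash onset times, s.
#' @param window Response window after each flash, s.
#' @param baseline_window Averaging window for the local baseline, s
#'   (ending just before the flash).
#' @param dt Sample interval for bare numeric input.
#' @return Single number, amplitude(during) / amplitude(pre), with the two
#'   amplitudes attached as attribute \code{"amplitudes"}.
#' @export
gain_ratio <- function(response, flash_time_pre, flash_time_during,
                       window = 0.2, baseline_window = 0.05, dt = NULL) {
  tr <- as_trace(response, dt = dt)
  t_end <- (length(tr$values) - 1) * tr$dt
  for (tt in c(flash_time_pre, flash_time_during))
    if (tt < baseline_window || tt + window > t_end)
      stop("flash window [", tt, ", ", tt + window, "] s falls outside the trace")
  if (flash_time_pre + window > flash_time_during &&
      flash_time_during + window > flash_time_pre)
    stop("flash windows overlap")
  amp <- function(onset) {
    i0 <- round(onset / tr$dt) + 1L
    ib <- max(1L, i0 - round(baseline_window / tr$dt)):(i0 - 1L)
    base <- mean(tr$values[ib])
    iw <- i0:min(length(tr$values), i0 + round(window / tr$dt))
    max(abs(tr$values[iw] - base))
  }
  a_pre <- amp(flash_time_pre)
  a_during <- amp(flash_time_during)
  if (a_pre <= .Machine$double.eps^0.5 * max(abs(tr$values), 1))
    stop("pre-step flash amplitude is zero: gain ratio undefined")
  structure(a_during / a_pre, amplitudes = c(pre = a_pre, during = a_during))
}

#' Time from stimulus onset to response peak
#'
#' Finds the extremum of the baseline-subtracted response after \code{onset}
#' and refines its time by local quadratic interpolation. The baseline is
#' the mean over a window ending at onset. Signals an error if the
#' extremum sits on the trace boundary (monotone response, no peak).
#'
#' @param response Response trace (or numeric with \code{dt}).
#' @param onset Stimulus onset time, s.
#' @param baseline_window Pre-onset averaging window, s.
#' @param dt Sample interval for bare numeric input.
#' @return Time to peak, s.
#' @export
time_to_peak <- function(response, onset = 0, baseline_window = 0.1,
                         dt = NULL) {
  tr <- as_trace(response, dt = dt)
  i0 <- round(onset / tr$dt) + 1L
  if (i0 < 1L || i0 >= length(tr$values))
    stop("`onset` falls outside the trace")
  ib <- max(1L, i0 - round(baseline_window / tr$dt)):i0
  base <- mean(tr$values[ib])
  seg <- abs(tr$values[i0:length(tr$values)] - base)
  ipk <- which.max(seg)
  if (ipk == 1L || ipk == length(seg))
    stop("no interior extremum after onset: response is monotone over the trace")
  y1 <- seg[ipk - 1L]; y2 <- seg[ipk]; y3 <- seg[ipk + 1L]
  denom <- y1 - 2 * y2 + y3
  shift <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
  (ipk - 1L + shift) * tr$dt
}

#' Loop area of a stimulus-response trajectory
#'
#' Area enclosed by the closed (stimulus, response) trajectory over one
#' stimulus cycle, after normalizing each axis to unit peak-to-peak range.
#' A response that is any static function of the stimulus retraces its
#' path and encloses zero area; time-dependent nonlinearities (adaptation)
#' open the loop. The magnitude is reported regardless of traversal
#' direction.
#'
#' @param stimulus_cycle,response_cycle Traces covering exactly one period,
#'   equal length (or numeric vectors).
#' @return Dimensionless area in [0, 1].
#' @export
loop_area <- function(stimulus_cycle, response_cycle) {
  x <- if (inherits(stimulus_cycle, "ptrace")) stimulus_cycle$values
       else as.numeric(stimulus_cycle)
  y <- if (inherits(response_cycle, "ptrace")) response_cycle$values
       else as.numeric(response_cycle)
  if (length(x) != length(y)) stop("cycles must have equal length")
  rx <- diff(range(x)); ry <- diff(range(y))
  if (rx == 0 || ry == 0)
    stop("degenerate cycle: zero peak-to-peak range on one axis")
  x <- (x - min(x)) / rx
  y <- (y - min(y)) / ry
  nxt <- c(seq_along(x)[-1L], 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

#' Power spectra of stimulus and estimation residual
#'
#' Segment-averaged (Welch) periodograms of the stimulus and of the
#' residual (stimulus minus estimate). Where the estimate is accurate the
#' residual power sits far below the stimulus power; the two converge at
#' the frequencies the inversion cannot recover. The convergence frequency
#' is the lowest frequency at which residual power reaches a set fraction
#' of stimulus power and stays there for several consecutive bins.
#'
#' @param stimulus,estimate Traces of equal length (or numeric vectors with
#'   \code{dt}).
#' @param n_segments Number of Welch segments (Hann-windowed, non-overlapping).
#' @param threshold Residual/stimulus power fraction defining convergence.
#' @param sustain Number of consecutive bins the threshold must hold.
#' @param dt Sample interval for bare numeric input.
#' @return List with \code{freq} (Hz), \code{stimulus_power},
#'   \code{residual_power}, and \code{convergence_frequency} (Hz; \code{NA}
#'   if the spectra never converge in-band).
#' @export
residual_spectra <- function(stimulus, estimate, n_segments = 8,
                             threshold = 0.5, sustain = 3, dt = NULL) {
  st <- as_trace(stimulus, dt = dt, units = "a.u.")
  es <- if (inherits(estimate, "ptrace")) estimate
        else as_trace(estimate, dt = st$dt)
  if (length(st$values) != length(es$values))
    stop("stimulus and estimate must have equal length")
  resid <- st$values - es$values
  ps_s <- .welch(st$values, st$dt, n_segments)
  ps_r <- .welch(resid, st$dt, n_segments)
  ratio <- ps_r$power / pmax(ps_s$power, .Machine$double.xmin)
  conv <- NA_real_
  hits <- ratio >= threshold
  run <- rle(hits)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= sustain)
  if (length(ok)) conv <- ps_s$freq[starts[ok[1L]]]
  list(freq = ps_s$freq, stimulus_power = ps_s$power,
       residual_power = ps_r$power, convergence_frequency = conv)
}

.welch <- function(x, dt, n_segments) {
  n <- length(x)
  seg <- max(8L, n %/% n_segments)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  scale <- sum(win^2)
  nf <- seg %/% 2L
  acc <- numeric(nf)
  count <- 0L
  for (s in seq(1L, n - seg + 1L, by = seg)) {
    chunk <- x[s:(s + seg - 1L)]
    chunk <- (chunk - mean(chunk)) * win
    pxx <- Mod(stats::fft(chunk))^2 / scale
    acc <- acc + pxx[2:(nf + 1L)]
    count <- count + 1L
  }
  list(freq = (seq_len(nf)) / (seg * dt), power = acc / count * dt)
}
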