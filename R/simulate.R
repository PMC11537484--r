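#' Simulate the phototransduction cascade
#'
#' Integrates the six-variable cascade (opsin activity R, PDE activity P,
#' cGMP G, synthesis rate S, calcium C, current I) over a light stimulus.
#' Forward Euler at the per-type reference step (0.1 ms cones, 1 ms rods)
#' is the reference scheme; classical RK4 (with the stimulus linearly
#' interpolated within steps) is available as a convergence check.
#'
#' @param params \code{"cascade_params"}.
#' @param dark \code{"dark_point"} from [dark_operating_point()].
#' @param stimulus A \code{"ptrace"} in R*/s (nonnegative), or a numeric
#'   vector together with \code{dt}.
#' @param initial Optional named state vector \code{c(R, P, G, C)} to start
#'   from; defaults to the dark state. Use [steady_state()] to start
#'   equilibrated at a background.
#' @param method \code{"euler"} (reference) or \code{"rk4"}.
#' @param dt Sample interval when \code{stimulus} is a bare vector.
#' @return Object of class \code{"state_trace"}: traces \code{R}, \code{P},
#'   \code{G}, \code{S}, \code{C}, \code{I} sharing \code{dt} and length.
#'   \code{I = k * G^n} holds pointwise; currents are positive magnitudes.
#' @examples
#' pr <- consensus_params("primate_rod")
#' dk <- dark_operating_point(pr, default_dark_current("primate_rod"))
#' st <- simulate_cascade(pr, dk, rep(0, 100), dt = 1e-3)
#' range(st$I$values) / dk$i_dark  # stays at the dark current
#' @export
simulate_cascade <- function(params, dark, stimulus, initial = NULL,
                             method = c("euler", "rk4"), dt = NULL) {
  stopifnot(inherits(params, "cascade_params"), inherits(dark, "dark_point"))
  method <- match.arg(method)
  stim <- as_trace(stimulus, dt = dt %||% .default_dt_for(params), units = "R*/s")
  if (any(stim$values < 0))
    stop("stimulus must be nonnegative; first negative sample at index ",
         which(stim$values < 0)[1L])
  if (is.null(initial)) {
    initial <- c(R = 0, P = dark$p_dark, G = dark$g_dark, C = params$c_dark)
  }
  initial <- initial[c("R", "P", "G", "C")]
  if (any(is.na(initial)))
    stop("`initial` must be a named vector with components R, P, G, C")
  fn <- if (method == "euler") .cascade_euler_cpp else .cascade_rk4_cpp
  out <- fn(stim$values, stim$dt,
            params$gamma, params$sigma, params$phi, params$eta,
            params$k, params$n, params$m, params$beta,
            params$k_gc, dark$s_max, dark$q,
            initial[["R"]], initial[["P"]], initial[["G"]], initial[["C"]])
  units <- c(R = "a.u.", P = "s^-1", G = "uM", S = "uM", C = "uM", I = "pA")
  st <- lapply(names(units), function(nm)
    new_trace(out[[nm]], stim$dt, units[[nm]]))
  names(st) <- names(units)
  structure(c(st, list(dt = stim$dt, method = method)), class = "state_trace")
}

.default_dt_for <- function(params) {
  if (!is.na(params$cell_type)) default_dt(params$cell_type) else 1e-4
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("<state_trace> %d samples, dt = %g s, method = %s\n",
              length(x$I$values), x$dt, x$method))
  cat(sprintf("  I in [%.4g, %.4g] pA, G in [%.4g, %.4g] uM\n",
              min(x$I$values), max(x$I$values),
              min(x$G$values), max(x$G$values)))
  invisible(x)
}

# Pure-R forward Euler used as an in-package cross-check of the compiled
# integrator (tests also compare against deSolve::lsoda).
.cascade_euler_r <- function(params, dark, stim, dt, initial) {
  N <- length(stim)
  R <- P <- G <- S <- C <- I <- numeric(N)
  r <- initial[["R"]]; p <- initial[["P"]]
  g <- initial[["G"]]; cc <- initial[["C"]]
  for (i in seq_len(N)) {
    R[i] <- r; P[i] <- p; G[i] <- g; C[i] <- cc
    s <- dark$s_max / (1 + (cc / params$k_gc)^params$m)
    cur <- params$k * g^params$n
    S[i] <- s; I[i] <- cur
    rn <- r + dt * (params$gamma * stim[i] - params$sigma * r)
    pn <- p + dt * (r - params$phi * p + params$eta)
    gn <- g + dt * (s - p * g)
    cn <- cc + dt * (dark$q * cur - params$beta * cc)
    r <- rn; p <- pn; g <- gn; cc <- cn
  }
  list(R = R, P = P, G = G, S = S, C = C, I = I)
}

#' Steady state of the cascade at a constant background
#'
#' Finds the fixed point of the cascade under constant illumination by
#' root-finding on the cGMP concentration (the dark state seeds the
#' bracket), rather than by a burn-in simulation. At zero background the
#' dark state is returned exactly.
#'
#' @inheritParams simulate_cascade
#' @param background Constant stimulus level, R*/s (>= 0).
#' @param tol Relative tolerance on the cGMP root.
#' @return Named vector \code{c(R, P, G, S, C, I)} at the fixed point, with
#'   attribute \code{"residual"} giving the largest remaining state
#'   time-derivative (relative).
#' @export
steady_state <- function(params, dark, background, tol = 1e-12) {
  stopifnot(inherits(params, "cascade_params"), inherits(dark, "dark_point"))
  if (!is.numeric(background) || length(background) != 1L ||
      !is.finite(background) || background < 0)
    stop("`background` must be a single nonnegative intensity in R*/s")
  r <- params$gamma * background / params$sigma
  p <- (r + params$eta) / params$phi
  # dG/dt = 0  <=>  s_max / (1 + (C(G)/k_gc)^m) = p * G, with
  # C(G) = q * k * G^n / beta; the left side falls and the right side grows
  # in G, so the root is unique and bracketed by (0, s_max / p].
  f <- function(g) {
    cc <- dark$q * params$k * g^params$n / params$beta
    dark$s_max / (1 + (cc / params$k_gc)^params$m) - p * g
  }
  upper <- dark$s_max / p
  root <- stats::uniroot(f, lower = upper * 1e-12, upper = upper,
                         tol = tol * dark$g_dark)
  if (abs(root$f.root) > 1e-6 * dark$s_max)
    stop("steady-state root-finding did not converge: residual ",
         root$f.root, " at G = ", root$root)
  g <- root$root
  cc <- dark$q * params$k * g^params$n / params$beta
  s <- dark$s_max / (1 + (cc / params$k_gc)^params$m)
  state <- c(R = r, P = p, G = g, S = s, C = cc, I = params$k * g^params$n)
  derivs <- c(params$gamma * background - params$sigma * r,
              r - params$phi * p + params$eta,
              s - p * g,
              dark$q * state[["I"]] - params$beta * cc)
  scale <- c(max(r, 1e-12), p, g, cc)
  attr(state, "residual") <- max(abs(derivs) / scale)
  state
}

#' Flash response from an adapted state
#'
#' Simulates the baseline-subtracted response to a rectangular flash
#' delivered from the steady state at a background intensity, and reports
#' the time from flash onset to the response extremum.
#'
#' @inheritParams simulate_cascade
#' @param background Adapting background, R*/s.
#' @param flash_strength Flash strength in total isomerizations (R*);
#'   delivered as an increment of \code{flash_strength / flash_duration}
#'   R*/s for \code{flash_duration} seconds.
#' @param flash_duration Flash duration, s (>= one sample).
#' @param pre_dur,post_dur Baseline before the flash and recording time
#'   after it, s. Defaults scale with receptor kinetics (shorter for cones).
#' @return List with \code{response} (baseline-subtracted current change,
#'   \code{"ptrace"} in pA; negative when the light reduces the current
#'   magnitude), \code{time_to_peak} (s from flash onset), \code{onset}
#'   (s), and \code{baseline} (the adapted steady current, pA).
#' @export
flash_response <- function(params, dark, background, flash_strength,
                           flash_duration = NULL, dt = NULL,
                           pre_dur = NULL, post_dur = NULL) {
  dt <- dt %||% .default_dt_for(params)
  is_cone <- isTRUE(grepl("cone", params$cell_type))
  flash_duration <- flash_duration %||% (if (is_cone) 0.01 else 0.01)
  pre_dur <- pre_dur %||% (if (is_cone) 0.1 else 0.5)
  post_dur <- post_dur %||% (if (is_cone) 0.5 else 3)
  if (flash_duration < dt) stop("`flash_duration` must be at least one sample")
  if (flash_strength < 0 || background < 0)
    stop("flash strength and background must be nonnegative")
  n_pre <- round(pre_dur / dt)
  n_fl <- round(flash_duration / dt)
  n_post <- round(post_dur / dt)
  stim <- rep(background, n_pre + n_fl + n_post)
  stim[n_pre + seq_len(n_fl)] <- background + flash_strength / flash_duration
  init <- steady_state(params, dark, background)
  st <- simulate_cascade(params, dark, new_trace(stim, dt, "R*/s"),
                         initial = init[c("R", "P", "G", "C")])
  baseline <- init[["I"]]
  resp <- new_trace(st$I$values - baseline, dt, "pA")
  onset <- n_pre * dt
  if (flash_strength == 0) {
    warning("zero-strength flash: response is flat and time-to-peak is undefined")
    ttp <- NA_real_
  } else {
    ttp <- time_to_peak(resp, onset = onset)
  }
  list(response = resp, time_to_peak = ttp, onset = onset,
       baseline = baseline)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
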