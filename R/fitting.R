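#' Fraction of variance explained
#'
#' Goodness of fit \code{1 - SSE/SST}, where SSE is the sum of squared
#' differences between measured and predicted traces and SST is the total
#' sum of squares of the measurement. Equals 1 only for a perfect fit;
#' can be arbitrarily negative for predictions worse than the mean.
#'
#' @param measured,predicted Traces or numeric vectors of equal length.
#' @return Number in (-Inf, 1].
#' @examples
#' fraction_variance(c(0, 1, 2, 3), c(0, 1, 2, 2))  # 0.8
#' @export
fraction_variance <- function(measured, predicted) {
  m <- if (inherits(measured, "ptrace")) measured$values else as.numeric(measured)
  p <- if (inherits(predicted, "ptrace")) predicted$values else as.numeric(predicted)
  if (length(m) != length(p)) stop("traces must have equal length")
  sst <- sum((m - mean(m))^2)
  if (sst == 0) stop("measured trace has zero variance: fraction undefined")
  1 - sum((m - p)^2) / sst
}

# Free parameters per receptor class: beta is fixed for rods, fitted for
# cones; sigma and phi are tied when tie_sigma_phi is on.
.default_free <- function(cell_type) {
  if (isTRUE(grepl("cone", cell_type)))
    c("gamma", "sigma", "eta", "beta", "k_gc")
  else c("gamma", "sigma", "eta", "k_gc")
}

# Shared machinery: MSE of one cell's model against its recorded pairs.
# Each pair is list(stimulus =, response =); the initial state is the
# steady state at the mean of the first `equil_dur` seconds of stimulus,
# and the first `drop_dur` seconds are excluded from the error (absorbing
# any equilibration mismatch).
.cell_mse <- function(params, dark_current, pairs, drop_dur = 0.5,
                      equil_dur = 0.5) {
  dark <- dark_operating_point(params, dark_current)
  sse <- 0; nn <- 0L
  for (pr in pairs) {
    stim <- pr$stimulus
    bg <- mean(stim$values[seq_len(min(length(stim$values),
                                       max(1L, round(equil_dur / stim$dt))))])
    init <- steady_state(params, dark, bg)
    st <- simulate_cascade(params, dark, stim,
                           initial = init[c("R", "P", "G", "C")])
    keep <- seq.int(min(length(stim$values),
                        round(drop_dur / stim$dt) + 1L),
                    length(stim$values))
    d <- st$I$values[keep] - pr$response$values[keep]
    sse <- sse + sum(d^2)
    nn <- nn + length(keep)
  }
  sse / nn
}

.update_params <- function(base, values, names, tie_sigma_phi) {
  p <- unclass(base)
  for (i in seq_along(names)) p[[names[i]]] <- unname(values[i])
  if (tie_sigma_phi && "sigma" %in% names) p$phi <- p$sigma
  do.call(cascade_params, p)
}

.simplex_restarts <- function(obj, theta0, restarts, control) {
  best <- stats::optim(theta0, obj, method = "Nelder-Mead", control = control)
  trace <- data.frame(restart = 0L, objective = best$value,
                      evaluations = best$counts[["function"]])
  perturb <- c(0.15, -0.12, 0.08)
  for (r in seq_len(restarts)) {
    start <- best$par + perturb[((r - 1L) %% length(perturb)) + 1L] *
      rep_len(c(1, -1), length(best$par))
    fit <- stats::optim(start, obj, method = "Nelder-Mead", control = control)
    trace <- rbind(trace, data.frame(restart = r, objective = fit$value,
                                     evaluations = fit$counts[["function"]]))
    if (fit$value < best$value) best <- fit
  }
  list(best = best, trace = trace)
}

#' Fit the cascade model to one cell's recordings
#'
#' Nelder-Mead simplex minimization of the mean squared error between
#' model-predicted and measured photocurrents, summed uniformly per sample
#' across all of the cell's stimulus/response pairs. The dark cGMP
#' concentration is fixed by the cell's measured dark current; the free
#' parameters default to (gamma, sigma, eta, K_GC) for rods and add beta
#' for cones, with sigma and phi tied. Positivity is enforced by searching
#' in log-parameters; the search restarts from perturbed optima.
#'
#' @param pairs List of recordings, each \code{list(stimulus =, response =)}
#'   with \code{"ptrace"} elements sharing \code{dt} and length.
#' @param dark_current Measured dark current magnitude, pA.
#' @param init Starting \code{"cascade_params"}; defaults to the consensus
#'   set for \code{cell_type}.
#' @param free Character vector of free parameter names.
#' @param tie_sigma_phi Keep \code{phi == sigma} during the fit.
#' @param restarts Number of perturbed-restart simplex runs after the first.
#' @param control Passed to [stats::optim()] (defaults: relative tolerance
#'   1e-8, 2000 iterations).
#' @param cell_type Used only when \code{init} is missing.
#' @return Object of class \code{"fit_result"}: fitted \code{params},
#'   \code{mse}, \code{fraction_variance}, and a per-restart
#'   \code{iterations} table.
#' @export
fit_cell <- function(pairs, dark_current, init = NULL, free = NULL,
                     tie_sigma_phi = TRUE, restarts = 3,
                     control = list(), cell_type = NULL) {
  if (!length(pairs)) stop("need at least one stimulus/response pair")
  init <- init %||% consensus_params(cell_type)
  free <- free %||% .default_free(init$cell_type)
  if ("phi" %in% free && tie_sigma_phi)
    stop("phi cannot be free while tied to sigma")
  control <- utils::modifyList(list(reltol = 1e-8, maxit = 2000), control)
  obj <- function(theta) {
    p <- .update_params(init, exp(theta), free, tie_sigma_phi)
    .cell_mse(p, dark_current, pairs)
  }
  theta0 <- log(unlist(unclass(init)[free], use.names = FALSE))
  run <- .simplex_restarts(obj, theta0, restarts, control)
  params <- .update_params(init, exp(run$best$par), free, tie_sigma_phi)
  .as_fit_result(params, NULL, run, pairs_list = list(pairs),
                 dark_currents = dark_current)
}

.as_fit_result <- function(params, per_cell_gamma, run, pairs_list,
                           dark_currents) {
  meas <- pred <- numeric(0)
  for (ci in seq_along(pairs_list)) {
    p <- params
    if (!is.null(per_cell_gamma)) {
      pl <- unclass(params); pl$gamma <- per_cell_gamma[ci]
      p <- do.call(cascade_params, pl)
    }
    dark <- dark_operating_point(p, dark_currents[ci])
    for (pr in pairs_list[[ci]]) {
      bg <- mean(pr$stimulus$values[seq_len(min(length(pr$stimulus$values),
                                                round(0.5 / pr$stimulus$dt)))])
      init <- steady_state(p, dark, bg)
      st <- simulate_cascade(p, dark, pr$stimulus,
                             initial = init[c("R", "P", "G", "C")])
      keep <- seq.int(min(length(st$I$values),
                          round(0.5 / pr$stimulus$dt) + 1L),
                      length(st$I$values))
      meas <- c(meas, pr$response$values[keep])
      pred <- c(pred, st$I$values[keep])
    }
  }
  structure(list(params = params, per_cell_gamma = per_cell_gamma,
                 mse = run$best$value,
                 fraction_variance = fraction_variance(meas, pred),
                 iterations = run$trace,
                 convergence = run$best$convergence),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> mse = %.5g, fraction of variance = %.4f\n",
              x$mse, x$fraction_variance))
  if (!is.null(x$per_cell_gamma))
    cat("  per-cell gamma:", paste(signif(x$per_cell_gamma, 4),
                                   collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}

#' Consensus fit across cells with shared parameters
#'
#' Joint simplex fit over multiple cells of one type: kinetic parameters
#' (sigma, eta, K_GC, plus beta for cones) are shared across cells, the
#' dark cGMP concentration is fixed per cell from its dark current, and
#' the opsin gain gamma is fitted per cell to absorb sensitivity
#' differences.
#'
#' @param cells List of cells, each \code{list(pairs =, dark_current =)}
#'   where \code{pairs} is as in [fit_cell()].
#' @inheritParams fit_cell
#' @param shared Names of the shared free parameters; default drops
#'   \code{"gamma"} from the per-class free set.
#' @return A \code{"fit_result"} whose \code{params} hold the shared
#'   values (with \code{gamma} from the first cell) and
#'   \code{per_cell_gamma} the per-cell gains.
#' @export
fit_consensus <- function(cells, init = NULL, shared = NULL,
                          tie_sigma_phi = TRUE, restarts = 3,
                          control = list(), cell_type = NULL) {
  if (!length(cells)) stop("need at least one cell")
  init <- init %||% consensus_params(cell_type)
  shared <- shared %||% setdiff(.default_free(init$cell_type), "gamma")
  control <- utils::modifyList(list(reltol = 1e-8, maxit = 3000), control)
  n_cells <- length(cells)
  obj <- function(theta) {
    sh <- exp(theta[seq_along(shared)])
    gam <- exp(theta[length(shared) + seq_len(n_cells)])
    tot_sse <- 0; tot_n <- 0
    for (ci in seq_len(n_cells)) {
      p <- .update_params(init, c(sh, gam[ci]), c(shared, "gamma"),
                          tie_sigma_phi)
      m <- .cell_mse(p, cells[[ci]]$dark_current, cells[[ci]]$pairs)
      nn <- sum(vapply(cells[[ci]]$pairs,
                       function(pr) length(pr$response$values), numeric(1)))
      tot_sse <- tot_sse + m * nn
      tot_n <- tot_n + nn
    }
    tot_sse / tot_n
  }
  theta0 <- c(log(unlist(unclass(init)[shared], use.names = FALSE)),
              rep(log(init$gamma), n_cells))
  run <- .simplex_restarts(obj, theta0, restarts, control)
  sh <- exp(run$best$par[seq_along(shared)])
  gam <- exp(run$best$par[length(shared) + seq_len(n_cells)])
  params <- .update_params(init, c(sh, gam[1L]), c(shared, "gamma"),
                           tie_sigma_phi)
  .as_fit_result(params, gam, run,
                 pairs_list = lapply(cells, `[[`, "pairs"),
                 dark_currents = vapply(cells, `[[`, numeric(1), "dark_current"))
}

#' MSE-doubling sensitivity range for one parameter
#'
#' Finds, on each side of the optimum, the parameter value at which the
#' fit MSE doubles while all other parameters are held at their fitted
#' values. When sigma and phi are tied, varying sigma varies both (the
#' model depends only on the smaller of the two, so varying sigma alone
#' above phi would never change the error). Bounds that cannot be reached
#' within the search range are returned as \code{NA} and flagged open.
#'
#' @param params_opt Fitted \code{"cascade_params"} (a local optimum for
#'   the data).
#' @param pairs,dark_current Data as in [fit_cell()].
#' @param param_name Parameter to vary.
#' @param factor MSE multiple defining the range (default 2).
#' @param search_span Multiplicative search range around the optimum.
#' @param tie_sigma_phi Vary \code{phi} together with \code{sigma}.
#' @return \code{c(lower, upper)} with attributes \code{"open"} (logical
#'   pair), \code{"mse_opt"}, and \code{"mse_at_bounds"}.
#' @export
sensitivity_range <- function(params_opt, pairs, dark_current, param_name,
                              factor = 2, search_span = c(0.05, 20),
                              tie_sigma_phi = TRUE) {
  stopifnot(inherits(params_opt, "cascade_params"))
  if (!param_name %in% names(unclass(params_opt)))
    stop("unknown parameter: ", param_name)
  theta0 <- params_opt[[param_name]]
  mse_at <- function(value)
    .cell_mse(.update_params(params_opt, value, param_name, tie_sigma_phi),
              dark_current, pairs)
  m0 <- mse_at(theta0)
  target <- factor * m0
  side <- function(bound_factor) {
    f <- function(lv) mse_at(exp(lv)) - target
    l0 <- log(theta0); l1 <- log(theta0 * bound_factor)
    if (f(l1) < 0) return(list(value = NA_real_, open = TRUE,
                               mse = mse_at(exp(l1))))
    root <- stats::uniroot(f, sort(c(l0, l1)), tol = 1e-6)
    list(value = exp(root$root), open = FALSE, mse = mse_at(exp(root$root)))
  }
  lo <- side(search_span[1L])
  hi <- side(search_span[2L])
  structure(c(lower = lo$value, upper = hi$value),
            open = c(lower = lo$open, upper = hi$open),
            mse_opt = m0,
            mse_at_bounds = c(lower = lo$mse, upper = hi$mse))
}

#' Finite-difference Hessian of a cost surface (sloppy-model analysis)
#'
#' Numerically approximates the Hessian of a cost function at a point by
#' central second differences over parameter pairs, symmetrizes it, and
#' eigendecomposes it into stiff (large-eigenvalue) and sloppy
#' (small-eigenvalue) parameter combinations. A gradient outer-product
#' variant is available.
#'
#' @param cost Function of a numeric parameter vector returning a scalar
#'   cost (e.g. from [cascade_cost_function()]).
#' @param theta Expansion point (near a local optimum for the
#'   second-difference reading to describe curvature of the fit).
#' @param rel_step Relative finite-difference step per parameter (absolute
#'   \code{rel_step} where a component is zero).
#' @param method \code{"second_diff"} (Hessian of the cost) or
#'   \code{"grad_outer"} (outer product of the cost gradient).
#' @return List with \code{H} (symmetric), \code{eigenvalues} (decreasing),
#'   \code{eigenvectors}, and \code{steps}.
#' @export
sloppy_hessian <- function(cost, theta, rel_step = 0.01,
                           method = c("second_diff", "grad_outer")) {
  method <- match.arg(method)
  k <- length(theta)
  h <- ifelse(theta == 0, rel_step, abs(theta) * rel_step)
  ei <- function(i) { e <- numeric(k); e[i] <- h[i]; e }
  H <- matrix(NA_real_, k, k)
  if (method == "second_diff") {
    f0 <- cost(theta)
    for (i in seq_len(k)) {
      H[i, i] <- (cost(theta + ei(i)) - 2 * f0 + cost(theta - ei(i))) / h[i]^2
      if (i < k) for (j in seq.int(i + 1L, k)) {
        H[i, j] <- H[j, i] <-
          (cost(theta + ei(i) + ei(j)) - cost(theta + ei(i) - ei(j)) -
           cost(theta - ei(i) + ei(j)) + cost(theta - ei(i) - ei(j))) /
          (4 * h[i] * h[j])
      }
    }
  } else {
    g <- vapply(seq_len(k), function(i)
      (cost(theta + ei(i)) - cost(theta - ei(i))) / (2 * h[i]), numeric(1))
    H <- outer(g, g)
  }
  if (!all(is.finite(H))) {
    bad <- which(!is.finite(H), arr.ind = TRUE)[1L, ]
    stop("non-finite Hessian entry for parameter pair (", bad[1L], ", ",
         bad[2L], ")")
  }
  H <- (H + t(H)) / 2
  eig <- eigen(H, symmetric = TRUE)
  list(H = H, eigenvalues = eig$values, eigenvectors = eig$vectors,
       steps = h)
}

#' Cost function over cascade parameters for sensitivity analyses
#'
#' Builds the scalar MSE cost used by [sloppy_hessian()]: a function of a
#' named free-parameter vector that substitutes the values into
#' \code{params}, derives the dark state from \code{dark_current}, and
#' returns the fit MSE on \code{pairs}.
#'
#' @inheritParams fit_cell
#' @param params Baseline \code{"cascade_params"} (typically a fit optimum).
#' @return Function mapping a numeric vector (ordered as \code{free}) to
#'   the MSE.
#' @export
cascade_cost_function <- function(pairs, dark_current, params, free = NULL,
                                  tie_sigma_phi = TRUE) {
  free <- free %||% .default_free(params$cell_type)
  function(theta) {
    stopifnot(length(theta) == length(free))
    .cell_mse(.update_params(params, theta, free, tie_sigma_phi),
              dark_current, pairs)
  }
}
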