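#' Phototransduction cascade parameters
#'
#' The eleven biochemical parameters of the cascade model. Light activates
#' opsin with gain \code{gamma}; active opsin decays at rate \code{sigma}
#' and drives phosphodiesterase (PDE), whose activity decays at rate
#' \code{phi} with spontaneous activation rate \code{eta}. cGMP is
#' hydrolyzed by PDE and synthesized by guanylate cyclase; synthesis is
#' accelerated when calcium falls (Hill curve with affinity \code{k_gc},
#' cooperativity \code{m}). The outer-segment current is
#' \code{I = k * G^n}; calcium enters through the channels and is extruded
#' at rate \code{beta}.
#'
#' @param gamma Opsin gain (unitless, > 0).
#' @param sigma Opsin decay rate constant (s^-1).
#' @param phi PDE decay rate constant (s^-1). Model output depends only on
#'   the smaller of \code{sigma} and \code{phi}; consensus models tie them.
#' @param eta Spontaneous (dark) PDE activation rate (s^-1).
#' @param k cGMP-to-current constant (pA per uM^n).
#' @param n cGMP channel cooperativity (>= 1).
#' @param m Cooperativity of the cyclase calcium dependence (>= 1).
#' @param beta Calcium extrusion rate constant (s^-1).
#' @param k_gc Affinity of the cyclase calcium dependence (uM).
#' @param c_dark Dark calcium concentration (uM).
#' @param cell_type One of \code{"primate_cone"}, \code{"mouse_cone"},
#'   \code{"primate_rod"}, \code{"mouse_rod"}, or \code{NA} for a custom set.
#' @return Object of class \code{"cascade_params"}.
#' @seealso [consensus_params()], [dark_operating_point()]
#' @export
cascade_params <- function(gamma, sigma, phi, eta, k, n, m, beta, k_gc,
                           c_dark, cell_type = NA_character_) {
  p <- list(gamma = gamma, sigma = sigma, phi = phi, eta = eta, k = k,
            n = n, m = m, beta = beta, k_gc = k_gc, c_dark = c_dark,
            cell_type = cell_type)
  num <- p[setdiff(names(p), "cell_type")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1L))))
    stop("all cascade parameters must be single finite numbers")
  positive <- c("gamma", "sigma", "phi", "eta", "k", "beta", "k_gc", "c_dark")
  for (nm in positive)
    if (p[[nm]] <= 0) stop("parameter `", nm, "` must be strictly positive")
  if (p$n < 1 || p$m < 1) stop("cooperativities `n` and `m` must be >= 1")
  if (!is.na(cell_type) && !cell_type %in% names(.consensus_table))
    stop("unknown cell_type: ", cell_type, " (supported: ",
         paste(names(.consensus_table), collapse = ", "), ")")
  structure(p, class = "cascade_params")
}

# Consensus parameter values per photoreceptor type. sigma and phi are tied;
# k, n, m, c_dark are fixed across types; beta is fixed for rods and free
# (fitted) for cones.
.consensus_table <- list(
  primate_cone = list(sigma = 22,   eta = 2000, beta = 9,    k_gc = 0.5, gamma = 10),
  mouse_cone   = list(sigma = 9.74, eta = 761,  beta = 2.64, k_gc = 0.4, gamma = 10),
  primate_rod  = list(sigma = 7.07, eta = 2.53, beta = 25,   k_gc = 0.5, gamma = 4.2),
  mouse_rod    = list(sigma = 7.66, eta = 1.62, beta = 25,   k_gc = 0.4, gamma = 8)
)

# Default (magnitude of) dark current per type, pA: the upper end of the
# measured ranges, consistent with the upper derived dark cGMP values.
.default_dark_current <- c(primate_cone = 428, mouse_cone = 80,
                           primate_rod = 37, mouse_rod = 24)

# Reference integration step, s: 0.1 ms for cones, 1 ms for rods.
.default_dt <- c(primate_cone = 1e-4, mouse_cone = 1e-4,
                 primate_rod = 1e-3, mouse_rod = 1e-3)

# Recoverable stimulus band per type, Hz.
.default_band_limit <- c(primate_cone = 60, mouse_cone = 30,
                         primate_rod = 15, mouse_rod = 15)

#' Consensus model parameters for a photoreceptor type
#'
#' Returns the consensus parameter set for one of the four supported
#' photoreceptor types. The opsin and PDE decay rates are tied
#' (\code{sigma == phi}); \code{k = 0.01}, \code{n = 3}, \code{m = 4} and
#' \code{c_dark = 1} uM are fixed for all types.
#'
#' @param cell_type \code{"primate_cone"}, \code{"mouse_cone"},
#'   \code{"primate_rod"}, or \code{"mouse_rod"}.
#' @return A \code{"cascade_params"} object.
#' @examples
#' consensus_params("primate_cone")$eta  # 2000 s^-1
#' @export
consensus_params <- function(cell_type) {
  if (!is.character(cell_type) || length(cell_type) != 1L ||
      !cell_type %in% names(.consensus_table))
    stop("unsupported cell_type: ", paste(cell_type, collapse = ", "),
         " (supported: ", paste(names(.consensus_table), collapse = ", "), ")")
  v <- .consensus_table[[cell_type]]
  cascade_params(gamma = v$gamma, sigma = v$sigma, phi = v$sigma,
                 eta = v$eta, k = 0.01, n = 3, m = 4, beta = v$beta,
                 k_gc = v$k_gc, c_dark = 1, cell_type = cell_type)
}

#' Default dark current, time step, and stimulus band per cell type
#'
#' Conveniences exposing the per-type defaults used throughout:
#' dark-current magnitude (pA, the upper end of the measured ranges),
#' reference integration step (0.1 ms cones, 1 ms rods), and the
#' recoverable stimulus band limit (60 Hz primate cones, 30 Hz mouse cones,
#' 15 Hz rods).
#'
#' @param cell_type Photoreceptor type tag.
#' @return A single number.
#' @export
default_dark_current <- function(cell_type) {
  .lookup_default(.default_dark_current, cell_type)
}

#' @rdname default_dark_current
#' @export
default_dt <- function(cell_type) .lookup_default(.default_dt, cell_type)

#' @rdname default_dark_current
#' @export
default_band_limit <- function(cell_type) {
  .lookup_default(.default_band_limit, cell_type)
}

.lookup_default <- function(table, cell_type) {
  if (!is.character(cell_type) || length(cell_type) != 1L ||
      !cell_type %in% names(table))
    stop("unsupported cell_type: ", paste(cell_type, collapse = ", "))
  unname(table[[cell_type]])
}

#' @export
print.cascade_params <- function(x, ...) {
  cat(sprintf("<cascade_params> cell_type = %s\n", x$cell_type))
  cat(sprintf("  gamma = %g, sigma = %g s^-1, phi = %g s^-1, eta = %g s^-1\n",
              x$gamma, x$sigma, x$phi, x$eta))
  cat(sprintf("  k = %g pA/uM^n, n = %g, m = %g, beta = %g s^-1, k_gc = %g uM, c_dark = %g uM\n",
              x$k, x$n, x$m, x$beta, x$k_gc, x$c_dark))
  invisible(x)
}

#' Dark operating point of the cascade
#'
#' Derives the dark (zero-light) steady state from the measured dark
#' current. With no stimulus, opsin activity is zero and PDE activity rests
#' at \code{eta/phi}; the dark cGMP concentration follows from the current
#' relation as \code{G_D = (I_D/k)^(1/n)}. Two parameters are fixed by
#' requiring the dark state to be a fixed point: the current-to-calcium
#' conversion \code{q = beta * c_dark / I_D} and the maximal cyclase rate
#' \code{s_max = G_D * (eta/phi) * (1 + (c_dark/k_gc)^m)}.
#'
#' Dark currents may be supplied with either sign (recordings list them as
#' negative); the magnitude is used.
#'
#' @param params A \code{"cascade_params"} object.
#' @param dark_current Measured dark current, pA (nonzero; sign ignored).
#' @return Object of class \code{"dark_point"} with fields \code{i_dark},
#'   \code{g_dark}, \code{p_dark}, \code{q}, \code{s_max}.
#' @examples
#' dark_operating_point(consensus_params("mouse_cone"), 80)$g_dark  # 20 uM
#' @export
dark_operating_point <- function(params, dark_current) {
  stopifnot(inherits(params, "cascade_params"))
  if (!is.numeric(dark_current) || length(dark_current) != 1L ||
      !is.finite(dark_current) || dark_current == 0)
    stop("`dark_current` must be a single nonzero current in pA")
  i_dark <- abs(dark_current)
  g_dark <- (i_dark / params$k)^(1 / params$n)
  p_dark <- params$eta / params$phi
  q <- params$beta * params$c_dark / i_dark
  s_max <- g_dark * p_dark * (1 + (params$c_dark / params$k_gc)^params$m)
  structure(list(i_dark = i_dark, g_dark = g_dark, p_dark = p_dark,
                 q = q, s_max = s_max),
            class = "dark_point")
}

#' @export
print.dark_point <- function(x, ...) {
  cat(sprintf("<dark_point> I_D = %g pA, G_D = %g uM, P_D = %g s^-1\n",
              x$i_dark, x$g_dark, x$p_dark))
  cat(sprintf("  q = %g uM/s/pA, S_max = %g uM/s\n", x$q, x$s_max))
  invisible(x)
}

#' Save / load parameter sets as YAML
#'
#' Parameter sets (and fitted linear filters, see
#' [linear_filter_params()]) round-trip through a small YAML config, one
#' file per parameter set.
#'
#' @param params A \code{"cascade_params"} or \code{"linear_filter"} object.
#' @param path File path.
#' @return \code{read_params()} returns the reconstructed object.
#' @export
write_params <- function(params, path) {
  if (inherits(params, "cascade_params")) {
    out <- c(list(kind = "cascade_params"), unclass(params))
  } else if (inherits(params, "linear_filter")) {
    out <- c(list(kind = "linear_filter"), unclass(params))
  } else stop("unsupported object; expected cascade_params or linear_filter")
  out <- lapply(out, function(v) if (is.na(v) && !is.numeric(v)) NULL else v)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  v <- yaml::read_yaml(path)
  kind <- v$kind
  v$kind <- NULL
  if (identical(kind, "cascade_params")) {
    do.call(cascade_params, c(v[c("gamma", "sigma", "phi", "eta", "k", "n",
                                  "m", "beta", "k_gc", "c_dark")],
                              list(cell_type = if (is.null(v$cell_type))
                                NA_character_ else v$cell_type)))
  } else if (identical(kind, "linear_filter")) {
    linear_filter_params(alpha = v$alpha, tau_r = v$tau_r, tau_d = v$tau_d,
                         mean_level = v$mean_level,
                         cell_type = if (is.null(v$cell_type))
                           NA_character_ else v$cell_type)
  } else stop("unrecognized parameter file kind: ", kind)
}
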