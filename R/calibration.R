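#' Spectral curve (emission or sensitivity)
#'
#' Two-column wavelength/value table: relative power per wavelength for an
#' emitter, or probability of isomerization per photon for a receptor's
#' spectral sensitivity.
#'
#' @param wavelengths Wavelength grid, nm, strictly increasing.
#' @param values Nonnegative per-wavelength magnitudes.
#' @return Object of class \code{"spectral_curve"}.
#' @export
spectral_curve <- function(wavelengths, values) {
  if (length(wavelengths) != length(values) || length(wavelengths) < 2L)
    stop("need matching wavelength/value vectors of length >= 2")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(values < 0)) stop("spectral values must be nonnegative")
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values)),
            class = "spectral_curve")
}

#' Collecting area of a photoreceptor class
#'
#' Effective area converting photon-flux density into isomerization rate:
#' 1 um^2 for primate rods, 0.37 um^2 for primate cones, 0.5 um^2 for
#' mouse rods, 0.2 um^2 for mouse cones.
#'
#' @param cell_type Photoreceptor type tag.
#' @return Collecting area, um^2.
#' @export
collecting_area <- function(cell_type) {
  .lookup_default(c(primate_rod = 1, primate_cone = 0.37,
                    mouse_rod = 0.5, mouse_cone = 0.2), cell_type)
}

.PLANCK <- 6.62607015e-34   # J s
.C_LIGHT <- 2.99792458e8    # m/s

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Convert optical power to isomerization rate
#'
#' Three-step calibration: (1) total power over the illuminated spot
#' becomes a power density (W/um^2); (2) the emission spectrum is rescaled
#' so its integral over wavelength matches that density; (3) the rescaled
#' spectrum is converted to photon-flux density per wavelength (dividing
#' by photon energy hc/lambda) and integrated against the receptor's
#' per-photon spectral sensitivity, scaled by the collecting area.
#' The integration is photon-weighted (not energy-weighted) because
#' sensitivities are probabilities per photon.
#'
#' @param total_power Calibrated power at the preparation, W (> 0).
#' @param emission Emitter spectrum, a \code{"spectral_curve"} (any
#'   normalization; only the shape matters after step 2).
#' @param sensitivity Receptor spectral sensitivity, probability of
#'   isomerization per photon at each wavelength.
#' @param cell_type Receptor class for the collecting area; alternatively
#'   pass \code{area} directly.
#' @param spot_diameter Diameter of the uniformly illuminated spot, um
#'   (default 600 um).
#' @param area Collecting area override, um^2.
#' @return Isomerization rate, R*/s.
#' @examples
#' em <- spectral_curve(c(480, 500, 520), c(0, 1, 0))
#' sens <- spectral_curve(c(400, 700), c(1, 1))
#' power_to_isomerizations(1e-12, em, sens, "primate_rod")
#' @export
power_to_isomerizations <- function(total_power, emission, sensitivity,
                                    cell_type = NULL, spot_diameter = 600,
                                    area = NULL) {
  stopifnot(inherits(emission, "spectral_curve"),
            inherits(sensitivity, "spectral_curve"))
  if (total_power <= 0 || spot_diameter <= 0)
    stop("power and spot diameter must be positive")
  area <- area %||% collecting_area(cell_type)
  density <- total_power / (pi * (spot_diameter / 2)^2)  # W/um^2

  lo <- max(min(emission$wavelengths), min(sensitivity$wavelengths))
  hi <- min(max(emission$wavelengths), max(sensitivity$wavelengths))
  if (lo >= hi)
    stop("emission and sensitivity spectra have no overlapping wavelengths")
  wl <- sort(unique(c(emission$wavelengths[emission$wavelengths >= lo &
                                             emission$wavelengths <= hi],
                      lo, hi)))
  em <- stats::approx(emission$wavelengths, emission$values, wl)$y
  sens <- stats::approx(sensitivity$wavelengths, sensitivity$values, wl)$y

  em_integral <- .trapz(wl, em)
  if (em_integral <= 0) stop("emission spectrum has zero power in the overlap")
  em_scaled <- em * density / em_integral          # W/um^2/nm
  photon_flux <- em_scaled * (wl * 1e-9) / (.PLANCK * .C_LIGHT)  # photons/s/um^2/nm
  area * .trapz(wl, photon_flux * sens)
}
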