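# Inherent-optical-property model of water transparency.
#
# Secchi depth is modelled as SD = gamma / (c + Kd), where the beam
# attenuation c = a + b is assembled from component-specific absorption and
# scattering of chlorophyll-a, inorganic suspended solids (ISS) and detritus
# carbon (DC), and Kd is Kirk's downwelling diffuse attenuation
# Kd = (a / mu0) * sqrt(1 + (0.425 * mu0 - 0.19) * b / a).
# All coefficients are broadband (PAR-averaged); there is no spectral
# resolution.

#' Optical coefficient set for the transparency model
#'
#' Bundles every coefficient of the Secchi-depth model: the contrast-threshold
#' coupling constant `gamma`, pure-water and constituent-specific absorption
#' and scattering coefficients, and the average cosine of the refracted solar
#' angle `mu0`. Concentration units are chlorophyll-a in µg/L (numerically
#' equal to mg/m³), ISS and DC in mg/L (numerically equal to g/m³), so the
#' m²/mg and m²/g specific coefficients yield attenuation in 1/m directly.
#'
#' `b_phi`, `b_dc` and `mu0` are not constrained by the calibrated optical
#' parameter set this package ships; their defaults are package choices
#' (a conventional clear-sky average cosine for `mu0`, a moderate
#' phytoplankton-specific scattering for `b_phi`, and half the ISS-specific
#' scattering for `b_dc`). Set `verbose = TRUE` to be reminded whenever these
#' defaults are in effect.
#'
#' @param gamma Contrast-threshold coupling constant (m). Default 8.9.
#' @param a_w Pure-water absorption (1/m). Default 0.050.
#' @param a_phi Chlorophyll-specific absorption (m²/mg Chl-a). Default 0.020.
#' @param a_iss ISS-specific absorption (m²/g ISS). Default 0.08.
#' @param a_dc Detritus-carbon-specific absorption (m²/g DC). Default 0.24.
#' @param b_w Pure-water scattering (1/m). Default 0.0019.
#' @param b_phi Chlorophyll-specific scattering (m²/mg Chl-a). Default 0.12
#'   (package default, not part of the calibrated set).
#' @param b_iss ISS-specific scattering (m²/g ISS). Default 0.025.
#' @param b_dc Detritus-carbon-specific scattering (m²/g DC). Default
#'   `0.5 * b_iss` (package default).
#' @param mu0 Average cosine of the refracted solar angle, dimensionless in
#'   (0, 1]. Default 0.856 (package default).
#' @param wavelength_note Metadata string recording the broadband treatment.
#' @param verbose If `TRUE`, message when unprinted coefficients take their
#'   package defaults.
#' @return An object of class `optical_coefficients` (a named list).
#' @examples
#' oc <- optical_coefficients()
#' oc$a_w
#' @export
optical_coefficients <- function(gamma = 8.9,
                                 a_w = 0.050, a_phi = 0.020,
                                 a_iss = 0.08, a_dc = 0.24,
                                 b_w = 0.0019, b_phi = 0.12,
                                 b_iss = 0.025, b_dc = 0.5 * b_iss,
                                 mu0 = 0.856,
                                 wavelength_note = "broadband (PAR-averaged); no spectral resolution",
                                 verbose = FALSE) {
  vals <- c(gamma = gamma, a_w = a_w, a_phi = a_phi, a_iss = a_iss,
            a_dc = a_dc, b_w = b_w, b_phi = b_phi, b_iss = b_iss,
            b_dc = b_dc, mu0 = mu0)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all optical coefficients must be finite and non-negative")
  }
  if (gamma <= 0) stop("gamma must be positive")
  if (mu0 <= 0 || mu0 > 1) stop("mu0 must lie in (0, 1]")
  if (verbose) {
    defaulted <- c(
      if (missing(b_phi)) "b_phi = 0.12 m2/mg Chl-a",
      if (missing(b_dc)) "b_dc = 0.5 * b_iss",
      if (missing(mu0)) "mu0 = 0.856"
    )
    if (length(defaulted)) {
      message("using package defaults for uncalibrated optical coefficients: ",
              paste(defaulted, collapse = "; "))
    }
  }
  structure(
    list(gamma = gamma, a_w = a_w, a_phi = a_phi, a_iss = a_iss, a_dc = a_dc,
         b_w = b_w, b_phi = b_phi, b_iss = b_iss, b_dc = b_dc, mu0 = mu0,
         wavelength_note = wavelength_note),
    class = "optical_coefficients"
  )
}

# Extract (and validate) the optically active constituent concentrations from
# a lake_state, list or data.frame. Returns a list of equal-length vectors.
as_constituents <- function(state) {
  if (inherits(state, "lake_state")) {
    x <- list(chl = state$chl, iss = state$iss, dc = state$dc)
  } else if (is.data.frame(state) || is.list(state)) {
    missing_cols <- setdiff(c("chl", "iss", "dc"), names(state))
    if (length(missing_cols)) {
      stop("state must carry constituents: missing ",
           paste(missing_cols, collapse = ", "))
    }
    x <- list(chl = as.numeric(state$chl), iss = as.numeric(state$iss),
              dc = as.numeric(state$dc))
  } else {
    stop("state must be a lake_state, list or data.frame")
  }
  for (nm in names(x)) {
    if (any(!is.finite(x[[nm]]))) {
      stop("non-finite concentration for constituent '", nm, "'")
    }
    if (any(x[[nm]] < 0)) {
      stop("negative concentration for constituent '", nm, "'")
    }
  }
  x
}

#' Total absorption coefficient
#'
#' Sums pure-water absorption and the constituent-specific contributions of
#' chlorophyll-a (µg/L), ISS (mg/L) and detritus carbon (mg/L). Because
#' 1 µg/L = 1 mg/m³ and 1 mg/L = 1 g/m³, the concentrations multiply the
#' m²/mg and m²/g coefficients without further conversion.
#'
#' @param state A [lake_state()], or a list/data.frame with elements `chl`,
#'   `iss`, `dc` (vectorized).
#' @param coeffs An [optical_coefficients()] set.
#' @return Total absorption in 1/m; always `>= coeffs$a_w`.
#' @examples
#' absorption(list(chl = 10, iss = 20, dc = 1)) # 2.090
#' @export
absorption <- function(state, coeffs = optical_coefficients()) {
  x <- as_constituents(state)
  coeffs$a_w + coeffs$a_phi * x$chl + coeffs$a_iss * x$iss + coeffs$a_dc * x$dc
}

#' Total scattering coefficient
#'
#' As [absorption()], with the scattering coefficients.
#'
#' @inheritParams absorption
#' @return Total scattering in 1/m; always `>= coeffs$b_w`.
#' @examples
#' scattering(list(chl = 0, iss = 31, dc = 0)) # 0.7769
#' @export
scattering <- function(state, coeffs = optical_coefficients()) {
  x <- as_constituents(state)
  coeffs$b_w + coeffs$b_phi * x$chl + coeffs$b_iss * x$iss + coeffs$b_dc * x$dc
}

#' Beam attenuation coefficient
#'
#' The exact sum `c = a + b` of total absorption and total scattering.
#'
#' @param a Total absorption (1/m), non-negative.
#' @param b Total scattering (1/m), non-negative.
#' @return Beam attenuation in 1/m.
#' @export
beam_attenuation <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a < 0) || any(b < 0)) {
    stop("a and b must be finite and non-negative")
  }
  a + b
}

#' Downwelling diffuse attenuation coefficient (Kirk)
#'
#' `Kd = (a / mu0) * sqrt(1 + (0.425 * mu0 - 0.19) * b / a)`. At `b = 0` this
#' collapses to `a / mu0`; for `mu0 <= 1` it is never smaller than `a`. The
#' radicand is guaranteed non-negative for `mu0 >= 0.19 / 0.425`; inputs that
#' make it negative are rejected.
#'
#' @param a Total absorption (1/m), strictly positive.
#' @param b Total scattering (1/m), non-negative.
#' @param mu0 Average cosine of the refracted solar angle in (0, 1].
#' @return Diffuse attenuation in 1/m.
#' @examples
#' diffuse_attenuation(0.050, 0.0019, mu0 = 1)
#' @export
diffuse_attenuation <- function(a, b, mu0 = 0.856) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("a must be finite and strictly positive (Kd divides by a)")
  }
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be finite and non-negative")
  if (length(mu0) != 1 || !is.finite(mu0) || mu0 <= 0 || mu0 > 1) {
    stop("mu0 must be a single value in (0, 1]")
  }
  radicand <- 1 + (0.425 * mu0 - 0.19) * b / a
  if (any(radicand < 0)) {
    stop("negative radicand in Kirk's formula; mu0 = ", mu0,
         " is below the admissible range for these a, b")
  }
  a * sqrt(radicand) / mu0
}

#' Secchi depth from constituent concentrations
#'
#' Composes the absorption, scattering, beam-attenuation and
#' diffuse-attenuation operations into `SD = gamma / (c + Kd)`. Strictly
#' decreasing in each constituent concentration.
#'
#' @inheritParams absorption
#' @return Secchi depth in metres.
#' @examples
#' secchi_depth(list(chl = 10, iss = 20, dc = 1))
#' @export
secchi_depth <- function(state, coeffs = optical_coefficients()) {
  a <- absorption(state, coeffs)
  b <- scattering(state, coeffs)
  cc <- beam_attenuation(a, b)
  kd <- diffuse_attenuation(a, b, coeffs$mu0)
  coeffs$gamma / (cc + kd)
}

#' Full optical budget
#'
#' @inheritParams absorption
#' @return A tibble with columns `a`, `b`, `c`, `kd` (all 1/m) and `sd` (m),
#'   one row per input state.
#' @export
optical_budget <- function(state, coeffs = optical_coefficients()) {
  a <- absorption(state, coeffs)
  b <- scattering(state, coeffs)
  cc <- beam_attenuation(a, b)
  kd <- diffuse_attenuation(a, b, coeffs$mu0)
  tibble::tibble(a = a, b = b, c = cc, kd = kd,
                 sd = coeffs$gamma / (cc + kd))
}
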