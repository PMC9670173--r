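# Temperature-dependent pure-water properties and the Grueneisen parameter.
#
# Correlation sources (all at atmospheric pressure, plain water):
#   density          Kell (1975), J. Chem. Eng. Data 20:97, rational polynomial
#   expansion coeff  analytic derivative of the Kell polynomial, beta = -rho'/rho
#   sound speed      Marczak (1997), J. Acoust. Soc. Am. 102:2776, degree-5 fit
#   heat capacity    quartic least-squares fit to IAPWS-95 isobaric values at
#                    0.1013 MPa, 0-60 degC (fit residual < 0.6 J/kg/K)

.kell_num <- c(999.83952, 16.945176, -7.9870401e-3, -46.170461e-6,
               105.56302e-9, -280.54253e-12)
.kell_den <- 16.879850e-3
.marczak <- c(1.402385e3, 5.038813, -5.799136e-2, 3.287156e-4,
              -1.398845e-6, 2.787860e-9)
.cp_fit <- c(4217.295, -3.492013, 0.1152271, -1.697381e-3, 9.921843e-6)

.polyval_asc <- function(coef, x) {
  # coefficients in ascending order
  out <- 0
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

#' Density of pure water
#'
#' Kell (1975) correlation for air-free water at atmospheric pressure.
#'
#' @param temperature Temperature in degrees Celsius.
#' @return Density in kg m^-3.
#' @export
water_density <- function(temperature) {
  .polyval_asc(.kell_num, temperature) / (1 + .kell_den * temperature)
}

#' Speed of sound in pure water
#'
#' Marczak (1997) correlation at atmospheric pressure.
#'
#' @inheritParams water_density
#' @return Sound speed in m s^-1.
#' @export
water_sound_speed <- function(temperature) {
  .polyval_asc(.marczak, temperature)
}

#' Volumetric thermal expansion coefficient of pure water
#'
#' Analytic derivative of the Kell (1975) density correlation,
#' beta = -(1/rho) drho/dT. Negative below the density maximum near 4 degC.
#'
#' @inheritParams water_density
#' @return Expansion coefficient in K^-1.
#' @export
water_expansion_coeff <- function(temperature) {
  t <- temperature
  num <- .polyval_asc(.kell_num, t)
  dnum <- .polyval_asc(.kell_num[-1] * seq_len(5), t)
  den <- 1 + .kell_den * t
  drho <- (dnum * den - num * .kell_den) / den^2
  -(drho / den) / (num / den^2) # = -drho/rho with rho = num/den
}

#' Isobaric specific heat capacity of pure water
#'
#' @inheritParams water_density
#' @return Heat capacity in J kg^-1 K^-1.
#' @export
water_heat_capacity <- function(temperature) {
  .polyval_asc(.cp_fit, temperature)
}

#' Water properties and Grueneisen parameter at a given temperature
#'
#' Bundles the temperature-dependent pure-water properties needed to convert
#' deposited dose into initial acoustic pressure and time of flight into
#' distance. The dimensionless Grueneisen parameter
#' \deqn{\Gamma = \beta v_s^2 / C_p}
#' is the thermoacoustic conversion efficiency: the initial pressure rise per
#' unit volumetric energy density deposited under stress confinement.
#'
#' Any entry of `overrides` replaces the correlated value (for example to pin
#' the sound speed to an experimentally adopted value); the Grueneisen
#' parameter is always recomputed from the possibly overridden
#' `expansion_coeff`, `sound_speed` and `heat_capacity`.
#'
#' @param temperature Water temperature in degrees Celsius, 0 < T < 60.
#' @param overrides Optional named list with any of `density`, `sound_speed`,
#'   `expansion_coeff`, `heat_capacity` (SI units as in the return value).
#' @return An object of class `medium_properties`: a list with fields
#'   `temperature` (degC), `density` (kg m^-3), `sound_speed` (m s^-1),
#'   `expansion_coeff` (K^-1), `heat_capacity` (J kg^-1 K^-1) and `gruneisen`
#'   (dimensionless).
#' @examples
#' water_properties(20.1)$gruneisen # about 0.108
#' @export
water_properties <- function(temperature, overrides = list()) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature)) {
    stop("`temperature` must be a single finite number (degC)")
  }
  if (temperature <= 0 || temperature >= 60) {
    stop("temperature ", temperature,
         " degC is outside the validity range (0, 60) of the water correlations")
  }
  bad <- setdiff(names(overrides),
                 c("density", "sound_speed", "expansion_coeff", "heat_capacity"))
  if (length(bad)) stop("unknown override field(s): ", paste(bad, collapse = ", "))
  pick <- function(name, value) {
    if (!is.null(overrides[[name]])) overrides[[name]] else value
  }
  rho <- pick("density", water_density(temperature))
  vs <- pick("sound_speed", water_sound_speed(temperature))
  beta <- pick("expansion_coeff", water_expansion_coeff(temperature))
  cp <- pick("heat_capacity", water_heat_capacity(temperature))
  structure(list(
    temperature = temperature,
    density = rho,
    sound_speed = vs,
    expansion_coeff = beta,
    heat_capacity = cp,
    gruneisen = beta * vs^2 / cp
  ), class = "medium_properties")
}

#' @export
print.medium_properties <- function(x, ...) {
  cat(sprintf("water at %.2f degC:\n", x$temperature))
  cat(sprintf("  density          %9.2f kg/m^3\n", x$density))
  cat(sprintf("  sound speed      %9.2f m/s\n", x$sound_speed))
  cat(sprintf("  expansion coeff  %9.3e 1/K\n", x$expansion_coeff))
  cat(sprintf("  heat capacity    %9.1f J/kg/K\n", x$heat_capacity))
  cat(sprintf("  Grueneisen       %9.4f\n", x$gruneisen))
  invisible(x)
}
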