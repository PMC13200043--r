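#' Angular velocity of a rotating nanochain
#'
#' Converts a rotation frequency in Hz to angular velocity in rad/s,
#' `omega = 2 * pi * freq`.
#'
#' @param freq Rotation frequency in Hz. Must be non-negative. Vectorised.
#' @return Angular velocity in rad/s.
#' @examples
#' angular_velocity(3)  # 18.8496 rad/s
#' @export
angular_velocity <- function(freq) {
  if (!is.numeric(freq) || anyNA(freq)) {
    stop("`freq` must be a numeric rotation frequency in Hz", call. = FALSE)
  }
  if (any(freq < 0)) {
    stop("rotation frequency must be >= 0 Hz (got ",
         min(freq), ")", call. = FALSE)
  }
  2 * pi * freq
}

#' Capillary pressure of a porous membrane
#'
#' Young-Laplace estimate used to drive the Lucas-Washburn wetting front:
#' `P_cap = 2 * gamma / pore`.
#'
#' @param gamma Surface tension in N/m (>= 0). Vectorised.
#' @param pore Characteristic pore size in m (> 0). Vectorised.
#' @return Capillary pressure in Pa.
#' @examples
#' capillary_pressure(0.072, 20e-6)  # 7200 Pa
#' @export
capillary_pressure <- function(gamma, pore) {
  if (!is.numeric(gamma) || !is.numeric(pore)) {
    stop("`gamma` and `pore` must be numeric", call. = FALSE)
  }
  if (any(pore <= 0)) {
    stop("pore size must be > 0 m (got ", min(pore), ")", call. = FALSE)
  }
  2 * gamma / pore
}

#' Convert a per-molar rate constant to SI units
#'
#' Single audited conversion from the biochemist's 1/(M*s) to the SI
#' m^3/(mol*s) used internally: 1 M = 1 mol/L = 1000 mol/m^3, hence the
#' factor 1/1000.
#'
#' @param k Rate constant in 1/(M*s).
#' @return Rate constant in m^3/(mol*s).
#' @export
per_molar_rate_to_si <- function(k) {
  if (!is.numeric(k)) stop("`k` must be numeric", call. = FALSE)
  k / 1000
}

#' Test-line association rate constant in SI units
#'
#' The membrane model parameterises the antibody-nanochain association rate
#' through the dimensionless binding-efficiency factor `N_Abs`:
#' `kon = N_Abs * 1e4` per molar per second, which this helper returns in
#' SI units (`N_Abs * 10` m^3/(mol*s)).
#'
#' @param N_Abs Dimensionless binding-efficiency factor (>= 0). Vectorised.
#' @return Association rate constant in m^3/(mol*s).
#' @examples
#' si_association_rate(100)  # 1000 m^3/(mol*s)
#' @export
si_association_rate <- function(N_Abs) {
  if (!is.numeric(N_Abs) || anyNA(N_Abs)) {
    stop("`N_Abs` must be numeric", call. = FALSE)
  }
  if (any(N_Abs < 0)) {
    stop("`N_Abs` must be >= 0 (got ", min(N_Abs), ")", call. = FALSE)
  }
  per_molar_rate_to_si(N_Abs * 1e4)
}
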