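#' Reynolds number
#'
#' \eqn{Re = \rho U Z / \mu}: inertial versus viscous forces. `U` is a
#' reference velocity, operationally the maximum velocity in the channel.
#'
#' @param rho Fluid density, kg m^-3.
#' @param U Reference velocity, m s^-1.
#' @param Z Channel half-thickness, m.
#' @param mu Dynamic viscosity, Pa s (> 0).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(rho, U, Z, mu) {
  if (any(mu <= 0)) stop("viscosity must be > 0")
  rho * U * Z / mu
}

#' Dimensionless frequency number
#'
#' \eqn{N_f = \rho f^2 d^5 / (F / L)}: membrane resistance relative to the
#' stress generated by the oscillating flow. `F` is the flexural rigidity in
#' N m^2 per unit width.
#'
#' @param rho Fluid density, kg m^-3.
#' @param f Oscillation frequency, s^-1.
#' @param d Membrane thickness, m.
#' @param F Flexural rigidity, N m^2 (> 0).
#' @param L Membrane length, m.
#' @return Dimensionless frequency number.
#' @export
freq_number <- function(rho, f, d, F, L) {
  if (any(F <= 0)) stop("flexural rigidity must be > 0")
  rho * f^2 * d^5 / (F / L)
}

#' Channel-membrane aspect ratio
#'
#' \eqn{\Lambda = Z / L}: channel half-thickness over membrane length.
#'
#' @param Z Channel half-thickness, m.
#' @param L Membrane length, m (> 0).
#' @return Dimensionless aspect ratio.
#' @export
aspect_ratio <- function(Z, L) {
  if (any(L <= 0)) stop("membrane length must be > 0")
  Z / L
}

#' Membrane deformation number
#'
#' \eqn{N_R = Re \cdot N_f = \rho^2 f^2 d^5 U Z / (\mu F / L)}: the
#' composite group comparing forces that deform the membrane with those that
#' oppose deformation. Scenarios with equal `N_R` produce the same type of
#' membrane deformation even when `Re`, `N_f`, `f` and `U` differ.
#'
#' @param Re Reynolds number.
#' @param N_f Frequency number.
#' @return Dimensionless membrane number.
#' @export
membrane_number <- function(Re, N_f) Re * N_f

#' Full dimensionless characterization of a scenario
#'
#' @param rho Fluid density, kg m^-3.
#' @param U Reference (maximum channel) velocity, m s^-1.
#' @param Z Channel half-thickness, m.
#' @param mu Dynamic viscosity, Pa s.
#' @param f Oscillation frequency, s^-1.
#' @param d Membrane thickness, m.
#' @param F Flexural rigidity, N m^2.
#' @param L Membrane length, m.
#' @return A `dimensionless_set` list with `Re`, `N_f`, `Lambda` and `N_R`
#'   (with `N_R = Re * N_f` exactly).
#' @export
dimensionless_set <- function(rho, U, Z, mu, f, d, F, L) {
  stopifnot(rho > 0, U >= 0, Z > 0, mu > 0, f >= 0, d > 0, F > 0, L > 0)
  Re <- reynolds_number(rho, U, Z, mu)
  N_f <- freq_number(rho, f, d, F, L)
  structure(list(Re = Re, N_f = N_f, Lambda = aspect_ratio(Z, L),
                 N_R = membrane_number(Re, N_f)),
            class = "dimensionless_set")
}

#' @export
print.dimensionless_set <- function(x, ...) {
  cat(sprintf("Re = %.6g, N_f = %.6g, Lambda = %.6g, N_R = %.6g\n",
              x$Re, x$N_f, x$Lambda, x$N_R))
  invisible(x)
}
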