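#' Fluid specification (weakly-compressible SPH closure)
#'
#' Blood is treated as a Newtonian fluid; pressure closes through the Tait
#' equation of state \eqn{p = c_0^2 \rho_0 / \gamma ((\rho/\rho_0)^\gamma - 1)}.
#' The weak-compressibility contract requires the numerical sound speed to be
#' at least ten times the expected maximum flow speed so density fluctuations
#' stay within a few percent.
#'
#' @param rest_density Rest density \eqn{\rho_0}, kg m^-3.
#' @param dynamic_viscosity Dynamic viscosity \eqn{\mu}, Pa s.
#' @param sound_speed Numerical sound speed \eqn{c_0}, m s^-1.
#' @param eos_exponent Tait exponent \eqn{\gamma} (default 7).
#' @return A `fluid_spec` list.
#' @export
fluid_spec <- function(rest_density, dynamic_viscosity, sound_speed,
                       eos_exponent = 7) {
  stopifnot(rest_density > 0, dynamic_viscosity > 0, sound_speed > 0,
            eos_exponent > 0)
  structure(list(rest_density = rest_density,
                 dynamic_viscosity = dynamic_viscosity,
                 sound_speed = sound_speed,
                 eos_exponent = eos_exponent),
            class = "fluid_spec")
}

#' Blood at the study conditions
#' @return A [fluid_spec()] with \eqn{\rho = 1056} kg m^-3 and
#'   \eqn{\mu = 0.0035} Pa s; the sound speed defaults to ten times the
#'   expected 0.9 m/s peak channel velocity.
#' @param sound_speed Numerical sound speed, m s^-1.
#' @export
blood <- function(sound_speed = 9) {
  fluid_spec(1056, 0.0035, sound_speed)
}

#' Pulsatile body forcing
#'
#' The sinusoidal pressure gradient is imposed as a per-particle acceleration
#' \eqn{g(t) = g_0 \sin(2\pi f t)} on fluid particles only. The equivalent
#' pressure-gradient amplitude is \eqn{A = \rho_0 g_0}.
#'
#' @param amplitude Acceleration amplitude \eqn{g_0}, m s^-2 (>= 0).
#' @param frequency Oscillation frequency \eqn{f}, s^-1 (> 0).
#' @param waveform `"sinusoidal"` (default) or `"constant"` (steady body
#'   force `g0`, used by the Poiseuille fixture).
#' @param direction Unit direction of the forcing (default streamwise +x).
#' @return A `forcing_spec` list with derived `period = 1/frequency`.
#' @export
forcing_spec <- function(amplitude, frequency,
                         waveform = c("sinusoidal", "constant"),
                         direction = c(1, 0)) {
  waveform <- match.arg(waveform)
  stopifnot(amplitude >= 0, frequency > 0, length(direction) == 2)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  structure(list(amplitude = amplitude, frequency = frequency,
                 period = 1 / frequency, waveform = waveform,
                 direction = direction / nrm),
            class = "forcing_spec")
}

#' Pressure-gradient amplitude of a forcing
#' @param forcing A [forcing_spec()].
#' @param fluid A [fluid_spec()].
#' @return \eqn{A = \rho_0 g_0} in Pa m^-1.
#' @export
pressure_gradient_amplitude <- function(forcing, fluid) {
  fluid$rest_density * forcing$amplitude
}

#' SPH kernel specification
#'
#' 2D cubic-spline kernel with support radius `2 h`. The default smoothing
#' length is 1.3 times the lattice spacing.
#'
#' @param h Smoothing length, m (> 0).
#' @return A `kernel_spec` list with `support = 2 * h`.
#' @export
kernel_spec <- function(h) {
  if (h <= 0) stop("smoothing length must be > 0")
  structure(list(h = h, support = 2 * h, family = "cubic-spline"),
            class = "kernel_spec")
}

#' No-penetration repulsion between fluid and solid particles
#'
#' Short-range Monaghan-type boundary force
#' \eqn{f(r) = D [(r_c/r)^4 - (r_c/r)^2]} for \eqn{r < r_c}, zero at and
#' beyond the contact distance, purely radial and repulsive. This is what
#' gives the point-particle membrane its effective no-penetration thickness.
#' The force is capped below `0.3 * r_c` for integrator stability.
#'
#' @param contact_distance Cutoff \eqn{r_c}, m (typically the lattice
#'   spacing).
#' @param strength Coefficient \eqn{D}, N.
#' @param solid_solid Also apply between non-bonded solid particles
#'   (leaflet-leaflet / aggregate contact)? Default `FALSE`.
#' @return A `repulsion_spec` list.
#' @export
repulsion_spec <- function(contact_distance, strength, solid_solid = FALSE) {
  stopifnot(contact_distance > 0, strength >= 0)
  structure(list(contact_distance = contact_distance, strength = strength,
                 exponents = c(4, 2), solid_solid = solid_solid),
            class = "repulsion_spec")
}

#' Map spring and hinge constants to continuum membrane properties
#'
#' Discrete-beam equivalence for a chain with particle spacing `l0`: axial
#' stiffness per unit width \eqn{k_b = E d / l_0} and bending stiffness
#' \eqn{k_a = E d^3 / (12 l_0)}, giving thickness
#' \eqn{d = \sqrt{12 k_a / k_b}}, flexural rigidity \eqn{F = k_a l_0}
#' (N m^2 per unit width) and Young modulus \eqn{E = k_b l_0 / d}. The
#' round-trip identity \eqn{F = E d^3 / 12} holds exactly.
#'
#' @param k_a Hinge stiffness, N m rad^-1 per unit width (> 0).
#' @param k_b Spring stiffness, N m^-1 per unit width (> 0).
#' @param l0 Particle spacing, m (> 0).
#' @return List with `d` (m), `F` (N m^2) and `E` (Pa).
#' @export
membrane_properties <- function(k_a, k_b, l0) {
  if (any(c(k_a, k_b, l0) <= 0)) stop("membrane constants must be > 0")
  d <- sqrt(12 * k_a / k_b)
  list(d = d, F = k_a * l0, E = k_b * l0 / d)
}

#' Invert continuum membrane properties to spring/hinge constants
#'
#' Inverse of [membrane_properties()]: given thickness `d` and flexural
#' rigidity `F` (N m^2 per unit width), returns `k_a = F / l0` and
#' `k_b = 12 k_a / d^2`.
#'
#' @param d Membrane thickness, m.
#' @param F Flexural rigidity, N m^2 per unit width.
#' @param l0 Particle spacing, m.
#' @return List with `k_a` and `k_b`.
#' @export
membrane_constants <- function(d, F, l0) {
  if (any(c(d, F, l0) <= 0)) stop("membrane properties must be > 0")
  k_a <- F / l0
  list(k_a = k_a, k_b = 12 * k_a / d^2)
}

#' Membrane specification
#'
#' @param k_a,k_b Hinge and spring stiffness (see [membrane_properties()]).
#' @param l0 Particle spacing along the leaflet, m.
#' @return A `membrane_spec` list carrying the derived thickness `d`,
#'   flexural rigidity `F` and Young modulus `E`.
#' @export
membrane_spec <- function(k_a, k_b, l0) {
  props <- membrane_properties(k_a, k_b, l0)
  structure(c(list(k_a = k_a, k_b = k_b, l0 = l0), props),
            class = "membrane_spec")
}
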