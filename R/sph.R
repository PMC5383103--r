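#' Evaluate the 2D cubic-spline kernel
#'
#' Kernel with compact support `2 h`, normalized to unit integral over the
#' plane; `W(0, h) = 10 / (7 pi h^2)`.
#'
#' @param r Distances, m (>= 0).
#' @param h Smoothing length, m (> 0).
#' @return List with `W` (m^-2) and `gradW_magnitude` = |dW/dr| (m^-3);
#'   `dWdr` carries the signed radial derivative.
#' @export
kernel_eval <- function(r, h) {
  if (length(h) != 1 || h <= 0) stop("smoothing length h must be a positive scalar")
  if (any(r < 0)) stop("distances must be >= 0")
  k <- cpp_kernel(as.numeric(r), h)
  list(W = k$W, gradW_magnitude = abs(k$dWdr), dWdr = k$dWdr)
}

ps_box <- function(ps) {
  if (!is.null(ps$box)) {
    list(xlo = ps$box[1], xhi = ps$box[2], periodic = TRUE)
  } else {
    n <- length(ps$x)
    if (n == 0) return(list(xlo = 0, xhi = 1, periodic = FALSE))
    list(xlo = min(ps$x), xhi = max(ps$x) + 1, periodic = FALSE)
  }
}

#' Build the neighbor pair list
#'
#' Half list of unordered pairs within the support radius, with displacement
#' under the minimum-image convention in x (periodic inlet/outlet). The pair
#' set is identical to an all-pairs minimum-image search.
#'
#' @param ps A [particle_system()].
#' @param support Interaction cutoff, m; must not exceed half the periodic
#'   box length.
#' @return Data frame with columns `i, j, dx, dy, r` (i < j, `dx = x_i - x_j`).
#' @export
build_neighbors <- function(ps, support) {
  stopifnot(support > 0)
  bx <- ps_box(ps)
  if (bx$periodic && support > (bx$xhi - bx$xlo) / 2)
    stop("support exceeds half the periodic box length (minimum-image violation)")
  p <- cpp_pairs(ps$x, ps$y, support, bx$xlo, bx$xhi, bx$periodic)
  data.frame(i = p$i, j = p$j, dx = p$dx, dy = p$dy, r = p$r)
}

#' SPH density summation
#'
#' Direct summation \eqn{\rho_i = \sum_j m_j W(r_{ij})} including the self
#' term; wall, membrane and aggregate particles participate as boundary
#' neighbors. Updates `ps$rho` in place.
#'
#' @param ps A [particle_system()].
#' @param kernel A [kernel_spec()].
#' @param neighbors Optional precomputed pair list from [build_neighbors()]
#'   at support `kernel$support`.
#' @return The density vector, invisibly.
#' @export
compute_density <- function(ps, kernel, neighbors = NULL) {
  if (is.null(neighbors)) neighbors <- build_neighbors(ps, kernel$support)
  rho <- cpp_density(neighbors$i, neighbors$j, neighbors$r,
                     ps$mass, kernel$h, length(ps$x))
  ps$rho <- rho
  invisible(rho)
}

#' Tait equation of state
#'
#' \eqn{p(\rho) = c_0^2 \rho_0 / \gamma ((\rho/\rho_0)^\gamma - 1)}: zero at
#' the rest density and strictly increasing in density.
#'
#' @param rho Densities, kg m^-3 (> 0).
#' @param fluid A [fluid_spec()].
#' @return Pressures, Pa.
#' @export
eos_pressure <- function(rho, fluid) {
  if (any(rho <= 0)) stop("density must be > 0")
  cpp_eos(as.numeric(rho), fluid$rest_density, fluid$sound_speed,
          fluid$eos_exponent)
}

#' Update pressures from densities
#' @param ps A [particle_system()] with current densities.
#' @param fluid A [fluid_spec()].
#' @return The pressure vector, invisibly.
#' @export
compute_pressure <- function(ps, fluid) {
  ps$pressure <- eos_pressure(ps$rho, fluid)
  invisible(ps$pressure)
}

force_call <- function(ps, kernel, fluid, repulsion,
                       do_pv, do_rep, do_springs, do_hinges) {
  bx <- ps_box(ps)
  h <- if (!is.null(kernel)) kernel$h else 1
  mu <- if (!is.null(fluid)) fluid$dynamic_viscosity else 0
  rc <- if (!is.null(repulsion)) repulsion$contact_distance else 0
  st <- if (!is.null(repulsion)) repulsion$strength else 0
  ss <- if (!is.null(repulsion)) repulsion$solid_solid else FALSE
  rho <- ps$rho; p <- ps$pressure
  if (do_pv && (anyNA(rho) || anyNA(p)))
    stop("densities/pressures are not current; run compute_density()/compute_pressure()")
  if (!do_pv) { rho <- rep(1, length(ps$x)); p <- rep(0, length(ps$x)) }
  cpp_forces(kind_code(ps$kind), ps$x, ps$y, ps$vx, ps$vy, ps$mass,
             rho, p, h, mu, bx$xlo, bx$xhi, bx$periodic,
             rc, st, ss,
             ps$bond_i, ps$bond_j, ps$bond_k, ps$bond_rest,
             as.integer(ps$bond_active),
             ps$hinge_i, ps$hinge_j, ps$hinge_k, ps$hinge_ka, ps$hinge_rest,
             do_pv, do_rep, do_springs, do_hinges)
}

#' Pressure and viscous forces on fluid particles
#'
#' Symmetric WCSPH pressure term plus Morris laminar viscosity using the
#' physical dynamic viscosity, applied to every pair with at least one fluid
#' member; solid neighbors receive the equal-and-opposite reaction. The sum
#' of all added internal forces is zero to round-off.
#'
#' @param ps A [particle_system()] with current densities and pressures.
#' @param kernel A [kernel_spec()].
#' @param fluid A [fluid_spec()].
#' @return An n-by-2 force matrix (N) with attribute `imbalance` (relative
#'   net internal force); also accumulated into `ps$fx`, `ps$fy`.
#' @export
compute_fluid_forces <- function(ps, kernel, fluid) {
  r <- force_call(ps, kernel, fluid, NULL, TRUE, FALSE, FALSE, FALSE)
  ps$fx <- r$fx; ps$fy <- r$fy
  structure(cbind(fx = r$fx, fy = r$fy), imbalance = r$imbalance)
}

#' No-penetration repulsion forces
#'
#' @param ps A [particle_system()].
#' @param spec A [repulsion_spec()].
#' @return An n-by-2 force matrix (N) with attribute `imbalance`.
#' @export
repulsion_forces <- function(ps, spec) {
  r <- force_call(ps, kernel_spec(spec$contact_distance / 2), NULL, spec,
                  FALSE, TRUE, FALSE, FALSE)
  structure(cbind(fx = r$fx, fy = r$fy), imbalance = r$imbalance)
}

#' Spring (bond) forces
#'
#' Harmonic central force of magnitude `k_b * (|r| - rest_length)` per active
#' bond, equal and opposite on the endpoints.
#'
#' @param ps A [particle_system()].
#' @return An n-by-2 force matrix (N) with attributes `tension` (per-bond
#'   tension, positive when stretched) and `imbalance`.
#' @export
spring_forces <- function(ps) {
  r <- force_call(ps, NULL, NULL, NULL, FALSE, FALSE, TRUE, FALSE)
  structure(cbind(fx = r$fx, fy = r$fy),
            tension = r$tension, imbalance = r$imbalance)
}

#' Hinge (angular) forces
#'
#' Analytic gradient of \eqn{U = 0.5 k_a (\theta - \theta_0)^2}; each
#' triplet's net force and net torque vanish.
#'
#' @param ps A [particle_system()].
#' @return An n-by-2 force matrix (N) with attribute `imbalance`.
#' @export
hinge_forces <- function(ps) {
  r <- force_call(ps, NULL, NULL, NULL, FALSE, FALSE, FALSE, TRUE)
  structure(cbind(fx = r$fx, fy = r$fy), imbalance = r$imbalance)
}

#' Pulsatile body acceleration
#'
#' \eqn{g(t) = g_0 \sin(2 \pi f t)} (or constant `g0` for the steady
#' waveform), applied to fluid particles only.
#'
#' @param t Time, s (>= 0).
#' @param forcing A [forcing_spec()].
#' @return Acceleration magnitude, m s^-2 (signed along the forcing
#'   direction).
#' @export
body_force <- function(t, forcing) {
  if (any(t < 0)) stop("time must be >= 0")
  if (forcing$waveform == "constant") {
    rep_len(forcing$amplitude, length(t))
  } else {
    forcing$amplitude * sin(2 * pi * forcing$frequency * t)
  }
}

#' Stable time step
#'
#' Acoustic CFL bound `0.25 h / (c0 + u_max)` combined with the viscous
#' diffusion bound `0.125 h^2 rho0 / mu`.
#'
#' @param kernel A [kernel_spec()].
#' @param fluid A [fluid_spec()].
#' @param u_max Expected maximum flow speed, m s^-1 (defaults to `c0 / 10`).
#' @return Time step, s.
#' @export
stable_dt <- function(kernel, fluid, u_max = fluid$sound_speed / 10) {
  min(0.25 * kernel$h / (fluid$sound_speed + u_max),
      0.125 * kernel$h^2 * fluid$rest_density / fluid$dynamic_viscosity)
}

# internal: shared advance driver
advance_system <- function(ps, kernel, fluid, forcing, repulsion, dt, nsteps,
                           nsub = 0, damping = 0, break_check = TRUE,
                           probe = integer(0), check_cfl = TRUE) {
  bx <- ps_box(ps)
  if (check_cfl) {
    vmax <- if (length(ps$vx)) max(sqrt(ps$vx^2 + ps$vy^2)) else 0
    bound <- min(0.25 * kernel$h / (fluid$sound_speed + vmax),
                 0.125 * kernel$h^2 * fluid$rest_density / fluid$dynamic_viscosity)
    if (dt > bound * (1 + 1e-12))
      stop("dt = ", dt, " exceeds the CFL bound ", signif(bound, 6))
  }
  if (is.null(forcing)) forcing <- forcing_spec(0, 1, waveform = "constant")
  par <- list(h = kernel$h, rho0 = fluid$rest_density,
              mu = fluid$dynamic_viscosity, c0 = fluid$sound_speed,
              gamma = fluid$eos_exponent,
              g0 = forcing$amplitude, freq = forcing$frequency,
              waveform = if (forcing$waveform == "constant") 0L else 1L,
              gdir_x = forcing$direction[1], gdir_y = forcing$direction[2],
              rc = if (is.null(repulsion)) 0 else repulsion$contact_distance,
              rep_strength = if (is.null(repulsion)) 0 else repulsion$strength,
              rep_solid = if (is.null(repulsion)) FALSE else repulsion$solid_solid,
              damping = damping, dt = dt, nsteps = as.integer(nsteps),
              t0 = ps$time, xlo = bx$xlo, xhi = bx$xhi,
              periodic = bx$periodic, break_check = break_check,
              probe = as.integer(probe), nsub = as.integer(nsub))
  res <- cpp_advance(ps_state(ps), par)
  ps_absorb(ps, res, nsteps, dt)
  list(trace = res$trace, events = res$events,
       max_imbalance = res$max_imbalance, max_drho = res$max_drho,
       max_speed = res$max_speed, nsub = res$nsub, prof = res$prof)
}

#' Advance the system by one time step
#'
#' Kick-drift-kick (velocity-Verlet family) step of the coupled SPH /
#' mass-spring system: density summation, Tait pressure, pressure + viscous +
#' repulsion + body forces at the outer step, with spring/hinge forces
#' sub-stepped for stability. Positions are wrapped into the periodic box,
#' anchored particles stay put, and the clock advances by `dt`.
#'
#' @param ps A [particle_system()].
#' @param kernel,fluid,forcing,repulsion Specs ([kernel_spec()],
#'   [fluid_spec()], [forcing_spec()], [repulsion_spec()]); `forcing` and
#'   `repulsion` may be `NULL`.
#' @param dt Time step, s; rejected if it exceeds the CFL bound.
#' @param nsteps Number of steps to take (default 1).
#' @param damping Velocity-proportional damping coefficient (N s m^-1),
#'   for static validation runs; default 0.
#' @param break_check Check bond tensions against their break thresholds
#'   every step (default TRUE).
#' @param probe Ids whose mean `vx` is recorded each step.
#' @return List with per-step `trace` (time, max fluid speed, probe mean vx,
#'   max density fluctuation), fragmentation `events`, and run diagnostics
#'   `max_imbalance`, `max_drho`, `max_speed`, `nsub`.
#' @export
sph_step <- function(ps, kernel, fluid, forcing = NULL, repulsion = NULL,
                     dt, nsteps = 1, damping = 0, break_check = TRUE,
                     probe = integer(0)) {
  advance_system(ps, kernel, fluid, forcing, repulsion, dt, nsteps,
                 damping = damping, break_check = break_check, probe = probe)
}
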