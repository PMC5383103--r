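#' Valve geometry
#'
#' 2D bicuspid-valve geometry: a straight channel of half-thickness `Z`
#' with a circular chamber of radius `R`, and two flexible leaflets of
#' length `L` rooted at opposite walls at the chamber entrance. The origin
#' sits on the channel centerline at the membrane root plane; the chamber
#' disk is centered at `(R, 0)` so its upstream rim is tangent to the root
#' plane. x is streamwise and periodic (inlet/outlet), y transverse.
#'
#' @param Z Channel half-thickness, m (default 0.0125).
#' @param L Membrane (leaflet) length, m (default 0.016).
#' @param R Chamber radius, m (default 0.0215).
#' @param spacing Lattice spacing `s`, m.
#' @param upstream,downstream Channel length upstream/downstream of the
#'   chamber (defaults `6 Z` each; the total domain is periodic).
#' @param wall_layers Wall particle layers (>= 2 for full kernel support).
#' @return A `valve_geometry` list.
#' @export
valve_geometry <- function(Z = 0.0125, L = 0.016, R = 0.0215,
                           spacing = 1e-3, upstream = 6 * Z,
                           downstream = 6 * Z, wall_layers = 3) {
  stopifnot(Z > 0, L > 0, R > 0, spacing > 0, wall_layers >= 2,
            upstream > 0, downstream > 0)
  if (L / spacing < 8)
    stop("lattice too coarse: the membrane needs at least 8 particles (L/s >= 8)")
  structure(list(Z = Z, L = L, R = R, spacing = spacing,
                 upstream = upstream, downstream = downstream,
                 wall_layers = wall_layers),
            class = "valve_geometry")
}

# signed distance to the fluid region (channel strip union chamber disk);
# negative inside
region_sdf <- function(x, y, Z, R, cx) {
  pmin(abs(y) - Z, sqrt((x - cx)^2 + y^2) - R)
}

scene_new <- function(ps, kernel, fluid, forcing, repulsion, membrane,
                      geom, spacing, leaflets = NULL) {
  structure(list(ps = ps, kernel = kernel, fluid = fluid, forcing = forcing,
                 repulsion = repulsion, membrane = membrane, geom = geom,
                 spacing = spacing, leaflets = leaflets,
                 dt = stable_dt(kernel, fluid)),
            class = "sph_scene")
}

#' @export
print.sph_scene <- function(x, ...) {
  cat("<sph_scene> spacing ", format(x$spacing), " m, dt ", format(x$dt), " s\n", sep = "")
  print(x$ps)
  invisible(x)
}

default_repulsion <- function(spacing, fluid, solid_solid = FALSE) {
  m <- fluid$rest_density * spacing^2
  repulsion_spec(contact_distance = spacing,
                 strength = 0.01 * m * fluid$sound_speed^2 / spacing,
                 solid_solid = solid_solid)
}

#' Build the bicuspid-valve scene
#'
#' Deterministic particle placement: fluid on a square lattice filling the
#' channel and chamber, wall particles lining the channel and the chamber
#' arc (`wall_layers` deep, lattice-snapped), and two straight leaflets of
#' `floor(L/s) + 1` membrane particles each, rooted at opposite walls at the
#' chamber entrance with tips approaching the centerline (closed position,
#' tips separated by `tip_gap`). Leaflet particles are chained with springs
#' (`k_b`) and hinges (`k_a`, straight rest shape); the two root-most
#' particles of each leaflet are anchored. Fluid lattice sites closer than
#' `0.7 s` to a membrane particle (and wall sites overlapping the roots) are
#' left empty.
#'
#' @param geom A [valve_geometry()].
#' @param fluid A [fluid_spec()]; default [blood()].
#' @param membrane A [membrane_spec()]; default is the intermediate
#'   (`F = 0.056` N m^2, `d = 1.6e-4` m) membrane of the study conditions.
#' @param forcing A [forcing_spec()]; default `g0 = 500` m s^-2 at 1 Hz.
#' @param repulsion A [repulsion_spec()]; default contact distance `s` with
#'   solid-solid contact enabled (leaflet-leaflet sliding).
#' @param tip_gap Initial tip separation at the centerline, m (default `s`).
#' @return An `sph_scene` with elements `ps`, specs, `leaflets` (id vectors
#'   `upper`/`lower`, root to tip) and the default `dt`.
#' @export
build_valve <- function(geom = valve_geometry(), fluid = blood(),
                        membrane = NULL, forcing = forcing_spec(500, 1),
                        repulsion = NULL, tip_gap = geom$spacing) {
  s <- geom$spacing
  Z <- geom$Z; L <- geom$L; R <- geom$R
  cx <- R
  nm <- floor(L / s) + 1
  l0 <- L / (nm - 1)
  if (is.null(membrane)) {
    k <- membrane_constants(d = 1.6e-4, F = 0.056, l0 = l0)
    membrane <- membrane_spec(k$k_a, k$k_b, l0)
  }
  if (is.null(repulsion)) repulsion <- default_repulsion(s, fluid, solid_solid = TRUE)
  kernel <- kernel_spec(1.3 * s)
  mass <- fluid$rest_density * s^2

  jlo <- -ceiling(geom$upstream / s)
  jhi <- ceiling((2 * R + geom$downstream) / s) - 1
  klim <- ceiling((R + geom$wall_layers * s) / s)
  grid <- expand.grid(j = jlo:jhi, k = -klim:klim)
  gx <- grid$j * s
  gy <- grid$k * s
  d <- region_sdf(gx, gy, Z, R, cx)
  is_fluid <- d < -0.25 * s
  is_wall <- !is_fluid & d < (geom$wall_layers - 0.25) * s

  # leaflets: straight chains from the wall roots toward the centerline
  xt <- sqrt(L^2 - (Z - tip_gap / 2)^2)
  mk_leaf <- function(sgn) {
    root <- c(0, sgn * Z)
    tip <- c(xt, sgn * tip_gap / 2)
    dir <- (tip - root) / sqrt(sum((tip - root)^2))
    t(sapply(0:(nm - 1), function(k) root + k * l0 * dir))
  }
  leaf_up <- mk_leaf(+1)
  leaf_lo <- mk_leaf(-1)
  mempos <- rbind(leaf_up, leaf_lo)

  # clear lattice sites that would overlap the leaflets
  min_d2 <- function(px, py) {
    out <- rep(Inf, length(px))
    for (q in seq_len(nrow(mempos)))
      out <- pmin(out, (px - mempos[q, 1])^2 + (py - mempos[q, 2])^2)
    out
  }
  is_fluid <- is_fluid & min_d2(gx, gy) > (0.7 * s)^2
  is_wall <- is_wall & min_d2(gx, gy) > (0.45 * s)^2

  box <- c(jlo * s, (jhi + 1) * s, -(klim + 0.5) * s, (klim + 0.5) * s)
  ps <- particle_system(box = box)
  add_particles(ps, "WALL", cbind(gx[is_wall], gy[is_wall]), mass, anchored = TRUE)
  add_particles(ps, "FLUID", cbind(gx[is_fluid], gy[is_fluid]), mass)
  up_ids <- add_particles(ps, "MEMBRANE", leaf_up, mass)
  lo_ids <- add_particles(ps, "MEMBRANE", leaf_lo, mass)
  ps$anchored[c(up_ids[1:2], lo_ids[1:2])] <- TRUE

  for (ids in list(up_ids, lo_ids)) {
    for (q in seq_len(nm - 1))
      add_bond(ps, ids[q], ids[q + 1], membrane$k_b, l0)
    for (q in seq_len(nm - 2))
      add_hinge(ps, ids[q], ids[q + 1], ids[q + 2], membrane$k_a, pi)
  }
  scene_new(ps, kernel, fluid, forcing, repulsion, membrane, geom, s,
            leaflets = list(upper = up_ids, lower = lo_ids))
}

#' Build a straight periodic channel (validation fixture)
#'
#' Walls top and bottom (`wall_layers` deep), no membrane, periodic in x.
#' The domain length is snapped to a whole number of lattice columns. The
#' fluid occupies rows `|y| < Z`, i.e. `2 floor(Z/s) - 1` rows when `Z` is a
#' lattice multiple; the scene is mirror-symmetric about `y = 0`.
#'
#' @param Z Channel half-thickness, m.
#' @param length Channel length, m (snapped down to `floor(length/s) * s`).
#' @param spacing Lattice spacing `s`, m.
#' @param fluid A [fluid_spec()].
#' @param forcing A [forcing_spec()] or `NULL`.
#' @param repulsion A [repulsion_spec()]; default from the spacing.
#' @param wall_layers Wall particle layers.
#' @return An `sph_scene`.
#' @export
build_channel <- function(Z, length, spacing, fluid,
                          forcing = NULL, repulsion = NULL, wall_layers = 3) {
  s <- spacing
  stopifnot(Z > 0, length > 0, s > 0, wall_layers >= 2)
  if (Z / s < 4) stop("lattice too coarse for the channel half-thickness")
  if (is.null(repulsion)) repulsion <- default_repulsion(s, fluid)
  kernel <- kernel_spec(1.3 * s)
  mass <- fluid$rest_density * s^2
  ncol_ <- floor(length / s)
  klim <- ceiling(Z / s) + wall_layers
  grid <- expand.grid(j = 0:(ncol_ - 1), k = -klim:klim)
  gx <- grid$j * s
  gy <- grid$k * s
  d <- abs(gy) - Z
  is_fluid <- d < -0.25 * s
  is_wall <- !is_fluid & d < (wall_layers - 0.25) * s
  box <- c(0, ncol_ * s, -(klim + 0.5) * s, (klim + 0.5) * s)
  ps <- particle_system(box = box)
  add_particles(ps, "WALL", cbind(gx[is_wall], gy[is_wall]), mass, anchored = TRUE)
  add_particles(ps, "FLUID", cbind(gx[is_fluid], gy[is_fluid]), mass)
  geom <- list(Z = Z, length = ncol_ * s, wall_layers = wall_layers)
  scene_new(ps, kernel, fluid, forcing, repulsion, NULL, geom, s)
}

#' Build a clamped cantilever chain (membrane validation fixture)
#'
#' A straight chain of membrane particles along +x, clamped by anchoring the
#' two root-most particles, with a constant transverse point load applied to
#' the tip particle. Relaxed under damped dynamics it converges to the
#' Euler-Bernoulli deflection for small loads.
#'
#' @param membrane A [membrane_spec()]; `l0` sets the particle spacing.
#' @param L Chain length, m (number of particles is `floor(L/l0) + 1`).
#' @param tip_load Downward (-y) tip force, N per unit width.
#' @param mass Particle mass, kg; affects only the relaxation dynamics.
#' @return A list with `ps`, `ids` (root to tip), `membrane`, `tip_load`,
#'   and `L_eff` (clamp-to-tip distance used by the analytic reference).
#' @export
build_cantilever <- function(membrane, L, tip_load,
                             mass = 1056 * membrane$l0^2) {
  l0 <- membrane$l0
  n <- floor(L / l0) + 1
  if (n < 8) stop("cantilever needs at least 8 particles")
  ps <- particle_system()
  ids <- add_particles(ps, "MEMBRANE", cbind((0:(n - 1)) * l0, 0), mass)
  ps$anchored[ids[1:2]] <- TRUE
  for (q in seq_len(n - 1)) add_bond(ps, ids[q], ids[q + 1], membrane$k_b, l0)
  for (q in seq_len(n - 2))
    add_hinge(ps, ids[q], ids[q + 1], ids[q + 2], membrane$k_a, pi)
  ps$ext_fy[ids[n]] <- -tip_load
  # the effective clamp plane of the discrete chain sits half a spacing
  # behind the first free hinge (exact for the pure-bending chain)
  list(ps = ps, ids = ids, membrane = membrane, tip_load = tip_load,
       L_eff = (n - 1.5) * l0)
}

#' Analytic Poiseuille profile
#'
#' Steady plane-channel flow under a constant pressure gradient `G`:
#' \eqn{u(y) = G (Z^2 - y^2) / (2 \mu)}, no-slip at \eqn{y = \pm Z}. The
#' profile integrates to a flow rate \eqn{2 G Z^3 / (3 \mu)} per unit width.
#'
#' @param y Transverse positions, m; must satisfy `|y| <= Z`.
#' @param G Pressure-gradient magnitude, Pa m^-1.
#' @param mu Dynamic viscosity, Pa s.
#' @param Z Channel half-thickness, m.
#' @return Streamwise velocity, m s^-1.
#' @export
poiseuille_profile <- function(y, G, mu, Z) {
  if (any(abs(y) > Z)) stop("|y| must not exceed the half-thickness Z")
  G * (Z^2 - y^2) / (2 * mu)
}

#' Analytic Womersley (oscillating channel) profile
#'
#' Exact laminar solution for a plane channel driven by the sinusoidal
#' pressure gradient \eqn{G_0 \sin(2\pi f t)}:
#' \deqn{u(y,t) = \Im\left[\frac{G_0/\rho}{i\omega}\left(1 -
#'   \frac{\cosh(\lambda y)}{\cosh(\lambda Z)}\right) e^{i\omega t}\right],
#'   \quad \lambda = \sqrt{i\omega/\nu}.}
#' No-slip at \eqn{y = \pm Z}; in the limit \eqn{f \to 0} it reduces to the
#' quasi-steady Poiseuille profile.
#'
#' @param y Transverse positions, m (`|y| <= Z`).
#' @param t Time, s.
#' @param G0 Pressure-gradient amplitude, Pa m^-1.
#' @param f Frequency, s^-1.
#' @param rho Fluid density, kg m^-3.
#' @param mu Dynamic viscosity, Pa s.
#' @param Z Channel half-thickness, m.
#' @return Streamwise velocity, m s^-1 (vectorized over `y` and `t`).
#' @export
womersley_profile <- function(y, t, G0, f, rho, mu, Z) {
  if (any(abs(y) > Z)) stop("|y| must not exceed the half-thickness Z")
  nu <- mu / rho
  om <- 2 * pi * f
  lam <- sqrt(complex(real = 0, imaginary = om / nu))
  uhat <- (G0 / rho) / complex(imaginary = om) *
    (1 - cosh(lam * y) / cosh(lam * Z))
  Im(uhat * exp(complex(imaginary = om) * t))
}

#' Complex centerline amplitude of the Womersley solution
#' @inheritParams womersley_profile
#' @return Modulus of the centerline velocity oscillation, m s^-1.
#' @export
womersley_amplitude <- function(G0, f, rho, mu, Z) {
  nu <- mu / rho
  om <- 2 * pi * f
  lam <- sqrt(complex(real = 0, imaginary = om / nu))
  Mod((G0 / rho) / complex(imaginary = om) * (1 - 1 / cosh(lam * Z)))
}

#' Euler-Bernoulli cantilever tip deflection
#'
#' \eqn{\delta = P L^3 / (3 F)} for a clamped beam of flexural rigidity `F`
#' under a transverse tip point load `P` (valid for small deflections).
#'
#' @param P Tip load, N per unit width (> 0).
#' @param L Beam length, m (> 0).
#' @param F Flexural rigidity, N m^2 per unit width (> 0).
#' @return Tip deflection, m.
#' @export
cantilever_tip_deflection <- function(P, L, F) {
  stopifnot(P > 0, L > 0, F > 0)
  P * L^3 / (3 * F)
}
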