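#' Particle kinds
#'
#' The four particle kinds of the discrete multi-physics model: `FLUID`
#' particles obey the weakly-compressible SPH force laws, `WALL` particles
#' are fixed SPH boundary particles, `MEMBRANE` particles form the flexible
#' leaflets (mass-spring-hinge model), and `AGGREGATE` particles are former
#' fluid particles converted by the phase-change algorithm. `WALL` particles
#' never change kind; `FLUID` may become `AGGREGATE`; `MEMBRANE` and
#' `AGGREGATE` never revert to `FLUID`.
#'
#' @format Character vector of the four kind labels.
#' @export
PARTICLE_KINDS <- c("FLUID", "WALL", "MEMBRANE", "AGGREGATE")

kind_code <- function(kind) {
  m <- match(kind, PARTICLE_KINDS)
  if (anyNA(m)) stop("unknown particle kind: ", paste(setdiff(kind, PARTICLE_KINDS), collapse = ", "))
  m - 1L
}

#' Create an empty particle system
#'
#' The particle system is the single source of truth for simulation state:
#' flat per-particle arrays (kind, position, velocity, force, mass, density,
#' pressure, anchoring and seed flags) indexed by integer id, plus the bond
#' and hinge tables that define the mass-spring solids. It has reference
#' semantics (an environment), so the engine and the aggregation algorithm
#' update it in place; use [ps_clone()] for an independent copy.
#'
#' @param box Optional domain box `c(xlo, xhi, ylo, yhi)`; when present the
#'   x direction is treated as periodic (inlet/outlet) with minimum-image
#'   distances.
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(box = NULL) {
  ps <- new.env(parent = emptyenv())
  ps$kind <- character(0)
  ps$x <- ps$y <- ps$vx <- ps$vy <- numeric(0)
  ps$fx <- ps$fy <- numeric(0)
  ps$mass <- ps$rho <- ps$pressure <- numeric(0)
  ps$anchored <- ps$seed_active <- logical(0)
  ps$ext_fx <- ps$ext_fy <- numeric(0)
  ps$bond_i <- ps$bond_j <- integer(0)
  ps$bond_k <- ps$bond_rest <- ps$bond_thr <- numeric(0)
  ps$bond_active <- logical(0)
  ps$hinge_i <- ps$hinge_j <- ps$hinge_k <- integer(0)
  ps$hinge_ka <- ps$hinge_rest <- numeric(0)
  ps$step <- 0L
  ps$time <- 0
  if (!is.null(box)) {
    stopifnot(length(box) == 4, box[2] > box[1])
    ps$box <- as.numeric(box)
  } else {
    ps$box <- NULL
  }
  class(ps) <- "particle_system"
  ps
}

#' Number of particles in a system
#' @param ps A [particle_system()].
#' @return Integer count.
#' @export
particle_count <- function(ps) length(ps$x)

#' Number of (active) bonds
#' @param ps A [particle_system()].
#' @param active_only Count only unbroken bonds?
#' @return Integer count.
#' @export
bond_count <- function(ps, active_only = TRUE) {
  if (active_only) sum(ps$bond_active) else length(ps$bond_i)
}

#' Deep copy of a particle system
#' @param ps A [particle_system()].
#' @return An independent `particle_system` with identical state.
#' @export
ps_clone <- function(ps) {
  out <- particle_system()
  for (nm in ls(ps, all.names = TRUE)) assign(nm, get(nm, envir = ps), envir = out)
  class(out) <- "particle_system"
  out
}

#' Add particles of one kind
#'
#' New particles get consecutive ids following the existing ones (ids are
#' 1-based). Velocities start at zero, densities and pressures are unset
#' until the next density pass.
#'
#' @param ps A [particle_system()] (modified in place).
#' @param kind One of [PARTICLE_KINDS].
#' @param positions Two-column matrix (or length-2 vector) of positions, m.
#' @param mass Particle mass, kg (per unit out-of-plane width); scalar or
#'   one value per particle.
#' @param anchored Logical; anchored particles are integrated to zero
#'   velocity (walls, leaflet roots) but still act as SPH neighbors.
#' @return The new ids, invisibly.
#' @export
add_particles <- function(ps, kind, positions, mass, anchored = FALSE) {
  kind <- match.arg(kind, PARTICLE_KINDS)
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) stop("positions must have two columns")
  k <- nrow(positions)
  if (k == 0) return(invisible(integer(0)))
  if (!all(is.finite(positions))) stop("non-finite position")
  if (any(mass <= 0) || !all(is.finite(mass))) stop("mass must be positive and finite")
  n0 <- length(ps$x)
  ids <- seq.int(n0 + 1L, n0 + k)
  ps$kind <- c(ps$kind, rep(kind, k))
  ps$x <- c(ps$x, positions[, 1]); ps$y <- c(ps$y, positions[, 2])
  ps$vx <- c(ps$vx, numeric(k)); ps$vy <- c(ps$vy, numeric(k))
  ps$fx <- c(ps$fx, numeric(k)); ps$fy <- c(ps$fy, numeric(k))
  ps$mass <- c(ps$mass, rep_len(as.numeric(mass), k))
  ps$rho <- c(ps$rho, rep(NA_real_, k))
  ps$pressure <- c(ps$pressure, rep(NA_real_, k))
  ps$anchored <- c(ps$anchored, rep_len(as.logical(anchored), k))
  ps$seed_active <- c(ps$seed_active, logical(k))
  ps$ext_fx <- c(ps$ext_fx, numeric(k)); ps$ext_fy <- c(ps$ext_fy, numeric(k))
  invisible(ids)
}

#' Relabel particle kinds under the allowed phase-change transitions
#'
#' Only `FLUID -> AGGREGATE` is a legal transition (the liquid-to-solid
#' phase change); anything else errors. Total particle count never changes.
#'
#' @param ps A [particle_system()].
#' @param ids Particle ids to convert.
#' @param to Target kind (must be `"AGGREGATE"`).
#' @return `ps`, invisibly.
#' @export
convert_kind <- function(ps, ids, to = "AGGREGATE") {
  to <- match.arg(to, PARTICLE_KINDS)
  if (to != "AGGREGATE") stop("only FLUID -> AGGREGATE transitions are allowed")
  if (!all(ids >= 1 & ids <= length(ps$x))) stop("unknown particle id")
  if (!all(ps$kind[ids] == "FLUID")) stop("only FLUID particles may become AGGREGATE")
  ps$kind[ids] <- to
  invisible(ps)
}

#' Register a spring bond between two particles
#'
#' @param ps A [particle_system()].
#' @param i,j Particle ids (1-based); must exist, differ, and not already be
#'   bonded.
#' @param stiffness Spring constant, N m^-1 per unit width.
#' @param rest_length Rest length, m (> 0).
#' @param break_threshold Tension (N) above which the bond breaks, or
#'   `"unbreakable"` / `Inf`.
#' @return The bond index, invisibly.
#' @export
add_bond <- function(ps, i, j, stiffness, rest_length,
                     break_threshold = "unbreakable") {
  n <- length(ps$x)
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1 || i > n || j < 1 || j > n) stop("bond endpoint id does not exist")
  if (i == j) stop("self-bond rejected")
  if (rest_length <= 0) stop("rest_length must be > 0")
  if (identical(break_threshold, "unbreakable")) break_threshold <- Inf
  lo <- min(i, j); hi <- max(i, j)
  dup <- ps$bond_active & pmin(ps$bond_i, ps$bond_j) == lo &
    pmax(ps$bond_i, ps$bond_j) == hi
  if (any(dup)) stop("pair (", lo, ",", hi, ") already bonded")
  ps$bond_i <- c(ps$bond_i, i); ps$bond_j <- c(ps$bond_j, j)
  ps$bond_k <- c(ps$bond_k, stiffness)
  ps$bond_rest <- c(ps$bond_rest, rest_length)
  ps$bond_thr <- c(ps$bond_thr, as.numeric(break_threshold))
  ps$bond_active <- c(ps$bond_active, TRUE)
  invisible(length(ps$bond_i))
}

#' Register an angular hinge on a particle triplet
#'
#' The hinge resists deviation of the angle at vertex `j` (between arms
#' `j->i` and `j->k`) from `rest_angle`, with potential
#' `U = 0.5 * stiffness * (theta - rest_angle)^2`.
#'
#' @param ps A [particle_system()].
#' @param i,j,k Three distinct particle ids; `j` is the vertex.
#' @param stiffness Angular stiffness k_a, N m rad^-1 per unit width.
#' @param rest_angle Rest angle in radians, within `[0, pi]`.
#' @return The hinge index, invisibly.
#' @export
add_hinge <- function(ps, i, j, k, stiffness, rest_angle) {
  n <- length(ps$x)
  ids <- c(i, j, k)
  if (any(ids < 1 | ids > n)) stop("hinge id does not exist")
  if (anyDuplicated(ids)) stop("hinge ids must be distinct")
  if (rest_angle < 0 || rest_angle > pi) stop("rest_angle must lie in [0, pi]")
  ps$hinge_i <- c(ps$hinge_i, as.integer(i))
  ps$hinge_j <- c(ps$hinge_j, as.integer(j))
  ps$hinge_k <- c(ps$hinge_k, as.integer(k))
  ps$hinge_ka <- c(ps$hinge_ka, stiffness)
  ps$hinge_rest <- c(ps$hinge_rest, rest_angle)
  invisible(length(ps$hinge_i))
}

#' Census of particle kinds
#'
#' @param ps A [particle_system()].
#' @return Named integer vector over all four kinds; sums to
#'   [particle_count()].
#' @export
kind_census <- function(ps) {
  out <- stats::setNames(integer(length(PARTICLE_KINDS)), PARTICLE_KINDS)
  tab <- table(ps$kind)
  out[names(tab)] <- as.integer(tab)
  out
}

#' @export
print.particle_system <- function(x, ...) {
  cen <- kind_census(x)
  cat("<particle_system> ", particle_count(x), " particles (",
      paste(names(cen), cen, sep = ":", collapse = ", "), ")\n", sep = "")
  cat("  bonds: ", bond_count(x), " active / ", length(x$bond_i),
      ", hinges: ", length(x$hinge_i), "\n", sep = "")
  cat("  clock: step ", x$step, ", t = ", format(x$time), " s\n", sep = "")
  invisible(x)
}

#' Snapshot data frame of a particle system
#'
#' @param x A [particle_system()].
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return A data frame with columns `id, kind, x, y, vx, vy, rho, p`.
#' @export
as.data.frame.particle_system <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(id = seq_along(x$x), kind = x$kind,
             x = x$x, y = x$y, vx = x$vx, vy = x$vy,
             rho = x$rho, p = x$pressure,
             stringsAsFactors = FALSE)
}

# internal: state list handed to the compiled stepper
ps_state <- function(ps) {
  list(kind = kind_code(ps$kind),
       x = ps$x, y = ps$y, vx = ps$vx, vy = ps$vy,
       mass = ps$mass, anchored = as.integer(ps$anchored),
       ext_fx = ps$ext_fx, ext_fy = ps$ext_fy,
       bond_i = ps$bond_i, bond_j = ps$bond_j, bond_k = ps$bond_k,
       bond_rest = ps$bond_rest, bond_thr = ps$bond_thr,
       bond_active = as.integer(ps$bond_active),
       hinge_i = ps$hinge_i, hinge_j = ps$hinge_j, hinge_k = ps$hinge_k,
       hinge_ka = ps$hinge_ka, hinge_rest = ps$hinge_rest)
}

# internal: write integrator output back into the system
ps_absorb <- function(ps, res, nsteps, dt) {
  ps$x <- res$x; ps$y <- res$y; ps$vx <- res$vx; ps$vy <- res$vy
  ps$rho <- res$rho; ps$pressure <- res$p
  ps$fx <- res$fx; ps$fy <- res$fy
  ps$bond_active <- as.logical(res$bond_active)
  ps$step <- ps$step + as.integer(nsteps)
  ps$time <- res$t
  invisible(ps)
}
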