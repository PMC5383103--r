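#' Aggregation (liquid-to-solid phase change) configuration
#'
#' Parameters of the seeded growth algorithm: every `interval_steps` time
#' steps, each active seed identifies the fluid particles within
#' `capture_radius` and converts each with probability
#' `conversion_probability`, relabeling it `AGGREGATE`, bonding it to the
#' seed (rest length = distance at conversion, i.e. stress-free birth), and
#' making it a seed for the next invocation. In `circular` mode previous
#' seeds stay active (compact, roughly circular deposits); in `filiform`
#' mode a seed is active for a single invocation and converts at most one
#' particle, producing thread-like aggregates.
#'
#' @param interval_steps Steps between aggregation invocations (>= 1).
#' @param capture_radius Capture distance R_MAX, m (> 0).
#' @param conversion_probability Per-candidate conversion probability in
#'   `[0, 1]`.
#' @param mode `"circular"` or `"filiform"`.
#' @param max_new_per_seed Cap on conversions per seed per invocation;
#'   defaults to unlimited for circular and 1 for filiform growth.
#' @param bond_stiffness Stiffness of aggregate bonds, N m^-1; the default
#'   puts the fragmentation threshold at a 1 percent bond strain of the
#'   capture radius.
#' @param break_threshold Bond tension (N) above which an aggregate bond
#'   breaks; default `1.3e-7` N.
#' @return An `aggregation_config` list.
#' @export
aggregation_config <- function(interval_steps, capture_radius,
                               conversion_probability,
                               mode = c("circular", "filiform"),
                               max_new_per_seed = NULL,
                               bond_stiffness = NULL,
                               break_threshold = 1.3e-7) {
  mode <- match.arg(mode)
  if (interval_steps < 1) stop("interval_steps must be >= 1")
  if (capture_radius <= 0) stop("capture_radius must be > 0")
  if (conversion_probability < 0 || conversion_probability > 1)
    stop("conversion_probability must lie in [0, 1]")
  if (is.null(max_new_per_seed))
    max_new_per_seed <- if (mode == "filiform") 1 else Inf
  if (is.null(bond_stiffness))
    bond_stiffness <- break_threshold / (0.01 * capture_radius)
  structure(list(interval_steps = as.integer(interval_steps),
                 capture_radius = capture_radius,
                 conversion_probability = conversion_probability,
                 mode = mode, max_new_per_seed = max_new_per_seed,
                 bond_stiffness = bond_stiffness,
                 break_threshold = break_threshold),
            class = "aggregation_config")
}

empty_events <- function() {
  data.frame(time = numeric(0), step = integer(0), kind = character(0),
             id = integer(0), seed = integer(0), bond_i = integer(0),
             bond_j = integer(0), tension = numeric(0),
             stringsAsFactors = FALSE)
}

pair_dist <- function(ps, ids_a, x0, y0) {
  dx <- ps$x[ids_a] - x0
  if (!is.null(ps$box)) {
    Lx <- ps$box[2] - ps$box[1]
    dx <- dx - Lx * round(dx / Lx)
  }
  sqrt(dx^2 + (ps$y[ids_a] - y0)^2)
}

#' Select aggregation seeds
#'
#' Seeds either by explicit particle ids or by a shear-stress criterion
#' (particles whose local shear exceeds `tau_star`). Explicitly selected
#' fluid particles are relabeled `AGGREGATE`; wall or membrane particles may
#' also be designated as initial seeds, keeping their kind. Selected
#' particles are flagged `seed_active`.
#'
#' @param ps A [particle_system()].
#' @param ids Explicit particle ids (explicit mode; must be non-empty).
#' @param shear Per-particle shear-stress magnitudes, Pa (criterion mode).
#' @param tau_star Shear threshold, Pa; fluid particles with
#'   `shear > tau_star` become seeds (possibly none, without error).
#' @param anchor Anchor the seeds in place (deposits pinned to a wall or
#'   leaflet)?
#' @return The seed ids, invisibly.
#' @export
select_seeds <- function(ps, ids = NULL, shear = NULL, tau_star = NULL,
                         anchor = FALSE) {
  if (!is.null(ids)) {
    if (length(ids) == 0) stop("explicit seed selection must be non-empty")
    if (!all(ids >= 1 & ids <= particle_count(ps))) stop("unknown seed id")
    fl <- ids[ps$kind[ids] == "FLUID"]
    if (length(fl)) convert_kind(ps, fl, "AGGREGATE")
  } else {
    if (is.null(shear) || is.null(tau_star))
      stop("criterion mode needs both a shear field and tau_star")
    if (length(shear) != particle_count(ps))
      stop("shear field length must match the particle count")
    ids <- which(ps$kind == "FLUID" & shear > tau_star)
    if (length(ids)) convert_kind(ps, ids, "AGGREGATE")
  }
  if (length(ids)) {
    ps$seed_active[ids] <- TRUE
    if (anchor) ps$anchored[ids] <- TRUE
  }
  invisible(ids)
}

#' One aggregation invocation
#'
#' For each active seed (ascending id), fluid candidates within the capture
#' radius are visited in (distance, id) order with one RNG draw each;
#' successful candidates are converted to `AGGREGATE`, bonded to the seed
#' with rest length equal to the current separation, and flagged as seeds
#' for the next invocation. Bonds connect only a seed and a formerly-fluid
#' particle, never two existing aggregate particles, so the aggregate bond
#' graph is a forest by construction. In filiform mode the previous seeds
#' are deactivated after the invocation.
#'
#' @param ps A [particle_system()] with at least one active seed.
#' @param cfg An [aggregation_config()].
#' @return Event data frame (one `convert` row per conversion).
#' @export
aggregation_step <- function(ps, cfg) {
  if (!inherits(cfg, "aggregation_config")) stop("invalid aggregation config")
  seeds <- which(ps$seed_active)
  if (length(seeds) == 0) stop("aggregation_step called with no active seed")
  ev <- list()
  new_ids <- integer(0)
  for (sd in sort(seeds)) {
    cand <- which(ps$kind == "FLUID")
    if (length(cand) == 0) break
    dist <- pair_dist(ps, cand, ps$x[sd], ps$y[sd])
    keep <- dist <= cfg$capture_radius
    cand <- cand[keep]; dist <- dist[keep]
    ord <- order(dist, cand)
    cand <- cand[ord]
    dist <- dist[ord]
    converted <- 0L
    for (qi in seq_along(cand)) {
      if (converted >= cfg$max_new_per_seed) break
      id <- cand[qi]
      if (ps$kind[id] != "FLUID") next
      if (stats::runif(1) < cfg$conversion_probability) {
        convert_kind(ps, id, "AGGREGATE")
        add_bond(ps, sd, id, cfg$bond_stiffness, max(dist[qi], 1e-12),
                 cfg$break_threshold)
        new_ids <- c(new_ids, id)
        converted <- converted + 1L
        ev[[length(ev) + 1]] <- data.frame(
          time = ps$time, step = ps$step, kind = "convert",
          id = id, seed = sd, bond_i = sd, bond_j = id, tension = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (cfg$mode == "filiform") ps$seed_active[seeds] <- FALSE
  if (length(new_ids)) ps$seed_active[new_ids] <- TRUE
  if (length(ev)) do.call(rbind, ev) else empty_events()
}

#' Fragmentation check
#'
#' Computes the current tension of every active bond and removes, in the
#' same step, every breakable bond whose tension exceeds its break
#' threshold. Because aggregate bonds form a forest, removing `b` bonds
#' increases the number of connected components by exactly `b`.
#'
#' @param ps A [particle_system()].
#' @return Event data frame (one `break` row per removed bond).
#' @export
fragment_step <- function(ps) {
  if (length(ps$bond_i) == 0) return(empty_events())
  tension <- attr(spring_forces(ps), "tension")
  brk <- which(ps$bond_active & is.finite(ps$bond_thr) & tension > ps$bond_thr)
  if (length(brk) == 0) return(empty_events())
  ps$bond_active[brk] <- FALSE
  data.frame(time = ps$time, step = ps$step, kind = "break",
             id = NA_integer_, seed = NA_integer_,
             bond_i = ps$bond_i[brk], bond_j = ps$bond_j[brk],
             tension = tension[brk], stringsAsFactors = FALSE)
}

#' Connected components of the aggregate bond graph
#'
#' Union-find over the active bonds whose endpoints both belong to the
#' aggregate node set (`AGGREGATE` particles plus any explicitly included
#' ids, e.g. a wall- or membrane-designated initial seed).
#'
#' @param ps A [particle_system()].
#' @param include Extra particle ids treated as part of the aggregate graph.
#' @return Integer component labels (1, 2, ...) named by particle id.
#' @export
aggregate_components <- function(ps, include = integer(0)) {
  agg <- sort(unique(c(which(ps$kind == "AGGREGATE"), as.integer(include))))
  if (length(agg) == 0) return(stats::setNames(integer(0), character(0)))
  inset <- logical(particle_count(ps))
  inset[agg] <- TRUE
  parent <- seq_len(particle_count(ps))
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  keep <- ps$bond_active & inset[ps$bond_i] & inset[ps$bond_j]
  for (q in which(keep)) {
    ra <- find(ps$bond_i[q]); rb <- find(ps$bond_j[q])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(agg, find, integer(1))
  stats::setNames(match(roots, unique(roots)), agg)
}
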