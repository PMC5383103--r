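#' Run a coupled simulation
#'
#' Advances a scene for `duration` seconds with the kick-drift-kick WCSPH /
#' mass-spring integrator, applying the aggregation algorithm every
#' `interval_steps` steps (when configured) and checking bond fragmentation
#' every step. All randomness (the conversion draws) comes from R's RNG:
#' set `seed` for bit-reproducible event logs.
#'
#' @param scene An `sph_scene` from [build_valve()] or [build_channel()].
#' @param duration Simulated time, s.
#' @param dt Time step, s (default: the scene's stable step).
#' @param aggregation Optional [aggregation_config()]; seeds must have been
#'   selected with [select_seeds()] first.
#' @param snapshot_every Interval between stored snapshots, s (`NULL` for
#'   none; the final state is always available in `scene$ps`).
#' @param probe Particle ids whose mean streamwise velocity is traced.
#' @param damping Velocity-proportional damping (static tests only).
#' @param fragment Check bond break thresholds every step (default TRUE).
#' @param seed RNG seed for the aggregation draws.
#' @param verbose Print per-burst progress?
#' @return List with the updated `scene`, per-step `trace` (time, max fluid
#'   speed, probe velocity, density fluctuation), unified `events` log
#'   (conversions and bond breaks), `snapshots`, and diagnostics
#'   (`max_imbalance`, `max_drho`, `max_speed`, `nsub`).
#' @export
run_simulation <- function(scene, duration, dt = NULL, aggregation = NULL,
                           snapshot_every = NULL, probe = integer(0),
                           damping = 0, fragment = TRUE, seed = NULL,
                           verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dt)) dt <- scene$dt
  ps <- scene$ps
  nsteps <- max(1L, round(duration / dt))
  agg_n <- if (!is.null(aggregation)) aggregation$interval_steps else nsteps
  snap_n <- if (!is.null(snapshot_every)) max(1L, round(snapshot_every / dt)) else Inf
  traces <- list(); events <- list(); snapshots <- list()
  diag <- list(max_imbalance = 0, max_drho = 0, max_speed = 0, nsub = 1)
  done <- 0L
  next_snap <- snap_n
  while (done < nsteps) {
    burst <- min(agg_n, next_snap - done, nsteps - done)
    r <- advance_system(ps, scene$kernel, scene$fluid, scene$forcing,
                        scene$repulsion, dt, burst, damping = damping,
                        break_check = fragment, probe = probe,
                        check_cfl = (done == 0L))
    done <- done + burst
    traces[[length(traces) + 1]] <- r$trace
    if (nrow(r$events) > 0) {
      ev <- r$events
      events[[length(events) + 1]] <- data.frame(
        time = ev$time, step = ps$step - burst + ev$step, kind = "break",
        id = NA_integer_, seed = NA_integer_,
        bond_i = ev$i, bond_j = ev$j, tension = ev$tension,
        stringsAsFactors = FALSE)
    }
    diag$max_imbalance <- max(diag$max_imbalance, r$max_imbalance)
    diag$max_drho <- max(diag$max_drho, r$max_drho)
    diag$max_speed <- max(diag$max_speed, r$max_speed)
    diag$nsub <- max(diag$nsub, r$nsub)
    if (!is.null(aggregation) && done %% agg_n == 0L &&
        any(ps$seed_active) && done < nsteps) {
      ev <- aggregation_step(ps, aggregation)
      if (nrow(ev) > 0) events[[length(events) + 1]] <- ev
    }
    if (done >= next_snap) {
      sn <- as.data.frame(ps)
      attr(sn, "time") <- ps$time
      snapshots[[length(snapshots) + 1]] <- sn
      next_snap <- next_snap + snap_n
    }
    if (verbose)
      message(sprintf("t = %.4f s (%d/%d steps), max speed %.3g m/s",
                      ps$time, done, nsteps, diag$max_speed))
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_events()
  ev <- ev[order(ev$time), , drop = FALSE]
  list(scene = scene, trace = do.call(rbind, traces), events = ev,
       snapshots = snapshots, max_imbalance = diag$max_imbalance,
       max_drho = diag$max_drho, max_speed = diag$max_speed,
       nsub = diag$nsub)
}

#' Write an event log as JSON lines
#' @param events Event data frame from [run_simulation()].
#' @param path Output path (one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (q in seq_len(nrow(events)))
    writeLines(jsonlite::toJSON(as.list(events[q, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Validation suites (analytic oracles at desk scale)

#' Poiseuille channel validation
#'
#' Steady body-forced plane channel at rest start; the terminal velocity
#' profile is compared with the analytic parabola. The fixture uses a
#' generic viscous fluid scaled so the flow settles in a few seconds of
#' simulated time.
#'
#' @param spacing Lattice spacing, m (default `Z/10`).
#' @param Z Channel half-thickness, m.
#' @param duration Simulated time, s (several viscous times).
#' @return List with `l2_error`, `tol`, `pass`, `max_drho`,
#'   `max_imbalance`, and the sampled `profile`.
#' @export
validate_poiseuille <- function(spacing = 1e-3, Z = 0.01, duration = 3) {
  fluid <- fluid_spec(1000, 0.1, sound_speed = 0.05)
  g <- 0.01
  forcing <- forcing_spec(g, 1, waveform = "constant")
  scene <- build_channel(Z, length = 4 * Z, spacing = spacing, fluid = fluid,
                         forcing = forcing)
  res <- run_simulation(scene, duration)
  ps <- scene$ps
  fl <- ps$kind == "FLUID"
  ua <- poiseuille_profile(ps$y[fl], G = fluid$rest_density * g,
                           mu = fluid$dynamic_viscosity, Z = Z)
  l2 <- sqrt(sum((ps$vx[fl] - ua)^2) / sum(ua^2))
  list(l2_error = l2, tol = 0.05, pass = l2 <= 0.05,
       max_drho = res$max_drho, max_imbalance = res$max_imbalance,
       profile = data.frame(y = ps$y[fl], u = ps$vx[fl], u_analytic = ua),
       n = sum(fl))
}

#' Womersley oscillating-channel validation
#'
#' Sinusoidally forced plane channel; the centerline velocity amplitude in
#' the periodic regime is compared with the analytic oscillating-channel
#' solution (Womersley number about 3 at the defaults).
#'
#' @param spacing Lattice spacing, m.
#' @param Z Channel half-thickness, m.
#' @param periods Number of forcing periods to run (the last one is
#'   measured).
#' @return List with `amplitude`, `amplitude_analytic`, `rel_error`, `tol`,
#'   `pass`, `max_drho`, `max_imbalance`.
#' @export
validate_womersley <- function(spacing = 1e-3, Z = 0.01, periods = 6) {
  rho <- 1000; mu <- 1
  om <- 90 # rad/s -> Womersley alpha = Z * sqrt(om * rho / mu) = 3
  f <- om / (2 * pi)
  g0 <- 4.5
  fluid <- fluid_spec(rho, mu, sound_speed = 0.5)
  forcing <- forcing_spec(g0, f)
  scene <- build_channel(Z, length = 4 * Z, spacing = spacing, fluid = fluid,
                         forcing = forcing)
  ps <- scene$ps
  probe <- which(ps$kind == "FLUID" & abs(ps$y) < spacing / 2)
  dt <- scene$dt
  Tn <- 1 / f
  res <- run_simulation(scene, periods * Tn, dt = dt, probe = probe)
  tr <- res$trace
  last <- tr$time > (periods - 1) * Tn
  amp <- (max(tr$probe_vx[last]) - min(tr$probe_vx[last])) / 2
  ref <- womersley_amplitude(G0 = rho * g0, f = f, rho = rho, mu = mu, Z = Z)
  rel <- abs(amp - ref) / ref
  list(amplitude = amp, amplitude_analytic = ref, rel_error = rel,
       tol = 0.10, pass = rel <= 0.10,
       max_drho = res$max_drho, max_imbalance = res$max_imbalance,
       n = sum(ps$kind == "FLUID"))
}

#' Cantilever (mass-spring membrane) validation
#'
#' A clamped chain under a small transverse tip load is relaxed with damped
#' dynamics; the static tip deflection is compared with the Euler-Bernoulli
#' value `P L^3 / (3 F)` using the clamp-to-tip length.
#'
#' @param tip_load Tip load, N per unit width.
#' @param duration Relaxation time, s.
#' @return List with `deflection`, `deflection_analytic`, `rel_error`,
#'   `tol`, `pass`.
#' @export
validate_cantilever <- function(tip_load = 1e-3, duration = 0.04) {
  l0 <- 5e-4
  k <- membrane_constants(d = 3e-4, F = 0.008, l0 = l0)
  mem <- membrane_spec(k$k_a, k$k_b, l0)
  fix <- build_cantilever(mem, L = 0.016, tip_load = tip_load)
  fluid <- fluid_spec(1000, 1e-3, 10) # inert: no fluid particles present
  kern <- kernel_spec(l0)
  nst <- round(duration / 1e-5)
  advance_system(fix$ps, kern, fluid, NULL, NULL, dt = 1e-5, nsteps = nst,
                 damping = 0.5, break_check = FALSE)
  tip <- fix$ids[length(fix$ids)]
  defl <- -fix$ps$y[tip]
  ref <- cantilever_tip_deflection(tip_load, fix$L_eff, mem$F)
  rel <- abs(defl - ref) / ref
  list(deflection = defl, deflection_analytic = ref, rel_error = rel,
       tol = 0.05, pass = rel <= 0.05, residual_speed = max(abs(fix$ps$vy)))
}

#' Aggregation lattice-count validation
#'
#' Single circular invocation with conversion probability 1 on a quiescent
#' unit lattice: capture radius 1.2 converts exactly the 4 axial neighbors
#' (diagonals at sqrt(2) excluded); capture radius 1.5 converts exactly 8.
#'
#' @return List with `count_r12`, `count_r15`, `pass`.
#' @export
validate_aggregation_lattice <- function() {
  mk <- function() {
    ps <- particle_system()
    g <- expand.grid(x = -10:10, y = -10:10)
    add_particles(ps, "FLUID", cbind(g$x, g$y), mass = 1)
    ps
  }
  counts <- vapply(c(1.2, 1.5), function(rmax) {
    ps <- mk()
    ctr <- which(ps$x == 0 & ps$y == 0)
    select_seeds(ps, ids = ctr)
    cfg <- aggregation_config(1, rmax, 1, mode = "circular",
                              bond_stiffness = 1)
    nrow(aggregation_step(ps, cfg))
  }, numeric(1))
  list(count_r12 = counts[1], count_r15 = counts[2],
       pass = counts[1] == 4 && counts[2] == 8)
}

# ---------------------------------------------------------------------------
# Study scenarios

#' Peak-velocity scenario (coarse pulsatile valve run)
#'
#' Runs the full pulsatile valve scene (sinusoidal forcing, blood
#' properties, default geometry) at the coarse lattice spacing and measures
#' the peak channel velocity: the largest streamwise particle speed in a
#' cross-section slab of the straight channel far upstream of the valve.
#' The run is truncated once the fastest fluid particle exceeds the sound
#' speed, beyond which the weakly-compressible solution is no longer
#' meaningful; the reported peak is taken over the valid (subsonic) window.
#'
#' @param spacing Lattice spacing, m.
#' @param sound_speed Numerical sound speed, m s^-1 (reduced, desk scale).
#' @param horizon Maximum simulated time, s (one forcing cycle).
#' @param burst Burst length between validity checks, s.
#' @return List with `peak_velocity` (m s^-1), `peak_velocity_mean` (slab
#'   cross-section mean), `valid_until` (s), `elapsed` (s simulated),
#'   `trace`, and the final `scene`.
#' @export
peak_velocity_scenario <- function(spacing = 1e-3, sound_speed = 15,
                                   horizon = 1, burst = 0.01) {
  scene <- build_valve(valve_geometry(spacing = spacing),
                       fluid = blood(sound_speed = sound_speed))
  ps <- scene$ps
  bx <- ps$box
  slab <- which(ps$kind == "FLUID" & ps$x < bx[1] + 4 * spacing)
  dt <- 0.25 * scene$kernel$h / (2 * sound_speed)
  traces <- list()
  repeat {
    res <- run_simulation(scene, burst, dt = dt, probe = slab)
    traces[[length(traces) + 1]] <- res$trace
    if (res$max_speed > sound_speed || ps$time >= horizon) break
  }
  tr <- do.call(rbind, traces)
  nvalid <- Position(function(v) v > sound_speed, tr$max_speed,
                     nomatch = nrow(tr) + 1) - 1
  valid <- seq_len(nvalid)
  list(peak_velocity = if (nvalid > 0) max(tr$probe_max_vx[valid]) else NA_real_,
       peak_velocity_mean = if (nvalid > 0) max(abs(tr$probe_vx[valid])) else NA_real_,
       valid_until = if (nvalid > 0) tr$time[nvalid] else 0,
       elapsed = ps$time, trace = tr, scene = scene, n = particle_count(ps))
}

#' Fragmentation scenario (filiform clot at the leaflet tip)
#'
#' Grows a filiform aggregate seeded at the lower leaflet tip in quiescent
#' fluid (the valve scene is first relaxed with damping and re-initialized
#' at rest, so the freshly created bonds are stress-free), then switches on
#' the pulsatile forcing and advances until the first bond tension crosses
#' the break threshold. The fragmentation contract removes every
#' over-threshold bond in that step; because the bonded aggregate is a
#' tree, removing `b` bonds yields `b + 1` parts (one part stays attached
#' to the leaflet, the rest float free).
#'
#' @param spacing Lattice spacing, m.
#' @param sound_speed Numerical sound speed, m s^-1.
#' @param n_grow Number of growth invocations (chain length).
#' @param interval_steps Aggregation interval N, steps.
#' @param settle_time Damped relaxation time before growth, s.
#' @param break_threshold Bond break threshold, N.
#' @param seed RNG seed for the conversion draws.
#' @param max_time Cap on the forced phase, s.
#' @return List with `parts` (components of the seed + aggregate graph
#'   after the first crossing), `n_aggregate`, `broken` (bonds removed at
#'   the first crossing), `t_break` (s after forcing onset), `events`, and
#'   the `scene`.
#' @export
fragmentation_scenario <- function(spacing = 1e-3, sound_speed = 15,
                                   n_grow = 10, interval_steps = 25,
                                   settle_time = 0.4,
                                   break_threshold = 1.3e-7, seed = 1,
                                   max_time = 0.5) {
  scene <- build_valve(valve_geometry(spacing = spacing),
                       fluid = blood(sound_speed = sound_speed))
  ps <- scene$ps
  dt <- 0.25 * scene$kernel$h / (2 * sound_speed)
  quiet <- scene
  quiet$forcing <- NULL
  run_simulation(quiet, settle_time, dt = dt, damping = 0.5)
  # re-initialize at rest: quiescent start, stress-free bond birth
  ps$vx[] <- 0; ps$vy[] <- 0
  ps$time <- 0; ps$step <- 0L
  tip <- scene$leaflets$lower[length(scene$leaflets$lower)]
  select_seeds(ps, ids = tip)
  cfg <- aggregation_config(interval_steps, 1.5 * spacing, 1,
                            mode = "filiform",
                            break_threshold = break_threshold)
  # grow on the quiescent scene: every bond is born stress-free, so the
  # intact chain enters the forced phase with zero tension everywhere
  set.seed(seed)
  events <- list()
  for (q in seq_len(n_grow)) {
    ev <- aggregation_step(ps, cfg)
    if (nrow(ev)) events[[length(events) + 1]] <- ev
  }
  events <- if (length(events)) do.call(rbind, events) else empty_events()
  n_agg <- sum(ps$kind == "AGGREGATE")
  # forced phase: advance until the first threshold crossing
  t0 <- ps$time
  broken <- events[events$kind == "break", , drop = FALSE]
  while (nrow(broken) == 0 && ps$time - t0 < max_time) {
    # single steps: stop exactly at the step of the first crossing
    res <- run_simulation(scene, dt, dt = dt)
    if (nrow(res$events)) broken <- res$events[res$events$kind == "break", , drop = FALSE]
  }
  comp <- aggregate_components(ps, include = tip)
  list(parts = length(unique(comp)), n_aggregate = n_agg,
       broken = nrow(broken), t_break = ps$time - t0,
       events = rbind(events, broken), scene = scene,
       n = particle_count(ps))
}

# ---------------------------------------------------------------------------
# Run configuration (structured text, YAML)

#' Read / write a run configuration
#'
#' The run configuration is a YAML document holding the scene type and
#' geometry, fluid, membrane (`d` and `F`), forcing, repulsion and optional
#' aggregation parameters plus run controls (duration, dt, snapshot
#' cadence, RNG seed). It round-trips losslessly through
#' [write_run_config()].
#'
#' @param path YAML file path.
#' @return The configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scene) || is.null(cfg$scene$type))
    stop("malformed run config: missing scene.type")
  if (!cfg$scene$type %in% c("valve", "channel"))
    stop("malformed run config: unknown scene type '", cfg$scene$type, "'")
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg A `run_config` list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build a scene from a run configuration
#' @param cfg A `run_config` from [read_run_config()].
#' @return An `sph_scene`.
#' @export
build_scene_from_config <- function(cfg) {
  sc <- cfg$scene
  fl <- cfg$fluid
  fluid <- if (is.null(fl)) blood()
           else fluid_spec(fl$rest_density, fl$dynamic_viscosity,
                           fl$sound_speed,
                           if (is.null(fl$eos_exponent)) 7 else fl$eos_exponent)
  fo <- cfg$forcing
  forcing <- if (is.null(fo)) forcing_spec(500, 1)
             else forcing_spec(fo$amplitude, fo$frequency,
                               if (is.null(fo$waveform)) "sinusoidal" else fo$waveform)
  if (sc$type == "channel") {
    return(build_channel(sc$Z, sc$length, sc$spacing, fluid, forcing))
  }
  geom <- valve_geometry(Z = sc$Z %||% 0.0125, L = sc$L %||% 0.016,
                         R = sc$R %||% 0.0215, spacing = sc$spacing %||% 1e-3)
  mem <- NULL
  if (!is.null(cfg$membrane)) {
    nm <- floor(geom$L / geom$spacing) + 1
    l0 <- geom$L / (nm - 1)
    kk <- membrane_constants(cfg$membrane$d, cfg$membrane$F, l0)
    mem <- membrane_spec(kk$k_a, kk$k_b, l0)
  }
  build_valve(geom, fluid = fluid, membrane = mem, forcing = forcing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Command-line entry point (thin wrapper; see inst/cli/sphvalve.R)

cli_usage <- function() {
  cat("usage: sphvalve <build|run|analyze|validate> [options]\n",
      "  build    --config FILE --out FILE.csv\n",
      "  run      --config FILE --out DIR [--seed N] [--duration S]",
      " [--snapshot-every S]\n",
      "  analyze  --snapshot FILE.csv --config FILE --out PREFIX\n",
      "  validate <poiseuille|womersley|cantilever|aggregation-lattice>\n",
      sep = "")
}

cli_opts <- function(args) {
  out <- list(); pos <- character(0)
  q <- 1
  while (q <= length(args)) {
    a <- args[q]
    if (startsWith(a, "--")) {
      if (q == length(args)) stop("missing value for ", a)
      out[[substring(a, 3)]] <- args[q + 1]
      q <- q + 2
    } else {
      pos <- c(pos, a)
      q <- q + 1
    }
  }
  out$positional <- pos
  out
}

#' Command-line interface
#'
#' Subcommands: `build` (construct a scene from a config and write its
#' initial snapshot), `run` (time integration with snapshot cadence and
#' event log), `analyze` (field reconstruction and membrane kinematics from
#' a snapshot), and `validate` (the analytic validation suites; non-zero
#' exit on failure).
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 = success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) { cli_usage(); return(invisible(2L)) }
    cmd <- args[1]
    opt <- cli_opts(args[-1])
    if (cmd == "validate") {
      suite <- opt$positional[1]
      if (is.na(suite) || !suite %in%
          c("poiseuille", "womersley", "cantilever", "aggregation-lattice")) {
        cli_usage(); return(invisible(2L))
      }
      r <- switch(suite,
                  poiseuille = validate_poiseuille(),
                  womersley = validate_womersley(),
                  cantilever = validate_cantilever(),
                  `aggregation-lattice` = validate_aggregation_lattice())
      for (nm in setdiff(names(r), "profile"))
        if (is.atomic(r[[nm]]) && length(r[[nm]]) == 1)
          cat(nm, "=", format(r[[nm]]), "\n")
      return(invisible(if (isTRUE(r$pass)) 0L else 1L))
    }
    if (cmd == "build") {
      cfg <- read_run_config(opt$config)
      scene <- build_scene_from_config(cfg)
      compute_density(scene$ps, scene$kernel)
      compute_pressure(scene$ps, scene$fluid)
      write_snapshot(scene$ps, opt$out)
      cat("scene:", particle_count(scene$ps), "particles; spacing",
          scene$spacing, "m; dt", scene$dt, "s\n")
      return(invisible(0L))
    }
    if (cmd == "run") {
      cfg <- read_run_config(opt$config)
      scene <- build_scene_from_config(cfg)
      duration <- as.numeric(opt$duration %||% cfg$run$duration %||% 1)
      snap <- as.numeric(opt[["snapshot-every"]] %||%
                           cfg$run$snapshot_every %||% (duration / 10))
      seed <- as.integer(opt$seed %||% cfg$run$seed %||% 1)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      res <- run_simulation(scene, duration, snapshot_every = snap,
                            seed = seed)
      for (q in seq_along(res$snapshots))
        write_snapshot(res$snapshots[[q]],
                       file.path(opt$out, sprintf("snapshot_%04d.csv", q)))
      write_snapshot(scene$ps, file.path(opt$out, "final.csv"))
      write_snapshot(scene$ps, file.path(opt$out, "final.vtk"), format = "vtk")
      write_events(res$events, file.path(opt$out, "events.jsonl"))
      utils::write.csv(res$trace, file.path(opt$out, "trace.csv"),
                       row.names = FALSE)
      cat("run complete: max speed", format(res$max_speed),
          "m/s, max density fluctuation", format(res$max_drho), "\n")
      return(invisible(0L))
    }
    if (cmd == "analyze") {
      cfg <- read_run_config(opt$config)
      scene <- build_scene_from_config(cfg)
      df <- read_snapshot(opt$snapshot)
      ps <- scene$ps
      ps$x <- df$x; ps$y <- df$y; ps$vx <- df$vx; ps$vy <- df$vy
      ps$rho <- df$rho; ps$pressure <- df$p; ps$kind <- df$kind
      grid <- scene_grid(scene)
      gi <- interpolate_grid(ps, scene$kernel, grid)
      tau <- shear_stress_field(ps, scene$kernel, grid,
                                scene$fluid$dynamic_viscosity)
      xy <- grid_xy(grid)
      flat <- expand.grid(y = xy$y, x = xy$x)[, c("x", "y")]
      utils::write.csv(cbind(flat, speed = as.vector(gi$speed),
                             tau = as.vector(tau$tau)),
                       paste0(opt$out, "_fields.csv"), row.names = FALSE)
      U <- max(sqrt(df$vx^2 + df$vy^2)[df$kind == "FLUID"])
      dims <- dimensionless_set(scene$fluid$rest_density, max(U, 1e-12),
                                scene$geom$Z, scene$fluid$dynamic_viscosity,
                                scene$forcing$frequency,
                                scene$membrane$d %||% 1e-4,
                                scene$membrane$F %||% 1, scene$geom$L %||% 1)
      print(dims)
      return(invisible(0L))
    }
    cli_usage()
    invisible(2L)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    cli_usage()
    invisible(1L)
  })
  invisible(status)
}
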