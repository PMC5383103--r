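# Independent oracles used by the DERIVED-value tests. These deliberately
# re-derive results with brute-force / third-party routes, never through the
# package's own optimized paths.

# all-pairs O(n^2) neighbor search with minimum image in x
brute_neighbors <- function(x, y, support, Lx = NULL) {
  n <- length(x)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      dx <- x[i] - x[j]
      if (!is.null(Lx)) dx <- dx - Lx * round(dx / Lx)
      dy <- y[i] - y[j]
      r <- sqrt(dx^2 + dy^2)
      if (r < support) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

pair_key_set <- function(i, j) sort(paste(pmin(i, j), pmax(i, j), sep = "-"))

# direct-summation density at one point from explicit positions
brute_density_at <- function(xi, yi, x, y, m, h) {
  r <- sqrt((x - xi)^2 + (y - yi)^2)
  q <- r / h
  sig <- 10 / (7 * pi * h^2)
  w <- ifelse(q < 1, sig * (1 - 1.5 * q^2 + 0.75 * q^3),
              ifelse(q < 2, sig * 0.25 * (2 - q)^3, 0))
  sum(m * w)
}

# independent enumeration of the channel fluid lattice (point-in-region)
channel_fluid_count <- function(Z, length_, s) {
  ncol_ <- floor(length_ / s)
  ks <- seq(-ceiling(Z / s) - 5, ceiling(Z / s) + 5)
  rows <- sum(abs(ks * s) - Z < -0.25 * s)
  ncol_ * rows
}

# independent enumeration of the valve-scene lattices, following the
# documented placement rules (strip-union-disk signed distance, leaflet
# clearances) with plain loops
valve_counts <- function(geom, tip_gap = geom$spacing) {
  s <- geom$spacing; Z <- geom$Z; L <- geom$L; R <- geom$R
  cx <- R
  nm <- floor(L / s) + 1
  l0 <- L / (nm - 1)
  xt <- sqrt(L^2 - (Z - tip_gap / 2)^2)
  mem <- NULL
  for (sgn in c(1, -1)) {
    root <- c(0, sgn * Z); tip <- c(xt, sgn * tip_gap / 2)
    u <- (tip - root) / sqrt(sum((tip - root)^2))
    for (k in 0:(nm - 1)) mem <- rbind(mem, root + k * l0 * u)
  }
  jlo <- -ceiling(geom$upstream / s)
  jhi <- ceiling((2 * R + geom$downstream) / s) - 1
  klim <- ceiling((R + geom$wall_layers * s) / s)
  nf <- 0L; nw <- 0L
  for (j in jlo:jhi) {
    for (k in -klim:klim) {
      px <- j * s; py <- k * s
      d <- min(abs(py) - Z, sqrt((px - cx)^2 + py^2) - R)
      md <- sqrt(min((px - mem[, 1])^2 + (py - mem[, 2])^2))
      if (d < -0.25 * s) {
        if (md > 0.7 * s) nf <- nf + 1L
      } else if (d < (geom$wall_layers - 0.25) * s) {
        if (md > 0.45 * s) nw <- nw + 1L
      }
    }
  }
  list(fluid = nf, wall = nw, membrane = as.integer(2 * nm))
}

# fluid lattice for aggregation fixtures
lattice_system <- function(half = 10, spacing = 1) {
  ps <- particle_system()
  g <- expand.grid(x = (-half:half) * spacing, y = (-half:half) * spacing)
  add_particles(ps, "FLUID", cbind(g$x, g$y), mass = 1)
  ps
}

# finite-difference (method of lines) integration of the oscillating
# channel PDE: u_t = g0 sin(w t) + nu u_yy, u(+-Z) = 0
womersley_fd_amplitude <- function(g0, f, rho, mu, Z, ny = 201, periods = 8) {
  nu <- mu / rho
  om <- 2 * pi * f
  y <- seq(-Z, Z, length.out = ny)
  dy <- y[2] - y[1]
  rhs <- function(t, u, parms) {
    d2 <- c(0, diff(u, differences = 2), 0) / dy^2
    du <- g0 * sin(om * t) + nu * d2
    du[1] <- 0; du[ny] <- 0
    list(du)
  }
  times <- seq(0, periods / f, by = 1 / (f * 400))
  sol <- deSolve::ode(y = numeric(ny), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  uc <- sol[, 1 + (ny + 1) / 2]
  last <- sol[, 1] > (periods - 1) / f
  (max(uc[last]) - min(uc[last])) / 2
}
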