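test_that("spring forces follow Hooke's law with Newton's third law", {
  ps <- particle_system()
  add_particles(ps, "MEMBRANE", rbind(c(0, 0), c(1, 0)), 1)
  add_bond(ps, 1, 2, stiffness = 2, rest_length = 1)
  F <- spring_forces(ps)
  expect_equal(max(abs(F)), 0) # at rest length

  ps$x[2] <- 1.1 # extension 0.1, k = 2 -> tension 0.2 N
  F <- spring_forces(ps)
  expect_equal(unname(F[1, "fx"]), 0.2)
  expect_equal(unname(F[2, "fx"]), -0.2)
  expect_equal(unname(attr(F, "tension")), 0.2)

  # bonded chain: forces sum to zero
  ps2 <- particle_system()
  set.seed(5)
  add_particles(ps2, "MEMBRANE", cbind((0:9) + rnorm(10, 0, 0.1), rnorm(10, 0, 0.1)), 1)
  for (q in 1:9) add_bond(ps2, q, q + 1, 3, 1)
  F2 <- spring_forces(ps2)
  expect_lt(attr(F2, "imbalance"), 1e-12)
})

test_that("hinge forces derive from the angular potential", {
  # straight chain at rest angle pi: no force
  ps <- particle_system()
  add_particles(ps, "MEMBRANE", rbind(c(-1, 0), c(0, 0), c(1, 0)), 1)
  add_hinge(ps, 1, 2, 3, stiffness = 1, rest_angle = pi)
  expect_equal(max(abs(hinge_forces(ps))), 0)

  # bend to theta = pi - 0.01: restoring torque magnitude k * dtheta = 0.01
  th <- pi - 0.01
  ps$x[3] <- cos(pi - th); ps$y[3] <- sin(pi - th)
  F <- hinge_forces(ps)
  torque_on_3 <- unname(ps$x[3] * F[3, 2] - ps$y[3] * F[3, 1]) # about the vertex
  expect_equal(abs(torque_on_3), 0.01, tolerance = 1e-10)
  # net force and net torque of the triplet vanish
  expect_lt(max(abs(colSums(F))), 1e-12)
  net_torque <- sum(ps$x * F[, 2] - ps$y * F[, 1])
  expect_lt(abs(net_torque), 1e-10)
})

test_that("hinge forces equal the finite-difference gradient of the potential", {
  U <- function(xy, ka, th0) {
    a <- xy[1, ] - xy[2, ]; b <- xy[3, ] - xy[2, ]
    th <- atan2(abs(a[1] * b[2] - a[2] * b[1]), sum(a * b))
    0.5 * ka * (th - th0)^2
  }
  set.seed(21)
  for (case in 1:5) {
    xy <- matrix(rnorm(6), 3, 2)
    ka <- runif(1, 0.5, 3)
    th0 <- runif(1, 0.2, pi - 0.2)
    ps <- particle_system()
    add_particles(ps, "MEMBRANE", xy, 1)
    add_hinge(ps, 1, 2, 3, ka, th0)
    F <- hinge_forces(ps)
    eps <- 1e-7
    for (i in 1:3) for (d in 1:2) {
      xp <- xy; xp[i, d] <- xp[i, d] + eps
      xm <- xy; xm[i, d] <- xm[i, d] - eps
      fd <- -(U(xp, ka, th0) - U(xm, ka, th0)) / (2 * eps)
      expect_equal(unname(F[i, d]), fd, tolerance = 1e-5)
    }
  }
})

test_that("a bent hinge relaxes monotonically under damped dynamics", {
  ps <- particle_system()
  add_particles(ps, "MEMBRANE", rbind(c(-1, 0), c(0, 0), c(0.8, 0.6)), 0.01)
  add_bond(ps, 1, 2, 50, 1); add_bond(ps, 2, 3, 50, 1)
  add_hinge(ps, 1, 2, 3, stiffness = 1, rest_angle = pi)
  kern <- kernel_spec(0.5)
  fl <- fluid_spec(1000, 1e-3, 10)
  energy <- function() {
    a <- c(ps$x[1] - ps$x[2], ps$y[1] - ps$y[2])
    b <- c(ps$x[3] - ps$x[2], ps$y[3] - ps$y[2])
    th <- atan2(abs(a[1] * b[2] - a[2] * b[1]), sum(a %*% b))
    0.5 * (th - pi)^2 + 0.5 * 50 * (sqrt(sum(a^2)) - 1)^2 +
      0.5 * 50 * (sqrt(sum(b^2)) - 1)^2 +
      0.5 * 0.01 * sum(ps$vx^2 + ps$vy^2)
  }
  e <- energy()
  for (q in 1:20) {
    sph_step(ps, kern, fl, dt = 1e-4, nsteps = 100, damping = 0.05)
    e2 <- energy()
    expect_lt(e2, e + 1e-12)
    e <- e2
  }
})

test_that("membrane property mapping matches the discrete-beam equivalence", {
  # the soft/hard membrane thickness: k_a / k_b = 7.5e-9 m^2 -> d = 3e-4 m
  p <- membrane_properties(k_a = 7.5e-9 * 2, k_b = 2, l0 = 1e-3)
  expect_equal(p$d, 3e-4)
  # soft-membrane flexural rigidity: k_a = 8, l0 = 1e-3 -> F = 0.008
  expect_equal(membrane_properties(8, 2, 1e-3)$F, 0.008)
  # scaling: (4 k_a, k_b) doubles d and quadruples F
  p1 <- membrane_properties(3, 5, 1e-3)
  p4 <- membrane_properties(12, 5, 1e-3)
  expect_equal(p4$d, 2 * p1$d)
  expect_equal(p4$F, 4 * p1$F)
  # internal consistency F = E d^3 / 12 and bijective round trip
  expect_equal(p1$F, p1$E * p1$d^3 / 12)
  k <- membrane_constants(p1$d, p1$F, 1e-3)
  expect_equal(k$k_a, 3, tolerance = 1e-12)
  expect_equal(k$k_b, 5, tolerance = 1e-12)
  expect_error(membrane_properties(-1, 2, 1), "> 0")
})

test_that("repulsion is zero beyond contact and pushes pairs apart inside", {
  ps <- particle_system()
  add_particles(ps, "FLUID", c(0, 0), 1)
  add_particles(ps, "WALL", c(1.2e-3, 0), 1, anchored = TRUE)
  spec <- repulsion_spec(1e-3, strength = 0.5)
  expect_equal(max(abs(repulsion_forces(ps, spec))), 0)
  ps$x[2] <- 0.5e-3 # r = rc / 2
  F <- repulsion_forces(ps, spec)
  expect_lt(F[1, 1], 0)  # fluid pushed away from the wall particle
  expect_equal(F[1, ], -F[2, ])
  expect_equal(unname(abs(F[1, 1])), 0.5 * (2^4 - 2^2))
})

test_that("a settling fluid column never penetrates the wall", {
  s <- 1e-3
  rho0 <- 1000
  fl <- fluid_spec(rho0, 0.05, sound_speed = 1.5)
  ps <- particle_system(box = c(0, 10 * s, -0.5, 0.5))
  wall <- expand.grid(j = 0:9, k = -3:0)
  add_particles(ps, "WALL", cbind(wall$j * s, wall$k * s), rho0 * s^2,
                anchored = TRUE)
  col_ <- expand.grid(j = 2:7, k = 2:9)
  set.seed(9)
  add_particles(ps, "FLUID",
                cbind(col_$j * s, col_$k * s + runif(nrow(col_), 0, 0.1 * s)),
                rho0 * s^2)
  kern <- kernel_spec(1.3 * s)
  rep_ <- repulsion_spec(s, strength = 0.01 * rho0 * s^2 * 1.5^2 / s)
  grav <- forcing_spec(1, 1, waveform = "constant", direction = c(0, -1))
  dt <- stable_dt(kern, fl)
  res <- sph_step(ps, kern, fl, grav, rep_, dt = dt, nsteps = 1e4,
                  damping = 2e-4)
  fluid <- ps$kind == "FLUID"
  walls <- which(!fluid)
  mind <- min(vapply(which(fluid), function(i)
    min(sqrt((ps$x[walls] - ps$x[i])^2 + (ps$y[walls] - ps$y[i])^2)),
    numeric(1)))
  expect_gt(mind, 0.4 * s)
  expect_true(all(is.finite(ps$x)))
})

test_that("cantilever tip deflection matches Euler-Bernoulli theory", {
  # formula oracle
  expect_equal(cantilever_tip_deflection(1e-3, 0.016, 0.008), 1.70667e-7,
               tolerance = 1e-5)
  expect_equal(cantilever_tip_deflection(1, 1, 2),
               cantilever_tip_deflection(1, 1, 1) / 2)
  expect_equal(cantilever_tip_deflection(1, 2, 1),
               8 * cantilever_tip_deflection(1, 1, 1))
  # damped relaxation of the discrete chain
  v <- validate_cantilever()
  expect_lt(v$rel_error, v$tol)
  expect_lt(v$residual_speed, 1e-8)
})
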