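make_pair_system <- function(vx = c(0, 0)) {
  ps <- particle_system()
  add_particles(ps, "FLUID", rbind(c(0, 0), c(1e-3, 0)), mass = 1e-3)
  ps$vx <- vx
  kern <- kernel_spec(1.3e-3)
  fl <- fluid_spec(1000, 0.1, 1)
  compute_density(ps, kern)
  compute_pressure(ps, fl)
  list(ps = ps, kern = kern, fl = fl)
}

test_that("pressure and viscous pair forces are equal and opposite", {
  s <- make_pair_system()
  F <- compute_fluid_forces(s$ps, s$kern, s$fl)
  expect_equal(F[1, ], -F[2, ])
  expect_equal(unname(F[1, "fy"]), 0)
  expect_lt(attr(F, "imbalance"), 1e-12)
})

test_that("uniform velocity produces no viscous force", {
  still <- make_pair_system(vx = c(0, 0))
  moving <- make_pair_system(vx = c(0.37, 0.37))
  expect_equal(compute_fluid_forces(moving$ps, moving$kern, moving$fl)[, ],
               compute_fluid_forces(still$ps, still$kern, still$fl)[, ])
})

test_that("pulsatile body force follows g0 sin(2 pi f t)", {
  fo <- forcing_spec(500, 1)
  expect_equal(body_force(0, fo), 0)
  expect_equal(body_force(0.25, fo), 500)
  expect_lt(abs(body_force(0.5, fo)), 1e-10)
  expect_equal(body_force(c(0.1, 0.2), forcing_spec(3, 2, "constant")),
               c(3, 3))
  expect_error(body_force(-1, fo), ">= 0")
})

test_that("free streaming advances positions by v dt exactly", {
  ps <- particle_system(box = c(0, 1, -1, 1))
  add_particles(ps, "FLUID", c(0.2, 0.05), mass = 1)
  ps$vx <- 0.31; ps$vy <- -0.07
  kern <- kernel_spec(0.01)
  fl <- fluid_spec(1000, 1e-3, 10)
  dt <- 1e-4
  sph_step(ps, kern, fl, dt = dt, nsteps = 1)
  expect_identical(ps$x, 0.2 + 0.31 * dt)
  expect_identical(ps$y, 0.05 - 0.07 * dt)
  expect_equal(ps$time, dt)
})

test_that("time steps beyond the CFL bound are rejected", {
  ps <- particle_system(box = c(0, 1, -1, 1))
  add_particles(ps, "FLUID", c(0.5, 0), mass = 1)
  kern <- kernel_spec(0.01)
  fl <- fluid_spec(1000, 1e-3, 10)
  expect_error(sph_step(ps, kern, fl, dt = 1, nsteps = 1), "CFL")
})

test_that("mirror-symmetric channel stays mirror-symmetric under forcing", {
  fl <- fluid_spec(1000, 0.1, 0.05)
  scene <- build_channel(Z = 0.005, length = 0.02, spacing = 1e-3,
                         fluid = fl, forcing = forcing_spec(0.01, 5))
  ps <- scene$ps
  mirror <- order(ps$x, -ps$y)
  straight <- order(ps$x, ps$y)
  run_simulation(scene, 100 * scene$dt, dt = scene$dt)
  expect_lt(max(abs(ps$vx[straight] - ps$vx[mirror])), 1e-8)
  expect_lt(max(abs(ps$vy[straight] + ps$vy[mirror])), 1e-8)
  expect_lt(max(abs(ps$y[straight] + ps$y[mirror])), 1e-8)
})

test_that("advecting the whole system by one box length reproduces forces", {
  fl <- fluid_spec(1000, 0.1, 0.05)
  scene <- build_channel(Z = 0.005, length = 0.02, spacing = 1e-3, fluid = fl)
  ps <- scene$ps
  set.seed(3)
  ps$vx <- rnorm(particle_count(ps), 0, 1e-3)
  compute_density(ps, scene$kernel)
  compute_pressure(ps, fl)
  F1 <- compute_fluid_forces(ps, scene$kernel, fl)
  ps$x <- ps$x + (ps$box[2] - ps$box[1])
  F2 <- compute_fluid_forces(ps, scene$kernel, fl)
  scale <- max(abs(F1))
  expect_lt(max(abs(F1[, ] - F2[, ])) / scale, 1e-12)
})

test_that("internal forces balance to round-off during a forced run", {
  fl <- fluid_spec(1000, 0.1, 0.05)
  scene <- build_channel(Z = 0.005, length = 0.02, spacing = 1e-3,
                         fluid = fl, forcing = forcing_spec(0.01, 1, "constant"))
  res <- run_simulation(scene, 200 * scene$dt, dt = scene$dt)
  expect_lt(res$max_imbalance, 1e-12)
})

test_that("channel flow converges toward the analytic parabola under refinement", {
  errs <- vapply(c(2e-3, 1e-3, 5e-4), function(s)
    validate_poiseuille(spacing = s, duration = 2.5)$l2_error, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("analytic Womersley solution matches a finite-difference PDE oracle", {
  g0 <- 4.5; f <- 90 / (2 * pi); rho <- 1000; mu <- 1; Z <- 0.01
  ref <- womersley_fd_amplitude(g0, f, rho, mu, Z)
  ana <- womersley_amplitude(G0 = rho * g0, f = f, rho = rho, mu = mu, Z = Z)
  expect_lt(abs(ana - ref) / ref, 1e-4)
})
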