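test_that("valve builder places the documented leaflets and lattice", {
  geom <- valve_geometry(spacing = 5e-4)
  scene <- build_valve(geom)
  ps <- scene$ps
  # floor(0.016 / 5e-4) + 1 = 33 membrane particles per leaflet
  expect_length(scene$leaflets$upper, 33)
  expect_length(scene$leaflets$lower, 33)
  # roots anchored at opposite walls
  ru <- scene$leaflets$upper[1]; rl <- scene$leaflets$lower[1]
  expect_equal(ps$y[ru], geom$Z)
  expect_equal(ps$y[rl], -geom$Z)
  expect_true(all(ps$anchored[c(scene$leaflets$upper[1:2],
                                scene$leaflets$lower[1:2])]))
  # tips approach the centerline, one lattice spacing apart
  tu <- scene$leaflets$upper[33]; tl <- scene$leaflets$lower[33]
  expect_equal(ps$y[tu] - ps$y[tl], geom$spacing)

  # coarse lattices are rejected
  expect_error(valve_geometry(spacing = 4e-3), "at least 8")
})

test_that("valve scene is deterministic, mirror-symmetric and keeps clearances", {
  s1 <- build_valve(valve_geometry(spacing = 1e-3))
  s2 <- build_valve(valve_geometry(spacing = 1e-3))
  expect_identical(as.data.frame(s1$ps), as.data.frame(s2$ps))

  ps <- s1$ps
  fl <- ps$kind == "FLUID"
  key <- function(x, y) paste(round(x / 1e-9), round(y / 1e-9))
  expect_setequal(key(ps$x[fl], ps$y[fl]), key(ps$x[fl], -ps$y[fl]))

  # every fluid particle at least half a spacing from every wall particle
  wl <- which(ps$kind == "WALL")
  nb <- build_neighbors(ps, 0.5 * s1$spacing * 0.999)
  kinds <- cbind(ps$kind[nb$i], ps$kind[nb$j])
  expect_false(any(rowSums(kinds == "FLUID") == 1 &
                     rowSums(kinds == "WALL") == 1))
})

test_that("halving the lattice spacing quadruples the fluid count", {
  n1 <- kind_census(build_valve(valve_geometry(spacing = 1e-3))$ps)["FLUID"]
  n2 <- kind_census(build_valve(valve_geometry(spacing = 5e-4))$ps)["FLUID"]
  expect_lt(abs(n2 / n1 - 4), 0.08)
})

test_that("channel builder matches the enumeration oracle and is symmetric", {
  fl <- fluid_spec(1000, 0.1, 0.05)
  scene <- build_channel(Z = 0.01, length = 0.04, spacing = 1e-3, fluid = fl)
  cen <- kind_census(scene$ps)
  expect_equal(unname(cen["FLUID"]), channel_fluid_count(0.01, 0.04, 1e-3))
  expect_equal(unname(cen["FLUID"]), 40L * 19L)
  ps <- scene$ps
  flid <- ps$kind == "FLUID"
  expect_setequal(paste(ps$x[flid], ps$y[flid]),
                  paste(ps$x[flid], -ps$y[flid]))
  # the experimental half-thickness scenario builds cleanly
  exp_scene <- build_channel(Z = 0.015, length = 0.05, spacing = 1e-3, fluid = fl)
  expect_equal(unname(kind_census(exp_scene$ps)["FLUID"]),
               channel_fluid_count(0.015, 0.05, 1e-3))
})

test_that("Poiseuille profile obeys no-slip, the formula, and the flow-rate integral", {
  expect_equal(poiseuille_profile(c(-0.01, 0.01), 100, 0.1, 0.01), c(0, 0))
  expect_equal(poiseuille_profile(0, 100, 0.1, 0.01), 0.05)
  expect_error(poiseuille_profile(0.02, 100, 0.1, 0.01), "half-thickness")
  G <- 37; mu <- 0.21; Z <- 0.013
  q <- integrate(function(y) poiseuille_profile(y, G, mu, Z), -Z, Z,
                 rel.tol = 1e-10)$value
  expect_equal(q, 2 * G * Z^3 / (3 * mu), tolerance = 1e-8)
})

test_that("Womersley profile obeys no-slip and the quasi-steady limit", {
  G0 <- 50; rho <- 1000; mu <- 0.5; Z <- 0.01
  expect_equal(womersley_profile(c(-Z, Z), 0.3, G0, 2, rho, mu, Z), c(0, 0))
  # f -> 0 at peak phase reduces to Poiseuille
  f <- 1e-4
  u <- womersley_profile(0, 1 / (4 * f), G0, f, rho, mu, Z)
  expect_equal(u, poiseuille_profile(0, G0, mu, Z), tolerance = 0.01)
})

test_that("default scene dt respects the acoustic and viscous bounds", {
  fl <- fluid_spec(1000, 0.1, 0.05)
  kern <- kernel_spec(1.3e-3)
  expect_equal(stable_dt(kern, fl),
               min(0.25 * 1.3e-3 / (0.05 + 0.005),
                   0.125 * 1.3e-3^2 * 1000 / 0.1))
})
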