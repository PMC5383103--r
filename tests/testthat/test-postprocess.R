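lattice_with_velocity <- function(fun, half = 15, s = 1e-3, rho0 = 1000) {
  ps <- particle_system()
  g <- expand.grid(x = (-half:half) * s, y = (-half:half) * s)
  add_particles(ps, "FLUID", cbind(g$x, g$y), mass = rho0 * s^2)
  v <- fun(ps$x, ps$y)
  ps$vx <- v$vx; ps$vy <- v$vy
  compute_density(ps, kernel_spec(1.3 * s))
  ps$pressure <- rep(0, particle_count(ps))
  ps
}

test_that("Shepard interpolation reproduces constants exactly and masks voids", {
  s <- 1e-3
  ps <- lattice_with_velocity(function(x, y)
    list(vx = rep(0.37, length(x)), vy = rep(-0.11, length(x))))
  grid <- field_grid(c(-0.01, -0.01), s / 2, 15, 15)
  gi <- interpolate_grid(ps, kernel_spec(1.3 * s), grid)
  expect_true(all(abs(gi$ux[!gi$mask] - 0.37) < 1e-12))
  expect_true(all(abs(gi$uy[!gi$mask] + 0.11) < 1e-12))

  far <- field_grid(c(1, 1), s, 3, 3) # far from every particle
  gf <- interpolate_grid(ps, kernel_spec(1.3 * s), far)
  expect_true(all(gf$mask))
  expect_true(all(is.na(gf$ux)))
})

test_that("linear velocity fields interpolate within tolerance in the interior", {
  s <- 1e-3
  ps <- lattice_with_velocity(function(x, y)
    list(vx = 2 + 30 * y, vy = 0.5 - 10 * x))
  # interior nodes offset from the particle lattice
  grid <- field_grid(c(-0.008 + s / 4, -0.008 + s / 4), s, 17, 17)
  gi <- interpolate_grid(ps, kernel_spec(1.3 * s), grid)
  xy <- expand.grid(y = grid$origin[2] + (0:16) * s,
                    x = grid$origin[1] + (0:16) * s)
  exact <- matrix(2 + 30 * xy$y, 17, 17)
  expect_lt(max(abs(gi$ux - exact) / max(abs(exact))), 0.02)
})

test_that("shear-stress field recovers uniform and linear-shear cases", {
  s <- 1e-3
  mu <- 0.0035
  uni <- lattice_with_velocity(function(x, y)
    list(vx = rep(1, length(x)), vy = rep(0, length(x))))
  grid <- field_grid(c(-0.008, -0.008), s, 17, 17)
  tu <- shear_stress_field(uni, kernel_spec(1.3 * s), grid, mu)
  expect_lt(max(abs(tu$tau[!tu$mask])), 1e-10)

  gdot <- 25
  lin <- lattice_with_velocity(function(x, y)
    list(vx = gdot * y, vy = rep(0, length(x))))
  tl <- shear_stress_field(lin, kernel_spec(1.3 * s), grid, mu)
  expect_lt(max(abs(tl$tau[!tl$mask] - mu * gdot)) / (mu * gdot), 0.03)
})

test_that("shear profile of an analytic Poiseuille state is linear in y", {
  s <- 5e-4
  Z <- 0.01
  G <- 100; mu <- 0.1
  fl <- fluid_spec(1000, mu, 1)
  scene <- build_channel(Z, length = 0.02, spacing = s, fluid = fl)
  ps <- scene$ps
  flid <- ps$kind == "FLUID"
  ps$vx[flid] <- poiseuille_profile(ps$y[flid], G, mu, Z)
  compute_density(ps, scene$kernel)
  ps$pressure <- rep(0, particle_count(ps))
  grid <- field_grid(c(0.005, -0.008), s, 3, 33)
  tf <- shear_stress_field(ps, scene$kernel, grid, mu)
  ys <- grid$origin[2] + (0:32) * s
  mid <- which(abs(ys) < 0.75 * Z)
  got <- tf$tau[mid, 2]
  expect_lt(max(abs(got - (-G * ys[mid]))) / (G * Z), 0.05)
  # zero at the centerline, extrema toward the walls
  expect_lt(abs(tf$tau[which.min(abs(ys)), 2]), 0.1 * G * Z)
})

test_that("membrane kinematics reports opening, tips and symmetry", {
  ps <- particle_system()
  add_particles(ps, "MEMBRANE", rbind(c(0, 0.004), c(0.001, 0.002),
                                      c(0, -0.004), c(0.001, -0.002)), 1)
  leaflets <- list(upper = c(1, 2), lower = c(3, 4))
  kin <- membrane_kinematics(ps, leaflets, Z = 0.0125)
  expect_equal(kin$opening, 0.004)
  expect_equal(kin$symmetry_index, 0)
  expect_equal(kin$y_tip_upper, 0.002)

  # static series: constant opening
  snaps <- list(as.data.frame(ps), as.data.frame(ps))
  kin2 <- membrane_kinematics(snaps, leaflets, Z = 0.0125, times = c(0, 1))
  expect_equal(kin2$opening, rep(0.004, 2))

  ps$kind[] <- "FLUID"
  expect_error(membrane_kinematics(ps, leaflets, Z = 0.0125), "membrane")
})

test_that("CSV snapshots round-trip bit-identically", {
  ps <- particle_system()
  add_particles(ps, "FLUID", rbind(c(1 / 3, sqrt(2)), c(-pi, exp(1))), 1.7)
  add_particles(ps, "WALL", c(0.1, 0.2), 2, anchored = TRUE)
  ps$vx <- c(1e-17, -3.2, 0); ps$vy <- c(0.1, 0.2, 0.3)
  ps$rho <- c(1056.000000001, 1000, 999.5); ps$pressure <- c(1, -2, 3e-8)
  path <- tempfile(fileext = ".csv")
  write_snapshot(ps, path)
  back <- read_snapshot(path)
  orig <- as.data.frame(ps)
  expect_identical(back$x, orig$x)
  expect_identical(back$vx, orig$vx)
  expect_identical(back$rho, orig$rho)
  expect_identical(back$kind, orig$kind)

  # empty system: valid file with zero points
  empty <- particle_system()
  p2 <- tempfile(fileext = ".csv")
  write_snapshot(empty, p2)
  expect_equal(nrow(read_snapshot(p2)), 0)
})

test_that("VTK legacy output is well-formed POLYDATA", {
  ps <- particle_system()
  add_particles(ps, "FLUID", rbind(c(0, 0), c(1, 2), c(3, 4)), 1)
  ps$rho <- rep(1000, 3); ps$pressure <- c(1, 2, 3)
  path <- tempfile(fileext = ".vtk")
  write_snapshot(ps, path, format = "vtk")
  lines <- readLines(path)
  expect_match(lines[1], "^# vtk DataFile")
  expect_true("DATASET POLYDATA" %in% lines)
  ip <- grep("^POINTS", lines)
  expect_equal(as.integer(strsplit(lines[ip], " ")[[1]][2]), 3)
  # point coordinates parse as numbers, z = 0
  pts <- do.call(rbind, strsplit(lines[(ip + 1):(ip + 3)], " "))
  expect_equal(as.numeric(pts[, 3]), rep(0, 3))
  expect_equal(as.numeric(pts[2, 1:2]), c(1, 2))
  expect_true(any(grepl("^POINT_DATA 3", lines)))
  expect_true(any(grepl("^SCALARS pressure", lines)))
})

test_that("malformed snapshots are rejected with the offending line", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,kind,x,y,vx,vy,rho,p", "1,FLUID,0,0,0,0,1000,0",
               "2,FLUID,broken"), path)
  expect_error(read_snapshot(path), "line 3")
  writeLines(c("wrong,header"), path)
  expect_error(read_snapshot(path), "line 1")
  writeLines(c("id,kind,x,y,vx,vy,rho,p", "1,PLASMA,0,0,0,0,1,0"), path)
  expect_error(read_snapshot(path), "line 2")
})

test_that("run configurations round-trip through YAML", {
  cfg <- structure(list(
    scene = list(type = "channel", Z = 0.01, length = 0.04, spacing = 1e-3),
    fluid = list(rest_density = 1000, dynamic_viscosity = 0.1,
                 sound_speed = 0.05),
    forcing = list(amplitude = 0.01, frequency = 1, waveform = "constant"),
    run = list(duration = 0.01, seed = 7)), class = "run_config")
  path <- tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(unclass(back), unclass(cfg))
  scene <- build_scene_from_config(back)
  expect_s3_class(scene, "sph_scene")
  expect_equal(scene$geom$Z, 0.01)
})

test_that("the CLI validates, runs deterministically, and rejects bad input", {
  expect_equal(run_cli(c("validate", "aggregation-lattice")), 0L)
  expect_equal(run_cli("frobnicate"), 2L)
  expect_equal(run_cli(character(0)), 2L)

  bad <- tempfile(fileext = ".yaml")
  writeLines("scene:\n  type: warp-drive\n", bad)
  expect_gt(run_cli(c("build", "--config", bad,
                      "--out", tempfile(fileext = ".csv"))), 0L)

  cfg <- structure(list(
    scene = list(type = "channel", Z = 0.005, length = 0.02, spacing = 1e-3),
    fluid = list(rest_density = 1000, dynamic_viscosity = 0.1,
                 sound_speed = 0.05),
    forcing = list(amplitude = 0.01, frequency = 1, waveform = "constant"),
    run = list(duration = 0.02, seed = 3)), class = "run_config")
  cpath <- tempfile(fileext = ".yaml")
  write_run_config(cfg, cpath)
  d1 <- tempfile(); d2 <- tempfile()
  expect_equal(run_cli(c("run", "--config", cpath, "--out", d1,
                         "--seed", "3", "--duration", "0.02")), 0L)
  expect_equal(run_cli(c("run", "--config", cpath, "--out", d2,
                         "--seed", "3", "--duration", "0.02")), 0L)
  f1 <- file.path(d1, "final.csv"); f2 <- file.path(d2, "final.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
})
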