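center_id <- function(ps) which(ps$x == 0 & ps$y == 0)

test_that("seed selection supports explicit ids and shear thresholds", {
  ps <- lattice_system(3)
  ids <- select_seeds(ps, ids = center_id(ps))
  expect_true(ps$seed_active[ids])
  expect_equal(ps$kind[ids], "AGGREGATE")
  expect_error(select_seeds(lattice_system(2), ids = integer(0)), "non-empty")

  # shear criterion: threshold above the maximum selects nothing, silently
  ps2 <- lattice_system(3)
  shear <- abs(ps2$y)
  expect_length(select_seeds(ps2, shear = shear, tau_star = 100), 0)
  # threshold zero selects every sheared fluid particle
  ps3 <- lattice_system(3)
  shear <- abs(ps3$y) + 1
  sel <- select_seeds(ps3, shear = shear, tau_star = 0)
  expect_setequal(sel, seq_len(particle_count(ps3)))
})

test_that("lattice conversion counts equal the brute-force distance oracle", {
  for (rmax in c(1.2, 1.5)) {
    ps <- lattice_system(10)
    ctr <- center_id(ps)
    x0 <- ps$x[ctr]; y0 <- ps$y[ctr]
    oracle <- sum(sqrt((ps$x - x0)^2 + (ps$y - y0)^2) <= rmax) - 1
    select_seeds(ps, ids = ctr)
    cfg <- aggregation_config(1, rmax, 1, "circular", bond_stiffness = 1)
    ev <- aggregation_step(ps, cfg)
    expect_equal(nrow(ev), oracle)
    expect_equal(nrow(ev), if (rmax == 1.2) 4L else 8L)
    expect_true(all(ev$kind == "convert"))
  }
  # p = 0: nothing happens
  ps <- lattice_system(5)
  select_seeds(ps, ids = center_id(ps))
  ev <- aggregation_step(ps, aggregation_config(1, 1.5, 0, bond_stiffness = 1))
  expect_equal(nrow(ev), 0)
  expect_equal(unname(kind_census(ps)["AGGREGATE"]), 1L)
})

test_that("filiform growth builds a simple path", {
  ps <- lattice_system(15)
  select_seeds(ps, ids = center_id(ps))
  cfg <- aggregation_config(1, 1.2, 1, "filiform", bond_stiffness = 1)
  k <- 8
  set.seed(1)
  for (q in seq_len(k)) aggregation_step(ps, cfg)
  expect_equal(unname(kind_census(ps)["AGGREGATE"]), k + 1L)
  expect_equal(bond_count(ps), k)
  g <- igraph::graph_from_edgelist(cbind(ps$bond_i, ps$bond_j), directed = FALSE)
  deg <- igraph::degree(g)
  expect_lte(max(deg), 2)
  expect_equal(igraph::components(g)$no,
               igraph::gorder(g) - igraph::gsize(g)) # forest
  expect_equal(sum(ps$seed_active), 1) # only the newest tip stays active
})

test_that("aggregate bond graph stays a forest under stochastic growth", {
  set.seed(42)
  ps <- lattice_system(12)
  select_seeds(ps, ids = center_id(ps))
  cfg <- aggregation_config(1, 1.5, 0.5, "circular", bond_stiffness = 1)
  for (q in 1:6) {
    aggregation_step(ps, cfg)
    agg <- which(ps$kind == "AGGREGATE")
    keep <- ps$bond_active
    g <- igraph::graph_from_edgelist(cbind(ps$bond_i[keep], ps$bond_j[keep]),
                                     directed = FALSE)
    expect_equal(igraph::gsize(g), 0 +
                   sum(igraph::components(g)$csize - 1)) # acyclic
    # |edges| = |aggregate particles| - |components containing them|
    labels <- aggregate_components(ps)
    expect_equal(sum(keep), length(agg) - length(unique(labels)))
  }
})

test_that("conversion rate is binomial with the configured probability", {
  p <- 0.35
  reps <- 200
  set.seed(2024)
  total <- 0
  for (r in seq_len(reps)) {
    ps <- lattice_system(4)
    select_seeds(ps, ids = center_id(ps))
    cfg <- aggregation_config(1, 1.5, p, "circular", bond_stiffness = 1)
    total <- total + nrow(aggregation_step(ps, cfg))
  }
  n <- reps * 8
  expect_lt(abs(total - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("event logs are bit-reproducible under a fixed seed", {
  run_once <- function() {
    set.seed(77)
    ps <- lattice_system(8)
    select_seeds(ps, ids = center_id(ps))
    cfg <- aggregation_config(1, 1.5, 0.6, "circular", bond_stiffness = 1)
    do.call(rbind, lapply(1:3, function(q) aggregation_step(ps, cfg)))
  }
  expect_identical(run_once(), run_once())
})

test_that("fragmentation removes exactly the over-threshold bonds", {
  ps <- particle_system()
  add_particles(ps, "AGGREGATE", rbind(c(0, 0), c(1 + 1.4e-7, 0),
                                       c(2 + 1.4e-7 + 1.2e-7, 0)), 1)
  add_bond(ps, 1, 2, stiffness = 1, rest_length = 1, break_threshold = 1.3e-7)
  add_bond(ps, 2, 3, stiffness = 1, rest_length = 1, break_threshold = 1.3e-7)
  ev <- fragment_step(ps)
  expect_equal(nrow(ev), 1) # tension 1.4e-7 breaks, 1.2e-7 survives
  expect_equal(ev$bond_i, 1)
  expect_false(ps$bond_active[1])
  expect_true(ps$bond_active[2])
  # tree edge-cut property: components increased by exactly one
  expect_equal(length(unique(aggregate_components(ps))), 2)
})

test_that("component labels match an igraph oracle on a random forest", {
  set.seed(13)
  ps <- particle_system()
  n <- 30
  add_particles(ps, "FLUID", cbind(runif(n), runif(n)), 1)
  convert_kind(ps, 1:n)
  # random forest: attach each node to a random earlier node, skip some
  for (q in 2:n)
    if (stats::runif(1) < 0.8)
      add_bond(ps, sample(q - 1, 1), q, 1, 1, break_threshold = 1)
  labels <- aggregate_components(ps)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(ps$bond_i, ps$bond_j))
  oracle <- igraph::components(g)$membership
  expect_equal(length(unique(labels)), max(oracle))
  # same partition: labels agree up to renaming
  expect_equal(length(unique(paste(labels, oracle))), max(oracle))

  # removing one bond adds exactly one component
  before <- length(unique(aggregate_components(ps)))
  ps$bond_active[1] <- FALSE
  expect_equal(length(unique(aggregate_components(ps))), before + 1)

  # no bonds -> every aggregate its own component
  ps$bond_active[] <- FALSE
  expect_equal(length(unique(aggregate_components(ps))), n)
})

test_that("freshly converted particles immediately divert the fluid", {
  s <- 1e-3
  fl <- fluid_spec(1000, 0.1, 0.5)
  scene <- build_channel(Z = 0.005, length = 0.02, spacing = s, fluid = fl,
                         forcing = forcing_spec(1, 1, "constant"))
  scene2 <- build_channel(Z = 0.005, length = 0.02, spacing = s, fluid = fl,
                          forcing = forcing_spec(1, 1, "constant"))
  ps <- scene$ps; ps2 <- scene2$ps
  ctr <- which(ps$kind == "FLUID" & abs(ps$y) < s / 2 & abs(ps$x - 0.01) < s / 2)
  convert_kind(ps2, ctr)
  dt <- scene$dt
  run_simulation(scene, 5 * dt, dt = dt)
  run_simulation(scene2, 5 * dt, dt = dt)
  near <- which(ps$kind == "FLUID" &
                  sqrt((ps$x - 0.01)^2 + ps$y^2) < 3 * s & seq_along(ps$x) != ctr)
  dv <- abs(ps$vx[near] - ps2$vx[near]) + abs(ps$vy[near] - ps2$vy[near])
  expect_gt(max(dv), 0)
})
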