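test_that("one-way rates follow mass action including squared species", {
  net <- reaction_network(4, rbind(c(1, 3)), rbind(c(2, 4)))
  th <- unit_thermo(net)
  v <- one_way_rates(net, th, rep(1, 4))
  expect_equal(v$v_plus, 1); expect_equal(v$v_minus, 1)
  net2 <- reaction_network(4, rbind(c(1, 1)), rbind(c(2, 4)))
  v2 <- one_way_rates(net2, unit_thermo(net2), c(2, 1, 1, 1))
  expect_equal(v2$v_plus, 4)
  expect_error(one_way_rates(net, th, c(-1, 1, 1, 1)), "nonnegative")
})

test_that("the ODE right-hand side conserves mass and vanishes at equilibrium", {
  fx <- mini_nonlinear(53)
  x <- runif(fx$net$n_species, 0.2, 2)
  expect_equal(sum(ode_rhs(fx$net, fx$thermo, x)), 0, tolerance = 1e-10)
  dx_eq <- ode_rhs(fx$net, fx$thermo, exp(-fx$thermo$mu0))
  expect_equal(max(abs(dx_eq)), 0, tolerance = 1e-12)
  # 3-species chain with both ends clamped: db/dt = c1 + c2 - 2 x_b
  net <- chain_network(3)
  th <- unit_thermo(net)
  b <- boundary_condition(1, 3, 0.1, 1)
  dx <- ode_rhs(net, th, c(0.1, 0.3, 1), boundary = b)
  expect_equal(dx, c(0, 0.1 + 1 - 2 * 0.3, 0))
})

test_that("initial concentrations are positive draws clamped at the boundary", {
  b <- boundary_condition(1, 2, 0.1, 1)
  x <- initialize_concentrations(10000, b, seed = 3)
  expect_true(all(x > 0))
  expect_identical(x[1:2], c(0.1, 1))
  b2 <- boundary_condition(1, 2, 0.7, 0.7)
  expect_true(all(initialize_concentrations(50, b2, seed = 1) == 0.7))
})

test_that("two clamped species give the closed-form flow and entropy production", {
  net <- chain_network(2)
  th <- unit_thermo(net)
  st <- integrate_to_steady_state(net, th, boundary_condition(1, 2, 0.1, 1),
                                  accelerate = "none")
  expect_equal(st$boundary_flow, -0.9, tolerance = 1e-9)
  expect_equal(sum(steady_state_sigma(st)), 0.9 * log(10), tolerance = 1e-8)
})

test_that("the clamped chain reaches its algebraic steady state on every route", {
  net <- chain_network(3)
  th <- unit_thermo(net)
  b <- boundary_condition(1, 3, 0.1, 1)
  for (acc in c("auto", "none")) {
    st <- integrate_to_steady_state(net, th, b, x0 = c(0.1, 0.4, 1),
                                    accelerate = acc)
    expect_equal(st$x[2], 0.55, tolerance = 1e-5)
    expect_equal(abs(st$boundary_flow), 0.45, tolerance = 1e-5)
  }
  stl <- integrate_to_steady_state(net, th, b, x0 = c(0.1, 0.4, 1),
                                   method = "lsoda", accelerate = "none")
  expect_equal(stl$x[2], 0.55, tolerance = 1e-6)
})

test_that("a closed network started at equilibrium stays there with zero flow", {
  net <- chain_network(4)
  th <- assign_reaction_energetics(net, mu0 = c(0.2, -0.1, 0.4, 0),
                                   sampled_ea = rep(0.5, 3))
  x0 <- exp(-th$mu0)
  st <- integrate_to_steady_state(net, th, boundary = NULL, x0 = x0,
                                  accelerate = "none")
  expect_true(st$converged)
  expect_lt(st$t_final, 1)
  expect_equal(st$x, x0, tolerance = 1e-9)
})

test_that("closed integration conserves total concentration", {
  fx <- mini_nonlinear(59)
  x0 <- runif(fx$net$n_species, 0.2, 2)
  st <- integrate_to_steady_state(fx$net, fx$thermo, boundary = NULL,
                                  x0 = x0, accelerate = "none", t_max = 50)
  expect_equal(sum(st$x), sum(x0), tolerance = 1e-9)
  expect_true(all(st$x >= 0))
})

test_that("accelerated and plain integration agree on nonlinear steady states", {
  for (s in c(61, 67, 71)) {
    fx <- mini_nonlinear(s)
    gu <- substrate_graph(fx$net)
    pr <- sample_boundary_pairs(gu, 1, distances = 2, seed = s)
    b <- boundary_condition(pr$b1[1], pr$b2[1], 0.1, 1)
    th <- rezero_boundary(fx$thermo, fx$net, b$b1, b$b2)
    x0 <- initialize_concentrations(fx$net$n_species, b, seed = s + 1)
    sA <- integrate_to_steady_state(fx$net, th, b, x0 = x0)
    sN <- integrate_to_steady_state(fx$net, th, b, x0 = x0,
                                    accelerate = "none", t_max = 2e5)
    expect_true(sA$converged)
    expect_equal(sA$boundary_flow, sN$boundary_flow, tolerance = 1e-5)
  }
})

test_that("the steady flow of a linear network is antisymmetric in the boundary", {
  for (s in 1:5) {
    g <- generate_er(40, 150, seed = s)
    net <- linear_network_from_graph(g)
    th0 <- assign_reaction_energetics(net, seed = s + 7)
    pr <- sample_boundary_pairs(substrate_graph(net), 1, distances = 2,
                                seed = s)
    th <- rezero_boundary(th0, net, pr$b1[1], pr$b2[1])
    f1 <- integrate_to_steady_state(net, th,
      boundary_condition(pr$b1[1], pr$b2[1], 0.1, 1), seed = s)$boundary_flow
    f2 <- integrate_to_steady_state(net, th,
      boundary_condition(pr$b2[1], pr$b1[1], 1, 0.1), seed = s)$boundary_flow
    expect_equal(f1, -f2, tolerance = 1e-9)
  }
})

test_that("boundary production balances boundary consumption at steady state", {
  fx <- mini_nonlinear(73)
  pr <- sample_boundary_pairs(substrate_graph(fx$net), 1, distances = 3,
                              seed = 2)
  b <- boundary_condition(pr$b1[1], pr$b2[1], 0.1, 1)
  th <- rezero_boundary(fx$thermo, fx$net, b$b1, b$b2)
  st <- integrate_to_steady_state(fx$net, th, b, seed = 4)
  N <- stoichiometric_matrices(fx$net)$N
  prod <- as.vector(N %*% st$v_net)
  expect_equal(prod[b$b2], -prod[b$b1], tolerance = 1e-8)
  expect_equal(boundary_flow(st, fx$net, b), prod[b$b2])
})

test_that("boundary pairs are stratified by true shortest-path distance", {
  g <- generate_er(60, 150, seed = 81)
  gu <- substrate_graph(linear_network_from_graph(g))
  pr <- sample_boundary_pairs(gu, 10, seed = 5)
  expect_true(all(pr$d >= 1))
  expect_true(all(table(pr$d) <= 10))
  und <- gu$edges
  for (i in sample.int(nrow(pr), min(20, nrow(pr)))) {
    d_oracle <- bfs_distance(und, 60, pr$b1[i])[pr$b2[i]]
    expect_identical(unname(d_oracle), as.numeric(pr$d[i]))
  }
  # a path graph has exactly the pairs its distances allow
  path <- rrn_graph(3, rbind(c(1, 2), c(2, 3)), directed = FALSE)
  pp <- sample_boundary_pairs(path, 50, seed = 1)
  expect_identical(sort(unique(pp$d)), c(1, 2))
  expect_identical(nrow(pp), 3L)
})
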