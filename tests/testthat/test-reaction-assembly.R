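test_that("linear networks round-trip the generating multigraph", {
  g <- generate_er(40, 120, seed = 1)
  net <- linear_network_from_graph(g)
  expect_identical(n_reactions(net), 120L)
  expect_false(any(is_nonlinear(net)))
  gs <- substrate_graph(net, directed = TRUE)
  expect_identical(gs$edges[order(gs$edges[, 1], gs$edges[, 2]), ],
                   g$edges[order(g$edges[, 1], g$edges[, 2]), ])
})

test_that("stoichiometric matrices follow multiset semantics and conserve molecules", {
  net <- reaction_network(4, rbind(c(1, NA), c(1, 1), c(1, 3)),
                          rbind(c(2, NA), c(2, 4), c(2, 4)))
  m <- stoichiometric_matrices(net)
  expect_identical(as.vector(m$L[, 2]), c(2, 0, 0, 0))
  expect_identical(as.vector(m$N[, 1]), c(-1, 1, 0, 0))
  expect_identical(as.vector(m$N[, 3]), c(-1, 1, -1, 1))
  expect_true(all(Matrix::colSums(m$N) == 0))
})

test_that("substrate graph lists one edge per reactant-product cross pair", {
  net <- reaction_network(4, rbind(c(1, 3)), rbind(c(2, 4)))
  e <- substrate_graph(net)$edges
  expect_identical(e[order(e[, 1], e[, 2]), ],
                   rbind(c(1L, 2L), c(1L, 4L), c(3L, 2L), c(3L, 4L)))
  # a species on both sides yields a substrate self-edge
  net2 <- reaction_network(3, rbind(c(1, 2)), rbind(c(2, 3)))
  e2 <- substrate_graph(net2)$edges
  expect_identical(sum(e2[, 1] == e2[, 2]), 1L)
})

test_that("directed substrate edges follow the sign of the net rate", {
  net <- reaction_network(2, cbind(1, NA), cbind(2, NA))
  expect_identical(directed_substrate_graph(net, +1)$edges, cbind(1L, 2L))
  expect_identical(directed_substrate_graph(net, -1)$edges, cbind(2L, 1L))
  expect_identical(directed_substrate_graph(net, 0)$edges, cbind(1L, 2L))
  net2 <- reaction_network(3, rbind(c(1, 2)), rbind(c(2, 3)))
  e <- directed_substrate_graph(net2, +1)$edges
  expect_identical(e[order(e[, 1], e[, 2]), ],
                   rbind(c(1L, 2L), c(1L, 3L), c(2L, 2L), c(2L, 3L)))
})

test_that("coupling replaces pairs of linear reactions and keeps the edge budget", {
  g <- generate_er(50, 150, seed = 3)
  net <- couple_reactions(linear_network_from_graph(g), 50, seed = 4)
  expect_identical(sum(!is_nonlinear(net)), 50L)   # 150 - 2*50
  expect_identical(sum(is_nonlinear(net)), 50L)
  expect_identical(nrow(substrate_graph(net)$edges), 50L + 4L * 50L)
})

test_that("coupling A<=>B with C<=>D yields A+C<=>B+D and its four cross edges", {
  net <- reaction_network(4, rbind(c(1, NA), c(3, NA)),
                          rbind(c(2, NA), c(4, NA)), model = "ER")
  cp <- couple_reactions(net, 1, seed = 1)
  expect_identical(sort(cp$reactants[1, ]), c(1L, 3L))
  expect_identical(sort(cp$products[1, ]), c(2L, 4L))
  e <- substrate_graph(cp)$edges
  expect_identical(e[order(e[, 1], e[, 2]), ],
                   rbind(c(1L, 2L), c(1L, 4L), c(3L, 2L), c(3L, 4L)))
})

test_that("coupling weights implement the per-model rules", {
  er <- linear_network_from_graph(generate_er(20, 10, seed = 1))
  expect_identical(coupling_weight(er, 1, 2), 1)

  # WS: both new edges must stay within ring distance k/2
  ws_meta <- list(k = 10L)
  ws <- reaction_network(100, rbind(c(1, NA), c(6, NA), c(50, NA)),
                         rbind(c(2, NA), c(4, NA), c(52, NA)), model = "WS",
                         meta = ws_meta)
  expect_identical(coupling_weight(ws, 1, 2), 1)  # new edges 1-4 and 6-2
  expect_identical(coupling_weight(ws, 1, 3), 0)  # 1-52 spans the ring

  # PS: p^l1 * p^l2 for the two new edges
  ps <- reaction_network(8, rbind(c(1, NA), c(5, NA)),
                         rbind(c(2, NA), c(6, NA)), model = "PS",
                         meta = list(p = 0.5, h = 2,
                                     module0 = c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L)))
  # new edges 1-6 (levels: modules 0 vs 2 -> l = 2) and 5-2 (l = 2)
  expect_equal(coupling_weight(ps, 1, 2), 0.5^2 * 0.5^2)

  # BA: product of the current substrate degrees of the two products
  ba <- reaction_network(4, rbind(c(1, NA), c(3, NA)),
                         rbind(c(2, NA), c(4, NA)), model = "BA")
  expect_equal(coupling_weight(ba, 1, 2), 1 * 1)
  cp <- couple_reactions(er, 2, seed = 1)
  expect_error(coupling_weight(cp, 7, 8), "linear") # the two coupled ones
})

test_that("WS couplings only ever create ring-local substrate edges", {
  g <- generate_ws(200, 600, 0.1, seed = 8)
  net <- couple_reactions(linear_network_from_graph(g), 100, seed = 9)
  k <- net$meta$k
  nl <- which(is_nonlinear(net))
  ring <- function(u, v) { d <- abs(u - v); pmin(d, 200 - d) }
  a <- net$reactants[nl, ]; b <- net$products[nl, ]
  expect_true(all(ring(a[, 1], b[, 2]) <= k / 2))
  expect_true(all(ring(a[, 2], b[, 1]) <= k / 2))
})

test_that("a linear network built from a substrate graph has one reaction per edge", {
  fx <- mini_nonlinear(21)
  lin <- linear_from_substrate(fx$net)
  expect_identical(n_reactions(lin), nrow(substrate_graph(fx$net)$edges))
  expect_false(any(is_nonlinear(lin)))
})

test_that("reaction-list and JSON formats round-trip", {
  fx <- mini_nonlinear(31)
  tl <- tempfile(fileext = ".txt")
  write_reaction_list(fx$net, tl)
  back <- read_reaction_list(tl, n_species = fx$net$n_species)
  expect_identical(back$reactants, fx$net$reactants)
  expect_identical(back$products, fx$net$products)

  tj <- tempfile(fileext = ".json")
  write_network_json(fx$net, tj, thermo = fx$thermo)
  got <- read_network_json(tj)
  expect_identical(got$net$reactants, fx$net$reactants)
  expect_equal(got$thermo$k_fwd, fx$thermo$k_fwd)
  expect_equal(got$thermo$mu0, fx$thermo$mu0)

  g <- generate_ps(64, 100, 0.5, 3, seed = 2)
  tg <- tempfile(fileext = ".json")
  write_graph_json(g, tg)
  gb <- read_graph_json(tg)
  expect_identical(gb$edges, g$edges)
  expect_identical(gb$meta$module0, g$meta$module0)
  tgm <- tempfile(fileext = ".graphml")
  write_graphml(g, tgm)
  expect_identical(igraph::ecount(igraph::read_graph(tgm, format = "graphml")),
                   100)
})

test_that("BA coupling preserves the heavy-tailed substrate degree distribution", {
  tail_slope <- function(net) {
    d <- rrnsim:::substrate_degrees(net)
    d <- d[d > 0]
    ds <- 2^(1:7)
    cc <- vapply(ds, function(k) mean(d >= k), 0)
    keep <- cc > 0
    unname(coef(lm(log(cc[keep]) ~ log(ds[keep])))[2])
  }
  g <- generate_ba(500, 1500, seed = 11)
  lin <- linear_network_from_graph(g)
  non <- couple_reactions(lin, 500, seed = 111)
  er <- linear_network_from_graph(generate_er(500, 1500, seed = 11))
  # the coupled network keeps the scale-free tail: its cumulative degree
  # curve stays close to the linear one, and its hubs dwarf the ER null
  expect_lt(abs(tail_slope(lin) - tail_slope(non)), 0.5)
  expect_gt(max(rrnsim:::substrate_degrees(non)),
            5 * max(rrnsim:::substrate_degrees(er)))
})
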