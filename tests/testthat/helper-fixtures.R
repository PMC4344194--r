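# Small fixture builders used across the suite. Everything is generated in
# code; no stored data.

# a <-> b <-> c ... chain with unit rate constants (mu0 = 0, Ea = 0)
chain_network <- function(n) {
  reaction_network(n, cbind(seq_len(n - 1), NA_integer_),
                   cbind(seq_len(n - 1) + 1L, NA_integer_), model = "ER")
}

unit_thermo <- function(net) {
  assign_reaction_energetics(net, mu0 = rep(0, net$n_species),
                             sampled_ea = rep(0, n_reactions(net)))
}

# small mixed (linear + coupled) ER network with random energetics
mini_nonlinear <- function(seed, n = 30, m = 90, c = 20) {
  g <- generate_er(n, m, seed = seed)
  net <- couple_reactions(linear_network_from_graph(g), c, seed = seed + 1000)
  list(net = net, thermo = assign_reaction_energetics(net, seed = seed + 2000))
}

# independent breadth-first search used as the shortest-path oracle
bfs_distance <- function(edges, n, from) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  d <- rep(Inf, n)
  d[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) for (v in adj[[u]]) if (d[v] > d[u] + 1) {
      d[v] <- d[u] + 1
      nxt <- c(nxt, v)
    }
    frontier <- unique(nxt)
  }
  d
}

# quadrature CDF of the Planck-like activation-energy density (oracle,
# independent of the package's mixture sampler); the x^-2 tail is
# integrated from above to keep the quadrature stable
planck_cdf_oracle <- function(q) {
  vapply(q, function(x) {
    if (x <= 10)
      stats::integrate(planck_like_pdf, lower = 1e-12, upper = x,
                       rel.tol = 1e-10, subdivisions = 2000L)$value
    else
      1 - stats::integrate(planck_like_pdf, lower = x, upper = Inf,
                           rel.tol = 1e-10, subdivisions = 2000L)$value
  }, 0)
}
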