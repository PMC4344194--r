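#' Per-reaction entropy production rate
#'
#' `sigma_j = (v_plus_j - v_minus_j) * ln(v_plus_j / v_minus_j)`, in units
#' with `k_B T = 1`. Nonnegative, and zero exactly when the one-way rates
#' balance.
#'
#' @param v_plus,v_minus strictly positive one-way reaction rates.
#' @return nonnegative numeric vector.
#' @export
reaction_entropy_production <- function(v_plus, v_minus) {
  if (any(v_plus <= 0) || any(v_minus <= 0))
    stop("one-way rates must be strictly positive")
  s <- (v_plus - v_minus) * log(v_plus / v_minus)
  s[v_plus == v_minus] <- 0
  s
}

# stoichiometric route: sigma_j = -(sum_m mu_m N_mj) v_j, the rate times the
# (negative) reaction chemical-potential difference; identical to the
# one-way-rate route under mass action and used as a numerical cross-check
entropy_production_stoich <- function(mu, N, v_net) {
  as.vector(-Matrix::crossprod(N, mu)) * v_net
}

#' Per-reaction entropy production of a steady state
#'
#' Overflow-safe variant of [reaction_entropy_production()] working on the
#' log one-way rates stored in the state, so that reactions whose Arrhenius
#' constants underflow to zero (activation energies beyond ~745 under the
#' heavy-tailed barrier distribution) contribute exactly zero instead of
#' raising a domain error.
#'
#' @param state a `steady_state`.
#' @return nonnegative per-reaction entropy production rates.
#' @export
steady_state_sigma <- function(state) {
  lp <- state$log_v_plus; lm <- state$log_v_minus
  s <- (exp(lp) - exp(lm)) * (lp - lm)
  s[exp(lp) == exp(lm)] <- 0 # balanced or doubly-underflowed reactions
  s
}

#' Total entropy production and its boundary-balance residual
#'
#' At a clamped steady state with re-zeroed boundary formation energies the
#' whole network behaves like one imaginary linear reaction `b1 <=> b2`, so
#' the total entropy production must equal `v * ln(c1/c2)` with `v` the
#' boundary flow. Returns both the total and the relative residual of that
#' identity (defined as 0 at equilibrium where both sides vanish).
#'
#' @param state a `steady_state`.
#' @param net the owning `reaction_network`.
#' @param boundary the `boundary_condition` of the run.
#' @return list with `sigma_tot` and `eq_residual`.
#' @export
total_entropy_check <- function(state, net, boundary) {
  sigma <- steady_state_sigma(state)
  sigma_tot <- sum(sigma)
  rhs <- state$boundary_flow * log(boundary$c1 / boundary$c2)
  res <- if (sigma_tot == 0 && rhs == 0) 0 else
    abs(sigma_tot - rhs) / max(sigma_tot, .Machine$double.xmin)
  list(sigma_tot = sigma_tot, eq_residual = res)
}

#' Chemical potentials
#'
#' `mu_i = mu0_i + ln(x_i)`; for a re-zeroed boundary species this is just
#' the log of its clamped concentration.
#'
#' @param mu0 per-species formation energies.
#' @param x strictly positive concentrations.
#' @return numeric vector of chemical potentials.
#' @export
chemical_potentials <- function(mu0, x) {
  if (any(x <= 0)) stop("chemical potentials need strictly positive concentrations")
  mu0 + log(x)
}

#' Spread of chemical potentials relative to the boundary span
#'
#' Population standard deviation of the chemical potentials over all
#' species, normalized by the absolute difference of the two boundary
#' species' potentials.
#'
#' @param mu per-species chemical potentials.
#' @param boundary a `boundary_condition`.
#' @return scalar `sigma_mu / delta_mu`.
#' @export
potential_spread <- function(mu, boundary) {
  dmu <- abs(mu[boundary$b2] - mu[boundary$b1])
  if (dmu == 0)
    stop("potential spread is undefined when the boundary potentials coincide")
  pop_sd(mu) / dmu
}

#' Fraction of dissipation carried by the top-dissipating reactions
#'
#' Sorts the per-reaction entropy productions in decreasing order, sums the
#' top `ceiling(q * n)` and divides by the total.
#'
#' @param sigma nonnegative per-reaction entropy productions.
#' @param q fraction of reactions considered, in (0, 1].
#' @return scalar in (0, 1].
#' @export
dissipation_fraction <- function(sigma, q = 0.1) {
  if (q <= 0 || q > 1) stop("`q` must be in (0, 1]")
  tot <- sum(sigma)
  if (tot == 0) stop("dissipation fraction undefined for all-zero sigma")
  k <- ceiling(q * length(sigma))
  sum(sort(sigma, decreasing = TRUE)[seq_len(k)]) / tot
}

#' Fit a power-law exponent to the entropy-production distribution
#'
#' Default method: the positive samples inside the central quantile
#' `window` are histogrammed in logarithmically spaced bins and the
#' least-squares slope of `log10 density` against `log10 sigma` over the
#' non-empty bins is the exponent estimate. The default window (quantiles
#' 0.70 to 0.999, i.e. the region where the complementary cumulative
#' distribution falls from about 0.3 to 1e-3) is the intermediate region
#' where the entropy-production distribution is power-law-like; below it
#' the distribution is dominated by near-frozen reactions and bends over. A maximum-likelihood variant
#' (continuous Pareto estimator with `xmin` at the lower window edge) is
#' available for sensitivity analysis; the complementary-cumulative slope
#' is this exponent plus one.
#'
#' @param sigma sample of (entropy-production) values; nonpositive values
#'   are dropped.
#' @param window lower/upper quantile pair delimiting the fitted region.
#' @param n_bins number of logarithmic bins.
#' @param method `"logbin_ls"` (default) or `"mle"`.
#' @return object of class `powerlaw_fit`: `exponent` (slope of the
#'   density, negative), `r_squared`, `window`, `n`, `method`.
#' @export
fit_powerlaw_exponent <- function(sigma, window = c(0.7, 0.999), n_bins = 25,
                                  method = c("logbin_ls", "mle")) {
  method <- match.arg(method)
  x <- sigma[is.finite(sigma) & sigma > 0]
  if (length(x) < 100)
    stop("power-law fit needs at least 100 positive samples")
  lim <- quantile(x, window, names = FALSE)
  xs <- x[x >= lim[1] & x <= lim[2]]
  if (method == "mle") {
    alpha <- 1 + length(xs) / sum(log(xs / lim[1]))
    fit <- list(exponent = -alpha, r_squared = NA_real_)
  } else {
    br <- exp(seq(log(lim[1]), log(lim[2]), length.out = n_bins + 1))
    cnt <- tabulate(findInterval(xs, br, rightmost.closed = TRUE), n_bins)
    dens <- cnt / (length(x) * diff(br))
    mid <- sqrt(br[-1] * br[-length(br)])
    ok <- dens > 0
    fit_lm <- lm(log10(dens[ok]) ~ log10(mid[ok]))
    fit <- list(exponent = unname(coef(fit_lm)[2]),
                r_squared = summary(fit_lm)$r.squared)
  }
  structure(c(fit, list(window = window, n = length(x), method = method)),
            class = "powerlaw_fit")
}

#' @exportS3Method base::print
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit (%s): exponent %.3f (R^2 %s, n = %d, window [%g, %g])\n",
              x$method, x$exponent,
              if (is.na(x$r_squared)) "-" else sprintf("%.3f", x$r_squared),
              x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Count directed cycles of length 1, 2 or 4 in a multigraph
#'
#' Length 1 counts self-loop edge instances; length 2 counts unordered
#' pairs of antiparallel edge instances between distinct nodes; length 4
#' counts simple directed cycles over 4 distinct nodes using 4 distinct
#' edge instances, once per rotation class. The default method uses
#' adjacency-matrix algebra (closed 4-walk counts corrected for repeated
#' nodes); `method = "enumerate"` is an independent depth-first enumeration
#' for cross-checking on small graphs.
#'
#' @param g a directed `rrn_graph` (or igraph).
#' @param length cycle length, one of 1, 2, 4.
#' @param method `"matrix"` (default) or `"enumerate"`.
#' @return nonnegative count.
#' @export
count_directed_cycles <- function(g, length, method = c("matrix", "enumerate")) {
  method <- match.arg(method)
  if (!length %in% c(1, 2, 4)) stop("supported cycle lengths: 1, 2, 4")
  if (inherits(g, "rrn_graph")) {
    n <- g$n_nodes; e <- g$edges
  } else {
    n <- igraph::vcount(g); e <- igraph::as_edgelist(g, names = FALSE)
  }
  if (length == 1) return(sum(e[, 1] == e[, 2]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  A <- A - Matrix::Diagonal(n, Matrix::diag(A)) # self-loops never sit in 2-/4-cycles
  if (method == "enumerate") return(enumerate_cycles(as.matrix(A), length))
  At <- Matrix::t(A)
  if (length == 2) return(sum(A * At) / 2)
  A2 <- A %*% A
  tr4 <- sum(A2 * Matrix::t(A2))
  C <- A * At
  s <- Matrix::rowSums(C)
  (tr4 - 2 * sum(s^2) + sum(C^2)) / 4
}

# brute-force reference: explicit sums over distinct node tuples with
# multiplicity products (feasible for graphs of a few dozen nodes)
enumerate_cycles <- function(A, length) {
  n <- nrow(A)
  if (length == 2) {
    tot <- 0
    for (u in seq_len(n - 1))
      for (v in (u + 1):n) tot <- tot + A[u, v] * A[v, u]
    return(tot)
  }
  tot <- 0
  for (u in seq_len(n)) {       # u is the smallest node in its cycle
    rest <- which(seq_len(n) > u)
    for (v in rest) {
      if (A[u, v] == 0) next
      for (w in setdiff(rest, v)) {
        if (A[v, w] == 0) next
        for (z in setdiff(rest, c(v, w))) {
          tot <- tot + A[u, v] * A[v, w] * A[w, z] * A[z, u]
        }
      }
    }
  }
  tot
}

#' Cycle excess of a flow-directed substrate graph over random directions
#'
#' Counts directed 1-, 2- and 4-cycles in the substrate graph oriented by
#' the steady-state net reaction rates, and subtracts the mean counts over
#' `reps` re-orientations of the same network with random reaction
#' directions (all cross-pair edges of a reaction flip together).
#'
#' @param net a `reaction_network`.
#' @param v_net signed net rate per reaction (e.g. from a `steady_state`).
#' @param reps number of random-direction baseline samples.
#' @param lengths cycle lengths to census.
#' @param seed optional integer seed.
#' @return data.frame with columns `length`, `observed`, `baseline_mean`,
#'   `baseline_sd`, `excess`.
#' @export
cycle_excess <- function(net, v_net, reps = 10, lengths = c(1, 2, 4),
                         seed = NULL) {
  gobs <- directed_substrate_graph(net, v_net)
  obs <- vapply(lengths, function(l) count_directed_cycles(gobs, l), 0)
  with_seed(seed, {
    base <- vapply(seq_len(reps), function(r) {
      dirs <- sample(c(-1, 1), n_reactions(net), replace = TRUE)
      grand <- directed_substrate_graph(net, dirs)
      vapply(lengths, function(l) count_directed_cycles(grand, l), 0)
    }, numeric(length(lengths)))
    base <- matrix(base, nrow = length(lengths))
    data.frame(length = lengths, observed = obs,
               baseline_mean = rowMeans(base),
               baseline_sd = apply(base, 1, sd),
               excess = obs - rowMeans(base))
  })
}

#' Topology metrics of a substrate graph
#'
#' Mean shortest-path length over connected ordered pairs (respecting edge
#' direction when the input graph is directed, which is how reaction
#' orientation enters the census), transitivity of the simple undirected
#' projection, and Newman modularity of the walktrap partition (4-step
#' random walks, best cut of the dendrogram) on that projection. The
#' default clustering coefficient is the global transitivity (closed
#' triples over connected triples); the average local clustering is
#' available via `clustering = "local"` (nodes of degree < 2 count as 0).
#'
#' @param g an `rrn_graph` or igraph object; pass the directed substrate
#'   graph to measure directed path lengths.
#' @param clustering `"global"` (default) or `"local"`.
#' @return list with `mean_shortest_path`, `clustering`, `modularity`.
#' @export
topology_metrics <- function(g, clustering = c("global", "local")) {
  clustering <- match.arg(clustering)
  ig <- if (inherits(g, "rrn_graph")) as_igraph(g) else g
  directed <- igraph::is_directed(ig)
  gu <- igraph::simplify(igraph::as_undirected(ig, mode = "each"))
  L <- if (directed) {
    igraph::mean_distance(igraph::simplify(ig), directed = TRUE,
                          unconnected = TRUE)
  } else {
    comp <- igraph::components(gu)
    big <- igraph::induced_subgraph(gu, which(comp$membership ==
                                                which.max(comp$csize)))
    igraph::mean_distance(big, directed = FALSE)
  }
  wt <- igraph::cluster_walktrap(gu, steps = 4)
  list(mean_shortest_path = L,
       clustering = if (clustering == "global")
         igraph::transitivity(gu, type = "global")
       else igraph::transitivity(gu, type = "localaverage",
                                 isolates = "zero"),
       modularity = igraph::modularity(gu, igraph::membership(wt)))
}

#' Dissipation as a function of species connectivity
#'
#' For every species, the mean entropy production of the reactions it takes
#' part in; species are then grouped by their substrate-graph degree
#' (multigraph degree, self-loops counted twice) and the per-degree mean is
#' normalized by the network-wide mean entropy production per reaction.
#'
#' @param net a `reaction_network`.
#' @param sigma per-reaction entropy productions.
#' @return data.frame with columns `degree`, `mean_sigma_norm`, `n_species`.
#' @export
degree_dissipation_profile <- function(net, sigma) {
  if (length(sigma) != n_reactions(net))
    stop("one sigma per reaction required")
  r <- net$reactants; p <- net$products
  sp <- c(r[, 1], r[, 2], p[, 1], p[, 2])
  rx <- rep(seq_len(n_reactions(net)), 4)
  keep <- !is.na(sp)
  inc <- unique(data.frame(sp = sp[keep], rx = rx[keep]))
  per_species <- tapply(sigma[inc$rx], inc$sp, mean)
  ids <- as.integer(names(per_species))
  deg <- substrate_degrees(net)[ids]
  agg <- aggregate(list(mean_sigma = as.vector(per_species)),
                   by = list(degree = deg), FUN = mean)
  cnt <- as.vector(table(deg))
  data.frame(degree = agg$degree,
             mean_sigma_norm = agg$mean_sigma / mean(sigma),
             n_species = cnt)
}
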