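#' Reaction networks of reversible 1-to-1 and 2-to-2 reactions
#'
#' A `reaction_network` holds `n_species` species and an ordered list of
#' reversible reactions, each either linear (`X <=> Y`) or nonlinear
#' (`X + Z <=> Y + W`). Reactants and products are stored as two-column
#' integer matrices with `NA` in the second column for linear reactions.
#' A species may appear on both sides of a reaction (this produces
#' self-edges in the substrate graph), and within one side (`A + A`, giving
#' stoichiometric coefficient 2).
#'
#' @param n_species number of species.
#' @param reactants,products two-column integer matrices (2nd column `NA`
#'   for linear reactions), one row per reaction.
#' @param model network-model tag inherited from the generating graph.
#' @param meta provenance metadata (seeds, model parameters).
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(n_species, reactants, products, model = NA,
                             meta = list()) {
  n_species <- check_count(n_species, "n_species", min = 1)
  reactants <- as.matrix(reactants); products <- as.matrix(products)
  storage.mode(reactants) <- "integer"; storage.mode(products) <- "integer"
  if (ncol(reactants) != 2L || ncol(products) != 2L ||
      nrow(reactants) != nrow(products))
    stop("reactants/products must be aligned two-column matrices")
  ord_r <- 2L - is.na(reactants[, 2]); ord_p <- 2L - is.na(products[, 2])
  if (any(ord_r != ord_p))
    stop("every reaction must have equally many reactants and products")
  rng <- range(c(reactants, products), na.rm = TRUE)
  if (nrow(reactants) > 0 && (rng[1] < 1 || rng[2] > n_species))
    stop("species id outside 1..n_species")
  dimnames(reactants) <- dimnames(products) <- NULL
  structure(list(n_species = n_species, reactants = reactants,
                 products = products, model = model, meta = meta),
            class = "reaction_network")
}

#' @exportS3Method base::print
print.reaction_network <- function(x, ...) {
  nl <- sum(is.na(x$reactants[, 2]))
  cat(sprintf(
    "reaction_network (%s): %d species, %d reactions (%d linear, %d nonlinear)\n",
    x$model, x$n_species, nrow(x$reactants), nl, nrow(x$reactants) - nl))
  invisible(x)
}

#' Number of reactions in a network
#' @param net a `reaction_network`.
#' @export
n_reactions <- function(net) nrow(net$reactants)

#' Which reactions are second order
#' @param net a `reaction_network`.
#' @return logical vector, `TRUE` for 2-to-2 reactions.
#' @export
is_nonlinear <- function(net) !is.na(net$reactants[, 2])

#' Build a linear reaction network from a directed multigraph
#'
#' Every edge `(u, v)` becomes one reversible reaction `u <=> v`; the species
#' set is the node set.
#'
#' @param g an `rrn_graph`.
#' @return a purely linear `reaction_network`.
#' @export
linear_network_from_graph <- function(g) {
  stopifnot(inherits(g, "rrn_graph"))
  if (nrow(g$edges) == 0) stop("graph has no edges")
  n <- nrow(g$edges)
  reaction_network(g$n_nodes,
                   cbind(g$edges[, 1], rep(NA_integer_, n)),
                   cbind(g$edges[, 2], rep(NA_integer_, n)),
                   model = g$model, meta = g$meta)
}

#' Substrate graph of a reaction network
#'
#' An edge joins two species that appear on opposite sides of some reaction:
#' one edge per (reactant, product) cross pair, with multiplicity, so a
#' linear reaction contributes 1 edge and a nonlinear reaction 4.
#'
#' @param net a `reaction_network`.
#' @param directed if `TRUE`, edges are oriented reactant to product in the
#'   as-written direction.
#' @return an `rrn_graph` (undirected by default).
#' @export
substrate_graph <- function(net, directed = FALSE) {
  e <- substrate_edges(net)
  rrn_graph(net$n_species, e[, c("from", "to")], model = net$model,
            directed = directed, meta = net$meta)
}

# cross-pair edge list with the owning reaction index attached
substrate_edges <- function(net) {
  r <- net$reactants; p <- net$products
  lin <- is.na(r[, 2])
  idx <- which(!lin)
  from <- c(r[lin, 1], r[idx, 1], r[idx, 1], r[idx, 2], r[idx, 2])
  to   <- c(p[lin, 1], p[idx, 1], p[idx, 2], p[idx, 1], p[idx, 2])
  rx   <- c(which(lin), idx, idx, idx, idx)
  cbind(from = as.integer(from), to = as.integer(to), reaction = rx)
}

#' Directed substrate graph under a set of net reaction rates
#'
#' Each reaction's cross-pair edges are oriented reactant to product when the
#' reaction's net rate is positive and product to reactant when negative;
#' a zero rate keeps the as-written direction.
#'
#' @param net a `reaction_network`.
#' @param net_rates one signed net rate per reaction.
#' @return a directed `rrn_graph`.
#' @export
directed_substrate_graph <- function(net, net_rates) {
  if (length(net_rates) != n_reactions(net))
    stop("one net rate per reaction required")
  e <- substrate_edges(net)
  rev <- net_rates[e[, "reaction"]] < 0
  e2 <- e[, c("from", "to"), drop = FALSE]
  e2[rev, ] <- e2[rev, c(2, 1), drop = FALSE]
  rrn_graph(net$n_species, e2, model = net$model, directed = TRUE,
            meta = net$meta)
}

#' Stoichiometric matrices of a reaction network
#'
#' Returns the left and right stoichiometric matrices and their difference.
#' Duplicated species within a side accumulate (`A + A` gives a coefficient
#' of 2). Every column of `N` sums to zero because reactions conserve the
#' total molecule count.
#'
#' @param net a `reaction_network`.
#' @return a list with sparse matrices `L`, `R` (species x reactions,
#'   nonnegative integers) and `N = R - L`.
#' @export
stoichiometric_matrices <- function(net) {
  nr <- n_reactions(net)
  tri <- function(m) {
    j <- rep(seq_len(nr), 2)
    keep <- !is.na(as.vector(m))
    Matrix::sparseMatrix(i = as.vector(m)[keep], j = j[keep],
                         x = rep(1, sum(keep)),
                         dims = c(net$n_species, nr))
  }
  L <- tri(net$reactants); R <- tri(net$products)
  list(L = L, R = R, N = R - L)
}

#' Weight of coupling two linear reactions into one 2-to-2 reaction
#'
#' Coupling `A <=> B` (reaction `i`) with `C <=> D` (reaction `j`) forms
#' `A + C <=> B + D` and introduces the substrate edges `A - D` and `C - B`.
#' The weight is the probability weight those two new edges would have in
#' the generating network model: ER, uniform (1); BA, the product of the
#' current substrate-graph degrees of the two products; WS, 1 if both new
#' edges span ring distance at most `k/2`, else 0; PS, `p^l1 * p^l2` for the
#' lowest-common-module levels of the two new edges.
#'
#' @param net a purely linear `reaction_network` carrying model metadata.
#' @param i,j reaction indices (both must be linear).
#' @param degrees optional precomputed substrate-graph degree vector (BA);
#'   defaults to the degrees of `net`'s substrate graph.
#' @return a nonnegative scalar weight.
#' @export
coupling_weight <- function(net, i, j, degrees = NULL) {
  if (any(is_nonlinear(net)[c(i, j)]))
    stop("coupling weights are defined for linear reactions only")
  A <- net$reactants[i, 1]; B <- net$products[i, 1]
  C <- net$reactants[j, 1]; D <- net$products[j, 1]
  switch(net$model,
    ER = 1,
    BA = {
      if (is.null(degrees)) degrees <- substrate_degrees(net)
      degrees[B] * degrees[D]
    },
    WS = {
      k <- net$meta$k
      as.numeric(ring_distance(A, D, net$n_species) <= k / 2 &&
                 ring_distance(C, B, net$n_species) <= k / 2)
    },
    PS = {
      p <- net$meta$p
      part <- list(module0 = net$meta$module0)
      p^lowest_common_level(A, D, part) * p^lowest_common_level(C, B, part)
    },
    stop(sprintf("unknown network model '%s'", net$model)))
}

ring_distance <- function(u, v, n) {
  d <- abs(u - v)
  pmin(d, n - d)
}

# multigraph degree (self-loops count twice) of the substrate graph
substrate_degrees <- function(net) {
  e <- substrate_edges(net)
  tabulate(c(e[, "from"], e[, "to"]), net$n_species)
}

#' Couple pairs of linear reactions into 2-to-2 reactions
#'
#' Performs `n_couplings` sequential draws of an unordered pair of distinct,
#' still-linear reactions with probability proportional to
#' [coupling_weight()], replacing `A <=> B` and `C <=> D` by
#' `A + C <=> B + D`; consumed reactions leave the pool. For BA networks the
#' degrees entering the weight are read from the substrate graph as it exists
#' at draw time. The result contains `n_reactions - 2 n_couplings` linear
#' and `n_couplings` nonlinear reactions (surviving linear reactions first,
#' in their original order).
#'
#' @param net a purely linear `reaction_network`.
#' @param n_couplings number of pairs to couple.
#' @param seed optional integer seed.
#' @return a `reaction_network` with mixed reaction orders.
#' @export
couple_reactions <- function(net, n_couplings, seed = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  if (any(is_nonlinear(net))) stop("input network must be purely linear")
  n_couplings <- check_count(n_couplings, "n_couplings", min = 1)
  M <- n_reactions(net)
  if (2 * n_couplings > M)
    stop("not enough linear reactions for the requested couplings")
  with_seed(seed, {
    pairs <- switch(net$model,
      ER = couple_pairs_uniform(M, n_couplings),
      BA = couple_pairs_ba(net, n_couplings),
      WS = couple_pairs_ws(net, n_couplings),
      PS = couple_pairs_ps(net, n_couplings),
      stop(sprintf("unknown network model '%s'", net$model)))
    build_coupled_network(net, pairs)
  })
}

build_coupled_network <- function(net, pairs) {
  used <- c(pairs[, 1], pairs[, 2])
  keep <- setdiff(seq_len(n_reactions(net)), used)
  reac <- rbind(cbind(net$reactants[keep, 1], rep(NA_integer_, length(keep))),
                cbind(net$reactants[pairs[, 1], 1],
                      net$reactants[pairs[, 2], 1]))
  prod <- rbind(cbind(net$products[keep, 1], rep(NA_integer_, length(keep))),
                cbind(net$products[pairs[, 1], 1],
                      net$products[pairs[, 2], 1]))
  meta <- net$meta
  meta$coupled_from <- pairs
  reaction_network(net$n_species, reac, prod, model = net$model, meta = meta)
}

# ER: sequential uniform draws of pairs of distinct unused reactions are
# equivalent to pairing up a uniform sample of 2C reactions
couple_pairs_uniform <- function(M, C) {
  sel <- sample.int(M, 2 * C)
  cbind(sel[seq_len(C)], sel[C + seq_len(C)])
}

# BA: pair weight deg(B_i) * deg(B_j) factorizes, so drawing the first
# reaction with probability ~ w_i (S - w_i) and the partner ~ w_j gives the
# exact pairwise law; degrees update as couplings add substrate edges
couple_pairs_ba <- function(net, C) {
  deg <- substrate_degrees(net)
  prod1 <- net$products[, 1]
  reac1 <- net$reactants[, 1]
  alive <- rep(TRUE, n_reactions(net))
  out <- matrix(0L, C, 2)
  for (c in seq_len(C)) {
    ids <- which(alive)
    w <- deg[prod1[ids]]
    S <- sum(w)
    i <- ids[sample.int(length(ids), 1L, prob = w * (S - w))]
    ids2 <- setdiff(ids, i)
    j <- ids2[sample.int(length(ids2), 1L, prob = deg[prod1[ids2]])]
    out[c, ] <- c(i, j)
    alive[c(i, j)] <- FALSE
    # new substrate edges A_i - B_j and A_j - B_i
    for (v in c(reac1[i], prod1[j], reac1[j], prod1[i]))
      deg[v] <- deg[v] + 1
  }
  out
}

# WS: weights are 0/1, so couplings are uniform over currently compatible
# pairs; the static compatibility graph (both new edges within ring
# distance k/2) is precomputed and degrees within it maintained under
# removals
couple_pairs_ws <- function(net, C) {
  M <- n_reactions(net)
  n <- net$n_species
  half <- net$meta$k / 2
  A <- net$reactants[, 1]; B <- net$products[, 1]
  by_source <- split(seq_len(M), A)
  ball <- function(v) (v - 1 + c(-half:half)) %% n + 1
  partners <- vector("list", M)
  for (i in seq_len(M)) {
    cand <- unlist(by_source[as.character(ball(B[i]))], use.names = FALSE)
    cand <- cand[ring_distance(A[i], B[cand], n) <= half & cand != i]
    partners[[i]] <- cand
  }
  cnt <- lengths(partners)
  alive <- rep(TRUE, M)
  out <- matrix(0L, C, 2)
  for (c in seq_len(C)) {
    if (sum(cnt[alive]) == 0)
      stop("coupling infeasible for WS: no compatible pairs left")
    ids <- which(alive)
    i <- ids[sample.int(length(ids), 1L, prob = cnt[ids])]
    ps <- partners[[i]][alive[partners[[i]]]]
    j <- ps[sample.int(length(ps), 1L)]
    out[c, ] <- c(i, j)
    for (r in c(i, j)) {
      alive[r] <- FALSE
      hit <- partners[[r]]
      cnt[hit] <- cnt[hit] - 1
    }
  }
  out
}

# PS: the full pairwise weight table is O(M^2) but feasible at M = 3000;
# weights are static, so marginals are maintained by subtraction
couple_pairs_ps <- function(net, C) {
  M <- n_reactions(net)
  p <- net$meta$p
  A <- net$reactants[, 1]; B <- net$products[, 1]
  # P1[i, j] = p^l(A_i, B_j); pair weight W = P1 * t(P1)
  l1 <- outer(net$meta$module0[A], net$meta$module0[B], bitwXor)
  l1[l1 > 0] <- floor(log2(l1[l1 > 0])) + 1
  W <- p^l1 * t(p^l1)
  diag(W) <- 0
  marg <- rowSums(W)
  alive <- rep(TRUE, M)
  out <- matrix(0L, C, 2)
  for (c in seq_len(C)) {
    ids <- which(alive)
    if (sum(marg[ids]) <= 0)
      stop("coupling infeasible for PS: all pair weights zero")
    i <- ids[sample.int(length(ids), 1L, prob = marg[ids])]
    ids2 <- setdiff(ids, i)
    j <- ids2[sample.int(length(ids2), 1L, prob = W[i, ids2])]
    out[c, ] <- c(i, j)
    for (r in c(i, j)) {
      alive[r] <- FALSE
      marg <- marg - W[, r]
    }
  }
  out
}

#' Linear network from the substrate graph of a (nonlinear) network
#'
#' One reversible linear reaction per substrate edge, in the as-written
#' orientation. Used to compare linear and nonlinear networks on an
#' identical substrate graph.
#'
#' @param net a `reaction_network`.
#' @return a purely linear `reaction_network` with as many reactions as
#'   `net`'s substrate graph has edges.
#' @export
linear_from_substrate <- function(net) {
  g <- substrate_graph(net, directed = TRUE)
  out <- linear_network_from_graph(g)
  out$meta$derived_from <- "substrate_graph"
  out
}
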