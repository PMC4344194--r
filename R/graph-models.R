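#' Directed multigraphs for reaction-network construction
#'
#' All four generators return an `rrn_graph`: a directed multigraph with
#' exactly `n_edges` edges in which self-loops and parallel edges are
#' permitted. Nodes are integers `1..n_nodes`. Edge orientation is assigned
#' uniformly at random for every edge, because the underlying complex-network
#' models are undirected while reactions need a direction.
#'
#' @param n_nodes number of nodes (chemical species), at least 2.
#' @param n_edges number of edges (first-order reactions), at least 1.
#' @param edges two-column integer matrix of (source, target) pairs.
#' @param model one of `"ER"`, `"BA"`, `"WS"`, `"PS"`.
#' @param directed logical; reaction graphs are directed, substrate graphs
#'   derived from them may be undirected.
#' @param meta list of model metadata (ring degree for WS, module partition
#'   for PS, the seed used, ...).
#' @return an object of class `rrn_graph` with fields `n_nodes`, `edges`,
#'   `model`, `directed` and `meta`.
#' @name rrn_graph
NULL

#' @rdname rrn_graph
#' @export
rrn_graph <- function(n_nodes, edges, model = "ER", directed = TRUE,
                      meta = list()) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 1)
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  if (nrow(edges) > 0 && (min(edges) < 1L || max(edges) > n_nodes))
    stop("edge endpoints outside 1..n_nodes")
  dimnames(edges) <- NULL
  structure(list(n_nodes = n_nodes, edges = edges, model = model,
                 directed = directed, meta = meta),
            class = "rrn_graph")
}

#' @exportS3Method base::print
print.rrn_graph <- function(x, ...) {
  cat(sprintf("%s %s multigraph: %d nodes, %d edges (%d self-loops)\n",
              x$model, if (x$directed) "directed" else "undirected",
              x$n_nodes, nrow(x$edges), sum(x$edges[, 1] == x$edges[, 2])))
  invisible(x)
}

#' Convert to an igraph object
#'
#' Multiplicity and self-loops are preserved.
#'
#' @param g an `rrn_graph`.
#' @param directed override the graph's own directedness.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(g, directed = g$directed) {
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = directed)
  igraph::add_edges(ig, t(g$edges))
}

# randomize edge orientation: swap endpoints with probability 1/2
orient_uniform <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  flip <- runif(nrow(edges)) < 0.5
  edges[flip, ] <- edges[flip, c(2, 1), drop = FALSE]
  edges
}

#' Erdős–Rényi directed multigraph
#'
#' Both endpoints of every edge are drawn independently and uniformly from
#' the node set, so self-loops occur with probability `1/n_nodes` per edge
#' and parallel edges are possible.
#'
#' @inheritParams rrn_graph
#' @param seed optional integer seed for a private RNG stream.
#' @return an `rrn_graph` with `model = "ER"`.
#' @export
generate_er <- function(n_nodes, n_edges, seed = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2)
  n_edges <- check_count(n_edges, "n_edges", min = 1)
  with_seed(seed, {
    edges <- cbind(sample.int(n_nodes, n_edges, replace = TRUE),
                   sample.int(n_nodes, n_edges, replace = TRUE))
    rrn_graph(n_nodes, edges, model = "ER", meta = list(seed = seed))
  })
}

#' Barabási–Albert directed multigraph
#'
#' Preferential attachment with `m = round(n_edges / n_nodes)` edges per
#' entering node. The seed core is a path over the first `m` nodes. When a
#' node enters, it is included in the attachment pool at initial weight 1
#' (so it can attach to itself); targets are drawn with probability
#' proportional to current total degree, degrees updating after every drawn
#' edge. If the construction does not hit `n_edges` exactly, uniformly
#' oriented preferential edges are added (both endpoints degree-weighted) or
#' uniformly chosen edges removed. Orientation is uniform per edge.
#'
#' @inheritParams generate_er
#' @export
generate_ba <- function(n_nodes, n_edges, seed = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2)
  n_edges <- check_count(n_edges, "n_edges", min = 1)
  m <- round(n_edges / n_nodes)
  if (m < 1) stop("n_edges/n_nodes must round to at least one edge per node")
  if (m >= n_nodes) stop("seed core larger than node set")
  with_seed(seed, {
    deg <- numeric(n_nodes)
    from <- integer(0); to <- integer(0)
    if (m > 1) { # path over the seed core
      from <- 1:(m - 1); to <- 2:m
      deg[1:m] <- tabulate(c(from, to), n_nodes)[1:m]
    }
    for (v in (m + 1):n_nodes) {
      w <- deg
      w[v] <- 1 # entering node at initial attachment weight 1
      for (j in seq_len(m)) {
        t <- sample.int(n_nodes, 1L, prob = w)
        from <- c(from, v); to <- c(to, t)
        deg[t] <- deg[t] + 1
        deg[v] <- deg[v] + 1
        w <- deg
      }
    }
    edges <- cbind(from, to)
    if (nrow(edges) > n_edges) {
      edges <- edges[-sample.int(nrow(edges), nrow(edges) - n_edges), ,
                     drop = FALSE]
    } else if (nrow(edges) < n_edges) {
      need <- n_edges - nrow(edges)
      deg <- tabulate(edges, n_nodes) # recompute (cheap, exact)
      extra <- matrix(0L, need, 2)
      for (i in seq_len(need)) {
        u <- sample.int(n_nodes, 1L, prob = deg)
        v <- sample.int(n_nodes, 1L, prob = deg)
        extra[i, ] <- c(u, v)
        deg[u] <- deg[u] + 1; deg[v] <- deg[v] + 1
      }
      edges <- rbind(edges, extra)
    }
    rrn_graph(n_nodes, orient_uniform(edges), model = "BA",
              meta = list(seed = seed, m = m))
  })
}

#' Watts–Strogatz directed multigraph
#'
#' Starts from a ring lattice connecting every node to its `k/2` nearest
#' neighbours on each side, with `k = 2 n_edges / n_nodes` (must be a
#' positive even integer). A fraction `rewire_fraction` of the edges is then
#' rewired: `floor(rewire_fraction * n_edges)` edges are selected uniformly
#' and one endpoint (chosen at random) is replaced by a uniform random node,
#' so self-loops become possible. Node ids double as ring positions and are
#' kept in the metadata for the coupling stage.
#'
#' @inheritParams generate_er
#' @param rewire_fraction fraction of edges rewired (the model's alpha).
#' @export
generate_ws <- function(n_nodes, n_edges, rewire_fraction = 0.1, seed = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2)
  n_edges <- check_count(n_edges, "n_edges", min = 1)
  if (rewire_fraction < 0 || rewire_fraction > 1)
    stop("`rewire_fraction` must be a probability")
  k <- 2 * n_edges / n_nodes
  if (k != round(k) || k %% 2 != 0 || k < 2)
    stop("2*n_edges/n_nodes must be a positive even integer for WS")
  with_seed(seed, {
    half <- k / 2
    from <- rep(seq_len(n_nodes), half)
    off <- rep(seq_len(half), each = n_nodes)
    to <- (from + off - 1L) %% n_nodes + 1L
    edges <- cbind(as.integer(from), as.integer(to))
    n_rw <- floor(rewire_fraction * n_edges)
    rewired <- logical(n_edges)
    if (n_rw > 0) {
      idx <- sample.int(n_edges, n_rw)
      side <- sample(1:2, n_rw, replace = TRUE)
      repl <- sample.int(n_nodes, n_rw, replace = TRUE)
      edges[cbind(idx, side)] <- repl
      rewired[idx] <- TRUE
    }
    rrn_graph(n_nodes, orient_uniform(edges), model = "WS",
              meta = list(seed = seed, k = as.integer(k),
                          rewire_fraction = rewire_fraction,
                          rewired = rewired))
  })
}

#' Pan–Sinha hierarchically modular directed multigraph
#'
#' Nodes are partitioned round-robin into `2^levels` elementary modules of
#' near-equal size; elementary modules are merged pairwise into a binary
#' module tree of height `levels`. Every edge is drawn by sampling an
#' unordered node pair (self-pairs allowed) with weight
#' `level_decay^l(u, v)` where `l(u, v)` is the lowest tree level at which
#' the two nodes share a module; the orientation is then uniform.
#'
#' @inheritParams generate_er
#' @param level_decay geometric decay `p` of the pair weight per tree level.
#' @param levels height `h` of the binary module tree; `2^levels` must not
#'   exceed `n_nodes`.
#' @export
generate_ps <- function(n_nodes, n_edges, level_decay = 0.5, levels = 8,
                        seed = NULL) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2)
  n_edges <- check_count(n_edges, "n_edges", min = 1)
  levels <- check_count(levels, "levels", min = 1)
  if (2^levels > n_nodes) stop("2^levels must not exceed n_nodes")
  if (level_decay <= 0 || level_decay > 1)
    stop("`level_decay` must be in (0, 1]")
  module0 <- (seq_len(n_nodes) - 1L) %% as.integer(2^levels) # 0-based
  part <- ps_partition(n_nodes, levels, module0)
  wtab <- ps_level_weights(part, level_decay)
  with_seed(seed, {
    lev <- sample.int(levels + 1L, n_edges, replace = TRUE,
                      prob = wtab$weight) - 1L
    edges <- matrix(0L, n_edges, 2)
    for (l in 0:levels) {
      sel <- which(lev == l)
      if (!length(sel)) next
      if (l == 0) {
        mods <- sample.int(length(part$elem_nodes), length(sel),
                           replace = TRUE, prob = part$elem_pairs)
        for (i in seq_along(sel)) {
          nodes <- part$elem_nodes[[mods[i]]]
          edges[sel[i], ] <- sample_unordered_pair(nodes)
        }
      } else {
        blocks <- part$level_blocks[[l]]
        mods <- sample.int(nrow(blocks), length(sel), replace = TRUE,
                           prob = blocks[, "pairs"])
        for (i in seq_along(sel)) {
          u <- part$node_sets[[l]]$left[[mods[i]]]
          v <- part$node_sets[[l]]$right[[mods[i]]]
          edges[sel[i], ] <- c(u[sample.int(length(u), 1L)],
                               v[sample.int(length(v), 1L)])
        }
      }
    }
    rrn_graph(n_nodes, orient_uniform(edges), model = "PS",
              meta = list(seed = seed, p = level_decay, h = levels,
                          module0 = module0))
  })
}

# uniform unordered pair {u, v} with u = v allowed, from a node vector:
# draw an ordered pair; distinct draws are accepted with probability 1/2 so
# that every unordered pair (self or not) has equal weight
sample_unordered_pair <- function(nodes) {
  s <- length(nodes)
  repeat {
    uv <- nodes[sample.int(s, 2L, replace = TRUE)]
    if (uv[1] == uv[2] || runif(1) < 0.5) return(uv)
  }
}

# Precompute the PS module tree bookkeeping. module0 is the 0-based
# elementary module per node; the level-l module of elementary module e is
# e %/% 2^l, so siblings differ in bit l-1.
ps_partition <- function(n_nodes, levels, module0) {
  elem_nodes <- split(seq_len(n_nodes), module0)
  elem_sizes <- lengths(elem_nodes)
  elem_ids <- as.integer(names(elem_nodes))
  node_sets <- vector("list", levels)
  level_blocks <- vector("list", levels)
  for (l in seq_len(levels)) {
    gid <- elem_ids %/% as.integer(2^l)          # level-l module of each elem
    side <- (elem_ids %/% as.integer(2^(l - 1))) %% 2L # which child
    groups <- sort(unique(gid))
    left <- right <- vector("list", length(groups))
    nl <- nr <- integer(length(groups))
    for (gi in seq_along(groups)) {
      le <- which(gid == groups[gi] & side == 0L)
      ri <- which(gid == groups[gi] & side == 1L)
      left[[gi]] <- unlist(elem_nodes[le], use.names = FALSE)
      right[[gi]] <- unlist(elem_nodes[ri], use.names = FALSE)
      nl[gi] <- length(left[[gi]]); nr[gi] <- length(right[[gi]])
    }
    node_sets[[l]] <- list(left = left, right = right)
    level_blocks[[l]] <- cbind(group = groups, pairs = nl * nr)
  }
  list(levels = levels, module0 = module0, elem_nodes = elem_nodes,
       elem_pairs = elem_sizes * (elem_sizes + 1) / 2,
       node_sets = node_sets, level_blocks = level_blocks)
}

# total unnormalized sampling weight per lowest-common level l = 0..h
ps_level_weights <- function(part, p) {
  w <- numeric(part$levels + 1)
  w[1] <- sum(part$elem_pairs)
  for (l in seq_len(part$levels))
    w[l + 1] <- p^l * sum(part$level_blocks[[l]][, "pairs"])
  data.frame(level = 0:part$levels, weight = w)
}

#' Lowest common module level of two nodes in a PS partition
#'
#' Returns 0 when the two nodes share an elementary module (including
#' `u == v`), otherwise the smallest level of the binary module tree whose
#' module contains both.
#'
#' @param u,v node ids.
#' @param partition a PS `rrn_graph`, or a list with elements `h` and
#'   `module0` (0-based elementary module per node).
#' @return integer level in `0..h` (vectorized over `u`, `v`).
#' @export
lowest_common_level <- function(u, v, partition) {
  if (inherits(partition, "rrn_graph")) {
    if (is.null(partition$meta$module0))
      stop("graph carries no PS module partition")
    module0 <- partition$meta$module0
  } else {
    module0 <- partition$module0
  }
  if (any(u < 1 | u > length(module0) | v < 1 | v > length(module0)))
    stop("node outside partition")
  x <- bitwXor(module0[u], module0[v])
  l <- integer(length(x))
  nz <- x > 0
  l[nz] <- as.integer(floor(log2(x[nz])) + 1)
  l
}
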