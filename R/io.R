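#' Read and write graphs, networks and runs
#'
#' Graphs serialize to GraphML (via igraph) and to a native JSON dialect
#' `{n_nodes, edges: [[u, v], ...], model_tag, metadata}` with 0-based node
#' ids. Reaction networks serialize to a plain reaction-list text format
#' (one reaction per line, `"a + c <=> b + d"`, 0-based integer species ids
#' or names) and to a native JSON form with explicit sparse L/R triplets;
#' the JSON form carries the thermodynamic assignment under a `"thermo"`
#' key (rate constants are derived, not stored). Steady-state runs
#' serialize to JSON.
#'
#' @param g an `rrn_graph`.
#' @param path file path.
#' @name rrn_io
NULL

#' @rdname rrn_io
#' @export
write_graph_json <- function(g, path) {
  meta <- g$meta
  meta$rewired <- NULL # bulky per-edge flag, reconstructible only at source
  obj <- list(n_nodes = g$n_nodes,
              edges = unname(apply(g$edges - 1L, 1, as.list)),
              model_tag = g$model, directed = g$directed,
              metadata = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname rrn_io
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- as.list(obj$metadata)
  if (!is.null(meta$module0)) meta$module0 <- as.integer(meta$module0)
  em <- obj$edges
  if (is.list(em)) em <- do.call(rbind, lapply(em, unlist))
  storage.mode(em) <- "integer"
  rrn_graph(obj$n_nodes, em + 1L,
            model = obj$model_tag,
            directed = isTRUE(obj$directed), meta = meta)
}

#' @rdname rrn_io
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Write a reaction network as a reaction-list text file
#'
#' One reaction per line, e.g. `"0 + 3 <=> 2 + 7"` (0-based integer species
#' ids) or with species names.
#'
#' @param net a `reaction_network`.
#' @param path file path.
#' @param names optional character vector of species names.
#' @export
write_reaction_list <- function(net, path, names = NULL) {
  fmt <- function(m) {
    lab <- if (is.null(names)) function(i) i - 1L else function(i) names[i]
    apply(m, 1, function(row) {
      row <- row[!is.na(row)]
      paste(vapply(row, function(i) as.character(lab(i)), ""),
            collapse = " + ")
    })
  }
  writeLines(paste(fmt(net$reactants), "<=>", fmt(net$products)), path)
  invisible(path)
}

#' Read a reaction network from a reaction-list text file
#'
#' Integer tokens are treated as 0-based species ids; otherwise tokens are
#' species names and ids are assigned in order of first appearance.
#'
#' @param path file path.
#' @param n_species optional species count (inferred from the ids when
#'   omitted).
#' @return a `reaction_network`.
#' @export
read_reaction_list <- function(path, n_species = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  sides <- strsplit(lines, "<=>", fixed = TRUE)
  if (any(lengths(sides) != 2)) stop("every line must contain one '<=>'")
  toks <- lapply(sides, function(s)
    lapply(strsplit(trimws(s), "\\s*\\+\\s*"), trimws))
  all_tok <- unlist(toks)
  if (all(grepl("^[0-9]+$", all_tok))) {
    to_id <- function(t) as.integer(t) + 1L
  } else {
    lev <- unique(all_tok)
    to_id <- function(t) match(t, lev)
  }
  pad <- function(v) { length(v) <- 2; v }
  reac <- t(vapply(toks, function(s) pad(to_id(s[[1]])), integer(2)))
  prod <- t(vapply(toks, function(s) pad(to_id(s[[2]])), integer(2)))
  if (is.null(n_species)) n_species <- max(c(reac, prod), na.rm = TRUE)
  reaction_network(n_species, reac, prod, model = NA)
}

#' Write a reaction network (with optional thermodynamics) as JSON
#'
#' @param net a `reaction_network`.
#' @param path file path.
#' @param thermo optional `thermo_assignment` stored under `"thermo"`.
#' @export
write_network_json <- function(net, path, thermo = NULL) {
  mats <- stoichiometric_matrices(net)
  trip <- function(M) {
    s <- methods::as(M, "TsparseMatrix")
    list(i = s@i, j = s@j, x = s@x)
  }
  obj <- list(n_species = net$n_species, model_tag = net$model,
              reactants = unname(apply(net$reactants - 1L, 1, function(r)
                as.list(r[!is.na(r)]))),
              products = unname(apply(net$products - 1L, 1, function(r)
                as.list(r[!is.na(r)]))),
              L = trip(mats$L), R = trip(mats$R))
  if (!is.null(thermo))
    obj$thermo <- list(mu0 = thermo$mu0, ea_sampled = thermo$ea_sampled,
                       ea_fwd = thermo$ea_fwd, ea_bwd = thermo$ea_bwd,
                       direction_rule = thermo$direction_rule)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a reaction network (and its thermodynamics) from JSON
#'
#' @param path file path.
#' @return a list with `net` and (possibly `NULL`) `thermo`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pad <- function(v) { v <- as.integer(v) + 1L; length(v) <- 2; v }
  reac <- t(vapply(obj$reactants, pad, integer(2)))
  prod <- t(vapply(obj$products, pad, integer(2)))
  net <- reaction_network(obj$n_species, reac, prod, model = obj$model_tag)
  thermo <- NULL
  if (!is.null(obj$thermo))
    thermo <- assign_reaction_energetics(
      net, mu0 = obj$thermo$mu0, sampled_ea = obj$thermo$ea_sampled,
      direction_rule = obj$thermo$direction_rule)
  list(net = net, thermo = thermo)
}

#' Write a steady-state run as JSON
#'
#' @param state a `steady_state`.
#' @param path file path.
#' @export
write_run_json <- function(state, path) {
  obj <- list(x = state$x, v_plus = state$v_plus, v_minus = state$v_minus,
              flow = state$boundary_flow, converged = state$converged,
              t_final = state$t_final, residual = state$residual,
              boundary = unclass(state$boundary), solver = state$solver)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
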