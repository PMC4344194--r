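#' Configuration for the three experiment suites
#'
#' Defaults reproduce the study conditions: networks of 1000 species with
#' 5000 first-order reactions (linear mode) or 3000 first-order reactions
#' of which 1000 pairs are coupled into second-order reactions (nonlinear
#' mode); WS rewiring fraction 0.1; PS decay 0.5 with tree height 8;
#' boundary concentrations c1 = 0.1, c2 = 1; 50 boundary pairs per
#' shortest-path distance; 10 network samples; integration to t = 50000 or
#' stationarity residual 1e-20.
#'
#' @param model one or more of `"ER"`, `"BA"`, `"WS"`, `"PS"`.
#' @param mode one or more of `"linear"`, `"nonlinear"`,
#'   `"linear_from_nonlinear_substrate"`.
#' @param n_species,m_linear,n_couplings network size parameters;
#'   `m_linear = NULL` picks 5000 (linear) or 3000 (pre-coupling).
#' @param alpha WS rewiring fraction.
#' @param ps_p,ps_h PS level decay and tree height.
#' @param c1,c2 boundary concentrations; `c2` may be a ladder vector.
#' @param ladder_distance boundary shortest-path distance of the
#'   disequilibrium ladder.
#' @param pairs_per_distance boundary pairs per distance value.
#' @param n_network_samples independent network replicates.
#' @param t_max,residual_tol integration controls.
#' @param master_seed master seed; all per-network / per-run seeds are
#'   derived from it with [seed_child()] and logged in every output row.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(model = c("ER", "BA", "WS", "PS"),
                              mode = "linear", n_species = 1000,
                              m_linear = NULL, n_couplings = 1000,
                              alpha = 0.1, ps_p = 0.5, ps_h = 8,
                              c1 = 0.1, c2 = 1.0, ladder_distance = 3,
                              pairs_per_distance = 50,
                              n_network_samples = 10, t_max = 50000,
                              residual_tol = 1e-20, master_seed = 1) {
  model <- match.arg(model, several.ok = TRUE)
  mode <- match.arg(mode, c("linear", "nonlinear",
                            "linear_from_nonlinear_substrate"),
                    several.ok = TRUE)
  structure(list(model = model, mode = mode, n_species = n_species,
                 m_linear = m_linear, n_couplings = n_couplings,
                 alpha = alpha, ps_p = ps_p, ps_h = ps_h, c1 = c1, c2 = c2,
                 ladder_distance = ladder_distance,
                 pairs_per_distance = pairs_per_distance,
                 n_network_samples = n_network_samples, t_max = t_max,
                 residual_tol = residual_tol, master_seed = master_seed),
            class = "experiment_config")
}

config_m_linear <- function(config, mode) {
  if (!is.null(config$m_linear)) return(config$m_linear)
  if (mode == "linear") 5 * config$n_species else 3 * config$n_species
}

#' Build one reaction network of a configured model and mode
#'
#' @param config an `experiment_config`.
#' @param model,mode single model/mode (default: the config's first).
#' @param sample_index replicate index entering the seed derivation.
#' @return a `reaction_network` whose `meta` records the seeds used.
#' @export
build_network <- function(config, model = config$model[1],
                          mode = config$mode[1], sample_index = 1) {
  m <- config_m_linear(config, mode)
  gseed <- seed_child(config$master_seed, 1, sample_index,
                      match(model, c("ER", "BA", "WS", "PS")))
  g <- switch(model,
    ER = generate_er(config$n_species, m, seed = gseed),
    BA = generate_ba(config$n_species, m, seed = gseed),
    WS = generate_ws(config$n_species, m, rewire_fraction = config$alpha,
                     seed = gseed),
    PS = generate_ps(config$n_species, m, level_decay = config$ps_p,
                     levels = config$ps_h, seed = gseed))
  net <- linear_network_from_graph(g)
  net$meta$network_seed <- gseed
  if (mode != "linear") {
    cseed <- seed_child(config$master_seed, 2, sample_index,
                        match(model, c("ER", "BA", "WS", "PS")))
    net <- couple_reactions(net, config$n_couplings, seed = cseed)
    net$meta$coupling_seed <- cseed
    if (mode == "linear_from_nonlinear_substrate")
      net <- linear_from_substrate(net)
  }
  net$meta$mode <- mode
  net
}

#' Simulate one clamped boundary run and analyze it
#'
#' Re-zeroes the boundary species' formation energies, initializes the
#' concentrations, integrates to steady state, and derives the analysis
#' record: boundary flow, total entropy production and its boundary-balance
#' residual, the top-10% dissipation fraction and the normalized
#' chemical-potential spread.
#'
#' @param net a `reaction_network`.
#' @param thermo a `thermo_assignment` (before re-zeroing).
#' @param b1,b2 boundary species.
#' @param c1,c2 clamped concentrations.
#' @param t_max,residual_tol,accelerate integration controls, see
#'   [integrate_to_steady_state()].
#' @param init_seed seed of the initial-concentration draw.
#' @return list with the `steady_state` (`$state`), the re-zeroed
#'   `thermo_assignment` (`$thermo`), the per-reaction entropy productions
#'   (`$sigma`) and a one-row data.frame `$record`.
#' @export
simulate_boundary_run <- function(net, thermo, b1, b2, c1 = 0.1, c2 = 1.0,
                                  t_max = 50000, residual_tol = 1e-20,
                                  accelerate = "auto", init_seed = NULL) {
  boundary <- boundary_condition(b1, b2, c1, c2)
  th <- rezero_boundary(thermo, net, b1, b2)
  state <- integrate_to_steady_state(net, th, boundary, t_max = t_max,
                                     residual_tol = residual_tol,
                                     accelerate = accelerate,
                                     seed = init_seed)
  sigma <- steady_state_sigma(state)
  tot <- total_entropy_check(state, net, boundary)
  mu <- chemical_potentials(th$mu0, pmax(state$x, .Machine$double.xmin))
  rec <- data.frame(
    b1 = b1, b2 = b2, c1 = c1, c2 = c2, init_seed = if (is.null(init_seed))
      NA_integer_ else init_seed,
    flow = state$boundary_flow, sigma_tot = tot$sigma_tot,
    eq_residual = tot$eq_residual,
    f_sigma_0.1 = if (tot$sigma_tot > 0) dissipation_fraction(sigma, 0.1)
      else NA_real_,
    sigma_mu_norm = if (mu[b1] == mu[b2]) NA_real_ # equilibrium: undefined
      else potential_spread(mu, boundary),
    converged = state$converged, t_final = state$t_final)
  list(state = state, thermo = th, sigma = sigma, record = rec)
}

#' Topology census over the configured models and modes
#'
#' Generates `n_network_samples` networks per (model, mode) combination and
#' reports ensemble mean and standard deviation of the substrate-graph
#' metrics: mean shortest path, clustering, walktrap modularity, and
#' directed 1-/2-/4-cycle counts under the as-generated random reaction
#' directions. No ODE is involved.
#'
#' @param config an `experiment_config`.
#' @return data.frame, one row per (model, mode), with `<metric>_mean` and
#'   `<metric>_sd` columns; the per-sample table is attached as attribute
#'   `"samples"`.
#' @export
run_topology_census <- function(config) {
  rows <- list()
  for (model in config$model) for (mode in config$mode) {
    for (s in seq_len(config$n_network_samples)) {
      net <- build_network(config, model, mode, s)
      gu <- substrate_graph(net)
      gd <- substrate_graph(net, directed = TRUE)
      tm <- topology_metrics(gd)
      rows[[length(rows) + 1]] <- data.frame(
        model = model, mode = mode, sample = s,
        network_seed = net$meta$network_seed,
        n_species = net$n_species, n_edges = nrow(gu$edges),
        mean_shortest_path = tm$mean_shortest_path,
        clustering = tm$clustering, modularity = tm$modularity,
        cycles_1 = count_directed_cycles(gd, 1),
        cycles_2 = count_directed_cycles(gd, 2),
        cycles_4 = count_directed_cycles(gd, 4))
    }
  }
  samples <- do.call(rbind, rows)
  metrics <- c("mean_shortest_path", "clustering", "modularity",
               "cycles_1", "cycles_2", "cycles_4")
  agg <- do.call(rbind, lapply(split(samples, samples[c("model", "mode")],
                                     drop = TRUE), function(d) {
    out <- data.frame(model = d$model[1], mode = d$mode[1],
                      n_species = d$n_species[1], n_edges = d$n_edges[1],
                      n_samples = nrow(d))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- if (nrow(d) > 1) sd(d[[m]]) else NA_real_
    }
    out
  }))
  rownames(agg) <- NULL
  attr(agg, "samples") <- samples
  agg
}

#' Mean steady-state flow as a function of boundary distance
#'
#' For every shortest-path distance present in the substrate graph, up to
#' `pairs_per_distance` boundary pairs are simulated per network sample and
#' the ensemble mean flow (direction fixed from the low- to the
#' high-concentration species) and its standard error are reported per
#' distance.
#'
#' @param config an `experiment_config`; `model` and `mode` must name a
#'   single combination.
#' @param distances optional restriction of the distances scanned.
#' @return data.frame with per-run rows attached as attribute `"runs"` and
#'   one row per distance: `d`, `mean_flow`, `se`, `n`.
#' @export
run_distance_scan <- function(config, distances = NULL) {
  model <- config$model[1]; mode <- config$mode[1]
  runs <- list()
  for (s in seq_len(config$n_network_samples)) {
    net <- build_network(config, model, mode, s)
    tseed <- seed_child(config$master_seed, 3, s)
    thermo <- assign_reaction_energetics(net, seed = tseed)
    pseed <- seed_child(config$master_seed, 5, s)
    pairs <- sample_boundary_pairs(substrate_graph(net),
                                   config$pairs_per_distance,
                                   distances = distances, seed = pseed)
    for (i in seq_len(nrow(pairs))) {
      iseed <- seed_child(config$master_seed, 4, s, i)
      run <- simulate_boundary_run(net, thermo, pairs$b1[i], pairs$b2[i],
                                   config$c1, config$c2,
                                   t_max = config$t_max,
                                   residual_tol = config$residual_tol,
                                   init_seed = iseed)
      rec <- cbind(data.frame(model = model, mode = mode, sample = s,
                              master_seed = config$master_seed,
                              network_seed = net$meta$network_seed,
                              thermo_seed = tseed, d = pairs$d[i]),
                   run$record)
      runs[[length(runs) + 1]] <- rec
    }
  }
  runs <- do.call(rbind, runs)
  # flow measured in the direction of the concentration drop: positive when
  # the network converts the high-concentration boundary species into the
  # low-concentration one
  drop_flow <- with(runs, ifelse(c1 >= c2, flow, -flow))
  agg <- aggregate(list(mean_flow = drop_flow), by = list(d = runs$d), mean)
  nn <- aggregate(list(n = drop_flow), by = list(d = runs$d), length)
  se <- aggregate(list(se = drop_flow), by = list(d = runs$d),
                  function(v) sd(v) / sqrt(length(v)))
  out <- merge(merge(agg, se, by = "d"), nn, by = "d")
  attr(out, "runs") <- runs
  out
}

#' Disequilibrium ladder over increasing boundary concentration
#'
#' Holds `c1` fixed while stepping `c2` through a ladder of values; for
#' each rung, boundary pairs at the configured shortest-path distance are
#' simulated on a nonlinear network and the flow, dissipation
#' concentration `f_sigma(0.1)`, normalized chemical-potential spread and
#' the 2-/4-cycle excess over random reaction directions are averaged.
#'
#' @param config an `experiment_config` with nonlinear `mode`; `config$c2`
#'   is the ladder (vector of rung values).
#' @param cycle_reps random-direction baseline replicates per rung.
#' @return data.frame with one row per rung; per-run rows in attribute
#'   `"runs"`.
#' @export
run_disequilibrium_ladder <- function(config, cycle_reps = 10) {
  model <- config$model[1]; mode <- config$mode[1]
  if (mode == "linear")
    stop("the disequilibrium ladder is defined for nonlinear networks")
  rungs <- sort(config$c2)
  out <- list(); runs <- list()
  for (s in seq_len(config$n_network_samples)) {
    net <- build_network(config, model, mode, s)
    tseed <- seed_child(config$master_seed, 3, s)
    thermo <- assign_reaction_energetics(net, seed = tseed)
    pseed <- seed_child(config$master_seed, 5, s)
    pairs <- sample_boundary_pairs(substrate_graph(net),
                                   config$pairs_per_distance,
                                   distances = config$ladder_distance,
                                   seed = pseed)
    for (r in seq_along(rungs)) {
      for (i in seq_len(nrow(pairs))) {
        iseed <- seed_child(config$master_seed, 4, s, r, i)
        run <- simulate_boundary_run(net, thermo, pairs$b1[i], pairs$b2[i],
                                     config$c1, rungs[r],
                                     t_max = config$t_max,
                                     residual_tol = config$residual_tol,
                                     init_seed = iseed)
        bseed <- seed_child(config$master_seed, 6, s, r, i)
        cyc <- cycle_excess(net, run$state$v_net, reps = cycle_reps,
                            lengths = c(2, 4), seed = bseed)
        rec <- cbind(data.frame(model = model, mode = mode, sample = s,
                                master_seed = config$master_seed,
                                network_seed = net$meta$network_seed,
                                thermo_seed = tseed,
                                d = config$ladder_distance),
                     run$record,
                     data.frame(excess_2 = cyc$excess[cyc$length == 2],
                                excess_4 = cyc$excess[cyc$length == 4]))
        runs[[length(runs) + 1]] <- rec
      }
    }
  }
  runs <- do.call(rbind, runs)
  drop_flow <- with(runs, ifelse(c1 >= c2, flow, -flow))
  runs$drop_flow <- drop_flow
  agg <- aggregate(runs[c("drop_flow", "f_sigma_0.1", "sigma_mu_norm",
                          "excess_2", "excess_4")],
                   by = list(c2 = runs$c2), FUN = mean, na.rm = TRUE)
  agg$n_converged <- aggregate(list(n = runs$converged),
                               by = list(c2 = runs$c2), FUN = sum)$n
  attr(agg, "runs") <- runs
  agg
}
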