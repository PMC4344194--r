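#' Boundary condition: two clamped species
#'
#' The environment drives the network out of equilibrium by holding species
#' `b1` at concentration `c1` and `b2` at `c2`.
#'
#' @param b1,b2 distinct species ids.
#' @param c1,c2 positive clamped concentrations.
#' @return an object of class `boundary_condition`.
#' @export
boundary_condition <- function(b1, b2, c1, c2) {
  if (b1 == b2) stop("boundary species must be distinct")
  if (c1 <= 0 || c2 <= 0) stop("clamped concentrations must be positive")
  structure(list(b1 = as.integer(b1), b2 = as.integer(b2),
                 c1 = as.numeric(c1), c2 = as.numeric(c2)),
            class = "boundary_condition")
}

#' One-way mass-action reaction rates
#'
#' `v_plus_j = k_fwd_j prod_i x_i^L_ij` and
#' `v_minus_j = k_bwd_j prod_i x_i^R_ij`.
#'
#' @param net a `reaction_network`.
#' @param thermo a `thermo_assignment`.
#' @param x nonnegative species concentrations.
#' @return list with numeric vectors `v_plus`, `v_minus`.
#' @export
one_way_rates <- function(net, thermo, x) {
  if (any(x < 0)) stop("concentrations must be nonnegative")
  if (length(x) != net$n_species) stop("one concentration per species required")
  r <- net$reactants; p <- net$products
  f2 <- ifelse(is.na(r[, 2]), 1, x[pmax(r[, 2], 1L)])
  b2 <- ifelse(is.na(p[, 2]), 1, x[pmax(p[, 2], 1L)])
  list(v_plus = thermo$k_fwd * x[r[, 1]] * f2,
       v_minus = thermo$k_bwd * x[p[, 1]] * b2)
}

#' Right-hand side of the reaction ODE
#'
#' `dx/dt = N (v_plus - v_minus)`, with the rows of the two clamped species
#' forced to zero when a boundary condition is given.
#'
#' @inheritParams one_way_rates
#' @param boundary a `boundary_condition`, or `NULL` for a closed network.
#' @return the concentration time-derivative vector.
#' @export
ode_rhs <- function(net, thermo, x, boundary = NULL) {
  v <- one_way_rates(net, thermo, x)
  N <- stoichiometric_matrices(net)$N
  dx <- as.vector(N %*% (v$v_plus - v$v_minus))
  if (!is.null(boundary)) dx[c(boundary$b1, boundary$b2)] <- 0
  dx
}

#' Initial concentrations for a clamped run
#'
#' i.i.d. draws from `Normal((c1+c2)/2, |c1-c2|)`, redrawn until strictly
#' positive; the two boundary entries are overwritten with their clamped
#' values.
#'
#' @param n_species number of species.
#' @param boundary a `boundary_condition`.
#' @param seed optional integer seed.
#' @return positive concentration vector of length `n_species`.
#' @export
initialize_concentrations <- function(n_species, boundary, seed = NULL) {
  n_species <- check_count(n_species, "n_species", min = 1)
  m <- (boundary$c1 + boundary$c2) / 2
  s <- abs(boundary$c1 - boundary$c2)
  with_seed(seed, {
    x <- rnorm(n_species, m, s)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), m, s)
    x[boundary$b1] <- boundary$c1
    x[boundary$b2] <- boundary$c2
    x
  })
}

#' Integrate a reaction network to its (non-equilibrium) steady state
#'
#' Integrates `dx/dt = N v(x)` with the boundary species clamped, using an
#' adaptive Dormand-Prince 5(4) scheme. After every accepted step the
#' stationarity residual - the mean over unclamped species of
#' `(dx_i/dt)^2` - is evaluated; integration stops when it falls below
#' `residual_tol` or when `t_max` is reached. Hitting `t_max` without
#' convergence is not an error: the final state is returned with
#' `converged = FALSE`, and its rates are used as steady-state rates.
#'
#' Two accelerations are available under `accelerate = "auto"` (the
#' default) and are validated against plain integration in the test suite:
#' for purely linear networks the clamped ODE is linear in `x` and the
#' steady state is obtained by a sparse linear solve (components not
#' containing a boundary species relax to their Boltzmann equilibrium,
#' which is known in closed form under detailed balance); for nonlinear
#' networks the integrator runs until a loose residual and the state is
#' then polished by a damped Newton iteration with the analytic sparse
#' Jacobian down to `residual_tol`. `accelerate = "none"` forces pure
#' time-stepping.
#'
#' @inheritParams ode_rhs
#' @param x0 initial concentrations; defaults to
#'   [initialize_concentrations()] for clamped runs (required for closed
#'   ones).
#' @param t_max maximal simulated time.
#' @param residual_tol stationarity threshold on the mean squared
#'   concentration change per species and unit time.
#' @param method `"dp45"` (explicit Dormand-Prince, default) or `"lsoda"`
#'   (stiff-capable multistep via deSolve, provided as a cross-check).
#' @param accelerate `"auto"` or `"none"` (see Details).
#' @param rtol,atol local error tolerances of the integrator.
#' @param max_steps step-count guard.
#' @param seed optional seed (used only when `x0` is drawn here).
#' @return an object of class `steady_state`: concentrations `x`, one-way
#'   rates `v_plus`/`v_minus`, net rates `v_net`, the signed
#'   `boundary_flow` (positive when net conversion runs b1 to b2),
#'   `converged`, `t_final`, `residual`, and diagnostics.
#' @export
integrate_to_steady_state <- function(net, thermo, boundary = NULL, x0 = NULL,
                                      t_max = 50000, residual_tol = 1e-20,
                                      method = c("dp45", "lsoda"),
                                      accelerate = c("auto", "none"),
                                      rtol = 1e-7, atol = 1e-12,
                                      max_steps = 2e7, seed = NULL) {
  method <- match.arg(method)
  accelerate <- match.arg(accelerate)
  stopifnot(inherits(net, "reaction_network"),
            inherits(thermo, "thermo_assignment"))
  if (is.null(x0)) {
    if (is.null(boundary))
      stop("closed simulations need explicit initial concentrations `x0`")
    x0 <- initialize_concentrations(net$n_species, boundary, seed = seed)
  }
  if (!is.null(boundary)) {
    x0[boundary$b1] <- boundary$c1
    x0[boundary$b2] <- boundary$c2
  }

  linear_only <- !any(is_nonlinear(net))
  if (accelerate == "auto" && linear_only && !is.null(boundary)) {
    res <- steady_state_linear(net, thermo, boundary, x0)
    return(finish_steady_state(net, thermo, boundary, res$x,
                               t_final = NA_real_, converged = TRUE,
                               solver = "linear_solve"))
  }

  clamped <- if (is.null(boundary)) integer(0) else c(boundary$b1, boundary$b2)
  if (method == "lsoda") {
    out <- integrate_lsoda(net, thermo, x0, clamped, t_max, residual_tol,
                           rtol, atol)
    return(finish_steady_state(net, thermo, boundary, out$x, out$t_final,
                               out$converged, solver = "lsoda"))
  }

  r <- net$reactants; p <- net$products
  na2 <- function(v) { v[is.na(v)] <- 0L; v - 1L }
  dp45 <- function(x, t_end, tol)
    .dp45_mass_action(r[, 1] - 1L, na2(r[, 2]), p[, 1] - 1L, na2(p[, 2]),
                      thermo$k_fwd, thermo$k_bwd, x, clamped - 1L,
                      t_end, tol, rtol, atol, 1e-6, max_steps)

  if (accelerate == "none") {
    out <- dp45(x0, t_max, residual_tol)
    if (out$failed)
      stop(sprintf("integration failed (non-finite state or vanishing step) at t = %g",
                   out$t_final))
    return(finish_steady_state(net, thermo, boundary, out$x, out$t_final,
                               out$converged, solver = "dp45"))
  }

  # chunked integration with periodic Newton polish: relax through
  # transients, then let Newton pin the stationary point exactly
  x <- x0
  t_final <- 0
  converged <- FALSE
  t_next <- min(10, t_max)
  loose <- max(residual_tol, 1e-12)
  repeat {
    out <- dp45(x, t_next - t_final, loose)
    if (out$failed)
      stop(sprintf("integration failed (non-finite state or vanishing step) at t = %g",
                   t_final + out$t_final))
    x <- out$x
    t_final <- t_final + out$t_final
    res_now <- residual_measure(net, thermo, x, clamped)
    if (res_now < 1e-2 || t_final >= t_max) { # transients mostly relaxed
      pol <- newton_polish(net, thermo, x, clamped, residual_tol)
      if (pol$converged) {
        x <- pol$x
        converged <- TRUE
        break
      }
    }
    if (out$converged || t_final >= t_max) {
      # the integrator's own stopping rule fired (or time ran out) and
      # Newton could not improve further
      converged <- res_now < residual_tol
      break
    }
    t_next <- min(t_next * 4, t_max)
  }
  finish_steady_state(net, thermo, boundary, x, t_final, converged,
                      solver = "dp45")
}

residual_measure <- function(net, thermo, x, clamped) {
  dx <- ode_rhs(net, thermo, x)
  if (length(clamped)) dx <- dx[-clamped]
  if (!length(dx)) return(0)
  mean(dx^2)
}

finish_steady_state <- function(net, thermo, boundary, x, t_final, converged,
                                solver) {
  clamped <- if (is.null(boundary)) integer(0) else c(boundary$b1, boundary$b2)
  v <- one_way_rates(net, thermo, x)
  v_net <- v$v_plus - v$v_minus
  N <- stoichiometric_matrices(net)$N
  prodrate <- as.vector(N %*% v_net)
  flow <- if (is.null(boundary)) NA_real_ else prodrate[boundary$b2]
  # log one-way rates: exact even where k = exp(-Ea) underflows to zero
  mats <- stoichiometric_matrices(net)
  lx <- log(pmax(x, .Machine$double.xmin))
  log_vp <- -thermo$ea_fwd + as.vector(Matrix::crossprod(mats$L, lx))
  log_vm <- -thermo$ea_bwd + as.vector(Matrix::crossprod(mats$R, lx))
  structure(list(x = x, v_plus = v$v_plus, v_minus = v$v_minus,
                 v_net = v_net, log_v_plus = log_vp, log_v_minus = log_vm,
                 boundary_flow = flow,
                 converged = converged, t_final = t_final,
                 residual = residual_measure(net, thermo, x, clamped),
                 boundary = boundary, solver = solver),
            class = "steady_state")
}

#' @exportS3Method base::print
print.steady_state <- function(x, ...) {
  cat(sprintf(
    "steady_state (%s): %s, residual %.3g, boundary flow %s\n",
    x$solver,
    if (x$converged) "converged" else sprintf("NOT converged (t = %g)",
                                              x$t_final),
    x$residual,
    if (is.na(x$boundary_flow)) "-" else sprintf("%.6g", x$boundary_flow)))
  invisible(x)
}

# Direct steady state of a purely linear clamped network. The ODE is
# dx/dt = A x; components attached to a boundary species are solved by a
# sparse grounded-Laplacian solve, closed components relax to the
# Boltzmann state x_i ~ exp(-mu0_i) scaled to conserve their initial total.
steady_state_linear <- function(net, thermo, boundary, x0) {
  n <- net$n_species
  r <- net$reactants[, 1]; p <- net$products[, 1]
  A <- Matrix::sparseMatrix(
    i = c(p, r, r, p), j = c(r, r, p, p),
    x = c(thermo$k_fwd, -thermo$k_fwd, thermo$k_bwd, -thermo$k_bwd),
    dims = c(n, n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(r, p))
  comp <- igraph::components(g)$membership
  clamped <- c(boundary$b1, boundary$b2)
  x <- x0
  for (cc in unique(comp)) {
    mem <- which(comp == cc)
    cl <- intersect(mem, clamped)
    if (length(cl)) {
      U <- setdiff(mem, cl)
      if (length(U)) {
        b <- -A[U, cl, drop = FALSE] %*% x0[cl]
        x[U] <- as.vector(Matrix::solve(A[U, U, drop = FALSE], b))
      }
    } else {
      w <- exp(-thermo$mu0[mem])
      x[mem] <- w * sum(x0[mem]) / sum(w)
    }
  }
  x[x < 0] <- 0 # guard against tiny negative round-off
  list(x = x)
}

# Damped Newton iteration on the unclamped stationarity conditions with the
# analytic sparse Jacobian of the mass-action rhs. Two singularity sources
# are handled explicitly: substrate components without a clamped species
# conserve their total concentration (one stationarity row per component is
# replaced by the conservation constraint at the entry total), and species
# whose incident reactions are all kinetically frozen (rate constants
# underflow for barriers beyond ~700) leave an all-but-zero Jacobian row
# and are pinned at their current concentration.
newton_polish <- function(net, thermo, x, clamped, tol, max_iter = 30) {
  n <- net$n_species
  mats <- stoichiometric_matrices(net)
  N <- mats$N; L <- mats$L; R <- mats$R
  U <- setdiff(seq_len(n), clamped)
  if (!length(U)) return(list(x = x, converged = TRUE))
  e <- substrate_edges(net)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(e[, "from"], e[, "to"]))
  comp <- igraph::components(g)$membership
  free_comps <- setdiff(unique(comp), comp[clamped])
  cons <- lapply(free_comps, function(cc) {
    mem <- which(comp == cc)
    list(row = mem[1], members = mem, total = sum(x[mem]))
  })
  fval <- function(x) {
    v <- one_way_rates(net, thermo, x)
    F <- as.vector(N %*% (v$v_plus - v$v_minus))
    for (cn in cons) F[cn$row] <- sum(x[cn$members]) - cn$total
    F
  }
  if (any(x[U] <= 0)) return(list(x = x, converged = FALSE))
  F <- fval(x)
  ss <- mean(F[U]^2)
  stall <- 0L
  for (it in seq_len(max_iter)) {
    if (ss < tol) return(list(x = x, converged = TRUE))
    v <- one_way_rates(net, thermo, x)
    xi <- ifelse(x > 0, 1 / x, 0)
    D <- (Matrix::t(L) * v$v_plus - Matrix::t(R) * v$v_minus) %*%
      Matrix::Diagonal(n, xi)
    J <- N %*% D
    for (cn in cons) { # conservation rows
      J[cn$row, ] <- 0
      J[cn$row, cn$members] <- 1
    }
    rs <- Matrix::rowSums(abs(J))
    frozen <- which(rs < 1e-18 * max(rs, 1))
    Fs <- F
    if (length(frozen)) { # pin kinetically frozen species
      J[frozen, ] <- 0
      J <- J + Matrix::sparseMatrix(i = frozen, j = frozen,
                                    x = rep(1, length(frozen)),
                                    dims = c(n, n))
      Fs[frozen] <- 0
    }
    delta <- tryCatch(as.vector(Matrix::solve(J[U, U, drop = FALSE],
                                              -Fs[U])),
                      error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta)))
      return(list(x = x, converged = FALSE))
    step <- 1
    repeat {
      xn <- x
      xn[U] <- x[U] + step * delta
      if (all(xn[U] > 0)) {
        Fn <- fval(xn)
        ssn <- mean(Fn[U]^2)
        if (is.finite(ssn) && (ssn < ss || ssn < tol)) break
      }
      step <- step / 2
      if (step < 1e-8) return(list(x = x, converged = FALSE))
    }
    stall <- if (ssn > 0.25 * ss) stall + 1L else 0L
    x <- xn; F <- Fn; ss <- ssn
    if (stall >= 4L) return(list(x = x, converged = FALSE)) # not contracting
  }
  list(x = x, converged = ss < tol)
}

integrate_lsoda <- function(net, thermo, x0, clamped, t_max, residual_tol,
                            rtol, atol) {
  mats <- stoichiometric_matrices(net)
  N <- mats$N
  func <- function(t, y, parms) {
    v <- one_way_rates(net, thermo, pmax(y, 0))
    dx <- as.vector(N %*% (v$v_plus - v$v_minus))
    if (length(clamped)) dx[clamped] <- 0
    list(dx)
  }
  # integrate over doubling checkpoints; test stationarity at each
  t <- 0; x <- x0; chunk <- 1
  converged <- FALSE
  while (t < t_max && !converged) {
    chunk <- min(chunk * 4, t_max - t)
    sol <- deSolve::lsoda(x, c(0, chunk), func, NULL, rtol = rtol,
                          atol = atol)
    x <- pmax(as.vector(sol[nrow(sol), -1]), 0)
    t <- t + chunk
    converged <- residual_measure(net, thermo, x, clamped) < residual_tol
  }
  list(x = x, t_final = t, converged = converged)
}

#' Net steady-state conversion flow between the boundary species
#'
#' The net production rate of `b2` by all reactions (row `b2` of
#' `N v_net`); positive when the net conversion runs from `b1` to `b2`. At a
#' converged steady state this equals the consumption rate of `b1`.
#'
#' @param state a `steady_state`.
#' @param net the `reaction_network` that produced it.
#' @param boundary the `boundary_condition` of the run.
#' @return signed scalar flow.
#' @export
boundary_flow <- function(state, net, boundary) {
  N <- stoichiometric_matrices(net)$N
  as.vector(N %*% state$v_net)[boundary$b2]
}

#' Sample boundary-species pairs stratified by shortest-path distance
#'
#' For every shortest-path distance `d` present in (the largest connected
#' component of) the substrate graph, up to `pairs_per_distance` unordered
#' node pairs at exactly that distance are sampled uniformly (all of them
#' when fewer exist).
#'
#' @param g an undirected `rrn_graph` (substrate graph) or igraph object.
#' @param pairs_per_distance maximal number of pairs per distance value.
#' @param distances optional integer vector restricting the distances
#'   sampled.
#' @param seed optional integer seed.
#' @return data.frame with columns `b1`, `b2`, `d`.
#' @export
sample_boundary_pairs <- function(g, pairs_per_distance = 50,
                                  distances = NULL, seed = NULL) {
  ig <- if (inherits(g, "rrn_graph")) as_igraph(g, directed = FALSE) else g
  ig <- igraph::as_undirected(ig, mode = "collapse")
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  D <- igraph::distances(ig, v = keep, to = keep)
  D[lower.tri(D, diag = TRUE)] <- NA
  with_seed(seed, {
    ds <- if (is.null(distances)) {
      v <- sort(unique(as.vector(D)))
      v[is.finite(v) & v > 0]
    } else distances
    out <- lapply(ds, function(d) {
      idx <- which(D == d)
      if (!length(idx)) return(NULL)
      if (length(idx) > pairs_per_distance)
        idx <- idx[sample.int(length(idx), pairs_per_distance)]
      rc <- arrayInd(idx, dim(D))
      data.frame(b1 = keep[rc[, 1]], b2 = keep[rc[, 2]], d = d)
    })
    do.call(rbind, out)
  })
}
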