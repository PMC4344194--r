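#' Gibbs formation energies of the species
#'
#' Formation energies are i.i.d. standard normal, in units with
#' `k_B * T = 1` (all energies in the package are dimensionless).
#'
#' @param n_species number of species.
#' @param seed optional integer seed.
#' @return numeric vector of length `n_species`.
#' @export
sample_formation_energies <- function(n_species, seed = NULL) {
  n_species <- check_count(n_species, "n_species", min = 1)
  with_seed(seed, rnorm(n_species))
}

#' Planck-like activation-energy density
#'
#' `P(x) = (6 / pi^2) / (x^3 (exp(1/x) - 1))` for `x > 0`. The density
#' vanishes super-exponentially as `x -> 0` (an effective nonzero lower
#' bound) and decays like `(6/pi^2) x^-2` for large `x` (a heavy right
#' tail with infinite mean).
#'
#' @param x positive activation energies.
#' @return density values.
#' @export
planck_like_pdf <- function(x) {
  if (any(x <= 0)) stop("planck_like_pdf is defined for x > 0 only")
  # exp(-1/x) form is overflow-safe for small x
  6 / pi^2 * exp(-1 / x) / (x^3 * (1 - exp(-1 / x)))
}

#' Sample activation energies from the Planck-like distribution
#'
#' Uses the exact mixture representation of the density: if `X` has the
#' Planck-like law then `U = 1/X` has density `(6/pi^2) u / (e^u - 1)
#' = (6/pi^2) sum_n u e^{-n u}`, i.e. `U | n ~ Gamma(shape 2, rate n)` with
#' `P(n) = (6/pi^2) n^-2`. Draws are therefore exact (no tabulation).
#'
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return positive numeric vector of length `n`.
#' @export
sample_activation_energy <- function(n = 1, seed = NULL) {
  n <- check_count(n, "n", min = 1)
  with_seed(seed, {
    k <- sample_zeta2(n)
    1 / rgamma(n, shape = 2, rate = k)
  })
}

# draw integers with P(k) = (6/pi^2) / k^2 by inversion on a cached table;
# the tiny tail beyond the table uses the continuous approximation
# P(K >= k) ~ (6/pi^2)/k
sample_zeta2 <- local({
  kmax <- 100000L
  cum <- NULL
  function(n) {
    if (is.null(cum)) cum <<- cumsum(6 / pi^2 / (1:kmax)^2)
    u <- runif(n)
    k <- findInterval(u, cum) + 1L
    over <- k > kmax
    if (any(over)) k[over] <- ceiling(6 / pi^2 / (1 - u[over]))
    k
  }
})

#' Detailed-balance consistent reaction energetics
#'
#' Given per-species formation energies `mu0` and one sampled activation
#' energy per reaction, assigns per-direction activation energies and
#' Arrhenius rate constants `k = exp(-E_a)` (prefactor 1). With the default
#' `direction_rule = "detailed_balance"` the sampled barrier sits on the
#' exergonic direction (the one whose products have the *lower* total
#' `mu0`) and the opposite direction receives `E_a + |dmu0|` with
#' `dmu0_j = sum_i N_ij mu0_i`, so that `k_fwd / k_bwd = exp(-dmu0)` and
#' one-way rates balance at Boltzmann concentrations.
#' `direction_rule = "literal_text"` instead puts the sampled barrier on the
#' endergonic direction; it is provided for comparison and violates
#' equilibrium balance.
#'
#' @param net a `reaction_network`.
#' @param mu0 per-species formation energies.
#' @param sampled_ea per-reaction sampled activation energies; drawn from
#'   [sample_activation_energy()] when omitted.
#' @param direction_rule `"detailed_balance"` (default) or `"literal_text"`.
#' @param seed optional seed (used only when `sampled_ea` is omitted).
#' @return an object of class `thermo_assignment` with fields `mu0`,
#'   `ea_sampled`, `ea_fwd`, `ea_bwd`, `k_fwd`, `k_bwd`, `dmu0`,
#'   `direction_rule`.
#' @export
assign_reaction_energetics <- function(net, mu0 = NULL, sampled_ea = NULL,
                                       direction_rule = c("detailed_balance",
                                                          "literal_text"),
                                       seed = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  direction_rule <- match.arg(direction_rule)
  with_seed(seed, {
    if (is.null(mu0)) mu0 <- sample_formation_energies(net$n_species)
    if (is.null(sampled_ea)) sampled_ea <- sample_activation_energy(n_reactions(net))
  })
  if (length(mu0) != net$n_species)
    stop("`mu0` must have one entry per species")
  if (length(sampled_ea) != n_reactions(net))
    stop("`sampled_ea` must have one entry per reaction")
  if (any(sampled_ea < 0)) stop("activation energies must be nonnegative")
  N <- stoichiometric_matrices(net)$N
  dmu0 <- as.vector(Matrix::crossprod(N, mu0))
  if (direction_rule == "detailed_balance") {
    ea_fwd <- sampled_ea + pmax(dmu0, 0)
    ea_bwd <- sampled_ea + pmax(-dmu0, 0)
  } else {
    ea_fwd <- sampled_ea + pmax(-dmu0, 0)
    ea_bwd <- sampled_ea + pmax(dmu0, 0)
  }
  structure(list(mu0 = mu0, ea_sampled = sampled_ea, ea_fwd = ea_fwd,
                 ea_bwd = ea_bwd, k_fwd = exp(-ea_fwd), k_bwd = exp(-ea_bwd),
                 dmu0 = dmu0, direction_rule = direction_rule),
            class = "thermo_assignment")
}

#' @exportS3Method base::print
print.thermo_assignment <- function(x, ...) {
  cat(sprintf(
    "thermo_assignment: %d species, %d reactions (rule: %s)\n  mu0 in [%.3g, %.3g], sampled Ea median %.3g\n",
    length(x$mu0), length(x$ea_sampled), x$direction_rule,
    min(x$mu0), max(x$mu0), stats::median(x$ea_sampled)))
  invisible(x)
}

#' Re-zero the boundary species' formation energies
#'
#' Before a clamped simulation the two boundary species get `mu0 = 0` and
#' all reaction energetics are recomputed: for every reaction the reaction
#' Gibbs energy is re-derived, the (possibly new) exergonic direction
#' re-identified, the originally sampled activation energy reattached to it
#' and both rate constants recomputed. Applying the operation twice equals
#' applying it once.
#'
#' @param thermo a `thermo_assignment`.
#' @param net the owning `reaction_network`.
#' @param b1,b2 distinct boundary species ids.
#' @return a new `thermo_assignment`.
#' @export
rezero_boundary <- function(thermo, net, b1, b2) {
  stopifnot(inherits(thermo, "thermo_assignment"))
  if (b1 == b2) stop("boundary species must be distinct")
  mu0 <- thermo$mu0
  mu0[c(b1, b2)] <- 0
  assign_reaction_energetics(net, mu0, thermo$ea_sampled,
                             direction_rule = thermo$direction_rule)
}
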