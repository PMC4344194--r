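#' @useDynLib rrnsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rgamma runif quantile sd lm coef aggregate setNames
#' @importFrom utils head tail
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based split of a master seed, so that any single
#' network / thermodynamic assignment / initialization in an experiment can be
#' re-derived in isolation. All returned seeds lie in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... one or more integer counters (e.g. network index, stage index).
#' @return a single integer seed.
#' @export
seed_child <- function(master, ...) {
  idx <- c(...)
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(master) %% m
  for (i in seq_along(idx)) {
    # 69069 * s stays below 2^53 so double arithmetic is exact
    s <- (69069 * s + as.double(idx[i]) + 1013904223) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be a single integer >= %s", name, min),
         call. = FALSE)
  as.integer(x)
}

# population standard deviation (divides by n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
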