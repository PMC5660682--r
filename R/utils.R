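#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under an explicit RNG seed without disturbing the caller's
## random state. All stochastic operations in this package take a required
## `seed` argument and route through this helper; there is no hidden global
## state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Draw one Dirichlet vector per row of the alpha matrix.
rdirichlet_mat <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
              nrow = nrow(alpha))
  g / rowSums(g)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name),
         call. = FALSE)
  }
  x
}

## Sample from a named distribution spec, e.g. c(`1` = 0.5, `2` = 0.3,
## `4` = 0.2): names are the integer outcomes, values the probabilities.
sample_dist_spec <- function(spec, n) {
  if (is.null(names(spec)) || any(!is.finite(spec)) || any(spec < 0) ||
      sum(spec) <= 0) {
    stop("distribution spec must be a named non-negative vector", call. = FALSE)
  }
  vals <- as.integer(names(spec))
  if (any(is.na(vals))) stop("distribution spec names must be integers",
                             call. = FALSE)
  sample(vals, n, replace = TRUE, prob = spec / sum(spec))
}
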