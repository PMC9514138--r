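#' @useDynLib scnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd median rnorm runif rbinom rpois quantile aov
#'   chisq.test p.adjust uniroot var setNames
#' @importFrom utils read.table write.csv head
NULL

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions do not perturb user simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Spawn n reproducible child seeds from a master seed, so any single
# (component, metric, contrast) cell can be re-run in isolation.
spawn_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
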