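#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd quantile kmeans median
#' @importFrom utils head tail combn
#' @importFrom graphics hist
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never perturb user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation: one user-facing seed fans out to
# independent streams for network init, batching, projections, etc.
# Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483629)
}

stop_cc <- function(fmt, ..., class = "cryoconsensus_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_cc("`%s` must be a single finite number in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_cc("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

as_numeric_matrix <- function(x, name = "X") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop_cc("`%s` contains a non-finite value at row %d, column %d",
            name, bad[1L], bad[2L])
  }
  x
}
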