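#' Sliced-Wasserstein configuration
#'
#' @param kappa Number of random unit projection vectors (default 100).
#' @param seed Integer seed for drawing the projections.
#' @return A `sw_config`.
#' @export
sw_config <- function(kappa = 100L, seed = 1L) {
  structure(list(kappa = assert_count(kappa, "kappa", min = 1L),
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "sw_config")
}

#' Rank particles by cross-space agreement
#'
#' Orders particle ids by ascending consensus error (best-agreeing first);
#' ties are broken by ascending particle id for determinism.
#'
#' @param mapping A `consensus_mapping`.
#' @return Character vector of particle ids.
#' @export
agreement_ranking <- function(mapping) {
  stopifnot(inherits(mapping, "consensus_mapping"))
  ord <- order(mapping$consensus_error, mapping$ids)
  mapping$ids[ord]
}

# kappa x d matrix of uniform-random unit vectors (rows), seeded.
random_projections <- function(kappa, d, seed) {
  with_seed(derive_seed(seed, 4L), {
    U <- matrix(rnorm(kappa * d), kappa, d)
    U / sqrt(rowSums(U^2))
  })
}

#' Sliced Wasserstein distance between two point clouds
#'
#' Approximates the k-dimensional Wasserstein distance as the mean 1-D
#' Wasserstein distance of the two clouds projected onto `kappa` seeded
#' uniform-random unit vectors. With a shared projection set (same `cfg`)
#' the estimate is symmetric and satisfies the triangle inequality.
#'
#' @param A,B Numeric matrices with the same column count.
#' @param cfg A [sw_config()].
#' @param projections Optional pre-drawn `kappa x d` projection matrix
#'   (rows = unit vectors); overrides `cfg`'s seed. Used to share
#'   projections across the permutation null.
#' @return Non-negative scalar.
#' @export
sliced_wasserstein <- function(A, B, cfg = sw_config(), projections = NULL) {
  A <- as_numeric_matrix(A, "A"); B <- as_numeric_matrix(B, "B")
  if (nrow(A) == 0L || nrow(B) == 0L) stop_cc("empty point cloud")
  if (ncol(A) != ncol(B)) {
    stop_cc("dimension mismatch: A has %d columns, B has %d", ncol(A), ncol(B))
  }
  if (is.null(projections)) {
    projections <- random_projections(cfg$kappa, ncol(A), cfg$seed)
  }
  PA <- tcrossprod(A, projections) # n x kappa
  PB <- tcrossprod(B, projections)
  mean(vapply(seq_len(ncol(PA)), function(k) {
    wasserstein_1d(PA[, k], PB[, k])
  }, 1))
}

#' Permutation test for distributional equality of two projections
#'
#' Computes the observed sliced-Wasserstein distance `d_obs` between the two
#' clouds, then builds a null by pooling the `2K` points and randomly
#' re-splitting them into two groups of `K` (`n_perm` label randomizations),
#' recomputing the sliced distance with the same projection vectors each
#' time.
#'
#' The default p-value is the standard one-sided permutation estimator with
#' add-one smoothing, `p = (1 + #\{d_perm >= d_obs\}) / (1 + n_perm)`:
#' small when `d_obs` exceeds the null, i.e. when the two distributions are
#' distinguishable. `direction = "paper-text"` instead returns the
#' proportion of randomized distances smaller than or equal to `d_obs`
#' (which is large, not small, for distinguishable distributions).
#'
#' @param A,B Numeric matrices of equal size (`K x d` each).
#' @param cfg A [sw_config()].
#' @param n_perm Number of label randomizations (default 100).
#' @param direction `"greater"` (default) or `"paper-text"`, see above.
#' @return A `permutation_test`: list with `d_obs`, `permuted` (length
#'   `n_perm`), `p_value`, `n_perm`, `direction`.
#' @export
permutation_pvalue <- function(A, B, cfg = sw_config(), n_perm = 100L,
                               direction = c("greater", "paper-text")) {
  direction <- match.arg(direction)
  A <- as_numeric_matrix(A, "A"); B <- as_numeric_matrix(B, "B")
  if (nrow(A) != nrow(B)) {
    stop_cc("A and B must hold the same number of points (the same top-K particles)")
  }
  n_perm <- assert_count(n_perm, "n_perm", min = 1L)
  K <- nrow(A)
  U <- random_projections(cfg$kappa, ncol(A), cfg$seed)

  pooled <- rbind(A, B)
  proj <- tcrossprod(pooled, U) # 2K x kappa, shared across d_obs and the null

  # Equal-size 1-D Wasserstein via the pooled empirical CDFs: sort every
  # projection once, then each label assignment only needs a signed
  # cumulative count: W1 = sum_j |#A_j - #B_j| * (v_(j+1) - v_(j)) / K.
  n2 <- 2L * K
  ord <- apply(proj, 2L, order)
  sorted <- matrix(proj[ord + rep((seq_len(ncol(proj)) - 1L) * n2, each = n2)],
                   n2, ncol(proj))
  gaps <- sorted[-1L, , drop = FALSE] - sorted[-n2, , drop = FALSE]
  sw_labels <- function(sign_vec) {
    cum <- apply(matrix(sign_vec[ord], n2, ncol(ord)), 2L, cumsum)
    mean(colSums(abs(cum[-n2, , drop = FALSE]) * gaps)) / K
  }
  base_sign <- rep(c(1, -1), each = K)
  d_obs <- sw_labels(base_sign)
  permuted <- with_seed(derive_seed(cfg$seed, 5L), {
    vapply(seq_len(n_perm), function(r) {
      sw_labels(base_sign[sample.int(n2)])
    }, 1)
  })

  p <- switch(direction,
    greater = (1 + sum(permuted >= d_obs)) / (1 + n_perm),
    `paper-text` = mean(permuted <= d_obs))
  structure(list(d_obs = d_obs, permuted = permuted, p_value = p,
                 n_perm = n_perm, direction = direction),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test: d_obs = %.6g, p = %.4g (%d randomizations)>\n",
              x$d_obs, x$p_value, x$n_perm))
  invisible(x)
}

#' Select the consensus particle set by a p-value sweep over K
#'
#' For each `K` in the grid, takes the `K` best-agreeing particles (by
#' consensus error) and tests whether their consensus projections from the
#' different spaces are still distributionally indistinguishable
#' ([permutation_pvalue()]). As `K` grows past the well-agreeing core the
#' projections become distinguishable and the p-value falls below `alpha`;
#' the largest `K` whose p-value is still `>= alpha` defines the consensus
#' set.
#'
#' With more than two spaces, each `K` is tested for every unordered space
#' pair and the per-K p-value is the Bonferroni-corrected minimum over
#' pairs.
#'
#' @param mapping A `consensus_mapping`.
#' @param cfg A [sw_config()].
#' @param alpha Significance threshold, strictly inside (0, 1); default
#'   0.05.
#' @param K_grid Ascending integers in `[2, num_particles]`; default 20
#'   geometrically spaced values from `min(100, n/2)` to `num_particles`.
#' @param n_perm Label randomizations per test (default 100).
#' @return A `consensus_selection`: list with `sweep` (data.frame `K`,
#'   `d_obs`, `p_value`), `K_star`, `selected_ids`, `alpha`.
#' @export
threshold_sweep <- function(mapping, cfg = sw_config(), alpha = 0.05,
                            K_grid = NULL, n_perm = 100L) {
  stopifnot(inherits(mapping, "consensus_mapping"))
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_cc("`alpha` must be strictly inside (0, 1)")
  n <- length(mapping$ids)
  N <- length(mapping$Z)
  if (is.null(K_grid)) K_grid <- default_k_grid(n)
  K_grid <- sort(unique(as.integer(K_grid)))
  if (length(K_grid) == 0L) stop_cc("`K_grid` is empty")
  if (K_grid[1L] < 2L || tail(K_grid, 1L) > n) {
    stop_cc("`K_grid` values must lie in [2, %d]", n)
  }

  ranked <- agreement_ranking(mapping)
  row_of <- match(ranked, mapping$ids)
  pairs <- utils::combn(N, 2L)
  n_pairs <- ncol(pairs)

  sweep <- data.frame(K = K_grid, d_obs = NA_real_, p_value = NA_real_)
  for (g in seq_along(K_grid)) {
    K <- K_grid[g]
    rows <- row_of[seq_len(K)]
    d_max <- -Inf
    p_min <- Inf
    for (q in seq_len(n_pairs)) {
      a <- pairs[1L, q]; b <- pairs[2L, q]
      pt <- permutation_pvalue(mapping$Z[[a]][rows, , drop = FALSE],
                               mapping$Z[[b]][rows, , drop = FALSE],
                               cfg = cfg, n_perm = n_perm)
      d_max <- max(d_max, pt$d_obs)
      p_min <- min(p_min, pt$p_value)
    }
    sweep$d_obs[g] <- d_max
    sweep$p_value[g] <- min(1, n_pairs * p_min)
  }

  keep <- which(sweep$p_value >= alpha)
  K_star <- if (length(keep)) K_grid[max(keep)] else 0L
  structure(
    list(sweep = sweep, K_star = K_star,
         selected_ids = ranked[seq_len(K_star)], alpha = alpha),
    class = "consensus_selection"
  )
}

default_k_grid <- function(n) {
  lo <- max(2L, min(100L, n %/% 2L))
  unique(round(exp(seq(log(lo), log(n), length.out = 20L))))
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat(sprintf("<consensus_selection: K* = %d of %d tested K values (alpha = %g); %d particles kept>\n",
              x$K_star, nrow(x$sweep), x$alpha, length(x$selected_ids)))
  invisible(x)
}

#' Write a consensus selection to disk
#'
#' Writes the selected particle ids (one per line, usable as a subset filter
#' for the landscape CSVs) and the sweep table (`K`, `d_obs`, `p_value`).
#'
#' @param selection A `consensus_selection`.
#' @param ids_path Output text file for selected ids.
#' @param sweep_path Output CSV for the sweep table.
#' @return `ids_path`, invisibly.
#' @export
write_selection <- function(selection, ids_path, sweep_path) {
  stopifnot(inherits(selection, "consensus_selection"))
  writeLines(selection$selected_ids, ids_path)
  data.table::fwrite(selection$sweep, sweep_path)
  invisible(ids_path)
}
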