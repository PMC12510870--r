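#' Loss-term weights
#'
#' The total training objective is the unweighted sum of the reconstruction
#' term and the three regularizers; these weights are an extension knob and
#' default to the plain sum.
#'
#' @param w_rep,w1,w2,w3 Non-negative finite weights for the reconstruction
#'   term, the latent pairing term, the distance-preservation stress, and the
#'   distance-distribution Wasserstein term.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(w_rep = 1, w1 = 1, w2 = 1, w3 = 1) {
  for (w in list(w_rep = w_rep, w1 = w1, w2 = w2, w3 = w3)) {
    assert_scalar_number(w, "loss weight", lower = 0)
  }
  structure(list(w_rep = w_rep, w1 = w1, w2 = w2, w3 = w3),
            class = "loss_weights")
}

#' Aligned batch views across spaces
#'
#' Bundles, for one mini-batch of particles, the input coordinates `X[[n]]`
#' and their consensus encodings `Z[[n]]` for every space, with identical row
#' (particle) order everywhere.
#'
#' @param X List of per-space input batches (matrices with equal row counts).
#' @param Z List of per-space encoded batches (equal row counts, equal
#'   latent dimension).
#' @return A `batch_views` list.
#' @export
batch_views <- function(X, Z) {
  stopifnot(is.list(X), is.list(Z), length(X) == length(Z))
  nr <- unique(c(vapply(X, nrow, 1L), vapply(Z, nrow, 1L)))
  if (length(nr) != 1L) {
    stop_cc("all batches in a batch_views must have the same row count (got %s)",
            paste(nr, collapse = ", "))
  }
  structure(list(X = X, Z = Z, N = length(X), batch = nr), class = "batch_views")
}

views_from_net <- function(net, X_list) {
  Z <- lapply(seq_along(X_list), function(n) encode(net, n, X_list[[n]]))
  batch_views(X_list, Z)
}

#' All-versus-all Euclidean distance matrix
#'
#' @param P Numeric matrix (`n x d`), `n >= 2`.
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
self_distance_matrix <- function(P) {
  P <- as_numeric_matrix(P, "P")
  if (nrow(P) < 2L) stop_cc("need at least 2 points for a distance matrix")
  sq <- rowSums(P * P)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0 # clip numerical negatives
  D <- sqrt(D2)
  diag(D) <- 0
  # exact symmetry regardless of float noise in tcrossprod
  (D + t(D)) / 2
}

# Off-diagonal entries of the self-distance matrix as a 1-D sample
# (ordered pairs; each unordered pair appears twice, which leaves empirical
# distributions unchanged).
distance_sample <- function(P) {
  D <- self_distance_matrix(P)
  D[row(D) != col(D)]
}

#' Latent pairing loss (L1)
#'
#' Sum over all ordered space pairs `(n, m)` and particles `i` of
#' `||Z_n[i,] - Z_m[i,]||^2`. Zero exactly when every encoder maps each
#' particle to the same consensus point.
#'
#' @param views A [batch_views()].
#' @return Non-negative scalar.
#' @export
latent_pair_mse <- function(views) {
  stopifnot(inherits(views, "batch_views"))
  Z <- views$Z
  total <- 0
  for (n in seq_len(views$N)) {
    for (m in seq_len(views$N)) {
      if (n == m) next
      total <- total + sum((Z[[n]] - Z[[m]])^2)
    }
  }
  total
}

#' Distance-preservation stress of one embedding (one L2 term)
#'
#' The Sammon/Shannon-style stress between the pairwise distances of an
#' input batch `X` and of its encoding `Z`:
#' `[sum_{ij} (d_ij(X) - d_ij(Z))^2 / d_ij(X)] / [sum_{ij} d_ij(X)]`
#' over ordered off-diagonal pairs, skipping pairs with `d_ij(X) = 0`
#' (duplicate input points contribute nothing). Zero when `Z` preserves all
#' pairwise distances of `X`, hence invariant under isometries of `Z`.
#'
#' @param X Input batch (`n x d_in`, `n >= 2`).
#' @param Z Its encoded batch (`n x d_latent`).
#' @return Non-negative scalar.
#' @export
shannon_stress <- function(X, Z) {
  X <- as_numeric_matrix(X, "X"); Z <- as_numeric_matrix(Z, "Z")
  if (nrow(X) != nrow(Z)) stop_cc("X and Z must have the same row count")
  if (nrow(X) < 2L) stop_cc("need at least 2 rows for the stress term")
  DX <- self_distance_matrix(X)
  DZ <- self_distance_matrix(Z)
  off <- row(DX) != col(DX)
  denom <- sum(DX[off])
  if (denom <= 0) {
    stop_cc("degenerate batch: all input pairwise distances are zero")
  }
  ok <- off & DX > 0
  sum((DX[ok] - DZ[ok])^2 / DX[ok]) / denom
}

# L2 over all spaces: sum of per-space stress terms.
stress_loss <- function(views) {
  total <- 0
  for (n in seq_len(views$N)) {
    total <- total + shannon_stress(views$X[[n]], views$Z[[n]])
  }
  total
}

#' One-dimensional Wasserstein-1 distance between samples
#'
#' Order-1 Wasserstein (earth mover's) distance between the empirical
#' distributions of two real-valued samples, allowing unequal sizes. For
#' equal sizes it reduces to the mean absolute difference of the sorted
#' samples.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Non-negative scalar; 0 iff the sorted multisets coincide.
#' @export
wasserstein_1d <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop_cc("wasserstein_1d needs non-empty samples")
  }
  if (length(a) == length(b)) {
    return(mean(abs(sort(a) - sort(b))))
  }
  # unequal sizes: integrate |F_a - F_b| over the merged support
  sa <- sort(a); sb <- sort(b)
  all_v <- sort(c(sa, sb))
  v <- all_v[-length(all_v)]
  deltas <- diff(all_v)
  cdf_a <- findInterval(v, sa) / length(sa)
  cdf_b <- findInterval(v, sb) / length(sb)
  sum(abs(cdf_a - cdf_b) * deltas)
}

#' Distance-distribution loss (L3)
#'
#' Sum over all ordered space pairs of the 1-D Wasserstein distance between
#' the distributions of encoded pairwise distances. Zero when every encoded
#' space has the same distance distribution; invariant under per-space
#' translations (and any isometry) of the encoded batches.
#'
#' @param views A [batch_views()].
#' @return Non-negative scalar.
#' @export
distance_distribution_loss <- function(views) {
  stopifnot(inherits(views, "batch_views"))
  if (views$batch < 2L) stop_cc("need at least 2 rows for distance distributions")
  samples <- lapply(views$Z, distance_sample)
  total <- 0
  for (n in seq_len(views$N)) {
    for (m in seq_len(views$N)) {
      if (n == m) next
      total <- total + wasserstein_1d(samples[[n]], samples[[m]])
    }
  }
  total
}

#' Cross-space reconstruction loss
#'
#' Sum over ordered space pairs `(n, m)` and particles of
#' `||x_i^n - D_n(E_m(x_i^m))||^2`: every space must be reconstructable from
#' every space's encoding, self pairs (`m = n`) included.
#'
#' @param views A [batch_views()].
#' @param net The `consensus_network` providing the decoders.
#' @return Non-negative scalar.
#' @export
representation_loss <- function(views, net) {
  stopifnot(inherits(views, "batch_views"))
  total <- 0
  for (n in seq_len(views$N)) {
    for (m in seq_len(views$N)) {
      R <- mlp_forward(net$decoders[[n]], views$Z[[m]])
      total <- total + sum((views$X[[n]] - R)^2)
    }
  }
  total
}

#' Total training loss with per-term breakdown
#'
#' `w_rep * rep + w1 * L1 + w2 * L2 + w3 * L3`; with default weights this is
#' the plain unweighted sum. With `reduction = "mean"` the per-particle sums
#' (reconstruction and L1) are divided by the batch size.
#'
#' @param views A [batch_views()].
#' @param net A `consensus_network`.
#' @param w A [loss_weights()].
#' @param reduction `"sum"` (as defined) or `"mean"`.
#' @return List with `total`, `rep`, `l1`, `l2`, `l3`.
#' @export
total_loss <- function(views, net, w = loss_weights(), reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  scale <- if (reduction == "mean") 1 / views$batch else 1
  rep <- representation_loss(views, net) * scale
  l1 <- latent_pair_mse(views) * scale
  l2 <- stress_loss(views)
  l3 <- distance_distribution_loss(views)
  list(total = w$w_rep * rep + w$w1 * l1 + w$w2 * l2 + w$w3 * l3,
       rep = rep, l1 = l1, l2 = l2, l3 = l3)
}
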