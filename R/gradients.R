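# Analytic gradients for the training objective.
#
# The network is small enough (plain fully connected stacks) that hand-written
# reverse-mode differentiation over BLAS matrix ops is both simple and fast;
# every formula here is verified against finite differences in the test
# suite.

# Forward with per-layer activation cache, then reverse pass.
# Returns per-layer parameter gradients and the gradient w.r.t. the input.
mlp_backward <- function(mlp, X, acts, dOut) {
  L <- length(mlp)
  grads <- vector("list", L)
  delta <- dOut
  for (k in L:1) {
    A_prev <- if (k == 1L) X else acts[[k - 1L]]
    grads[[k]] <- list(W = crossprod(A_prev, delta), b = colSums(delta))
    delta <- tcrossprod(delta, mlp[[k]]$W)
    if (k > 1L) delta[acts[[k - 1L]] <= 0] <- 0 # ReLU subgradient
  }
  list(grads = grads, dX = delta)
}

# d L1 / d Z_a for the ordered-pair latent pairing loss:
# L1 = sum_{n,m} sum_i ||Z_n[i,] - Z_m[i,]||^2  =>  dZ_a = 4 (N Z_a - sum_m Z_m)
grad_latent_pair <- function(Z) {
  N <- length(Z)
  Zsum <- Reduce(`+`, Z)
  lapply(Z, function(Za) 4 * (N * Za - Zsum))
}

# Value and gradient of one distance-preservation stress term, reusing the
# encoded distance matrix. Ordered-pair summation throughout.
stress_value_grad <- function(X, Z, DZ = NULL) {
  n <- nrow(X)
  DX <- self_distance_matrix(X)
  if (is.null(DZ)) DZ <- self_distance_matrix(Z)
  off <- row(DX) != col(DX)
  C <- sum(DX[off])
  if (C <= 0) stop_cc("degenerate batch: all input pairwise distances are zero")
  ok <- off & DX > 0
  diffs <- DX[ok] - DZ[ok]
  value <- sum(diffs^2 / DX[ok]) / C

  FF <- matrix(0, n, n)                 # d value / d DZ_ij (ordered pairs)
  FF[ok] <- -2 * diffs / DX[ok] / C
  G <- matrix(0, n, n)                  # chain through DZ_ij = ||Z_i - Z_j||
  nz <- ok & DZ > 0
  G[nz] <- 2 * FF[nz] / DZ[nz]          # F symmetric: (F_ij + F_ji) = 2 F_ij
  dZ <- Z * rowSums(G) - G %*% Z
  list(value = value, dZ = dZ)
}

# Value and subgradient of L3 = sum over ordered space pairs of the 1-D
# Wasserstein distance between encoded distance samples. Equal-length samples
# (same batch), so W1 is the mean absolute difference of sorted samples; its
# subgradient w.r.t. each sample entry is +-1/len at its sorted rank.
dist_distribution_value_grad <- function(Z, DZ_list) {
  N <- length(Z)
  n <- nrow(Z[[1L]])
  off <- which(rep(seq_len(n), each = n) != rep(seq_len(n), times = n)) # col-major off-diag
  samples <- lapply(DZ_list, function(D) as.vector(D)[off])
  orders <- lapply(samples, order)
  len <- length(samples[[1L]])

  value <- 0
  dS <- lapply(samples, function(s) numeric(len))
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      if (a == b) next
      sa <- samples[[a]][orders[[a]]]
      sb <- samples[[b]][orders[[b]]]
      d <- sa - sb
      value <- value + mean(abs(d))
      ga <- numeric(len)
      ga[orders[[a]]] <- sign(d) / len  # d W / d s_a at the sorted ranks
      gb <- numeric(len)
      gb[orders[[b]]] <- -sign(d) / len # d W / d s_b
      dS[[a]] <- dS[[a]] + ga
      dS[[b]] <- dS[[b]] + gb
    }
  }

  dZ <- vector("list", N)
  for (a in seq_len(N)) {
    gmat <- matrix(0, n, n)
    gmat[off] <- dS[[a]]
    M <- gmat + t(gmat)
    DZ <- DZ_list[[a]]
    M[DZ > 0] <- M[DZ > 0] / DZ[DZ > 0]
    M[DZ <= 0] <- 0
    dZ[[a]] <- Z[[a]] * rowSums(M) - M %*% Z[[a]]
  }
  list(value = value, dZ = dZ)
}

# All three regularizers (values + gradients w.r.t. the encoded batches) in
# one pass so distance matrices are computed once per step.
regularizer_value_grad <- function(X_list, Z_list, w, scale_l1 = 1) {
  N <- length(Z_list)
  DZ_list <- lapply(Z_list, self_distance_matrix)

  l1 <- 0
  for (a in seq_len(N)) for (b in seq_len(N)) {
    if (a != b) l1 <- l1 + sum((Z_list[[a]] - Z_list[[b]])^2)
  }
  dZ1 <- grad_latent_pair(Z_list)

  l2 <- 0
  dZ2 <- vector("list", N)
  for (a in seq_len(N)) {
    sv <- stress_value_grad(X_list[[a]], Z_list[[a]], DZ_list[[a]])
    l2 <- l2 + sv$value
    dZ2[[a]] <- sv$dZ
  }

  dd <- dist_distribution_value_grad(Z_list, DZ_list)

  dZ <- vector("list", N)
  for (a in seq_len(N)) {
    dZ[[a]] <- w$w1 * scale_l1 * dZ1[[a]] + w$w2 * dZ2[[a]] + w$w3 * dd$dZ[[a]]
  }
  list(l1 = l1 * scale_l1, l2 = l2, l3 = dd$value, dZ = dZ)
}
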