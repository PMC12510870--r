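test_that("self-distance matrix matches hand-computed distances", {
  D <- self_distance_matrix(matrix(c(0, 3, 4), 3, 1))
  expect_equal(D, matrix(c(0, 3, 4, 3, 0, 1, 4, 1, 0), 3, 3))
  # duplicated point gives an off-diagonal zero; exact symmetry always holds
  P <- rbind(c(1, 2), c(1, 2), c(0, 0))
  D2 <- self_distance_matrix(P)
  expect_identical(D2[1, 2], 0)
  set.seed(5)
  P3 <- matrix(rnorm(40), 10, 4)
  D3 <- self_distance_matrix(P3)
  expect_identical(D3, t(D3))
  expect_true(all(diag(D3) == 0))
  expect_error(self_distance_matrix(matrix(1, 1, 1)), "at least 2")
})

test_that("latent pairing loss follows the ordered double sum", {
  Z_same <- matrix(rnorm(10), 5, 2)
  v0 <- batch_views(list(Z_same, Z_same), list(Z_same, Z_same))
  expect_identical(latent_pair_mse(v0), 0)

  # one particle, encodings (0,0) and (3,4): ordered pairs (1,2) and (2,1)
  # each contribute 25; the (n,n) terms are zero.
  v1 <- batch_views(list(matrix(0, 1, 2), matrix(0, 1, 2)),
                    list(matrix(c(0, 0), 1), matrix(c(3, 4), 1)))
  expect_identical(latent_pair_mse(v1), 50)

  # homogeneity: scaling all encodings by c scales the loss by c^2
  set.seed(6)
  Z <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2))
  X <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2))
  l <- latent_pair_mse(batch_views(X, Z))
  l_scaled <- latent_pair_mse(batch_views(X, lapply(Z, `*`, 3)))
  expect_equal(l_scaled, 9 * l, tolerance = 1e-12)
})

test_that("distance-preservation stress vanishes under isometries", {
  set.seed(7)
  X <- matrix(rnorm(16), 8, 2)
  expect_equal(shannon_stress(X, X), 0)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(shannon_stress(X, X %*% R + 5), 0, tolerance = 1e-12)

  # 1-D hand case: X = (0),(1); Z = (0),(2) -> (1-2)^2/1 / 1 = 1
  expect_equal(shannon_stress(matrix(c(0, 1), 2, 1), matrix(c(0, 2), 2, 1)), 1)

  expect_error(shannon_stress(matrix(0, 3, 2), matrix(rnorm(6), 3, 2)),
               "degenerate")
})

test_that("1-D Wasserstein matches sorted-difference and quantile oracles", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(wasserstein_1d(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(wasserstein_1d(0, 5), 5)
  # CDF gap |1/2 - 1/3| over the interval [1, 5]
  expect_equal(wasserstein_1d(c(1, 5), c(1, 5, 5)), 4 * (1 / 2 - 1 / 3))
  # symmetry and equal-size reduction to mean |sorted difference|
  set.seed(8)
  a <- rnorm(17); b <- rnorm(17)
  expect_equal(wasserstein_1d(a, b), mean(abs(sort(a) - sort(b))))
  expect_equal(wasserstein_1d(a, b), wasserstein_1d(b, a))
  # unequal sizes agree with a fine common-refinement quantile evaluation
  a2 <- rnorm(7); b2 <- rnorm(12)
  qs <- (seq_len(7 * 12 * 2) - 0.5) / (7 * 12 * 2)
  ref <- mean(abs(quantile(a2, qs, type = 1) - quantile(b2, qs, type = 1)))
  expect_equal(wasserstein_1d(a2, b2), ref, tolerance = 1e-10)
  expect_error(wasserstein_1d(numeric(0), 1), "non-empty")
})

test_that("distance-distribution loss ignores per-space translations", {
  set.seed(9)
  Z <- matrix(rnorm(20), 10, 2)
  X <- list(matrix(rnorm(20), 10, 2), matrix(rnorm(20), 10, 2))
  expect_identical(distance_distribution_loss(batch_views(X, list(Z, Z))), 0)
  shifted <- sweep(Z, 2, c(100, -7), "+")
  expect_equal(distance_distribution_loss(batch_views(X, list(Z, shifted))),
               0, tolerance = 1e-9)
  # A vs 2A: both ordered pairs contribute W(s, 2s) = mean|sorted diff| = mean(s)
  s <- sort(as.vector(self_distance_matrix(Z)[row(diag(10)) != col(diag(10))]))
  expect_equal(distance_distribution_loss(batch_views(X, list(Z, 2 * Z))),
               2 * mean(abs(s - 2 * s)), tolerance = 1e-12)
})

test_that("representation loss matches a closed-form linear forward pass", {
  net <- linear_net_1d()
  # one particle: x^1 = 2, x^2 = 4 (positive, so every ReLU is the identity)
  # E_1 = 2x, E_2 = 3x, D_1 = z, D_2 = z/2
  X <- list(matrix(2, 1, 1), matrix(4, 1, 1))
  views <- batch_views(X, list(encode(net, 1, X[[1]]), encode(net, 2, X[[2]])))
  # rep = (2 - 4)^2 + (2 - 12)^2 + (4 - 2)^2 + (4 - 6)^2 = 4 + 100 + 4 + 4
  expect_equal(representation_loss(views, net), 112)
  # and a perfect-reconstruction configuration gives exactly zero
  net0 <- linear_net_1d()
  for (n in 1:2) {
    net0$encoders[[n]] <- list(list(W = matrix(1, 1, 1), b = 0),
                               list(W = matrix(1, 1, 1), b = 0))
    net0$decoders[[n]] <- list(list(W = matrix(1, 1, 1), b = 0),
                               list(W = matrix(1, 1, 1), b = 0))
  }
  Xp <- list(matrix(c(1, 2), 2, 1), matrix(c(1, 2), 2, 1))
  vp <- batch_views(Xp, list(encode(net0, 1, Xp[[1]]), encode(net0, 2, Xp[[2]])))
  expect_identical(representation_loss(vp, net0), 0)
})

test_that("total loss is additive in its terms and respects weights", {
  net <- tiny_net()
  X <- tiny_batch()
  views <- batch_views(X, list(encode(net, 1, X[[1]]), encode(net, 2, X[[2]])))
  parts <- total_loss(views, net)
  expect_equal(parts$total, parts$rep + parts$l1 + parts$l2 + parts$l3)
  expect_equal(parts$rep, representation_loss(views, net))
  expect_equal(parts$l1, latent_pair_mse(views))
  expect_equal(parts$l3, distance_distribution_loss(views))
  only_rep <- total_loss(views, net, loss_weights(w1 = 0, w2 = 0, w3 = 0))
  expect_equal(only_rep$total, parts$rep)
})

test_that("losses are invariant under a simultaneous particle permutation", {
  net <- tiny_net()
  for (trial in 1:5) {
    set.seed(100 + trial)
    X <- tiny_batch(n = 8L, seed = 100 + trial)
    Z <- list(encode(net, 1, X[[1]]), encode(net, 2, X[[2]]))
    perm <- sample(8)
    Xp <- lapply(X, function(M) M[perm, , drop = FALSE])
    Zp <- lapply(Z, function(M) M[perm, , drop = FALSE])
    v <- batch_views(X, Z); vp <- batch_views(Xp, Zp)
    expect_equal(latent_pair_mse(vp), latent_pair_mse(v), tolerance = 1e-12)
    expect_equal(cc_ns$stress_loss(vp), cc_ns$stress_loss(v), tolerance = 1e-12)
    expect_equal(distance_distribution_loss(vp),
                 distance_distribution_loss(v), tolerance = 1e-12)
    expect_equal(representation_loss(vp, net), representation_loss(v, net),
                 tolerance = 1e-12)
  }
})

test_that("analytic training gradients match central finite differences", {
  net <- tiny_net(dims = c(2L, 3L), latent = 2L, width = 4L, depth = 2L)
  X <- tiny_batch(n = 6L, dims = c(2L, 3L), seed = 42L)
  step_loss <- function(net, n) {
    Z <- lapply(1:2, function(m) cc_ns$mlp_forward(net$encoders[[m]], X[[m]]))
    rep_val <- 0
    for (m in 1:2) {
      rep_val <- rep_val +
        sum((cc_ns$mlp_forward(net$decoders[[n]], Z[[m]]) - X[[n]])^2)
    }
    v <- batch_views(X, Z)
    rep_val + (latent_pair_mse(v) + cc_ns$stress_loss(v) +
                 distance_distribution_loss(v)) / 2
  }
  analytic <- function(net, n) {
    enc_fwd <- lapply(1:2, function(m) {
      cc_ns$mlp_forward(net$encoders[[m]], X[[m]], cache = TRUE)
    })
    Z <- lapply(enc_fwd, `[[`, "out")
    reg <- cc_ns$regularizer_value_grad(X, Z, loss_weights(), scale_l1 = 1)
    dec <- net$decoders[[n]]
    dec_grads <- NULL; dZ <- vector("list", 2)
    for (m in 1:2) {
      fwd <- cc_ns$mlp_forward(dec, Z[[m]], cache = TRUE)
      bk <- cc_ns$mlp_backward(dec, Z[[m]], fwd$acts, 2 * (fwd$out - X[[n]]))
      dec_grads <- if (is.null(dec_grads)) bk$grads else {
        Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), dec_grads, bk$grads)
      }
      dZ[[m]] <- bk$dX
    }
    enc_grads <- lapply(1:2, function(m) {
      cc_ns$mlp_backward(net$encoders[[m]], X[[m]], enc_fwd[[m]]$acts,
                         dZ[[m]] + reg$dZ[[m]] / 2)$grads
    })
    list(dec = dec_grads, enc = enc_grads)
  }
  h <- 1e-6
  set.seed(12)
  for (n in 1:2) {
    an <- analytic(net, n)
    for (layer in 1:3) {
      for (trial in 1:3) {
        for (target in c("dec", "enc")) {
          np <- net; nm <- net
          if (target == "dec") {
            d <- dim(net$decoders[[n]][[layer]]$W)
            i <- sample(d[1], 1); j <- sample(d[2], 1)
            np$decoders[[n]][[layer]]$W[i, j] <- np$decoders[[n]][[layer]]$W[i, j] + h
            nm$decoders[[n]][[layer]]$W[i, j] <- nm$decoders[[n]][[layer]]$W[i, j] - h
            g_an <- an$dec[[layer]]$W[i, j]
          } else {
            m <- sample(2, 1)
            d <- dim(net$encoders[[m]][[layer]]$W)
            i <- sample(d[1], 1); j <- sample(d[2], 1)
            np$encoders[[m]][[layer]]$W[i, j] <- np$encoders[[m]][[layer]]$W[i, j] + h
            nm$encoders[[m]][[layer]]$W[i, j] <- nm$encoders[[m]][[layer]]$W[i, j] - h
            g_an <- an$enc[[m]][[layer]]$W[i, j]
          }
          g_fd <- (step_loss(np, n) - step_loss(nm, n)) / (2 * h)
          expect_equal(g_an, g_fd, tolerance = 1e-4)
        }
      }
    }
  }
})
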