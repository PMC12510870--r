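#' Training configuration
#'
#' Defaults follow the method's published settings: Adam optimizer with
#' learning rate `1e-5` and mini-batches of 1,024 particles drawn identically
#' across all spaces.
#'
#' @param learning_rate Adam step size (> 0, default `1e-5`).
#' @param batch_size Particles per mini-batch (>= 2, default 1024).
#' @param epochs Number of passes over the particle set (default 50).
#' @param seed Integer seed for batch shuffling (weight init is governed by
#'   the network spec's own seed).
#' @param weights A [loss_weights()].
#' @param reduction `"sum"` (losses as defined) or `"mean"` (per-particle
#'   sums divided by batch size).
#' @param regularizer_placement Where the three latent regularizers enter the
#'   sequential per-decoder schedule: `"per_step"` adds `(L1+L2+L3)/N` to
#'   every decoder step (total weight 1 per batch), `"first_step_only"` adds
#'   the full sum to the first decoder's step.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 1024L, epochs = 50L,
                         seed = 1L, weights = loss_weights(),
                         reduction = c("sum", "mean"),
                         regularizer_placement = c("per_step", "first_step_only")) {
  assert_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) stop_cc("`learning_rate` must be > 0")
  structure(
    list(learning_rate = learning_rate,
         batch_size = assert_count(batch_size, "batch_size", min = 2L),
         epochs = assert_count(epochs, "epochs", min = 1L),
         seed = assert_count(seed, "seed", min = 0L),
         weights = weights,
         reduction = match.arg(reduction),
         regularizer_placement = match.arg(regularizer_placement)),
    class = "train_config"
  )
}

#' Draw one paired mini-batch
#'
#' Samples a single index subset without replacement and applies it
#' identically to every landscape, so row `i` of every returned matrix is the
#' same particle — the pairing the latent agreement loss requires. Uses the
#' current RNG state; seed externally for reproducibility.
#'
#' @param set A `landscape_set`.
#' @param batch_size Number of particles to draw. If it exceeds the particle
#'   count the full set is used (with a warning) in a permuted order.
#' @return List of per-space matrices with an `idx` attribute giving the
#'   drawn particle rows.
#' @export
sample_paired_batch <- function(set, batch_size) {
  stopifnot(is_landscape_set(set))
  n <- set$num_particles
  batch_size <- assert_count(batch_size, "batch_size", min = 2L)
  if (batch_size > n) {
    warning(sprintf("batch_size %d > %d particles; using the full set",
                    batch_size, n))
    batch_size <- n
  }
  idx <- sample.int(n, batch_size)
  out <- lapply(set$landscapes, function(l) l$X[idx, , drop = FALSE])
  attr(out, "idx") <- idx
  out
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(net) {
  zero_like <- function(mlp) {
    lapply(mlp, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                 mb = l$b * 0, vb = l$b * 0))
  }
  list(encoders = lapply(net$encoders, zero_like),
       decoders = lapply(net$decoders, zero_like),
       t = 0L)
}

# One Adam update over a single MLP given its gradient list.
adam_apply <- function(mlp, grads, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (k in seq_along(mlp)) {
    g <- grads[[k]]
    st[[k]]$mW <- beta1 * st[[k]]$mW + (1 - beta1) * g$W
    st[[k]]$vW <- beta2 * st[[k]]$vW + (1 - beta2) * g$W^2
    st[[k]]$mb <- beta1 * st[[k]]$mb + (1 - beta1) * g$b
    st[[k]]$vb <- beta2 * st[[k]]$vb + (1 - beta2) * g$b^2
    mlp[[k]]$W <- mlp[[k]]$W - lr * (st[[k]]$mW / bc1) / (sqrt(st[[k]]$vW / bc2) + eps)
    mlp[[k]]$b <- mlp[[k]]$b - lr * (st[[k]]$mb / bc1) / (sqrt(st[[k]]$vb / bc2) + eps)
  }
  list(mlp = mlp, st = st)
}

#' One sequential training step over a paired mini-batch
#'
#' Implements the sequential-decoder schedule: for each decoder `n` in turn,
#' all spaces are encoded, decoder `n` reconstructs space `n` from every
#' space's encoding, the step loss (cross-reconstruction plus the scheduled
#' share of the latent regularizers) is backpropagated through decoder `n`
#' and all encoders, and one Adam update is applied — `N` optimizer updates
#' per batch.
#'
#' @param net A `consensus_network`.
#' @param X_batch List of per-space batch matrices (as from
#'   [sample_paired_batch()]).
#' @param opt Adam state (internal; created by [train()]).
#' @param config A [train_config()].
#' @return List with updated `net`, `opt`, and a data.frame `records` of
#'   per-decoder loss values (`decoder_index`, `rep_loss`, `l1`, `l2`, `l3`,
#'   `total`).
#' @export
train_step <- function(net, X_batch, opt, config) {
  N <- length(net$encoders)
  w <- config$weights
  B <- nrow(X_batch[[1L]])
  scale <- if (config$reduction == "mean") 1 / B else 1
  lr <- config$learning_rate
  records <- vector("list", N)

  for (n in seq_len(N)) {
    # fresh forward pass: parameters changed in the previous decoder step
    enc_fwd <- lapply(seq_len(N), function(m) {
      mlp_forward(net$encoders[[m]], X_batch[[m]], cache = TRUE)
    })
    Z <- lapply(enc_fwd, `[[`, "out")

    reg_w <- switch(config$regularizer_placement,
                    per_step = 1 / N,
                    first_step_only = if (n == 1L) 1 else 0)
    if (reg_w > 0) {
      reg <- regularizer_value_grad(X_batch, Z, w, scale_l1 = scale)
    } else {
      reg <- list(l1 = NA_real_, l2 = NA_real_, l3 = NA_real_,
                  dZ = lapply(Z, function(z) z * 0))
    }

    dec <- net$decoders[[n]]
    dec_grads <- NULL
    dZ <- vector("list", N)
    rep_val <- 0
    for (m in seq_len(N)) {
      fwd <- mlp_forward(dec, Z[[m]], cache = TRUE)
      E <- fwd$out - X_batch[[n]]
      rep_val <- rep_val + sum(E^2) * scale
      bk <- mlp_backward(dec, Z[[m]], fwd$acts, (2 * w$w_rep * scale) * E)
      dec_grads <- if (is.null(dec_grads)) bk$grads else {
        Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), dec_grads, bk$grads)
      }
      dZ[[m]] <- bk$dX
    }

    enc_grads <- vector("list", N)
    for (m in seq_len(N)) {
      dZm <- dZ[[m]] + reg_w * reg$dZ[[m]]
      bk <- mlp_backward(net$encoders[[m]], X_batch[[m]], enc_fwd[[m]]$acts, dZm)
      enc_grads[[m]] <- bk$grads
    }

    step_total <- w$w_rep * rep_val +
      reg_w * (w$w1 * reg$l1 + w$w2 * reg$l2 + w$w3 * reg$l3)
    if (reg_w == 0) step_total <- w$w_rep * rep_val
    if (!is.finite(step_total)) {
      bad <- c(rep = rep_val, l1 = reg$l1, l2 = reg$l2, l3 = reg$l3)
      stop_cc("non-finite loss in decoder step %d (%s)", n,
              paste(names(bad)[!is.finite(bad)], collapse = ", "))
    }

    # one Adam update over every parameter reached by this step's graph
    opt$t <- opt$t + 1L
    upd <- adam_apply(dec, dec_grads, opt$decoders[[n]], lr, opt$t)
    net$decoders[[n]] <- upd$mlp
    opt$decoders[[n]] <- upd$st
    for (m in seq_len(N)) {
      upd <- adam_apply(net$encoders[[m]], enc_grads[[m]], opt$encoders[[m]],
                        lr, opt$t)
      net$encoders[[m]] <- upd$mlp
      opt$encoders[[m]] <- upd$st
    }

    records[[n]] <- data.frame(decoder_index = n, rep_loss = rep_val,
                               l1 = reg$l1, l2 = reg$l2, l3 = reg$l3,
                               total = step_total)
  }
  list(net = net, opt = opt, records = do.call(rbind, records))
}

#' Train a consensus network on a landscape set
#'
#' Runs `config$epochs` passes of shuffled paired mini-batches through the
#' sequential-decoder schedule (see [train_step()]). Fully deterministic for
#' a fixed network seed and training seed.
#'
#' @param net A `consensus_network` whose input dims match `set$dims`.
#' @param set A `landscape_set`.
#' @param config A [train_config()].
#' @param checkpoint_path Optional file; if given, the trained network is
#'   saved there via [save_checkpoint()].
#' @param verbose Print per-epoch loss summaries.
#' @return A `train_result`: list with `net` (trained) and `history`
#'   (data.frame: `epoch`, `batch`, `decoder_index`, `rep_loss`, `l1`, `l2`,
#'   `l3`, `total`, `seconds`).
#' @export
train <- function(net, set, config = train_config(), checkpoint_path = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(net, "consensus_network"), is_landscape_set(set))
  if (!identical(as.integer(net$spec$input_dims), as.integer(set$dims))) {
    stop_cc("network input dims (%s) do not match landscape dims (%s)",
            paste(net$spec$input_dims, collapse = ","),
            paste(set$dims, collapse = ","))
  }
  n <- set$num_particles
  B <- min(config$batch_size, n)
  if (config$batch_size > n) {
    warning(sprintf("batch_size %d > %d particles; using the full set per batch",
                    config$batch_size, n))
  }
  history <- vector("list", config$epochs)

  with_seed(derive_seed(config$seed, 2L), {
    opt <- adam_init(net)
    for (epoch in seq_len(config$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      perm <- sample.int(n)
      starts <- seq(1L, n, by = B)
      recs <- list()
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + B - 1L, n)]
        if (length(idx) < 2L) next # distance terms need >= 2 particles
        X_batch <- lapply(set$landscapes, function(l) l$X[idx, , drop = FALSE])
        step <- train_step(net, X_batch, opt, config)
        net <- step$net
        opt <- step$opt
        step$records$batch <- bi
        recs[[bi]] <- step$records
      }
      h <- do.call(rbind, recs)
      h$epoch <- epoch
      h$seconds <- proc.time()[["elapsed"]] - t0
      history[[epoch]] <- h
      if (verbose) {
        message(sprintf("epoch %3d | total %.5g | rep %.5g | l1 %.5g | l2 %.5g | l3 %.5g (%.1fs)",
                        epoch, mean(h$total), mean(h$rep_loss),
                        mean(h$l1, na.rm = TRUE), mean(h$l2, na.rm = TRUE),
                        mean(h$l3, na.rm = TRUE), h$seconds[1L]))
      }
    }
  })

  history <- do.call(rbind, history)
  history <- history[, c("epoch", "batch", "decoder_index", "rep_loss",
                         "l1", "l2", "l3", "total", "seconds")]
  if (!is.null(checkpoint_path)) save_checkpoint(net, checkpoint_path)
  structure(list(net = net, history = history, config = config),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  last <- x$history[x$history$epoch == max(x$history$epoch), ]
  cat(sprintf("<train_result: %d epochs; final epoch-mean total loss %.6g>\n",
              max(x$history$epoch), mean(last$total)))
  invisible(x)
}

#' Write a training history to CSV
#'
#' @param result A `train_result` (or its `history` data.frame).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_history <- function(result, path) {
  h <- if (inherits(result, "train_result")) result$history else result
  data.table::fwrite(h, path)
  invisible(path)
}
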