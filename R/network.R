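#' Default consensus-space dimensionality
#'
#' The consensus bottleneck defaults to the minimum latent dimensionality
#' among the input spaces, so no input is forced to invent dimensions it does
#' not have; a user override replaces the default.
#'
#' @param input_dims Positive integers, one per input space.
#' @return `min(input_dims)`.
#' @examples
#' default_latent_dim(c(10, 8)) # 8
#' @export
default_latent_dim <- function(input_dims) {
  if (length(input_dims) < 2L) {
    stop_cc("consensus analysis needs N >= 2 input spaces, got %d",
            length(input_dims))
  }
  for (d in input_dims) assert_count(d, "input_dims", min = 1L)
  as.integer(min(input_dims))
}

#' Specify the consensus network architecture
#'
#' Each of the `N` encoders is `hidden_depth` fully connected ReLU layers of
#' `hidden_width` units followed by a linear layer to the consensus
#' (bottleneck) dimension; each decoder mirrors this, ending in a linear
#' layer back to its space's dimensionality.
#'
#' @param input_dims Integer vector (length `N >= 2`) of per-space latent
#'   dimensionalities.
#' @param latent_dim Consensus-space dimension; default
#'   [default_latent_dim()].
#' @param hidden_width Units per hidden layer (default 1024).
#' @param hidden_depth Hidden layers per encoder/decoder (default 3).
#' @param seed Integer seed controlling weight initialization.
#' @return A `network_spec`.
#' @export
network_spec <- function(input_dims, latent_dim = default_latent_dim(input_dims),
                         hidden_width = 1024L, hidden_depth = 3L, seed = 1L) {
  if (length(input_dims) < 2L) {
    stop_cc("a consensus network needs N >= 2 input spaces, got %d",
            length(input_dims))
  }
  input_dims <- vapply(input_dims, assert_count, 1L, name = "input_dims")
  structure(
    list(input_dims = input_dims,
         latent_dim = assert_count(latent_dim, "latent_dim"),
         hidden_width = assert_count(hidden_width, "hidden_width"),
         hidden_depth = assert_count(hidden_depth, "hidden_depth"),
         seed = assert_count(seed, "seed", min = 0L)),
    class = "network_spec"
  )
}

# One MLP: list of layers, each list(W = in x out, b = out). `act` marks the
# hidden nonlinearity; output layer is always linear.
init_mlp <- function(d_in, hidden, depth, d_out) {
  dims <- c(d_in, rep(hidden, depth), d_out)
  lapply(seq_len(length(dims) - 1L), function(k) {
    fan_in <- dims[k]
    s <- sqrt(6 / fan_in) # He-uniform, matched to the ReLU hidden units
    list(W = matrix(runif(fan_in * dims[k + 1L], -s, s), fan_in, dims[k + 1L]),
         b = numeric(dims[k + 1L]))
  })
}

#' Build a consensus network
#'
#' Instantiates the `N` encoders and `N` decoders of a [network_spec()] with
#' seeded He-uniform weight initialization (biases zero). Two builds from the
#' same spec are bit-identical.
#'
#' @param spec A [network_spec()].
#' @return A `consensus_network` holding `spec`, `encoders`, `decoders`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(derive_seed(spec$seed, 1L), {
    encoders <- lapply(spec$input_dims, function(d) {
      init_mlp(d, spec$hidden_width, spec$hidden_depth, spec$latent_dim)
    })
    decoders <- lapply(spec$input_dims, function(d) {
      init_mlp(spec$latent_dim, spec$hidden_width, spec$hidden_depth, d)
    })
  })
  structure(list(spec = spec, encoders = encoders, decoders = decoders),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf(
    "<consensus_network: N=%d spaces (dims %s) -> latent %d; %d x %d hidden; %s parameters>\n",
    length(x$spec$input_dims), paste(x$spec$input_dims, collapse = ","),
    x$spec$latent_dim, x$spec$hidden_depth, x$spec$hidden_width,
    format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#'
#' @param net A `consensus_network`.
#' @return Integer count of all weights and biases.
#' @export
parameter_count <- function(net) {
  count_mlp <- function(mlp) {
    sum(vapply(mlp, function(l) length(l$W) + length(l$b), 1))
  }
  sum(vapply(c(net$encoders, net$decoders), count_mlp, 1))
}

# Forward pass through an MLP. With cache = TRUE also returns the
# post-activation of every layer (needed by backprop).
mlp_forward <- function(mlp, X, cache = FALSE) {
  L <- length(mlp)
  acts <- if (cache) vector("list", L) else NULL
  A <- X
  for (k in seq_len(L)) {
    A <- A %*% mlp[[k]]$W
    A <- sweep2(A, mlp[[k]]$b)
    if (k < L) A[A < 0] <- 0 # ReLU on hidden layers, linear output
    if (cache) acts[[k]] <- A
  }
  if (cache) list(out = A, acts = acts) else A
}

# Row-broadcast bias add without sweep()'s overhead.
sweep2 <- function(A, b) {
  if (nrow(A) == 0L) return(A)
  A + matrix(b, nrow(A), length(b), byrow = TRUE)
}

check_space_index <- function(net, space_index) {
  n <- length(net$spec$input_dims)
  if (!is.numeric(space_index) || length(space_index) != 1L ||
      space_index < 1L || space_index > n || space_index != round(space_index)) {
    stop_cc("`space_index` must be an integer in 1..%d", n)
  }
  as.integer(space_index)
}

#' Encode points into the consensus space
#'
#' @param net A `consensus_network`.
#' @param space_index Which input space the points live in (1-based).
#' @param points Matrix `n x input_dims[space_index]` (0 rows allowed).
#' @return Matrix `n x latent_dim` of consensus coordinates.
#' @export
encode <- function(net, space_index, points) {
  space_index <- check_space_index(net, space_index)
  points <- coerce_points(points, net$spec$input_dims[space_index], "points")
  mlp_forward(net$encoders[[space_index]], points)
}

#' Decode consensus coordinates back into an input space
#'
#' @param net A `consensus_network`.
#' @param space_index Target input space (1-based).
#' @param latent_points Matrix `n x latent_dim`.
#' @return Matrix `n x input_dims[space_index]`.
#' @export
decode <- function(net, space_index, latent_points) {
  space_index <- check_space_index(net, space_index)
  latent_points <- coerce_points(latent_points, net$spec$latent_dim,
                                 "latent_points")
  mlp_forward(net$decoders[[space_index]], latent_points)
}

#' Convert coordinates between two landscape representations
#'
#' Maps points from one method's landscape to another's by routing them
#' through the consensus space: `decode(to, encode(from, points))`.
#'
#' @param net A trained `consensus_network`.
#' @param from_index,to_index Source and target space indices (1-based).
#' @param points Matrix in the source space.
#' @return Matrix in the target space.
#' @export
convert <- function(net, from_index, to_index, points) {
  decode(net, to_index, encode(net, from_index, points))
}

coerce_points <- function(points, expected_dim, name) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points)) points <- matrix(points, ncol = expected_dim)
  storage.mode(points) <- "double"
  if (ncol(points) != expected_dim) {
    stop_cc("`%s` has %d columns; this space expects %d",
            name, ncol(points), expected_dim)
  }
  if (nrow(points) > 0L && !all(is.finite(points))) {
    stop_cc("`%s` contains non-finite values", name)
  }
  points
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single-file archive holding the spec and all weights;
#' loading restores bit-identical encode/decode behaviour.
#'
#' @param net A `consensus_network`.
#' @param path Checkpoint file.
#' @return `path` (save) or the restored `consensus_network` (load).
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "consensus_network"))
  saveRDS(net, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_cc("checkpoint does not exist: %s", path)
  net <- readRDS(path)
  if (!inherits(net, "consensus_network")) {
    stop_cc("%s is not a consensus network checkpoint", path)
  }
  net
}
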