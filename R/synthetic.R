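#' Configure a synthetic landscape simulation
#'
#' The generator emulates the input regime of a consensus analysis: every
#' method images the same particles, whose true conformational state is a
#' low-dimensional coordinate drawn from a 3-component Gaussian mixture
#' (discrete states plus continuous within-state spread). Each method
#' reports those states through its own smooth distortion — an affine map
#' into the method's latent dimensionality, an optional mild coordinate-wise
#' `tanh` nonlinearity, and Gaussian noise. Planted defects with truth
#' labels make validation possible:
#'
#' * *discordant* particles are additionally displaced by a large random
#'   vector independently in every space — particles on which the methods
#'   genuinely disagree;
#' * *exclusive-cluster* particles are coherently displaced in one sighted
#'   space only — variability (e.g. a compositional state) that only one
#'   method can see.
#'
#' @param num_particles Number of particles (default 2000).
#' @param truth_dim Ground-truth state dimensionality (default 2).
#' @param space_dims Integer vector of per-space output dimensionalities
#'   (length N >= 2; default `c(2, 2)`).
#' @param affine `"random"` (seeded orthogonal-frame affine per space),
#'   `"identity"` (requires `space_dims == truth_dim`), or a list of
#'   per-space `list(A, b)` with `A` a `truth_dim x dim` matrix.
#' @param nonlinearity Per-space amplitude of the smooth distortion
#'   `y + amplitude * tanh(y)` (scalar recycled; default 0 = pure affine).
#' @param noise_sigma Per-space Gaussian noise standard deviation, as a
#'   fraction of the space's characteristic (RMS pairwise distance) scale
#'   (scalar recycled; default 0.05).
#' @param discordant_fraction Fraction of particles planted discordant, in
#'   `[0, 1)` (default 0).
#' @param discordant_displacement Displacement magnitude of discordant
#'   particles, in units of each space's characteristic scale (default 1).
#' @param exclusive_cluster Optional `list(fraction =, space =, displacement =)`
#'   planting a coherent cluster visible only to `space`.
#' @param mixture_weights Weights of the 3 truth mixture components
#'   (default `c(0.45, 0.35, 0.20)`).
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(num_particles = 2000L, truth_dim = 2L,
                              space_dims = c(2L, 2L), affine = "random",
                              nonlinearity = 0, noise_sigma = 0.05,
                              discordant_fraction = 0,
                              discordant_displacement = 1,
                              exclusive_cluster = NULL,
                              mixture_weights = c(0.45, 0.35, 0.20),
                              seed = 1L) {
  num_particles <- assert_count(num_particles, "num_particles", min = 2L)
  truth_dim <- assert_count(truth_dim, "truth_dim", min = 1L)
  if (length(space_dims) < 2L) stop_cc("need at least 2 spaces")
  space_dims <- vapply(space_dims, assert_count, 1L, name = "space_dims")
  N <- length(space_dims)
  nonlinearity <- rep_len(nonlinearity, N)
  noise_sigma <- rep_len(noise_sigma, N)
  if (any(noise_sigma < 0) || any(nonlinearity < 0)) {
    stop_cc("`noise_sigma` and `nonlinearity` must be >= 0")
  }
  assert_scalar_number(discordant_fraction, "discordant_fraction", 0, 1)
  if (discordant_fraction >= 1) stop_cc("`discordant_fraction` must be < 1")
  assert_scalar_number(discordant_displacement, "discordant_displacement", 0)
  if (!is.null(exclusive_cluster)) {
    stopifnot(is.list(exclusive_cluster))
    exclusive_cluster <- list(
      fraction = assert_scalar_number(exclusive_cluster$fraction,
                                      "exclusive_cluster$fraction", 0, 1),
      space = assert_count(exclusive_cluster$space, "exclusive_cluster$space"),
      displacement = if (is.null(exclusive_cluster$displacement)) 1 else
        assert_scalar_number(exclusive_cluster$displacement,
                             "exclusive_cluster$displacement", 0))
    if (exclusive_cluster$space > N) stop_cc("exclusive_cluster$space out of range")
  }
  if (identical(affine, "identity") && !all(space_dims == truth_dim)) {
    stop_cc("identity affines require space_dims == truth_dim")
  }
  if (length(mixture_weights) != 3L || any(mixture_weights <= 0)) {
    stop_cc("`mixture_weights` must be 3 positive weights")
  }
  structure(
    list(num_particles = num_particles, truth_dim = truth_dim,
         space_dims = space_dims, affine = affine,
         nonlinearity = nonlinearity, noise_sigma = noise_sigma,
         discordant_fraction = discordant_fraction,
         discordant_displacement = discordant_displacement,
         exclusive_cluster = exclusive_cluster,
         mixture_weights = mixture_weights / sum(mixture_weights),
         seed = assert_count(seed, "seed", min = 0L)),
    class = "simulation_config"
  )
}

# Fixed, well-separated component means on the truth scale (component sd 1).
mixture_means <- function(d) {
  M <- matrix(0, 3L, d)
  M[2L, 1L] <- 4
  M[3L, seq_len(min(2L, d))] <- if (d >= 2L) c(2, 3.5) else 2
  M
}

random_affine <- function(truth_dim, out_dim) {
  G <- matrix(rnorm(max(truth_dim, out_dim)^2), max(truth_dim, out_dim))
  Q <- qr.Q(qr(G))[seq_len(truth_dim), seq_len(out_dim), drop = FALSE]
  scale <- runif(1L, 0.5, 2)
  list(A = Q * scale, b = runif(out_dim, -1, 1))
}

#' Generate a synthetic landscape set with planted ground truth
#'
#' @param config A [simulation_config()].
#' @return A `simulation`: list with `set` (a `landscape_set`), and `truth`
#'   — list with `coords` (`n x truth_dim` ground-truth states),
#'   `component` (mixture component per particle), `discordant` and
#'   `exclusive` (logical labels), `affines` (per-space `list(A, b)`),
#'   `scales` (per-space characteristic scale of the clean signal), and the
#'   `config`.
#' @export
generate_landscapes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$num_particles
  N <- length(config$space_dims)

  with_seed(derive_seed(config$seed, 6L), {
    comp <- sample.int(3L, n, replace = TRUE, prob = config$mixture_weights)
    means <- mixture_means(config$truth_dim)
    truth <- means[comp, , drop = FALSE] +
      matrix(rnorm(n * config$truth_dim), n)

    affines <- lapply(seq_len(N), function(s) {
      if (identical(config$affine, "identity")) {
        list(A = diag(config$truth_dim), b = numeric(config$truth_dim))
      } else if (is.list(config$affine)) {
        config$affine[[s]]
      } else {
        random_affine(config$truth_dim, config$space_dims[s])
      }
    })

    n_disc <- round(config$discordant_fraction * n)
    discordant <- logical(n)
    if (n_disc > 0L) discordant[sample.int(n, n_disc)] <- TRUE
    exclusive <- logical(n)
    if (!is.null(config$exclusive_cluster)) {
      n_exc <- round(config$exclusive_cluster$fraction * n)
      pool <- which(!discordant)
      if (n_exc > length(pool)) stop_cc("exclusive cluster overlaps discordant set")
      exclusive[sample(pool, n_exc)] <- TRUE
    }

    scales <- numeric(N)
    landscapes <- vector("list", N)
    for (s in seq_len(N)) {
      Y <- truth %*% affines[[s]]$A
      Y <- sweep2(Y, affines[[s]]$b)
      amp <- config$nonlinearity[s]
      if (amp > 0) Y <- Y + amp * tanh(Y)
      scales[s] <- space_scale(Y, seed = derive_seed(config$seed, 60L + s))

      if (any(discordant)) {
        k <- sum(discordant)
        dir <- matrix(rnorm(k * ncol(Y)), k)
        dir <- dir / sqrt(rowSums(dir^2))
        Y[discordant, ] <- Y[discordant, , drop = FALSE] +
          config$discordant_displacement * scales[s] * dir
      }
      if (any(exclusive) && s == config$exclusive_cluster$space) {
        dir <- rnorm(ncol(Y))
        dir <- dir / sqrt(sum(dir^2))
        Y[exclusive, ] <- sweep2(Y[exclusive, , drop = FALSE],
                                 config$exclusive_cluster$displacement *
                                   scales[s] * dir)
      }
      if (config$noise_sigma[s] > 0) {
        Y <- Y + matrix(rnorm(n * ncol(Y), sd = config$noise_sigma[s] * scales[s]), n)
      }
      landscapes[[s]] <- landscape(Y, label = sprintf("sim-space%d", s))
    }
  })

  structure(
    list(set = pair_landscapes(landscapes),
         truth = list(coords = truth, component = comp,
                      discordant = discordant, exclusive = exclusive,
                      affines = affines, scales = scales, config = config)),
    class = "simulation"
  )
}

#' @export
print.simulation <- function(x, ...) {
  cat(sprintf("<simulation: %d particles, %d spaces; %d discordant, %d exclusive>\n",
              x$set$num_particles, x$set$N,
              sum(x$truth$discordant), sum(x$truth$exclusive)))
  invisible(x)
}

#' Named standard fixture configurations
#'
#' Ships the simulation settings used throughout the package's validation:
#'
#' * `affine_pair` — two 2-D spaces, pure affine distortions, 5% relative
#'   noise, no planted defects; used for merging/conversion checks.
#' * `discordant_10` — as above plus 10% discordant particles displaced by
#'   1.0 space scale; used for error-ranking checks.
#' * `discordant_30` — 30% discordant; used for consensus-set sweep checks.
#' * `exclusive_cluster` — 15% of particles form a cluster visible only to
#'   space 1 (emulating method-exclusive compositional variability).
#' * `null_identical` — two bit-identical noiseless spaces; the degenerate
#'   null for calibration.
#'
#' @return Named list of [simulation_config()] objects.
#' @export
standard_fixtures <- function() {
  list(
    affine_pair = simulation_config(
      num_particles = 2000L, space_dims = c(2L, 2L), noise_sigma = 0.05,
      seed = 101L),
    discordant_10 = simulation_config(
      num_particles = 2000L, space_dims = c(2L, 2L), noise_sigma = 0.05,
      discordant_fraction = 0.10, discordant_displacement = 1, seed = 102L),
    discordant_30 = simulation_config(
      num_particles = 1000L, space_dims = c(2L, 2L), noise_sigma = 0.05,
      discordant_fraction = 0.30, discordant_displacement = 1, seed = 103L),
    exclusive_cluster = simulation_config(
      num_particles = 2000L, space_dims = c(2L, 2L), noise_sigma = 0.05,
      exclusive_cluster = list(fraction = 0.15, space = 1L, displacement = 1),
      seed = 104L),
    null_identical = simulation_config(
      num_particles = 1000L, space_dims = c(2L, 2L), affine = "identity",
      noise_sigma = 0, seed = 105L)
  )
}

#' Write simulation truth labels to CSV
#'
#' @param sim A `simulation` from [generate_landscapes()].
#' @param path Output CSV (columns: id, discordant, exclusive, component,
#'   truth coordinates).
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "simulation"))
  tc <- sim$truth$coords
  colnames(tc) <- paste0("truth", seq_len(ncol(tc)))
  df <- data.frame(id = sim$set$ids,
                   discordant = as.integer(sim$truth$discordant),
                   exclusive = as.integer(sim$truth$exclusive),
                   component = sim$truth$component, tc)
  data.table::fwrite(df, path)
  invisible(path)
}
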