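#' Map a landscape set into the consensus space
#'
#' Encodes every space's particles into the shared consensus space and
#' computes the per-particle agreement metrics:
#'
#' * `consensus_error[i]`: mean over unordered space pairs of the Euclidean
#'   distance between particle `i`'s consensus projections — zero exactly
#'   when all projections coincide; low values mean the methods agree on
#'   that particle's conformational state.
#' * `representation_error[i, n, m]`: Euclidean norm of
#'   `x_i^n - D_n(E_m(x_i^m))` — how well space `n`'s coordinates are
#'   recovered from space `m`'s encoding. Reported as norms (not squared) so
#'   they live on the coordinate scale of space `n`.
#'
#' @param net A trained `consensus_network`.
#' @param set A `landscape_set` with dims matching the network.
#' @return A `consensus_mapping`: list with `ids`, `Z` (list of
#'   `num_particles x latent_dim` matrices, one per space),
#'   `consensus_error` (vector), `representation_error` (array
#'   `num_particles x N x N`, dims `[particle, target n, source m]`),
#'   `labels`, `scales` (per-space RMS pairwise distance, see
#'   [normalize_errors()]).
#' @export
map_to_consensus <- function(net, set) {
  stopifnot(inherits(net, "consensus_network"), is_landscape_set(set))
  if (!identical(as.integer(net$spec$input_dims), as.integer(set$dims))) {
    stop_cc("network input dims (%s) do not match landscape dims (%s)",
            paste(net$spec$input_dims, collapse = ","),
            paste(set$dims, collapse = ","))
  }
  N <- set$N
  n_particles <- set$num_particles
  Z <- lapply(seq_len(N), function(m) encode(net, m, set$landscapes[[m]]$X))

  ce <- numeric(n_particles)
  n_pairs <- 0L
  for (a in seq_len(N - 1L)) {
    for (b in (a + 1L):N) {
      ce <- ce + sqrt(rowSums((Z[[a]] - Z[[b]])^2))
      n_pairs <- n_pairs + 1L
    }
  }
  ce <- ce / n_pairs

  rep_err <- array(NA_real_, dim = c(n_particles, N, N))
  for (n in seq_len(N)) {
    for (m in seq_len(N)) {
      R <- decode(net, n, Z[[m]])
      rep_err[, n, m] <- sqrt(rowSums((set$landscapes[[n]]$X - R)^2))
    }
  }

  structure(
    list(ids = set$ids, Z = Z, consensus_error = ce,
         representation_error = rep_err,
         labels = vapply(set$landscapes, function(l) l$label, ""),
         scales = vapply(set$landscapes, function(l) {
           if (nrow(l$X) >= 2L) space_scale(l$X) else NA_real_
         }, 1)),
    class = "consensus_mapping"
  )
}

#' @export
print.consensus_mapping <- function(x, ...) {
  cat(sprintf("<consensus_mapping: %d particles, %d spaces, latent dim %d; median consensus error %.4g>\n",
              length(x$ids), length(x$Z), ncol(x$Z[[1L]]),
              stats::median(x$consensus_error)))
  invisible(x)
}

# Characteristic scale of a space: root-mean-square off-diagonal pairwise
# distance, subsampled for large sets (dimensionless, scale-equivariant).
space_scale <- function(X, max_points = 1000L, seed = 7L) {
  X <- as_numeric_matrix(X)
  n <- nrow(X)
  if (n < 2L) stop_cc("degenerate space: need >= 2 points for a scale")
  if (n > max_points) {
    idx <- with_seed(seed, sample.int(n, max_points))
    X <- X[idx, , drop = FALSE]
  }
  D <- self_distance_matrix(X)
  s <- sqrt(mean(D[row(D) != col(D)]^2))
  if (s <= 0) stop_cc("degenerate space: all points identical")
  s
}

#' Consensus error of one particle
#'
#' @param mapping A `consensus_mapping`.
#' @param i Particle row index (1-based) or particle id (character).
#' @return Mean pairwise distance between the particle's consensus
#'   projections.
#' @export
consensus_error <- function(mapping, i) {
  stopifnot(inherits(mapping, "consensus_mapping"))
  if (is.character(i)) i <- match(i, mapping$ids)
  if (anyNA(i)) stop_cc("unknown particle id")
  mapping$consensus_error[i]
}

#' Representation error of one particle
#'
#' @param mapping A `consensus_mapping`.
#' @param i Particle row index or id.
#' @param target Target space `n` (whose coordinates are reconstructed).
#' @param source Source space `m` (whose encoding is decoded).
#' @return `||x_i^n - D_n(E_m(x_i^m))||`.
#' @export
representation_error <- function(mapping, i, target, source) {
  stopifnot(inherits(mapping, "consensus_mapping"))
  if (is.character(i)) i <- match(i, mapping$ids)
  if (anyNA(i)) stop_cc("unknown particle id")
  mapping$representation_error[i, target, source]
}

#' Normalize per-space errors to a comparable range
#'
#' Raw representation errors live on each input space's own coordinate
#' scale, so histograms from different methods are not directly comparable.
#' Dividing by a per-space characteristic scale — the root-mean-square
#' pairwise distance of that input space — makes them dimensionless and
#' scale-equivariant: doubling a space's coordinates (and hence its raw
#' errors) leaves normalized errors unchanged, and within-space rank order
#' is preserved.
#'
#' @param errors Numeric vector (or matrix) of raw errors from one space.
#' @param scale That space's characteristic scale (> 0), e.g.
#'   `mapping$scales[n]`.
#' @return `errors / scale`.
#' @export
normalize_errors <- function(errors, scale) {
  assert_scalar_number(scale, "scale")
  if (scale <= 0) stop_cc("`scale` must be > 0 (degenerate space?)")
  errors / scale
}

#' Per-space histograms of representation errors
#'
#' Histograms of the self-reconstruction representation error
#' (`target = source = n`) for every space, on normalized errors so the
#' per-space panels share a comparable x-range.
#'
#' @param mapping A `consensus_mapping`.
#' @param bins Number of bins (>= 1).
#' @param normalized Divide errors by the per-space scale first (default
#'   TRUE).
#' @return A data.frame with columns `space`, `label`, `bin_low`, `bin_high`,
#'   `count`; counts per space sum to the particle count.
#' @export
error_histograms <- function(mapping, bins = 30L, normalized = TRUE) {
  stopifnot(inherits(mapping, "consensus_mapping"))
  bins <- assert_count(bins, "bins", min = 1L)
  N <- length(mapping$Z)
  out <- vector("list", N)
  for (n in seq_len(N)) {
    e <- mapping$representation_error[, n, n]
    if (normalized) e <- normalize_errors(e, mapping$scales[n])
    rng <- range(e)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    h <- graphics::hist(e, breaks = breaks, plot = FALSE)
    out[[n]] <- data.frame(space = n, label = mapping$labels[n],
                           bin_low = head(breaks, -1L),
                           bin_high = tail(breaks, -1L),
                           count = h$counts)
  }
  do.call(rbind, out)
}

#' Cluster representatives of a consensus landscape
#'
#' Splits a point cloud (typically consensus coordinates) into `k` clusters
#' with seeded k-means; the returned centroids are representative latent
#' vectors that can be fed to [convert()] or [decode()] to recover
#' coordinates in any input space.
#'
#' @param points Numeric matrix (`n x d`).
#' @param k Number of clusters (`<= n`).
#' @param seed Integer seed.
#' @return List with `centers` (`k x d`) and `assignments` (length `n`).
#' @export
cluster_representatives <- function(points, k, seed = 1L) {
  points <- as_numeric_matrix(points, "points")
  k <- assert_count(k, "k", min = 1L)
  if (k > nrow(points)) {
    stop_cc("k (%d) exceeds the number of points (%d)", k, nrow(points))
  }
  if (k == nrow(points)) { # every point is its own representative
    return(list(centers = points, assignments = seq_len(k)))
  }
  km <- with_seed(derive_seed(seed, 3L),
                  stats::kmeans(points, centers = k, nstart = 5L,
                                iter.max = 100L))
  list(centers = unname(km$centers), assignments = unname(km$cluster))
}

#' Write a consensus mapping to CSV
#'
#' One row per particle: id, per-space consensus coordinates, consensus
#' error, all `(target, source)` representation errors, and their normalized
#' variants.
#'
#' @param mapping A `consensus_mapping`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "consensus_mapping"))
  N <- length(mapping$Z)
  d <- ncol(mapping$Z[[1L]])
  df <- data.frame(id = mapping$ids)
  for (n in seq_len(N)) {
    Zn <- mapping$Z[[n]]
    colnames(Zn) <- sprintf("z%d_space%d", seq_len(d), n)
    df <- cbind(df, Zn)
  }
  df$consensus_error <- mapping$consensus_error
  for (n in seq_len(N)) {
    for (m in seq_len(N)) {
      e <- mapping$representation_error[, n, m]
      df[[sprintf("rep_error_t%d_s%d", n, m)]] <- e
      df[[sprintf("rep_error_norm_t%d_s%d", n, m)]] <-
        normalize_errors(e, mapping$scales[n])
    }
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a consensus mapping written by [write_mapping()]
#'
#' @param path Mapping CSV.
#' @return A `consensus_mapping` (scales reconstructed from the stored raw /
#'   normalized error ratio).
#' @export
read_mapping <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  zcols <- grep("^z\\d+_space\\d+$", names(df), value = TRUE)
  spaces <- sort(unique(as.integer(sub(".*_space", "", zcols))))
  N <- length(spaces)
  Z <- lapply(spaces, function(n) {
    cols <- grep(sprintf("^z\\d+_space%d$", n), names(df), value = TRUE)
    as.matrix(df[, cols, drop = FALSE])
  })
  rep_cols <- grep("^rep_error_t\\d+_s\\d+$", names(df), value = TRUE)
  rep_err <- array(NA_real_, dim = c(nrow(df), N, N))
  scales <- numeric(N)
  for (cn in rep_cols) {
    nm <- as.integer(strsplit(sub("rep_error_t", "", cn), "_s")[[1L]])
    rep_err[, nm[1L], nm[2L]] <- df[[cn]]
  }
  for (n in seq_len(N)) {
    raw <- df[[sprintf("rep_error_t%d_s%d", n, n)]]
    norm <- df[[sprintf("rep_error_norm_t%d_s%d", n, n)]]
    pos <- which(norm > 0)
    scales[n] <- if (length(pos)) raw[pos[1L]] / norm[pos[1L]] else 1
  }
  structure(
    list(ids = as.character(df$id), Z = Z,
         consensus_error = df$consensus_error,
         representation_error = rep_err,
         labels = paste0("space", seq_len(N)), scales = scales),
    class = "consensus_mapping"
  )
}
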