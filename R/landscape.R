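#' Construct a conformational landscape
#'
#' A landscape is one heterogeneity method's output: a matrix of per-particle
#' latent coordinates, one row per particle image, one column per latent
#' dimension, plus ordered particle identifiers and a label naming the method
#' or run that produced it.
#'
#' @param X Numeric matrix (`num_particles x dim`); all entries must be finite.
#' @param ids Ordered particle identifiers (character or integer-like), one per
#'   row of `X`. Defaults to the positional index `0..n-1`, the implicit
#'   convention of row-aligned per-image exports.
#' @param label Free-text name of the method/run (e.g. `"cryodrgn-run1"`).
#' @return An object of class `landscape` with fields `label`, `ids`, `X`,
#'   `dim`.
#' @examples
#' l <- landscape(matrix(rnorm(20), 10, 2), label = "demo")
#' l$dim
#' @export
landscape <- function(X, ids = NULL, label = "landscape") {
  X <- as_numeric_matrix(X, "X")
  if (nrow(X) < 1L) stop_cc("a landscape needs at least one particle row")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)) - 1L)
  ids <- as.character(ids)
  if (length(ids) != nrow(X)) {
    stop_cc("length(ids) [%d] != nrow(X) [%d]", length(ids), nrow(X))
  }
  if (anyDuplicated(ids)) {
    stop_cc("duplicate particle ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(
    list(label = as.character(label)[1L], ids = ids, X = unname(X),
         dim = ncol(X)),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape '%s': %d particles x %d dims>\n",
              x$label, nrow(x$X), x$dim))
  invisible(x)
}

#' @export
dim.landscape <- function(x) dim(x$X)

is_landscape <- function(x) inherits(x, "landscape")

#' Pair landscapes into an aligned set
#'
#' Aligns two or more landscapes over the identical ordered particle list so
#' that row `i` refers to the same particle image in every space. If the id
#' sets are equal but ordered differently, rows are re-ordered to match the
#' first landscape's order. Latent dimensionality may differ across
#' landscapes.
#'
#' @param landscapes List of [landscape()] objects, `N >= 2`.
#' @return A `landscape_set`: list with fields `landscapes` (aligned), `N`,
#'   `ids`, `num_particles`, `dims`.
#' @examples
#' a <- landscape(matrix(rnorm(8), 4, 2), label = "a")
#' b <- landscape(matrix(rnorm(12), 4, 3), label = "b")
#' ls <- pair_landscapes(list(a, b))
#' ls$dims
#' @export
pair_landscapes <- function(landscapes) {
  if (!is.list(landscapes) || !all(vapply(landscapes, is_landscape, TRUE))) {
    stop_cc("`landscapes` must be a list of landscape objects")
  }
  n <- length(landscapes)
  if (n < 2L) stop_cc("need at least 2 landscapes to form a set, got %d", n)
  ref <- landscapes[[1L]]
  aligned <- vector("list", n)
  aligned[[1L]] <- ref
  for (k in seq_len(n)[-1L]) {
    l <- landscapes[[k]]
    if (identical(l$ids, ref$ids)) {
      aligned[[k]] <- l
      next
    }
    missing_here <- setdiff(ref$ids, l$ids)
    extra_here <- setdiff(l$ids, ref$ids)
    if (length(missing_here) || length(extra_here)) {
      stop_cc(paste0(
        "landscape '%s' cannot be aligned with '%s': ids only in '%s': {%s};",
        " ids only in '%s': {%s}"),
        l$label, ref$label,
        ref$label, paste(head(missing_here, 10L), collapse = ", "),
        l$label, paste(head(extra_here, 10L), collapse = ", "))
    }
    ord <- match(ref$ids, l$ids)
    aligned[[k]] <- landscape(l$X[ord, , drop = FALSE], ids = ref$ids,
                              label = l$label)
  }
  structure(
    list(landscapes = aligned, N = n, ids = ref$ids,
         num_particles = length(ref$ids),
         dims = vapply(aligned, function(l) l$dim, 1L)),
    class = "landscape_set"
  )
}

#' @export
print.landscape_set <- function(x, ...) {
  cat(sprintf("<landscape_set: N=%d spaces, %d particles, dims (%s)>\n",
              x$N, x$num_particles, paste(x$dims, collapse = ", ")))
  invisible(x)
}

is_landscape_set <- function(x) inherits(x, "landscape_set")

# Matrix list view of the set (one matrix per space, aligned rows).
set_matrices <- function(set) lapply(set$landscapes, function(l) l$X)
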