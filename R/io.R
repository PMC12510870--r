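#' Read a conformational landscape from disk
#'
#' Supported formats: delimited text (`"csv"`, `"tsv"`) and a binary 2-D
#' array (`"npy"`, NPY v1.0 with an optional `<path>.ids` sidecar listing one
#' particle id per line in row order).
#'
#' Text dialect: a header row is detected when the first line contains any
#' non-numeric field; a column whose header is `id` (case-insensitive)
#' supplies particle identifiers, all remaining columns are latent dimensions
#' in file order. Without an id column, ids default to `0..n-1`.
#'
#' @param path File to read.
#' @param format One of `"csv"`, `"tsv"`, `"npy"`. Default guesses from the
#'   file extension.
#' @param label Method/run label attached to the landscape; defaults to the
#'   file name without extension.
#' @return A [landscape()].
#' @export
read_landscape <- function(path, format = c("auto", "csv", "tsv", "npy"),
                           label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_cc("file does not exist: %s", path)
  if (format == "auto") format <- guess_format(path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))

  if (format == "npy") {
    X <- read_npy(path)
    ids <- NULL
    sidecar <- paste0(path, ".ids")
    if (file.exists(sidecar)) {
      ids <- readLines(sidecar)
      ids <- ids[nzchar(ids)]
    }
    return(landscape(X, ids = ids, label = label))
  }

  sep <- if (format == "csv") "," else "\t"
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop_cc("empty landscape file: %s", path)
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))

  dt <- data.table::fread(path, sep = sep, header = has_header,
                          data.table = FALSE, colClasses = NULL)
  if (nrow(dt) == 0L) stop_cc("no particle rows in %s", path)

  ids <- NULL
  if (has_header) {
    id_col <- which(tolower(names(dt)) == "id")
    if (length(id_col) == 1L) {
      ids <- as.character(dt[[id_col]])
      dt <- dt[, -id_col, drop = FALSE]
    }
  }
  if (ncol(dt) == 0L) stop_cc("no coordinate columns in %s", path)
  for (j in seq_along(dt)) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num) & !anyNA(col)) {
        bad <- which(is.na(num))[1L]
        stop_cc("non-numeric value '%s' at data row %d, column %d of %s",
                col[bad], bad, j, path)
      }
      dt[[j]] <- num
    }
  }
  X <- as.matrix(dt)
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop_cc("non-finite value (NaN/Inf/NA) at data row %d, column %d of %s",
            bad[1L], bad[2L], path)
  }
  landscape(X, ids = ids, label = label)
}

#' Write a conformational landscape to disk
#'
#' Text formats store an `id` column followed by latent coordinates written
#' with round-trip decimal precision; `"npy"` stores the coordinate matrix as
#' a little-endian float64 NPY v1.0 array (lossless) with ids in a
#' `<path>.ids` sidecar.
#'
#' @param l A [landscape()].
#' @param path Output file.
#' @param format One of `"csv"`, `"tsv"`, `"npy"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(l, path, format = c("auto", "csv", "tsv", "npy")) {
  stopifnot(is_landscape(l))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "npy") {
    write_npy(l$X, path)
    writeLines(l$ids, paste0(path, ".ids"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(id = l$ids, l$X, check.names = FALSE)
  names(df) <- c("id", paste0("z", seq_len(l$dim)))
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  switch(ext,
         csv = "csv", tsv = "tsv", tab = "tsv", npy = "npy",
         stop_cc("cannot guess landscape format from extension '.%s'; pass `format`",
                 ext))
}

# ---- minimal NPY v1.0 codec (2-D numeric arrays) -------------------------
# No installed R package reads NPY, so a small codec for the subset this
# package emits/consumes lives here: little-endian f8/f4/i8/i4, C or Fortran
# order, 2-D shapes.

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop_cc("%s is not an NPY file (bad magic)", path)
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1L]) >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))

  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  descr <- sub(".*'([^']+)'$", "\\1", descr)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  shape <- as.integer(strsplit(gsub("[^0-9,]", "", shape_str), ",")[[1L]])
  if (length(shape) == 1L) shape <- c(shape, 1L)
  if (length(shape) != 2L) {
    stop_cc("NPY array in %s has %d dimensions; expected 2", path, length(shape))
  }

  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<i4" = as.double(readBin(con, "integer", n, size = 4L, endian = "little")),
    stop_cc("unsupported NPY dtype '%s' in %s", descr, path))
  if (length(vals) != n) stop_cc("truncated NPY payload in %s", path)
  if (fortran) matrix(vals, nrow = shape[1L], ncol = shape[2L])
  else t(matrix(vals, nrow = shape[2L], ncol = shape[1L]))
}

write_npy <- function(X, path) {
  X <- as_numeric_matrix(X)
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(X), ncol(X))
  # total pre-data length (10-byte preamble + header) padded to 64 bytes
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.vector(t(X)), con, size = 8L, endian = "little")
  invisible(path)
}
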