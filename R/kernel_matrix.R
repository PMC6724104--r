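#' Labeled kernel (Gram) matrix
#'
#' A `kernel_matrix` wraps a dense numeric matrix together with row and column
#' identifiers and two provenance flags recording whether the matrix has been
#' centered in feature space and cosine-normalized. Square matrices (identical
#' row and column identifiers) are validated to be symmetric; normalized square
#' matrices must have a unit diagonal. Rectangular matrices represent
#' cross-kernels between new points (rows) and a reference/training set
#' (columns), and carry the per-row / per-column self-kernel values needed to
#' normalize them later in `self_diagonals`.
#'
#' @param values numeric matrix.
#' @param row_ids,col_ids character identifiers; default to the dimnames of
#'   `values`.
#' @param centered,normalized provenance flags.
#' @param self_diagonals optional list with elements `row` and `col`: raw (or
#'   centered, depending on pipeline stage) self-kernel values aligned with the
#'   row and column identifiers.
#' @return an object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, row_ids = rownames(values),
                          col_ids = colnames(values),
                          centered = FALSE, normalized = FALSE,
                          self_diagonals = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(row_ids) || is.null(col_ids)) {
    stopf("kernel_matrix needs row and column identifiers")
  }
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values)) {
    stopf("identifier lengths (%d, %d) do not match matrix dimensions (%d x %d)",
          length(row_ids), length(col_ids), nrow(values), ncol(values))
  }
  if (anyDuplicated(row_ids) || anyDuplicated(col_ids)) {
    stopf("kernel_matrix identifiers must be unique")
  }
  if (any(!is.finite(values))) stopf("kernel_matrix contains non-finite values")
  dimnames(values) <- list(row_ids, col_ids)
  square <- length(row_ids) == length(col_ids) && all(row_ids == col_ids)
  if (square) {
    scale <- max(1, max(abs(values)))
    if (max(abs(values - t(values))) > 1e-10 * scale) {
      stopf("square kernel matrix is not symmetric within tolerance")
    }
    # symmetrize round-off so downstream eigen/chol see an exactly symmetric matrix
    values <- (values + t(values)) / 2
    if (normalized && max(abs(diag(values) - 1)) > 1e-10) {
      stopf("normalized square kernel matrix must have a unit diagonal")
    }
  }
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids,
                 centered = isTRUE(centered), normalized = isTRUE(normalized),
                 self_diagonals = self_diagonals),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d x %d%s [centered=%s, normalized=%s]\n",
              nrow(x$values), ncol(x$values),
              if (km_is_square(x)) " (square)" else "",
              x$centered, x$normalized))
  invisible(x)
}

#' @export
dim.kernel_matrix <- function(x) dim(x$values)

km_is_square <- function(K) {
  length(K$row_ids) == length(K$col_ids) && all(K$row_ids == K$col_ids)
}

# Accept either a kernel_matrix or a bare matrix in numeric entry points.
km_values <- function(K) {
  if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
}

#' Read a labeled kernel matrix from TSV
#'
#' The on-disk format is tab-separated text: an optional first comment line of
#' the form `#centered=true;normalized=false` carrying the provenance flags
#' (absent flags default to false), then a header line whose first cell is
#' empty or `id` followed by the column identifiers, then one line per row
#' (row identifier first). Values are written with 12 significant digits so a
#' write/read round trip reproduces them to that precision.
#'
#' @param path file path.
#' @return a [kernel_matrix()].
#' @export
read_kernel_matrix <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stopf("empty kernel matrix file: %s", path)
  centered <- FALSE
  normalized <- FALSE
  if (startsWith(lines[1L], "#")) {
    flags <- strsplit(sub("^#", "", lines[1L]), ";", fixed = TRUE)[[1L]]
    for (f in flags) {
      kv <- strsplit(f, "=", fixed = TRUE)[[1L]]
      if (length(kv) == 2L) {
        val <- tolower(trimws(kv[2L])) == "true"
        if (trimws(kv[1L]) == "centered") centered <- val
        if (trimws(kv[1L]) == "normalized") normalized <- val
      }
    }
    lines <- lines[-1L]
  }
  if (length(lines) < 2L) stopf("kernel matrix file has no data rows: %s", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  col_ids <- header[-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  row_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- lapply(body, function(cells) {
    v <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(v)) stopf("non-numeric cell in kernel matrix row '%s'", cells[1L])
    if (length(v) != length(col_ids)) {
      stopf("row '%s' has %d values, expected %d", cells[1L], length(v),
            length(col_ids))
    }
    v
  })
  values <- do.call(rbind, vals)
  kernel_matrix(values, row_ids = row_ids, col_ids = col_ids,
                centered = centered, normalized = normalized)
}

#' Write a labeled kernel matrix to TSV
#'
#' @param K a [kernel_matrix()].
#' @param path file path.
#' @seealso [read_kernel_matrix()] for the format.
#' @export
write_kernel_matrix <- function(K, path) {
  stopifnot(inherits(K, "kernel_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#centered=%s;normalized=%s",
                     tolower(as.character(K$centered)),
                     tolower(as.character(K$normalized))), con)
  writeLines(paste(c("id", K$col_ids), collapse = "\t"), con)
  for (i in seq_along(K$row_ids)) {
    writeLines(paste(c(K$row_ids[i], sprintf("%.12g", K$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(NULL)
}
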