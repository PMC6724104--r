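#' Molecular fingerprint table
#'
#' Binary molecular fingerprints: each molecule is a length-`d` vector of 0/1
#' bits encoding presence/absence of molecular properties (substructures,
#' bonds, atom configurations). Stored as an integer matrix with molecule
#' identifiers as row names; `d` is shared across the table.
#'
#' @param bits integer/numeric matrix with values in `{0, 1}` and unique,
#'   non-empty row names (molecule identifiers).
#' @return object of class `fingerprint_table` with fields `ids`, `d`, `bits`.
#' @export
fingerprint_table <- function(bits) {
  bits <- as.matrix(bits)
  if (is.null(rownames(bits))) stopf("fingerprint matrix needs row names (molecule ids)")
  if (anyDuplicated(rownames(bits))) {
    dup <- rownames(bits)[duplicated(rownames(bits))][1L]
    stopf("duplicated molecule id '%s' in fingerprint table", dup)
  }
  if (ncol(bits) < 1L) stopf("fingerprints must have at least one bit")
  storage.mode(bits) <- "integer"
  if (any(is.na(bits)) || any(bits != 0L & bits != 1L)) {
    stopf("fingerprint entries must all be 0 or 1")
  }
  structure(list(ids = rownames(bits), d = ncol(bits), bits = bits),
            class = "fingerprint_table")
}

#' @export
print.fingerprint_table <- function(x, ...) {
  cat(sprintf("fingerprint_table: %d molecules x %d bits (mean density %.3f)\n",
              length(x$ids), x$d, mean(x$bits)))
  invisible(x)
}

# Fetch rows for a set of ids, erroring on any missing id.
fp_rows <- function(fps, ids) {
  stopifnot(inherits(fps, "fingerprint_table"))
  missing <- setdiff(ids, fps$ids)
  if (length(missing)) {
    stopf("fingerprint table is missing id(s): %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  fps$bits[ids, , drop = FALSE]
}

#' Read a fingerprint table from delimited text
#'
#' Two dialects are accepted. The wide form is delimited text (tab or comma)
#' with a header row: first column molecule id, remaining columns 0/1 bits.
#' The compact form is two columns, id and a bitstring of `'0'`/`'1'`
#' characters, without header. The bit count `d` is inferred from the first
#' row and every row is validated against it; ragged rows and non-binary
#' cells are errors naming the offending id.
#'
#' @param path file path.
#' @return a [fingerprint_table()].
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty fingerprint file: %s", path)
  delim <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  first <- strsplit(lines[1L], delim, fixed = TRUE)[[1L]]
  bitstring_form <- length(first) == 2L && grepl("^[01]+$", trimws(first[2L]))
  if (bitstring_form) {
    parts <- strsplit(lines, delim, fixed = TRUE)
    ids <- vapply(parts, function(p) trimws(p[1L]), character(1))
    strs <- vapply(parts, function(p) trimws(p[2L]), character(1))
    d <- nchar(strs[1L])
    rows <- lapply(seq_along(strs), function(i) {
      if (!grepl("^[01]+$", strs[i])) stopf("non-binary bitstring for id '%s'", ids[i])
      if (nchar(strs[i]) != d) {
        stopf("ragged fingerprint row for id '%s' (%d bits, expected %d)",
              ids[i], nchar(strs[i]), d)
      }
      as.integer(strsplit(strs[i], "")[[1L]])
    })
    bits <- do.call(rbind, rows)
    rownames(bits) <- ids
    colnames(bits) <- paste0("b", seq_len(d))
    return(fingerprint_table(bits))
  }
  header <- trimws(first)
  d <- length(header) - 1L
  if (d < 1L) stopf("fingerprint header must name at least one bit column")
  body <- strsplit(lines[-1L], delim, fixed = TRUE)
  if (length(body) == 0L) stopf("fingerprint file has no data rows: %s", path)
  ids <- vapply(body, function(p) trimws(p[1L]), character(1))
  rows <- lapply(seq_along(body), function(i) {
    cells <- trimws(body[[i]][-1L])
    if (length(cells) != d) {
      stopf("ragged fingerprint row for id '%s' (%d cells, expected %d)",
            ids[i], length(cells), d)
    }
    v <- suppressWarnings(as.integer(cells))
    if (any(is.na(v)) || any(v != 0L & v != 1L)) {
      stopf("non-binary fingerprint cell for id '%s'", ids[i])
    }
    v
  })
  bits <- do.call(rbind, rows)
  rownames(bits) <- ids
  colnames(bits) <- header[-1L]
  fingerprint_table(bits)
}

#' Write a fingerprint table as wide TSV
#'
#' @param fps a [fingerprint_table()].
#' @param path output path.
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(inherits(fps, "fingerprint_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  cols <- colnames(fps$bits) %||% paste0("b", seq_len(fps$d))
  writeLines(paste(c("id", cols), collapse = "\t"), con)
  for (i in seq_along(fps$ids)) {
    writeLines(paste(c(fps$ids[i], fps$bits[i, ]), collapse = "\t"), con)
  }
  invisible(NULL)
}
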