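#' MS/MS spectrum
#'
#' A tandem mass spectrum is a peak list: pairs of mass-to-charge ratio
#' (Daltons per unit charge) and non-negative intensity (arbitrary units).
#' Each spectrum carries an identifier and a structure-group label used to keep
#' spectra of the same molecular structure inside one cross-validation fold.
#' Peaks are stored sorted by ascending m/z; the constructor sorts and
#' validates.
#'
#' @param id character identifier (unique within a spectrum collection).
#' @param peaks two-column numeric matrix or data frame `(mz, intensity)` with
#'   at least one row; all m/z strictly positive, intensities non-negative.
#' @param group_id structure-group label; defaults to `id`.
#' @param precursor_mz optional precursor m/z.
#' @param ionization_mode one of `"positive"`, `"negative"`, `"unspecified"`.
#' @return an object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(id, peaks, group_id = id, precursor_mz = NULL,
                        ionization_mode = c("unspecified", "positive", "negative")) {
  ionization_mode <- match.arg(ionization_mode)
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stopf("peaks must have two columns (mz, intensity)")
  storage.mode(peaks) <- "double"
  if (nrow(peaks) < 1L) stopf("spectrum '%s' has no peaks", id)
  if (any(!is.finite(peaks))) stopf("spectrum '%s' has non-finite peaks", id)
  if (any(peaks[, 1L] <= 0)) stopf("spectrum '%s' has non-positive m/z", id)
  if (any(peaks[, 2L] < 0)) stopf("spectrum '%s' has negative intensity", id)
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  colnames(peaks) <- c("mz", "intensity")
  structure(list(id = as.character(id), group_id = as.character(group_id),
                 peaks = peaks, precursor_mz = precursor_mz,
                 ionization_mode = ionization_mode),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("ms_spectrum '%s' (group '%s'): %d peaks, m/z %.4f-%.4f\n",
              x$id, x$group_id, nrow(x$peaks), min(x$peaks[, 1]),
              max(x$peaks[, 1])))
  invisible(x)
}

#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Parses `BEGIN IONS` / `END IONS` blocks. `TITLE` is used as the spectrum
#' identifier; a non-standard `GROUPID=` header carries the structure-group
#' label and defaults to the identifier when absent. `PEPMASS` (first token)
#' becomes the precursor m/z and `CHARGE` with a trailing `+`/`-` sets the
#' ionization mode. Peak lines are `mz intensity` pairs; peaks are re-sorted
#' by ascending m/z. Duplicate titles get suffixes `_2`, `_3`, ... with a
#' logged warning. Malformed peak lines raise an error naming the line number.
#'
#' @param path MGF file path.
#' @return list of [ms_spectrum()] objects, in file order.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stopf("empty MGF file: %s", path)
  spectra <- list()
  seen <- character(0)
  in_block <- FALSE
  id <- NULL; group <- NULL; pep <- NULL; mode <- "unspecified"
  mz <- numeric(0); int <- numeric(0)
  block_no <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) stopf("line %d: nested BEGIN IONS", ln)
      in_block <- TRUE
      block_no <- block_no + 1L
      id <- NULL; group <- NULL; pep <- NULL; mode <- "unspecified"
      mz <- numeric(0); int <- numeric(0)
      next
    }
    if (line == "END IONS") {
      if (!in_block) stopf("line %d: END IONS without BEGIN IONS", ln)
      in_block <- FALSE
      if (is.null(id)) id <- sprintf("spectrum_%d", block_no)
      if (id %in% seen) {
        k <- 2L
        while (sprintf("%s_%d", id, k) %in% seen) k <- k + 1L
        new_id <- sprintf("%s_%d", id, k)
        iokr_log(sprintf("duplicate TITLE '%s' renamed to '%s'", id, new_id),
                 level = "WARN")
        id <- new_id
      }
      seen <- c(seen, id)
      if (length(mz) == 0L) stopf("spectrum '%s' (ending line %d) has no peaks", id, ln)
      spectra[[length(spectra) + 1L]] <-
        ms_spectrum(id, cbind(mz, int), group_id = group %||% id,
                    precursor_mz = pep, ionization_mode = mode)
      next
    }
    if (!in_block) next
    if (grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "TITLE") id <- trimws(val)
      else if (key == "GROUPID") group <- trimws(val)
      else if (key == "PEPMASS") {
        pep <- suppressWarnings(as.numeric(strsplit(trimws(val), "\\s+")[[1L]][1L]))
        if (is.na(pep)) stopf("line %d: non-numeric PEPMASS", ln)
      } else if (key == "CHARGE") {
        if (grepl("-\\s*$", val)) mode <- "negative"
        else if (grepl("\\+\\s*$", val)) mode <- "positive"
      }
      # other headers (SCANS, RTINSECONDS, ...) are ignored
      next
    }
    toks <- strsplit(line, "[\t ]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      stopf("line %d: malformed peak line '%s'", ln, line)
    }
    mz <- c(mz, vals[1L]); int <- c(int, vals[2L])
  }
  if (in_block) stopf("unterminated BEGIN IONS block at end of file")
  if (length(spectra) == 0L) stopf("no spectra found in %s", path)
  spectra
}

#' Write spectra to an MGF file
#'
#' One `BEGIN IONS`/`END IONS` block per spectrum, in input order, with
#' `TITLE`, `GROUPID`, optional `PEPMASS` and `CHARGE` headers followed by the
#' peak list. Masses and intensities are written with 6 decimal places.
#'
#' @param spectra non-empty list of [ms_spectrum()] objects.
#' @param path output path.
#' @export
write_mgf <- function(spectra, path) {
  if (length(spectra) == 0L) stopf("nothing to write: empty spectrum list")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "ms_spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s$id), con)
    writeLines(sprintf("GROUPID=%s", s$group_id), con)
    if (!is.null(s$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    }
    if (s$ionization_mode == "positive") writeLines("CHARGE=1+", con)
    if (s$ionization_mode == "negative") writeLines("CHARGE=1-", con)
    writeLines(sprintf("%.6f %.6f", s$peaks[, 1L], s$peaks[, 2L]), con)
    writeLines("END IONS", con)
  }
  invisible(NULL)
}
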