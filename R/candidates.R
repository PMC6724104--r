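#' Candidate sets for pre-image ranking
#'
#' For each query spectrum, the pre-image search ranks a finite candidate set
#' of molecules (in real use: database molecules sharing the query's molecular
#' formula). A `candidate_sets` object maps each query id to its ordered
#' candidate list and records which candidate is the true molecule. Queries
#' whose truth is absent from their candidate list are flagged unrankable
#' with a logged warning and excluded from accuracy denominators downstream.
#'
#' @param candidates named list: query id -> character vector of candidate
#'   molecule ids.
#' @param truth named character vector: query id -> true molecule id.
#' @return object of class `candidate_sets` with fields `candidates`, `truth`,
#'   `unrankable`.
#' @export
candidate_sets <- function(candidates, truth) {
  if (is.null(names(candidates)) || anyDuplicated(names(candidates))) {
    stopf("candidate lists must be uniquely named by query id")
  }
  qids <- names(candidates)
  if (!all(qids %in% names(truth))) {
    stopf("every query needs a truth entry")
  }
  truth <- truth[qids]
  unrankable <- character(0)
  for (q in qids) {
    if (!truth[[q]] %in% candidates[[q]]) {
      unrankable <- c(unrankable, q)
    }
  }
  if (length(unrankable)) {
    iokr_log(sprintf("%d query(ies) have truth outside their candidate list: %s",
                     length(unrankable),
                     paste(utils::head(unrankable, 5L), collapse = ", ")),
             level = "WARN")
  }
  structure(list(candidates = candidates, truth = truth,
                 unrankable = unrankable),
            class = "candidate_sets")
}

#' @export
print.candidate_sets <- function(x, ...) {
  sizes <- lengths(x$candidates)
  cat(sprintf("candidate_sets: %d queries, %d-%d candidates each (%d unrankable)\n",
              length(x$candidates), min(sizes), max(sizes),
              length(x$unrankable)))
  invisible(x)
}

# Check every candidate and truth id resolves in a fingerprint table.
validate_candidates <- function(cands, fps) {
  all_ids <- unique(c(unlist(cands$candidates, use.names = FALSE), cands$truth))
  missing <- setdiff(all_ids, fps$ids)
  if (length(missing)) {
    stopf("candidate/truth id(s) missing from fingerprint table: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read candidate sets from delimited text
#'
#' Format: delimited text (tab or comma) with header
#' `query_id, candidate_id, is_true`, one candidate per row; candidate order
#' within a query follows file order. Exactly one `is_true = 1` row is
#' required per query; zero or several raise an error naming the query.
#'
#' @param path file path.
#' @return a [candidate_sets()].
#' @export
read_candidate_sets <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stopf("candidate file has no data rows: %s", path)
  delim <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  body <- strsplit(lines[-1L], delim, fixed = TRUE)
  qid <- vapply(body, function(p) trimws(p[1L]), character(1))
  cid <- vapply(body, function(p) trimws(p[2L]), character(1))
  flag <- vapply(body, function(p) trimws(p[3L]), character(1))
  if (any(!flag %in% c("0", "1"))) stopf("is_true column must be 0/1")
  cands <- split(cid, factor(qid, levels = unique(qid)))
  truths <- vapply(names(cands), function(q) {
    hits <- cid[qid == q & flag == "1"]
    if (length(hits) == 0L) stopf("query '%s' has no is_true row", q)
    if (length(hits) > 1L) stopf("query '%s' has %d is_true rows", q, length(hits))
    hits
  }, character(1))
  candidate_sets(as.list(cands), truths)
}

#' Write candidate sets as TSV
#'
#' @param cands a [candidate_sets()].
#' @param path output path.
#' @export
write_candidate_sets <- function(cands, path) {
  stopifnot(inherits(cands, "candidate_sets"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("query_id\tcandidate_id\tis_true", con)
  for (q in names(cands$candidates)) {
    for (m in cands$candidates[[q]]) {
      writeLines(sprintf("%s\t%s\t%d", q, m,
                         as.integer(identical(m, unname(cands$truth[[q]])))), con)
    }
  }
  invisible(NULL)
}
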