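# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds so that independent stages (fingerprints, fragment
# tables, per-spectrum noise, candidate sampling, fold shuffles, tuning CV)
# can be re-run in isolation from one master seed. Kept below 2^31 - 1.
child_seed <- function(seed, what, index = 0L) {
  offsets <- c(fingerprints = 1L, fragments = 2L, spectra = 3L,
               candidates = 4L, folds = 5L, tuning = 6L, fusion = 7L,
               views = 8L, noise = 9L, protocol = 10L)
  if (!what %in% names(offsets)) {
    stop("unknown seed stream: ", what)
  }
  (as.integer(seed) %% 100000L) * 20011L + offsets[[what]] * 10007L +
    as.integer(index)
}

# Evaluate `code` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Lightweight stderr logging; levels are cosmetic.
iokr_log <- function(..., level = "INFO") {
  message(sprintf("[iokr %s] %s", level, paste0(...)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
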