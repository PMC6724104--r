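# Synthetic benchmark generator. Real reference spectra come with an unknown
# fragmentation process linking molecular structure to peaks; the generator
# replaces it with an auditable dictionary mechanism: every fingerprint bit
# owns a few characteristic fragment masses, and a molecule's spectrum is the
# noisy union of the peaks of its active bits. This produces exactly the
# input-output kernel correlation the regression exploits, with difficulty
# knobs (mass jitter, dropout, noise peaks, decoy closeness) that can switch
# the signal off entirely.

#' Configuration for the synthetic benchmark generator
#'
#' All randomness flows from `seed` through named child seeds (fingerprints,
#' fragment table, per-spectrum noise, candidates) so each stage is
#' independently reproducible.
#'
#' @param n_molecules number of molecules (and of queries).
#' @param d_bits fingerprint length.
#' @param n_blocks number of correlated fingerprint blocks; bits within a
#'   block share a latent Bernoulli driver (`n_blocks = d_bits` gives fully
#'   independent bits).
#' @param bit_activation_prob marginal probability that a bit is active.
#' @param fragment_table_size size F of the shared pool of characteristic
#'   fragment masses bits draw from (shared masses create confusable bits).
#' @param peaks_per_active_bit characteristic peaks emitted per active bit.
#' @param mass_range numeric length-2, Daltons; characteristic and noise-peak
#'   masses are uniform on this range.
#' @param mass_noise_sd Gaussian jitter (Daltons) on each emitted peak mass.
#' @param intensity_noise_sd signal peak intensity is `|1 + N(0, sd)|`.
#' @param peak_dropout_prob probability each signal peak is dropped
#'   (set to 1 for pure-noise spectra).
#' @param n_noise_peaks uniform-random noise peaks added per spectrum.
#' @param candidates_per_query candidate-set size `n_c` (>= 2).
#' @param near_decoy_flip_bits bits flipped from the truth fingerprint to make
#'   a near decoy.
#' @param far_decoy_frac fraction of decoys drawn uniformly from the other
#'   molecules instead of perturbing the truth (0 keeps every candidate set
#'   confined to the query's own molecule plus fresh decoys).
#' @param n_views number of independent spectrum views (each view has its own
#'   fragment table and noise draws; views play the role of multiple input
#'   kernels).
#' @param seed master integer seed.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_molecules = 80L, d_bits = 64L, n_blocks = 16L,
                             bit_activation_prob = 0.3,
                             fragment_table_size = 200L,
                             peaks_per_active_bit = 2L,
                             mass_range = c(50, 500),
                             mass_noise_sd = 0.01,
                             intensity_noise_sd = 0.2,
                             peak_dropout_prob = 0.1,
                             n_noise_peaks = 3L,
                             candidates_per_query = 10L,
                             near_decoy_flip_bits = 2L,
                             far_decoy_frac = 0.5,
                             n_views = 2L,
                             seed = 1L) {
  cfg <- list(n_molecules = as.integer(n_molecules), d_bits = as.integer(d_bits),
              n_blocks = as.integer(n_blocks),
              bit_activation_prob = bit_activation_prob,
              fragment_table_size = as.integer(fragment_table_size),
              peaks_per_active_bit = as.integer(peaks_per_active_bit),
              mass_range = as.numeric(mass_range),
              mass_noise_sd = mass_noise_sd,
              intensity_noise_sd = intensity_noise_sd,
              peak_dropout_prob = peak_dropout_prob,
              n_noise_peaks = as.integer(n_noise_peaks),
              candidates_per_query = as.integer(candidates_per_query),
              near_decoy_flip_bits = as.integer(near_decoy_flip_bits),
              far_decoy_frac = far_decoy_frac,
              n_views = as.integer(n_views), seed = as.integer(seed))
  probs <- c(cfg$bit_activation_prob, cfg$peak_dropout_prob, cfg$far_decoy_frac)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_molecules, cfg$d_bits, cfg$n_blocks, cfg$fragment_table_size,
              cfg$peaks_per_active_bit, cfg$candidates_per_query, cfg$n_views)
  if (any(counts < 1L)) stopf("counts must be positive")
  if (cfg$d_bits < cfg$n_blocks) stopf("d_bits must be >= n_blocks")
  if (cfg$mass_range[1L] >= cfg$mass_range[2L]) stopf("mass_range must be increasing")
  if (cfg$candidates_per_query < 2L) stopf("need at least 2 candidates per query")
  if (cfg$mass_noise_sd < 0 || cfg$intensity_noise_sd < 0) stopf("noise sds must be >= 0")
  if (cfg$n_noise_peaks < 0L) stopf("n_noise_peaks must be >= 0")
  structure(cfg, class = "generator_config")
}

#' Sample correlated binary fingerprints
#'
#' Bits are organized in `n_blocks` contiguous blocks. For each molecule and
#' block a latent Bernoulli(`bit_activation_prob`) is drawn; each bit of the
#' block copies the latent with probability 0.8 and is an independent
#' Bernoulli(`bit_activation_prob`) otherwise, giving within-block correlation
#' with the configured marginal activation rate. When `n_blocks = d_bits`
#' every block holds one bit and all bits are independent. Duplicate rows are
#' resampled (up to 100 attempts) so molecules are structurally distinct.
#'
#' @param cfg a [generator_config()].
#' @return a [fingerprint_table()] with ids `mol001`, `mol002`, ...
#' @export
sample_fingerprints <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(child_seed(cfg$seed, "fingerprints"), {
    block_of <- sort(rep_len(seq_len(cfg$n_blocks), cfg$d_bits))
    draw_one <- function() {
      latent <- stats::rbinom(cfg$n_blocks, 1L, cfg$bit_activation_prob)
      copy <- stats::rbinom(cfg$d_bits, 1L, 0.8) == 1L
      bits <- ifelse(copy, latent[block_of],
                     stats::rbinom(cfg$d_bits, 1L, cfg$bit_activation_prob))
      as.integer(bits)
    }
    rows <- matrix(0L, cfg$n_molecules, cfg$d_bits)
    keys <- character(cfg$n_molecules)
    for (i in seq_len(cfg$n_molecules)) {
      for (attempt in seq_len(100L)) {
        v <- draw_one()
        key <- paste(v, collapse = "")
        if (!key %in% keys[seq_len(i - 1L)]) break
        if (attempt == 100L) stopf("could not sample %d distinct fingerprints", cfg$n_molecules)
      }
      rows[i, ] <- v
      keys[i] <- key
    }
    rownames(rows) <- sprintf("mol%03d", seq_len(cfg$n_molecules))
    colnames(rows) <- paste0("b", seq_len(cfg$d_bits))
    fingerprint_table(rows)
  })
}

#' Draw a fragment table for one view
#'
#' A pool of `fragment_table_size` characteristic masses is drawn uniformly on
#' `mass_range`; each fingerprint bit is assigned `peaks_per_active_bit`
#' masses sampled from the pool.
#'
#' @param cfg a [generator_config()].
#' @param view view index (distinct views get independent tables).
#' @return `d_bits x peaks_per_active_bit` matrix of masses.
#' @export
sample_fragment_table <- function(cfg, view = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(child_seed(cfg$seed, "fragments", view), {
    pool <- stats::runif(cfg$fragment_table_size, cfg$mass_range[1L], cfg$mass_range[2L])
    rows <- lapply(seq_len(cfg$d_bits), function(b) {
      sample(pool, cfg$peaks_per_active_bit,
             replace = cfg$peaks_per_active_bit > length(pool))
    })
    do.call(rbind, rows)
  })
}

#' Simulate one spectrum from a fingerprint
#'
#' Each active bit emits its characteristic peaks with Gaussian mass jitter
#' and intensity `|1 + N(0, intensity_noise_sd)|`; each signal peak is
#' independently dropped with `peak_dropout_prob`; `n_noise_peaks` peaks with
#' uniform mass and uniform (0, 1] intensity are added. At least one peak is
#' guaranteed (one noise peak is forced if everything was dropped).
#'
#' @param fp binary fingerprint vector.
#' @param fragment_table matrix from [sample_fragment_table()].
#' @param cfg a [generator_config()].
#' @param id,group_id spectrum identifier and structure group.
#' @param seed per-spectrum seed.
#' @return an [ms_spectrum()].
#' @export
spectrum_from_fingerprint <- function(fp, fragment_table, cfg, id,
                                      group_id = id, seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(seed, {
    active <- which(fp == 1L)
    mz <- as.numeric(t(fragment_table[active, , drop = FALSE]))
    n_sig <- length(mz)
    if (n_sig > 0L) {
      mz <- mz + stats::rnorm(n_sig, 0, cfg$mass_noise_sd)
      it <- abs(1 + stats::rnorm(n_sig, 0, cfg$intensity_noise_sd))
      keep <- stats::runif(n_sig) >= cfg$peak_dropout_prob
      mz <- mz[keep]; it <- it[keep]
    } else {
      it <- numeric(0)
    }
    n_noise <- cfg$n_noise_peaks
    if (length(mz) == 0L && n_noise == 0L) n_noise <- 1L
    if (n_noise > 0L) {
      mz <- c(mz, stats::runif(n_noise, cfg$mass_range[1L], cfg$mass_range[2L]))
      it <- c(it, stats::runif(n_noise, 0, 1))
    }
    if (length(mz) == 0L) {  # all signal dropped and n_noise_peaks = 0
      mz <- stats::runif(1L, cfg$mass_range[1L], cfg$mass_range[2L])
      it <- stats::runif(1L, 0, 1)
    }
    mz <- pmax(mz, .Machine$double.eps)
    ms_spectrum(id, cbind(mz, it), group_id = group_id)
  })
}

#' Build candidate sets with near and far decoys
#'
#' Each molecule becomes a query whose candidate set contains the truth plus
#' `candidates_per_query - 1` decoys: far decoys are other molecules sampled
#' uniformly, near decoys are copies of the truth fingerprint with
#' `near_decoy_flip_bits` random bits flipped. Near decoys get fresh ids
#' (`<query>_dk`) and their fingerprints are appended to the returned table,
#' so candidate difficulty is controlled by the flip count alone. Candidate
#' order is randomized per query.
#'
#' @param fps the molecule [fingerprint_table()].
#' @param cfg a [generator_config()].
#' @return list with `candidates` (a [candidate_sets()]) and `fingerprints`
#'   (the table augmented with decoy rows).
#' @export
make_candidate_sets <- function(fps, cfg) {
  stopifnot(inherits(fps, "fingerprint_table"), inherits(cfg, "generator_config"))
  n_dec <- cfg$candidates_per_query - 1L
  n_far <- round(n_dec * cfg$far_decoy_frac)
  n_near <- n_dec - n_far
  mols <- fps$ids
  if (n_near == 0L && n_far > length(mols) - 1L) {
    stopf("candidates_per_query exceeds the molecule pool with near decoys disabled")
  }
  with_seed(child_seed(cfg$seed, "candidates"), {
    extra_bits <- list()
    cand_list <- list()
    truth <- character(0)
    for (q in mols) {
      ids <- q
      if (n_far > 0L) {
        others <- setdiff(mols, q)
        ids <- c(ids, sample(others, min(n_far, length(others))))
      }
      if (n_near > 0L) {
        base <- fps$bits[q, ]
        for (k in seq_len(n_near)) {
          v <- base
          flip <- sample.int(cfg$d_bits, min(cfg$near_decoy_flip_bits, cfg$d_bits))
          v[flip] <- 1L - v[flip]
          did <- sprintf("%s_d%d", q, k)
          extra_bits[[did]] <- v
          ids <- c(ids, did)
        }
      }
      cand_list[[q]] <- sample(ids)
      truth[q] <- q
    }
    fp_all <- fps$bits
    if (length(extra_bits)) {
      extra <- do.call(rbind, extra_bits)
      rownames(extra) <- names(extra_bits)
      fp_all <- rbind(fp_all, extra)
    }
    list(candidates = candidate_sets(cand_list, truth),
         fingerprints = fingerprint_table(fp_all))
  })
}

#' Generate a complete synthetic benchmark
#'
#' Draws fingerprints once, then `n_views` independent spectrum sets (each
#' with its own fragment table and noise draws) over the same molecules —
#' the views play the role of multiple input kernels — plus candidate sets
#' with decoy fingerprints. Spectrum ids equal molecule ids within each view;
#' `group_id` is the molecule id, so structure-grouped cross-validation keeps
#' a molecule's spectra together.
#'
#' @param cfg a [generator_config()].
#' @return object of class `iokr_benchmark`: `views` (list of spectrum
#'   lists), `fingerprints` (augmented table), `molecule_fingerprints`
#'   (original table), `candidates`, `groups` (named vector), `cfg`.
#' @export
generate_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  fps <- sample_fingerprints(cfg)
  views <- lapply(seq_len(cfg$n_views), function(v) {
    ftab <- sample_fragment_table(cfg, v)
    lapply(seq_along(fps$ids), function(i) {
      m <- fps$ids[i]
      spectrum_from_fingerprint(fps$bits[m, ], ftab, cfg, id = m, group_id = m,
                                seed = child_seed(cfg$seed, "spectra",
                                                  v * 100000L + i))
    })
  })
  names(views) <- sprintf("view%d", seq_len(cfg$n_views))
  cand <- make_candidate_sets(fps, cfg)
  groups <- stats::setNames(fps$ids, fps$ids)
  structure(list(views = views, fingerprints = cand$fingerprints,
                 molecule_fingerprints = fps, candidates = cand$candidates,
                 groups = groups, cfg = cfg),
            class = "iokr_benchmark")
}

#' @export
print.iokr_benchmark <- function(x, ...) {
  cat(sprintf("iokr_benchmark: %d molecules, %d view(s), %d-bit fingerprints, n_c = %d\n",
              x$cfg$n_molecules, x$cfg$n_views, x$cfg$d_bits,
              x$cfg$candidates_per_query))
  invisible(x)
}
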