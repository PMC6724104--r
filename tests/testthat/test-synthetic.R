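# The synthetic benchmark generator: marginal bit statistics, determinism,
# the fingerprint-to-peak mechanism, and the signal it creates for the kernels.

test_that("independent-bit config hits the configured activation rate", {
  cfg <- generator_config(n_molecules = 500, d_bits = 32, n_blocks = 32,
                          bit_activation_prob = 0.3, seed = 71)
  fp <- sample_fingerprints(cfg)
  rate <- mean(fp$bits)
  se <- sqrt(0.3 * 0.7 / (500 * 32))
  expect_lt(abs(rate - 0.3), 3 * se)
})

test_that("fingerprints are reproducible and duplicate-free", {
  cfg <- generator_config(n_molecules = 100, d_bits = 64, seed = 72)
  fp1 <- sample_fingerprints(cfg)
  fp2 <- sample_fingerprints(cfg)
  expect_identical(fp1$bits, fp2$bits)
  expect_equal(anyDuplicated(apply(fp1$bits, 1, paste, collapse = "")), 0L)
  expect_error(generator_config(d_bits = 4, n_blocks = 8), "n_blocks")
})

test_that("blocked bits correlate within blocks", {
  cfg <- generator_config(n_molecules = 400, d_bits = 32, n_blocks = 8,
                          bit_activation_prob = 0.4, seed = 73)
  fp <- sample_fingerprints(cfg)
  # bits 1 and 2 share a block; bits 1 and 32 do not
  within <- cor(fp$bits[, 1], fp$bits[, 2])
  across <- cor(fp$bits[, 1], fp$bits[, 32])
  expect_gt(within, across + 0.2)
})

test_that("the noiseless spectrum is exactly the active-bit dictionary", {
  cfg <- generator_config(n_molecules = 5, d_bits = 8, n_blocks = 8,
                          peaks_per_active_bit = 1, mass_noise_sd = 0,
                          intensity_noise_sd = 0, peak_dropout_prob = 0,
                          n_noise_peaks = 2, seed = 74)
  ftab <- sample_fragment_table(cfg, 1)
  fp <- c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  sp <- spectrum_from_fingerprint(fp, ftab, cfg, id = "t", seed = 99)
  expect_equal(nrow(sp$peaks), 1 + 2)  # 1 signal + n_noise_peaks
  expect_true(any(abs(sp$peaks[, "mz"] - ftab[2, 1]) < 1e-9))

  # identical fingerprint and seed give identical spectra
  sp2 <- spectrum_from_fingerprint(fp, ftab, cfg, id = "t", seed = 99)
  expect_identical(sp$peaks, sp2$peaks)

  # a spectrum survives even when everything is dropped
  cfg_drop <- generator_config(n_molecules = 5, d_bits = 8, n_blocks = 8,
                               peak_dropout_prob = 1, n_noise_peaks = 0,
                               seed = 74)
  sp3 <- spectrum_from_fingerprint(fp, ftab, cfg_drop, id = "t", seed = 1)
  expect_gte(nrow(sp3$peaks), 1)
})

test_that("fingerprint similarity carries over to PPK similarity", {
  cfg <- generator_config(n_molecules = 4, d_bits = 40, n_blocks = 40,
                          mass_noise_sd = 0, intensity_noise_sd = 0,
                          peak_dropout_prob = 0, n_noise_peaks = 0, seed = 75)
  ftab <- sample_fragment_table(cfg, 1)
  base <- c(rep(1L, 20), rep(0L, 20))
  similar <- base; similar[1:2] <- 0L       # shares 90% of active bits
  far <- c(rep(0L, 20), rep(1L, 20)); far[1:2] <- 1L  # shares 10%
  p <- ppk_params(0.05, 0.5)
  wins <- vapply(1:20, function(s) {
    s_base <- spectrum_from_fingerprint(base, ftab, cfg, "b", seed = 1000 + s)
    s_sim <- spectrum_from_fingerprint(similar, ftab, cfg, "s", seed = 2000 + s)
    s_far <- spectrum_from_fingerprint(far, ftab, cfg, "f", seed = 3000 + s)
    ppk(s_base, s_sim, p) > ppk(s_base, s_far, p)
  }, logical(1))
  expect_true(all(wins))
})

test_that("candidate sets contain the truth and honour the flip count", {
  cfg <- generator_config(n_molecules = 10, d_bits = 32, n_blocks = 8,
                          candidates_per_query = 2, near_decoy_flip_bits = 1,
                          far_decoy_frac = 0, seed = 76)
  fp <- sample_fingerprints(cfg)
  cs <- make_candidate_sets(fp, cfg)
  expect_length(cs$candidates$unrankable, 0L)
  dt <- build_delta_table(cs$candidates, cs$fingerprints)
  for (q in names(dt)) {
    expect_equal(sort(unname(dt[[q]])), c(0, 1 / 32))  # decoy differs by 1 bit
  }
  # seeded determinism
  cs2 <- make_candidate_sets(fp, cfg)
  expect_identical(cs$candidates$candidates, cs2$candidates$candidates)
})

test_that("a benchmark yields MGF-writable views over the same molecules", {
  cfg <- generator_config(n_molecules = 12, n_views = 2,
                          candidates_per_query = 4, seed = 77)
  b <- generate_benchmark(cfg)
  expect_length(b$views, 2L)
  ids1 <- vapply(b$views$view1, `[[`, "", "id")
  ids2 <- vapply(b$views$view2, `[[`, "", "id")
  expect_setequal(ids1, ids2)
  expect_setequal(ids1, b$molecule_fingerprints$ids)
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(b$views$view1, f)
  back <- read_mgf(f)
  expect_equal(vapply(back, `[[`, "", "id"), ids1)

  # benchmark regeneration is exactly reproducible
  b2 <- generate_benchmark(cfg)
  expect_identical(b$views$view1[[3]]$peaks, b2$views$view1[[3]]$peaks)
  expect_identical(b$fingerprints$bits, b2$fingerprints$bits)
})

test_that("noiseless strong-signal data is interpolated end to end", {
  cfg <- generator_config(n_molecules = 20, d_bits = 48, n_blocks = 48,
                          mass_noise_sd = 1e-4, intensity_noise_sd = 0,
                          peak_dropout_prob = 0, n_noise_peaks = 0,
                          candidates_per_query = 8, n_views = 1, seed = 78)
  b <- generate_benchmark(cfg)
  mols <- b$molecule_fingerprints$ids
  Kx <- normalize_kernel(center_train(ppk_matrix(b$views$view1,
                                                 params = ppk_params(0.01, 0.5))))
  Ky_raw <- linear_fp_kernel(b$fingerprints)
  # training-set queries with truth among candidates, lambda ~ 0
  Ky_tr_raw <- kernel_matrix(Ky_raw$values[mols, mols])
  Ky_tr <- normalize_kernel(center_train(Ky_tr_raw))
  m <- iokr(Kx, Ky_tr, lambda = 1e-6)
  hits <- vapply(seq_along(mols), function(i) {
    q <- mols[i]
    ids <- b$candidates$candidates[[q]]
    cross <- kernel_matrix(Ky_raw$values[ids, mols, drop = FALSE],
                           row_ids = paste0(ids, "#c"), col_ids = mols)
    crossc <- normalize_kernel(center_cross(cross, Ky_tr_raw,
                                            row_self_raw = rowSums(b$fingerprints$bits[ids, , drop = FALSE])))
    a <- iokr_alpha(m, Kx$values[, i])
    s <- cosine_scores(a, m, t(crossc$values), 1)
    rank_candidates(s, ids, q)$rank_of_truth == 1L
  }, logical(1))
  expect_true(all(hits))
})

test_that("harder noise never helps identification", {
  top1_at_noise <- function(mass_sd, seed) {
    cfg <- generator_config(n_molecules = 24, d_bits = 48, n_blocks = 24,
                            mass_noise_sd = mass_sd, candidates_per_query = 6,
                            n_views = 1, peak_dropout_prob = 0.05, seed = seed)
    b <- generate_benchmark(cfg)
    rep <- run_protocol(b, ppk = ppk_params(0.02, 0.3),
                        output_kernels = "linear",
                        lambda_grid = c(0.01, 0.1), gamma_grid = 1,
                        fusion = list(lambda_grid = 0.1, batch_size = 5,
                                      epochs = 5),
                        n_folds = 4, seed = seed)
    rep$topk["view1.linear.forward", "top1"]
  }
  easy <- vapply(1:3, function(s) top1_at_noise(0.005, 80 + s), numeric(1))
  hard <- vapply(1:3, function(s) top1_at_noise(5, 80 + s), numeric(1))
  # one binomial standard error at n = 24 queries, p ~ mean accuracy
  p_hat <- mean(c(easy, hard)) / 100
  se <- 100 * sqrt(max(p_hat * (1 - p_hat), 0.01) / 24)
  expect_lt(mean(hard), mean(easy) + se)
})

test_that("the centered input kernel aligns with the centered output kernel", {
  cfg <- generator_config(n_molecules = 20, d_bits = 48, n_blocks = 24,
                          mass_noise_sd = 0, intensity_noise_sd = 0,
                          peak_dropout_prob = 0, n_noise_peaks = 0,
                          n_views = 1, seed = 82)
  b <- generate_benchmark(cfg)
  Kx <- center_train(ppk_matrix(b$views$view1, params = ppk_params(0.02, 0.5)))$values
  Ky <- center_train(tanimoto_kernel(b$molecule_fingerprints))$values
  alignment <- function(A, B) sum(A * B) / sqrt(sum(A * A) * sum(B * B))
  a_true <- alignment(Kx, Ky)
  expect_gt(a_true, 0)
  set.seed(83)
  perms <- vapply(1:20, function(i) {
    p <- sample(nrow(Ky))
    alignment(Kx, Ky[p, p])
  }, numeric(1))
  expect_true(all(a_true > perms))
})
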