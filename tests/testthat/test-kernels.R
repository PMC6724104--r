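# Input kernel on spectra (probability product kernel), output kernels on
# fingerprints, and the centering / normalization / combination machinery.

test_that("PPK matches its closed form on single peaks and its brute-force sum", {
  p <- ppk_params(0.5, 0.3)
  a <- ms_spectrum("a", cbind(100, 1))
  # self kernel of one peak: all exponents zero
  expect_equal(ppk(a, a, p), 1 / (4 * pi * 0.5 * 0.3))

  # far-apart peaks: Gaussian tail kills the value
  b <- ms_spectrum("b", cbind(900, 1))
  expect_lt(ppk(a, b, ppk_params(0.01, 1)), 1e-300)

  # 2x3-peak brute-force double sum
  x <- ms_spectrum("x", cbind(c(100, 150), c(1, 0.5)))
  y <- ms_spectrum("y", cbind(c(100.5, 149, 300), c(0.9, 0.4, 0.1)))
  p1 <- ppk_params(1, 1)
  expect_equal(ppk(x, y, p1), ppk_bruteforce(x, y, 1, 1), tolerance = 1e-12)
  expect_equal(ppk(x, y, p1, rescale = FALSE),
               ppk_bruteforce(x, y, 1, 1, rescale = FALSE), tolerance = 1e-12)
  # symmetry
  expect_equal(ppk(x, y, p1), ppk(y, x, p1), tolerance = 1e-14)
  expect_error(ppk_params(-1, 1), "positive")
})

test_that("ppk_matrix agrees elementwise with ppk and is symmetric PSD", {
  p <- ppk_params(0.8, 0.4)
  one <- random_spectra(1, seed = 11)
  K1 <- ppk_matrix(one, one, p)
  expect_equal(dim(K1), c(1L, 1L))
  expect_equal(K1$values[1, 1], ppk(one[[1]], one[[1]], p))

  sp <- random_spectra(5, seed = 12)
  K <- ppk_matrix(sp, sp, p)
  expect_lt(max(abs(K$values - t(K$values))), 1e-12)
  expect_gte(min_eig_ratio(K), -1e-8)

  rows <- random_spectra(2, seed = 13)
  cols <- random_spectra(3, seed = 14)
  Kr <- ppk_matrix(rows, cols, p)
  expect_equal(dim(Kr), c(2L, 3L))
  for (i in 1:2) for (j in 1:3) {
    expect_equal(Kr$values[i, j], ppk(rows[[i]], cols[[j]], p), tolerance = 1e-12)
  }
})

test_that("fingerprint kernels give the expected closed-form values", {
  m <- rbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 1L), c = c(0L, 0L, 1L))
  fp <- fingerprint_table(m)
  Kl <- linear_fp_kernel(fp, fp)
  expect_equal(Kl$values["a", "b"], 1)           # one shared active bit
  expect_equal(Kl$values["a", "a"], 2)           # self dot = #active bits
  Kt <- tanimoto_kernel(fp, fp)
  expect_equal(Kt$values["a", "b"], 1 / 3)       # |int|=1, |union|=3
  expect_equal(unname(diag(Kt$values)), rep(1, 3))
  expect_equal(Kt$values["a", "c"], 0)           # disjoint supports
  expect_true(all(Kt$values >= 0 & Kt$values <= 1))

  g <- gaussian_params(0.5)
  Kg <- gaussian_fp_kernel(fp, fp, g)
  expect_equal(unname(diag(Kg$values)), rep(1, 3))
  expect_equal(Kg$values["a", "b"], exp(-1))     # Hamming distance 2, gamma 0.5
  # monotone decreasing in gamma for distinct pairs
  Kg2 <- gaussian_fp_kernel(fp, fp, gaussian_params(5))
  expect_lt(Kg2$values["a", "b"], Kg$values["a", "b"])

  Kgt <- gaussian_tanimoto_kernel(fp, fp, gaussian_params(1))
  expect_equal(unname(diag(Kgt$values)), rep(1, 3))
  expect_equal(Kgt$values["a", "b"], exp(-(1 + 1 - 2 / 3)))
  # monotone in (1 - k_tan): c is further from a than b is
  expect_lt(Kgt$values["a", "c"], Kgt$values["a", "b"])
  expect_error(gaussian_params(0), "positive")
})

test_that("all-zero fingerprint pair takes the Tanimoto convention value 1", {
  m <- rbind(z1 = c(0L, 0L), z2 = c(0L, 0L), a = c(1L, 0L))
  expect_message(Kt <- tanimoto_kernel(fingerprint_table(m)), "convention")
  expect_equal(Kt$values["z1", "z2"], 1)
  expect_equal(Kt$values["z1", "a"], 0)
})

test_that("fingerprint Gram matrices are PSD on random instances", {
  fp <- random_fps(20, 32, seed = 21)
  g <- gaussian_params(0.1)
  for (K in list(linear_fp_kernel(fp), tanimoto_kernel(fp),
                 gaussian_fp_kernel(fp, fp, g),
                 gaussian_tanimoto_kernel(fp, fp, g))) {
    expect_gte(min_eig_ratio(K), -1e-8)
    expect_lt(max(abs(K$values - t(K$values))), 1e-12)
  }
})

test_that("center_train has the defining zero-sum property", {
  expect_equal(center_train(kernel_matrix(matrix(3, 1, 1, dimnames = list("a", "a"))))$values[1, 1], 0)

  K2 <- center_train(kernel_matrix(diag(2), row_ids = c("a", "b"),
                                   col_ids = c("a", "b")))
  expect_equal(unname(K2$values), matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))

  set.seed(31)
  V <- crossprod(matrix(rnorm(50 * 50), 50, 50))
  rownames(V) <- colnames(V) <- sprintf("s%02d", 1:50)
  Kc <- center_train(kernel_matrix(V))
  expect_lt(max(abs(rowSums(Kc$values))), 1e-8)
  expect_lt(max(abs(colSums(Kc$values))), 1e-8)
  expect_error(center_train(Kc), "already centered")
})

test_that("center_cross reproduces center_train and the four-term formula", {
  set.seed(32)
  V <- crossprod(matrix(rnorm(36), 6, 6))
  ids <- letters[1:6]
  rownames(V) <- colnames(V) <- ids
  K_raw <- kernel_matrix(V)
  K_tr <- center_train(K_raw)

  # consistency: centering the training matrix as a cross matrix is identical
  cross <- center_cross(kernel_matrix(V, row_ids = paste0(ids, "_q"),
                                      col_ids = ids),
                        K_raw, row_self_raw = diag(V))
  expect_equal(unname(cross$values), unname(K_tr$values), tolerance = 1e-10)
  expect_equal(unname(cross$self_diagonals$row), unname(diag(K_tr$values)),
               tolerance = 1e-10)

  # 1 test x 2 train hand expansion
  Vt <- matrix(c(2, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  kq <- matrix(c(0.3, 0.7), 1, 2, dimnames = list("q", c("a", "b")))
  out <- center_cross(kernel_matrix(kq), kernel_matrix(Vt))
  g <- mean(Vt)
  expect_equal(out$values[1, 1], 0.3 - mean(c(0.3, 0.7)) - mean(Vt[, 1]) + g)
  expect_equal(out$values[1, 2], 0.7 - mean(c(0.3, 0.7)) - mean(Vt[, 2]) + g)
  # per-train-column sums over the test points need not vanish (only the
  # train-side means are centered; sums along each test row cancel exactly)
  kq2 <- matrix(c(0.3, 0.7, 1.1, 0.2), 2, 2,
                dimnames = list(c("q1", "q2"), c("a", "b")))
  out2 <- center_cross(kernel_matrix(kq2), kernel_matrix(Vt))
  expect_gt(max(abs(colSums(out2$values))), 1e-8)
})

test_that("normalize_kernel gives unit diagonal, is idempotent, flags degeneracy", {
  V <- matrix(c(4, 2, 2, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  Kn <- normalize_kernel(kernel_matrix(V))
  expect_equal(unname(Kn$values), matrix(1, 2, 2))  # rank-one case

  fp <- random_fps(10, 24, seed = 41)
  K <- normalize_kernel(center_train(linear_fp_kernel(fp)))
  expect_equal(unname(diag(K$values)), rep(1, 10))
  expect_true(all(abs(K$values) <= 1 + 1e-10))
  expect_equal(normalize_kernel(K)$values, K$values, tolerance = 1e-12)
  expect_lt(max(abs(K$values - t(K$values))), 1e-12)

  V2 <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("a", "dgn"), c("a", "dgn")))
  expect_error(normalize_kernel(kernel_matrix(V2)), "dgn")
})

test_that("unimkl_combine averages entrywise and preserves PSD", {
  mk <- function(V) {
    rownames(V) <- colnames(V) <- c("a", "b")
    kernel_matrix(V, centered = TRUE, normalized = TRUE)
  }
  K1 <- mk(diag(2))
  K2 <- mk(matrix(1, 2, 2))
  comb <- unimkl_combine(list(K1, K2))
  expect_equal(unname(comb$values), matrix(c(1, 0.5, 0.5, 1), 2, 2))
  expect_true(comb$centered)
  expect_false(comb$normalized)

  one <- unimkl_combine(list(K1))
  expect_equal(one$values, K1$values)

  set.seed(42)
  Ks <- lapply(1:3, function(i) {
    V <- crossprod(matrix(rnorm(400), 20, 20))
    rownames(V) <- colnames(V) <- sprintf("s%02d", 1:20)
    normalize_kernel(center_train(kernel_matrix(V)))
  })
  expect_gte(min_eig_ratio(unimkl_combine(Ks)), -1e-8)

  K3 <- mk(diag(2)); K3$row_ids <- K3$col_ids <- c("x", "y")
  expect_error(unimkl_combine(list(K1, K3)), "mismatch")
  expect_error(unimkl_combine(list()), "empty")
})

test_that("entropy-based gamma selection matches an exhaustive oracle", {
  expect_equal(select_gamma_by_entropy(c(1, 2, 3), 0.7)$gamma, 0.7)

  # single off-diagonal distance: entropy identical for all gammas -> smallest
  expect_equal(select_gamma_by_entropy(2, c(0.1, 1, 10))$gamma, 0.1)

  fp <- random_fps(50, 32, seed = 43)
  d2 <- as.vector(dist(fp$bits))^2
  grid <- 10^seq(-3, 1, length.out = 9)
  picked <- select_gamma_by_entropy(d2, grid)$gamma
  ent <- vapply(grid, function(g) {
    v <- exp(-g * d2)
    cnt <- tabulate(pmin(100L, floor(v * 100) + 1L), nbins = 100L)
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log(p))
  }, numeric(1))
  expect_equal(picked, grid[which.max(ent)])
  expect_error(select_gamma_by_entropy(c(0, 0), c(1, 2)), "degenerate")
  expect_error(select_gamma_by_entropy(c(1, 2), numeric(0)), "empty")
})
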