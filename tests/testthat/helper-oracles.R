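# Independent oracles and small fixture builders used across the test files.
# The oracles deliberately avoid the package's kernel-trick code paths: they
# work with explicit feature matrices and dense solves.

# Brute-force probability product kernel: literal double sum over peak pairs.
ppk_bruteforce <- function(a, b, sigma_m, sigma_i, rescale = TRUE) {
  pa <- a$peaks; pb <- b$peaks
  if (rescale) {
    pa[, 2] <- pa[, 2] / max(pa[, 2])
    pb[, 2] <- pb[, 2] / max(pb[, 2])
  }
  s <- 0
  for (l1 in seq_len(nrow(pa))) {
    for (l2 in seq_len(nrow(pb))) {
      s <- s + exp(-(pa[l1, 1] - pb[l2, 1])^2 / (4 * sigma_m^2)) *
        exp(-(pa[l1, 2] - pb[l2, 2])^2 / (4 * sigma_i^2))
    }
  }
  as.numeric(s / (nrow(pa) * nrow(pb)) / (4 * pi * sigma_m * sigma_i))
}

# Explicit-feature ridge oracle for the forward direction with linear
# kernels: given input features X (l x p) and output features Y (l x q),
# predictions h(x) = Y' (lambda I + X X')^{-1} X x, and squared Euclidean
# distances to candidate feature vectors.
forward_oracle <- function(X, Y, lambda, X_query, Y_cand) {
  KX <- X %*% t(X)
  d2 <- matrix(NA_real_, nrow(X_query), nrow(Y_cand))
  for (i in seq_len(nrow(X_query))) {
    a <- solve(KX + diag(lambda, nrow(X)), X %*% X_query[i, ])
    h <- drop(t(Y) %*% a)
    for (j in seq_len(nrow(Y_cand))) {
      d2[i, j] <- sum((h - Y_cand[j, ])^2)
    }
  }
  d2
}

# Reverse-direction oracle: g(y) = X' (lambda I + Y Y')^{-1} Y y, distances in
# the input feature space to each query x.
reverse_oracle <- function(X, Y, lambda, X_query, Y_cand) {
  KY <- Y %*% t(Y)
  d2 <- matrix(NA_real_, nrow(X_query), nrow(Y_cand))
  B <- solve(KY + diag(lambda, nrow(Y)), Y %*% t(Y_cand))  # l x n_c
  G <- t(X) %*% B                                          # p x n_c predictions
  for (i in seq_len(nrow(X_query))) {
    d2[i, ] <- colSums((G - X_query[i, ])^2)
  }
  d2
}

# Random spectra for kernel-shape tests (not tied to any fingerprint model).
random_spectra <- function(n, seed = 1, n_peaks = 5:10) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(n_peaks, 1)
    ms_spectrum(sprintf("s%02d", i),
                cbind(sort(runif(k, 50, 500)), runif(k, 0.1, 1)))
  })
}

random_fps <- function(n, d, seed = 1, p = 0.4) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n * d, 1, p), n, d)
    if (all(rowSums(m) > 0) && !anyDuplicated(m)) break
  }
  rownames(m) <- sprintf("m%02d", seq_len(n))
  fingerprint_table(m)
}

min_eig_ratio <- function(K) {
  v <- if (inherits(K, "kernel_matrix")) K$values else K
  min(eigen((v + t(v)) / 2, symmetric = TRUE, only.values = TRUE)$values) /
    max(sum(diag(v)), .Machine$double.eps)
}
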