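# Feature-space centering, cosine normalization, uniform multiple-kernel
# combination and entropy-based bandwidth selection. The processing order used
# throughout the package is: center first, then normalize — the resulting
# kernel is the cosine similarity in the centered feature space.

#' Center a training Gram matrix in feature space
#'
#' Subtracts the feature-space mean of the training points:
#' `K_c = K - 1 colmeans/l - rowmeans 1'/l + grandmean`. Every row and column
#' of the result sums to zero (within round-off). The raw diagonal is retained
#' in `self_diagonals` so cross matrices against this training set can be
#' normalized later. Centering an already-centered matrix is an error: double
#' centering is numerically silent and a classic source of bugs.
#'
#' @param K square, symmetric, uncentered [kernel_matrix()].
#' @return centered [kernel_matrix()] (`centered = TRUE`).
#' @export
center_train <- function(K) {
  stopifnot(inherits(K, "kernel_matrix"))
  if (!km_is_square(K)) stopf("center_train expects a square training kernel")
  if (K$centered) stopf("kernel is already centered (double centering refused)")
  V <- K$values
  rm_ <- rowMeans(V); cm_ <- colMeans(V); g <- mean(V)
  Vc <- sweep(sweep(V, 2L, cm_), 1L, rm_) + g
  kernel_matrix(Vc, row_ids = K$row_ids, col_ids = K$col_ids,
                centered = TRUE, normalized = FALSE,
                self_diagonals = list(row = diag(V), col = diag(V)))
}

#' Center a cross (new-by-train) kernel matrix with training statistics
#'
#' Rows are new points (e.g. test spectra or candidate molecules), columns the
#' training set. Each entry is centered using training means only:
#' `k_c(x, x_j) = k(x, x_j) - mean_j' k(x, x_j') - mean_i k(x_i, x_j) +
#' grandmean(K_train)`. Applying this to the training matrix itself reproduces
#' [center_train()]. Sums along each centered row cancel exactly (the column
#' means of the training kernel average to its grand mean), but sums over the
#' new points in each train column do not: only train-side statistics enter
#' the centering.
#'
#' If `row_self_raw` (raw self-kernels `k(x, x)` of the new points) is
#' supplied, the centered self values
#' `k(x,x) - 2 mean_j k(x, x_j) + grandmean` are stored in
#' `self_diagonals$row` for later normalization; `self_diagonals$col` holds
#' the centered training diagonal.
#'
#' @param K_cross rectangular new-by-train [kernel_matrix()], columns aligned
#'   with `K_train_raw`.
#' @param K_train_raw square uncentered training [kernel_matrix()].
#' @param row_self_raw optional numeric vector of raw self-kernels of the new
#'   points, aligned with the rows of `K_cross`.
#' @return centered [kernel_matrix()].
#' @export
center_cross <- function(K_cross, K_train_raw, row_self_raw = NULL) {
  stopifnot(inherits(K_cross, "kernel_matrix"),
            inherits(K_train_raw, "kernel_matrix"))
  if (K_train_raw$centered) stopf("K_train_raw must be the uncentered training kernel")
  if (!identical(K_cross$col_ids, K_train_raw$col_ids)) {
    stopf("cross-matrix columns are not aligned with the training kernel ids")
  }
  Vt <- K_train_raw$values
  cm_train <- colMeans(Vt)   # mean_i k(x_i, x_j) per training column j
  g <- mean(Vt)
  V <- K_cross$values
  row_means <- rowMeans(V)   # mean_j' k(x, x_j') per new point
  Vc <- sweep(sweep(V, 1L, row_means), 2L, cm_train) + g
  self_d <- NULL
  train_centered_diag <- diag(Vt) - 2 * cm_train + g
  if (!is.null(row_self_raw)) {
    if (length(row_self_raw) != nrow(V)) {
      stopf("row_self_raw length %d does not match %d rows",
            length(row_self_raw), nrow(V))
    }
    self_d <- list(row = row_self_raw - 2 * row_means + g,
                   col = train_centered_diag)
  } else {
    self_d <- list(row = NULL, col = train_centered_diag)
  }
  kernel_matrix(Vc, row_ids = K_cross$row_ids, col_ids = K_cross$col_ids,
                centered = TRUE, normalized = FALSE, self_diagonals = self_d)
}

#' Cosine-normalize a kernel matrix
#'
#' Divides each entry by the geometric mean of the two self-kernels:
#' `k(x, x') / sqrt(k(x,x) k(x',x'))`. For a square matrix the self values
#' default to the diagonal; for cross matrices they default to the
#' `self_diagonals` recorded by [center_cross()] and must be consistent with
#' the matrix's preprocessing. The square result has unit diagonal and values
#' in `[-1, 1]`; the operation is idempotent. A self value at or below 1e-12
#' (a degenerate point, e.g. the centered duplicate of the whole dataset)
#' raises an error naming the offending id.
#'
#' @param K [kernel_matrix()].
#' @param row_self,col_self optional numeric self-kernel vectors.
#' @return normalized [kernel_matrix()] (`normalized = TRUE`).
#' @export
normalize_kernel <- function(K, row_self = NULL, col_self = NULL) {
  stopifnot(inherits(K, "kernel_matrix"))
  square <- km_is_square(K)
  if (is.null(row_self)) {
    row_self <- if (square) diag(K$values) else K$self_diagonals$row
  }
  if (is.null(col_self)) {
    col_self <- if (square) diag(K$values) else K$self_diagonals$col
  }
  if (is.null(row_self) || is.null(col_self)) {
    stopf("self-kernel values are required to normalize a cross matrix")
  }
  bad <- which(row_self <= 1e-12)
  if (length(bad)) {
    stopf("degenerate self-kernel (<= 1e-12) for id '%s'", K$row_ids[bad[1L]])
  }
  bad <- which(col_self <= 1e-12)
  if (length(bad)) {
    stopf("degenerate self-kernel (<= 1e-12) for id '%s'", K$col_ids[bad[1L]])
  }
  Vn <- K$values / sqrt(outer(row_self, col_self))
  if (square) Vn <- (Vn + t(Vn)) / 2
  kernel_matrix(Vn, row_ids = K$row_ids, col_ids = K$col_ids,
                centered = K$centered, normalized = TRUE,
                self_diagonals = list(row = rep(1, nrow(Vn)),
                                      col = rep(1, ncol(Vn))))
}

#' Uniform multiple-kernel combination
#'
#' Combines input kernels with equal weight by taking the entrywise mean of
#' centered and normalized Gram matrices — equivalent to uniform-weight
#' summation up to a scale that pre-image ranking and cosine scores are
#' invariant to. The result is flagged centered but not normalized; callers
#' re-normalize (a no-op when all inputs had unit diagonal, but kept explicit
#' so the flag honestly describes the matrix).
#'
#' @param Ks non-empty list of square [kernel_matrix()] objects with identical
#'   ids, all centered and normalized.
#' @return combined [kernel_matrix()].
#' @export
unimkl_combine <- function(Ks) {
  if (length(Ks) == 0L) stopf("empty kernel list")
  ref <- Ks[[1L]]
  for (K in Ks) {
    stopifnot(inherits(K, "kernel_matrix"))
    if (!km_is_square(K)) stopf("unimkl_combine expects square kernels")
    if (!K$centered || !K$normalized) {
      stopf("unimkl_combine expects centered and normalized kernels")
    }
    if (!identical(K$row_ids, ref$row_ids)) {
      stopf("kernel id mismatch in unimkl_combine")
    }
  }
  V <- Reduce(`+`, lapply(Ks, `[[`, "values")) / length(Ks)
  kernel_matrix(V, row_ids = ref$row_ids, col_ids = ref$col_ids,
                centered = TRUE, normalized = FALSE,
                self_diagonals = list(row = diag(V), col = diag(V)))
}

# Entrywise-mean combination for cross matrices (same convention as
# unimkl_combine); self_diagonals are averaged alongside.
unimkl_combine_cross <- function(Ks) {
  if (length(Ks) == 0L) stopf("empty kernel list")
  ref <- Ks[[1L]]
  for (K in Ks) {
    if (!identical(K$row_ids, ref$row_ids) || !identical(K$col_ids, ref$col_ids)) {
      stopf("kernel id mismatch in unimkl_combine_cross")
    }
  }
  V <- Reduce(`+`, lapply(Ks, `[[`, "values")) / length(Ks)
  rs <- lapply(Ks, function(K) K$self_diagonals$row)
  cs <- lapply(Ks, function(K) K$self_diagonals$col)
  self_d <- list(
    row = if (all(!vapply(rs, is.null, logical(1)))) Reduce(`+`, rs) / length(rs) else NULL,
    col = if (all(!vapply(cs, is.null, logical(1)))) Reduce(`+`, cs) / length(cs) else NULL
  )
  kernel_matrix(V, row_ids = ref$row_ids, col_ids = ref$col_ids,
                centered = ref$centered, normalized = FALSE,
                self_diagonals = self_d)
}

#' Select a Gaussian bandwidth by entropy maximization
#'
#' For each gamma in the grid, the kernel values `exp(-gamma * d2)` over all
#' supplied squared distances (off-diagonal pairs of the training fold) are
#' binned into 100 equal-width bins on `[0, 1]` and the Shannon entropy of the
#' bin distribution is computed; the gamma with maximal entropy is returned.
#' Ties break to the smaller gamma. A very small or very large gamma pushes
#' all values towards 1 or 0 (entropy near zero); the maximum-entropy gamma
#' spreads kernel values over their range.
#'
#' @param dist2 numeric vector of pairwise squared feature-space distances
#'   (training pairs only, diagonal excluded).
#' @param grid non-empty vector of positive gamma values.
#' @return a [gaussian_params()] holding the selected gamma.
#' @export
select_gamma_by_entropy <- function(dist2, grid) {
  if (length(grid) == 0L) stopf("empty gamma grid")
  if (any(grid <= 0)) stopf("gamma grid must be positive")
  if (length(dist2) == 0L) stopf("no distances supplied")
  if (all(dist2 == 0)) stopf("all pairwise distances are zero (degenerate dataset)")
  grid <- sort(grid)  # ties -> smaller gamma via which.max's first-hit rule
  ent <- vapply(grid, function(g) {
    v <- exp(-g * dist2)
    counts <- tabulate(pmin(100L, floor(v * 100) + 1L), nbins = 100L)
    p <- counts / sum(counts)
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  gaussian_params(grid[which.max(ent)])
}

# Pairwise squared feature-space distances among fingerprint rows, for the
# plain Gaussian (Hamming counts) and the Tanimoto feature space (2 - 2 k_tan).
fp_sq_distances <- function(fps, space = c("gaussian", "gaussian_tanimoto")) {
  space <- match.arg(space)
  F_ <- fp_bits(fps)
  if (space == "gaussian") {
    D2 <- outer(rowSums(F_), rowSums(F_), "+") - 2 * (F_ %*% t(F_))
  } else {
    D2 <- 2 - 2 * tanimoto_kernel(fps, fps)$values
  }
  D2[upper.tri(D2)]
}
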