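# Kernels on binary molecular fingerprints. All four return a kernel_matrix
# between the rows of two fingerprint tables (or 0/1 matrices with row names);
# the square case (same ids, same order) is symmetric and PSD.

fp_bits <- function(x) {
  if (inherits(x, "fingerprint_table")) return(x$bits)
  m <- as.matrix(x)
  if (is.null(rownames(m))) stopf("fingerprint matrix needs row names")
  storage.mode(m) <- "integer"
  m
}

check_same_d <- function(FA, FB) {
  if (ncol(FA) != ncol(FB)) {
    stopf("fingerprint length mismatch: %d vs %d bits", ncol(FA), ncol(FB))
  }
}

#' Linear kernel on fingerprints
#'
#' `k(y, y') = fp(y)' fp(y')`: the number of shared active bits, a
#' non-negative integer.
#'
#' @param A,B [fingerprint_table()] objects (or 0/1 matrices with row names)
#'   with the same bit count `d`.
#' @return a [kernel_matrix()].
#' @export
linear_fp_kernel <- function(A, B = A) {
  FA <- fp_bits(A); FB <- fp_bits(B)
  check_same_d(FA, FB)
  K <- FA %*% t(FB)
  kernel_matrix(K, row_ids = rownames(FA), col_ids = rownames(FB))
}

#' Tanimoto kernel on fingerprints
#'
#' `k(y, y') = |fp(y) ∩ fp(y')| / |fp(y) ∪ fp(y')|`, equivalently
#' `fp(y)'fp(y') / (||fp(y)||^2 + ||fp(y')||^2 - fp(y)'fp(y'))`. Values lie in
#' `[0, 1]`, with 1 exactly for identical non-zero vectors. The degenerate
#' 0/0 case of two all-zero fingerprints is defined as 1 by convention
#' (identical molecules) and logged once per call.
#'
#' @inheritParams linear_fp_kernel
#' @return a [kernel_matrix()].
#' @export
tanimoto_kernel <- function(A, B = A) {
  FA <- fp_bits(A); FB <- fp_bits(B)
  check_same_d(FA, FB)
  dot <- FA %*% t(FB)
  sa <- rowSums(FA); sb <- rowSums(FB)
  denom <- outer(sa, sb, "+") - dot
  zero <- denom == 0
  if (any(zero)) {
    iokr_log(sprintf("%d all-zero fingerprint pair(s): Tanimoto set to 1 by convention",
                     sum(zero)), level = "WARN")
    denom[zero] <- 1
    dot[zero] <- 1
  }
  kernel_matrix(dot / denom, row_ids = rownames(FA), col_ids = rownames(FB))
}

#' Gaussian parameters
#'
#' @param gamma strictly positive inverse squared bandwidth.
#' @export
gaussian_params <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0) stopf("gamma must be a positive number")
  structure(list(gamma = gamma), class = "gaussian_params")
}

#' Gaussian kernel on fingerprints
#'
#' `k(y, y') = exp(-gamma * ||fp(y) - fp(y')||^2)`. For binary vectors the
#' squared distance is the number of differing bits, so values lie in
#' `(0, 1]` with a unit diagonal.
#'
#' @inheritParams linear_fp_kernel
#' @param params [gaussian_params()] (or list with positive `gamma`).
#' @return a [kernel_matrix()].
#' @export
gaussian_fp_kernel <- function(A, B = A, params) {
  params <- gaussian_params(params$gamma)
  FA <- fp_bits(A); FB <- fp_bits(B)
  check_same_d(FA, FB)
  d2 <- outer(rowSums(FA), rowSums(FB), "+") - 2 * (FA %*% t(FB))
  kernel_matrix(exp(-params$gamma * d2),
                row_ids = rownames(FA), col_ids = rownames(FB))
}

#' Gaussian-Tanimoto kernel on fingerprints
#'
#' A Gaussian kernel in the feature space of the Tanimoto kernel:
#' `k(y, y') = exp(-gamma * (k_tan(y,y) + k_tan(y',y') - 2 k_tan(y,y')))`.
#' Since `k_tan(y, y) = 1`, the exponent is `2 - 2 k_tan(y, y')`; values lie
#' in `(0, 1]` with a unit diagonal and decrease monotonically in the
#' Tanimoto distance.
#'
#' @inheritParams gaussian_fp_kernel
#' @return a [kernel_matrix()].
#' @export
gaussian_tanimoto_kernel <- function(A, B = A, params) {
  params <- gaussian_params(params$gamma)
  Kt <- tanimoto_kernel(A, B)
  # self-Tanimoto is 1 for every fingerprint (all-zero handled by convention)
  kernel_matrix(exp(-params$gamma * (2 - 2 * Kt$values)),
                row_ids = Kt$row_ids, col_ids = Kt$col_ids)
}
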