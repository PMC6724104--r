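#' Fit an input-output kernel regression (IOKR) model
#'
#' Kernel ridge regression from the spectrum feature space into the
#' molecular-fingerprint feature space. Given training Gram matrices `K_X`
#' (input kernel on spectra) and `K_Y` (output kernel on molecules), both
#' centered and normalized in the same training order, the regression
#' `min_h sum_i ||h(x_i) - psi(y_i)||^2 + lambda ||h||^2` has the closed form
#' `h(x) = sum_i alpha_i(x) psi(y_i)` with
#' `alpha(x) = (lambda I + K_X)^{-1} k_X^x`. The model stores a Cholesky
#' factorization of `(lambda I + K_X)`; fitting cost is independent of any
#' candidate set. Centered kernels are singular by construction (rank at most
#' `l - 1`); `lambda > 0` restores positive definiteness, and a single jitter
#' of `1e-10 * trace / l` is added on the diagonal if the factorization still
#' fails from round-off, after which failure is an error.
#'
#' @param K_X square training input-kernel [kernel_matrix()] (or matrix),
#'   centered and normalized.
#' @param K_Y square training output-kernel [kernel_matrix()] (or matrix),
#'   same training order.
#' @param lambda positive ridge regularization parameter.
#' @return an object of class `iokr` with fields `train_ids`, `lambda`,
#'   `chol` (upper-triangular factor of `lambda I + K_X`), `K_Y` (matrix).
#' @seealso [iokr_alpha()], [candidate_sq_distances()], [cosine_scores()],
#'   [iokr_reverse()].
#' @export
iokr <- function(K_X, K_Y, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) stopf("lambda must be a positive number")
  KXv <- km_values(K_X)
  KYv <- km_values(K_Y)
  ids <- rownames(KXv) %||% as.character(seq_len(nrow(KXv)))
  if (nrow(KXv) != ncol(KXv) || nrow(KYv) != ncol(KYv)) {
    stopf("training kernels must be square")
  }
  if (nrow(KXv) != nrow(KYv)) {
    stopf("K_X (%d) and K_Y (%d) training sizes differ", nrow(KXv), nrow(KYv))
  }
  R <- chol_with_jitter(KXv + diag(lambda, nrow(KXv)))
  structure(list(train_ids = ids, lambda = lambda, chol = R, K_Y = KYv),
            class = "iokr")
}

chol_with_jitter <- function(M) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    jitter <- 1e-10 * sum(diag(M)) / nrow(M)
    iokr_log(sprintf("Cholesky failed; retrying once with jitter %.3e", jitter),
             level = "DEBUG")
    R <- tryCatch(chol(M + diag(jitter, nrow(M))), error = function(e) {
      stopf("Cholesky factorization failed even after jitter")
    })
  }
  R
}

# Apply the stored inverse factor: solve (lambda I + K) x = b for one or many
# right-hand sides.
solve_factor <- function(R, b) {
  backsolve(R, backsolve(R, as.matrix(b), transpose = TRUE))
}

#' @export
print.iokr <- function(x, ...) {
  cat(sprintf("iokr model: %d training examples, lambda = %g\n",
              length(x$train_ids), x$lambda))
  invisible(x)
}

#' Regression coefficients for query spectra
#'
#' `alpha(x) = (lambda I + K_X)^{-1} k_X^x`. The query kernel vector(s) must
#' be preprocessed (centered with training statistics, then normalized)
#' consistently with the training kernel. Multiple queries are solved as one
#' multi-right-hand-side triangular solve; results are identical to per-query
#' solves up to round-off.
#'
#' @param model an [iokr()] model.
#' @param k_x length-`l` vector, or `l x n_q` matrix of query kernel columns.
#' @return coefficient vector (one query) or `l x n_q` matrix.
#' @export
iokr_alpha <- function(model, k_x) {
  stopifnot(inherits(model, "iokr"))
  b <- as.matrix(k_x)
  if (nrow(b) != length(model$train_ids)) {
    stopf("query kernel length %d does not match %d training examples",
          nrow(b), length(model$train_ids))
  }
  A <- solve_factor(model$chol, b)
  if (ncol(A) == 1L) drop(A) else A
}

#' Squared pre-image distances to candidate molecules
#'
#' The pre-image search ranks candidates by the feature-space distance
#' `d^2(y) = alpha' K_Y alpha + k_y(y, y) - 2 alpha' k_Y^y` between the
#' prediction `h(x)` and each candidate's image `psi(y)`. Small negative
#' values from round-off are clipped to zero.
#'
#' @param a coefficient vector from [iokr_alpha()].
#' @param model an [iokr()] model.
#' @param k_Y_cand `l x n_c` matrix: output-kernel evaluations between
#'   training molecules (rows) and candidates (columns), preprocessed with
#'   training statistics.
#' @param cand_self length-`n_c` vector of candidate self-kernels `k_y(y, y)`
#'   under the same preprocessing (all 1 after normalization).
#' @return length-`n_c` vector of squared distances.
#' @export
candidate_sq_distances <- function(a, model, k_Y_cand, cand_self) {
  stopifnot(inherits(model, "iokr"))
  k_Y_cand <- as.matrix(k_Y_cand)
  if (nrow(k_Y_cand) != length(model$train_ids)) stopf("candidate cross-kernel misaligned")
  if (length(cand_self) == 1L) cand_self <- rep(cand_self, ncol(k_Y_cand))
  if (length(cand_self) != ncol(k_Y_cand)) stopf("cand_self length mismatch")
  a <- as.numeric(a)
  hh <- drop(crossprod(a, model$K_Y %*% a))
  d2 <- hh + cand_self - 2 * drop(crossprod(k_Y_cand, a))
  neg <- d2 < 0
  if (any(d2[neg] < -1e-8)) {
    iokr_log("squared distances below -1e-8 clipped to 0", level = "DEBUG")
  }
  d2[neg] <- 0
  d2
}

#' Cosine compatibility scores for candidate molecules
#'
#' `s(x, y) = <h(x), psi(y)> / (||h(x)|| ||psi(y)||)
#'          = alpha' k_Y^y / (sqrt(alpha' K_Y alpha) sqrt(k_y(y, y)))`.
#' Values lie in `[-1, 1]`. If the prediction norm `alpha' K_Y alpha` is at or
#' below 1e-12 (a degenerate prediction, e.g. `alpha = 0`), all scores are
#' defined as 0 and a warning is logged.
#'
#' @inheritParams candidate_sq_distances
#' @return length-`n_c` vector of cosine scores.
#' @export
cosine_scores <- function(a, model, k_Y_cand, cand_self) {
  stopifnot(inherits(model, "iokr"))
  k_Y_cand <- as.matrix(k_Y_cand)
  if (nrow(k_Y_cand) != length(model$train_ids)) stopf("candidate cross-kernel misaligned")
  if (length(cand_self) == 1L) cand_self <- rep(cand_self, ncol(k_Y_cand))
  a <- as.numeric(a)
  hh <- drop(crossprod(a, model$K_Y %*% a))
  if (hh <= 1e-12) {
    iokr_log("degenerate prediction norm; cosine scores set to 0", level = "WARN")
    return(rep(0, ncol(k_Y_cand)))
  }
  drop(crossprod(k_Y_cand, a)) / (sqrt(hh) * sqrt(cand_self))
}

#' Predict candidate scores or distances for query spectra
#'
#' Convenience wrapper chaining [iokr_alpha()] with [cosine_scores()] or
#' [candidate_sq_distances()] for one query.
#'
#' @param object an [iokr()] model.
#' @param k_x query kernel vector (preprocessed against the training set).
#' @param k_Y_cand,cand_self as in [candidate_sq_distances()].
#' @param type `"score"` (cosine, higher is better) or `"distance"` (squared
#'   pre-image distance, lower is better).
#' @param ... unused.
#' @return numeric vector over candidates.
#' @export
predict.iokr <- function(object, k_x, k_Y_cand, cand_self = 1,
                         type = c("score", "distance"), ...) {
  type <- match.arg(type)
  a <- iokr_alpha(object, k_x)
  if (type == "score") cosine_scores(a, object, k_Y_cand, cand_self)
  else candidate_sq_distances(a, object, k_Y_cand, cand_self)
}

#' Tune the ridge parameter by inner-CV mean squared error
#'
#' Estimates, for each lambda in the grid, the mean squared feature-space
#' error `||h(x_i) - psi(y_i)||^2` over held-out training points by inner
#' k-fold cross-validation, entirely with the kernel trick:
#' `alpha' K_Y alpha - 2 alpha' k_Y^{y_i} + k_y(y_i, y_i)`. Returns the
#' lambda minimizing the averaged MSE; ties break to the larger lambda (more
#' regularization). The supplied kernels are used as-is (no re-centering
#' inside the inner folds).
#'
#' @param K_X,K_Y square training kernels (matrices or [kernel_matrix()]),
#'   same order.
#' @param grid non-empty vector of positive lambdas.
#' @param n_folds number of inner folds (default 4).
#' @param seed integer seed for the fold shuffle.
#' @return the selected lambda (scalar).
#' @export
tune_lambda_by_mse <- function(K_X, K_Y, grid, n_folds = 4L, seed = 1L) {
  if (length(grid) == 0L) stopf("empty lambda grid")
  if (any(grid <= 0)) stopf("lambda grid must be positive")
  KXv <- km_values(K_X); KYv <- km_values(K_Y)
  l <- nrow(KXv)
  n_folds <- min(n_folds, l)
  if (n_folds < 2L) return(max(grid))
  fold <- with_seed(seed, sample(rep_len(seq_len(n_folds), l)))
  grid <- sort(grid)  # ascending; which.min keeps first, so reverse for tie -> larger
  mse <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    Kx_tr <- KXv[tr, tr, drop = FALSE]
    Kx_te <- KXv[tr, te, drop = FALSE]     # l_tr x n_te query columns
    Ky_tr <- KYv[tr, tr, drop = FALSE]
    Ky_te <- KYv[tr, te, drop = FALSE]
    ky_self <- diag(KYv)[te]
    for (j in seq_along(grid)) {
      R <- chol_with_jitter(Kx_tr + diag(grid[j], length(tr)))
      A <- solve_factor(R, Kx_te)          # l_tr x n_te
      quad <- colSums(A * (Ky_tr %*% A))
      cross <- colSums(A * Ky_te)
      mse[f, j] <- mean(quad - 2 * cross + ky_self)
    }
  }
  avg <- colMeans(mse)
  rev(grid)[which.min(rev(avg))]
}
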