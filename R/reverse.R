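#' Fit a reverse input-output kernel regression model
#'
#' The reverse direction regresses from the molecular-fingerprint feature
#' space into the spectrum feature space: `g(y) = sum_i beta_i(y) phi(x_i)`
#' with `beta(y) = (lambda I + K_Y)^{-1} k_Y^y`, the solution of
#' `min_g sum_i ||g(y_i) - phi(x_i)||^2 + lambda ||g||^2`. The pre-image then
#' becomes a nearest-neighbour search in the *input* feature space: the
#' candidate whose predicted spectrum embedding is closest to the observed
#' spectrum wins. Reversing the regression mitigates hubness in the
#' high-dimensional nearest-neighbour step. Per-query work grows with the
#' candidate count (one coefficient column per candidate), which is why this
#' direction is the computationally heavier one at prediction time.
#'
#' @param K_Y square training output kernel (centered + normalized), as a
#'   [kernel_matrix()] or matrix.
#' @param K_X square training input kernel, same order.
#' @param lambda positive ridge parameter.
#' @return object of class `iokr_reverse` with fields `train_ids`, `lambda`,
#'   `chol` (factor of `lambda I + K_Y`), `K_X`.
#' @seealso [iokr_beta()], [reverse_sq_distances()], [reverse_cosine_scores()]
#' @export
iokr_reverse <- function(K_Y, K_X, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) stopf("lambda must be a positive number")
  KYv <- km_values(K_Y)
  KXv <- km_values(K_X)
  ids <- rownames(KYv) %||% as.character(seq_len(nrow(KYv)))
  if (nrow(KYv) != ncol(KYv) || nrow(KXv) != ncol(KXv)) {
    stopf("training kernels must be square")
  }
  if (nrow(KYv) != nrow(KXv)) {
    stopf("K_Y (%d) and K_X (%d) training sizes differ", nrow(KYv), nrow(KXv))
  }
  R <- chol_with_jitter(KYv + diag(lambda, nrow(KYv)))
  structure(list(train_ids = ids, lambda = lambda, chol = R, K_X = KXv),
            class = "iokr_reverse")
}

#' @export
print.iokr_reverse <- function(x, ...) {
  cat(sprintf("iokr_reverse model: %d training examples, lambda = %g\n",
              length(x$train_ids), x$lambda))
  invisible(x)
}

#' Reverse-regression coefficients for candidate molecules
#'
#' One column per candidate: `beta(y) = (lambda I + K_Y)^{-1} k_Y^y`,
#' computed as a single multi-right-hand-side solve. Candidates recur across
#' queries, so in batch workflows the beta matrix for the union of a fold's
#' candidates is computed once and columns are reused.
#'
#' @param model an [iokr_reverse()] model.
#' @param k_Y_cand `l x n_c` matrix of output-kernel evaluations between
#'   training molecules and candidates, preprocessed with training statistics.
#' @return `l x n_c` coefficient matrix (columns named like the input).
#' @export
iokr_beta <- function(model, k_Y_cand) {
  stopifnot(inherits(model, "iokr_reverse"))
  b <- as.matrix(k_Y_cand)
  if (nrow(b) != length(model$train_ids)) {
    stopf("candidate kernel rows %d do not match %d training examples",
          nrow(b), length(model$train_ids))
  }
  solve_factor(model$chol, b)
}

#' Squared input-space pre-image distances
#'
#' `d^2(y) = beta(y)' K_X beta(y) + k_x(x, x) - 2 beta(y)' k_X^x` for every
#' candidate column of `B` against one query spectrum. Negative round-off is
#' clipped to zero.
#'
#' @param B `l x n_c` coefficient matrix from [iokr_beta()].
#' @param model an [iokr_reverse()] model.
#' @param k_x_query length-`l` input-kernel vector of the query against the
#'   training spectra, preprocessed with training statistics.
#' @param k_xx the query's preprocessed self-kernel (1 when normalized).
#' @return length-`n_c` vector of squared distances.
#' @export
reverse_sq_distances <- function(B, model, k_x_query, k_xx = 1) {
  stopifnot(inherits(model, "iokr_reverse"))
  B <- as.matrix(B)
  if (nrow(B) != length(model$train_ids)) stopf("beta matrix misaligned")
  if (length(k_x_query) != nrow(B)) stopf("query kernel vector misaligned")
  quad <- colSums(B * (model$K_X %*% B))
  d2 <- quad + k_xx - 2 * drop(crossprod(B, k_x_query))
  neg <- d2 < 0
  if (any(d2[neg] < -1e-8)) {
    iokr_log("squared distances below -1e-8 clipped to 0", level = "DEBUG")
  }
  d2[neg] <- 0
  d2
}

#' Cosine compatibility scores, reverse direction
#'
#' `s(x, y) = <g(y), phi(x)> / (||g(y)|| ||phi(x)||)
#'          = beta' k_X^x / (sqrt(beta' K_X beta) sqrt(k_x(x, x)))`.
#' A candidate with degenerate predicted norm (`beta' K_X beta <= 1e-12`)
#' gets score 0 with a logged warning.
#'
#' @inheritParams reverse_sq_distances
#' @return length-`n_c` vector of cosine scores.
#' @export
reverse_cosine_scores <- function(B, model, k_x_query, k_xx = 1) {
  stopifnot(inherits(model, "iokr_reverse"))
  B <- as.matrix(B)
  quad <- colSums(B * (model$K_X %*% B))
  cross <- drop(crossprod(B, k_x_query))
  out <- numeric(ncol(B))
  ok <- quad > 1e-12
  if (any(!ok)) {
    iokr_log(sprintf("%d candidate(s) with degenerate predicted norm scored 0",
                     sum(!ok)), level = "WARN")
  }
  out[ok] <- cross[ok] / (sqrt(quad[ok]) * sqrt(k_xx))
  out
}

#' Predict candidate scores or distances for one query, reverse direction
#'
#' @param object an [iokr_reverse()] model.
#' @param k_Y_cand candidate output-kernel matrix (see [iokr_beta()]).
#' @param k_x_query,k_xx as in [reverse_sq_distances()].
#' @param type `"score"` or `"distance"`.
#' @param ... unused.
#' @export
predict.iokr_reverse <- function(object, k_Y_cand, k_x_query, k_xx = 1,
                                 type = c("score", "distance"), ...) {
  type <- match.arg(type)
  B <- iokr_beta(object, k_Y_cand)
  if (type == "score") reverse_cosine_scores(B, object, k_x_query, k_xx)
  else reverse_sq_distances(B, object, k_x_query, k_xx)
}
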