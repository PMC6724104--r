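# Late fusion: combine the cosine scores of K kernel regression models with
# learned linear weights, by minimizing the margin-rescaled structured Hinge
# loss with mini-batch subgradient descent.

#' Per-query score tensor
#'
#' Collects, for every query, the compatibility scores of K models over that
#' query's candidate list: an `n_c x K` matrix with candidate ids as row names,
#' plus the index of the true candidate. All queries must share the same K
#' model names and all scores must be finite.
#'
#' @param model_names character vector of K model names.
#' @param scores named list (query id -> `n_c x K` numeric matrix with
#'   candidate ids as row names).
#' @param truth named character vector (query id -> true candidate id, which
#'   must appear among that query's rows).
#' @return object of class `score_tensor`.
#' @export
score_tensor <- function(model_names, scores, truth) {
  model_names <- as.character(model_names)
  K <- length(model_names)
  if (K < 1L) stopf("need at least one model")
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stopf("scores must be uniquely named by query id")
  }
  queries <- lapply(names(scores), function(q) {
    S <- as.matrix(scores[[q]])
    if (ncol(S) != K) stopf("query '%s' has %d score columns, expected %d", q, ncol(S), K)
    if (any(!is.finite(S))) stopf("non-finite scores for query '%s'", q)
    if (is.null(rownames(S))) stopf("query '%s' score matrix needs candidate row names", q)
    t_id <- truth[[q]]
    if (is.null(t_id) || !t_id %in% rownames(S)) {
      stopf("true candidate for query '%s' is missing from its score matrix", q)
    }
    colnames(S) <- model_names
    list(candidate_ids = rownames(S), scores = S,
         true_idx = match(t_id, rownames(S)))
  })
  names(queries) <- names(scores)
  structure(list(model_names = model_names, queries = queries),
            class = "score_tensor")
}

#' @export
print.score_tensor <- function(x, ...) {
  nc <- vapply(x$queries, function(q) nrow(q$scores), integer(1))
  cat(sprintf("score_tensor: %d queries x %d models, %d-%d candidates\n",
              length(x$queries), length(x$model_names), min(nc), max(nc)))
  invisible(x)
}

#' Normalized Hamming distance between two fingerprints
#'
#' `Delta(y, y') = (1/d) * #(differing bits)`, in `[0, 1]`; 0 iff identical.
#'
#' @param fp_a,fp_b binary vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
hamming_delta <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    stopf("fingerprint length mismatch: %d vs %d", length(fp_a), length(fp_b))
  }
  if (length(fp_a) == 0L) stopf("empty fingerprints")
  mean(fp_a != fp_b)
}

#' Structural loss table over candidate sets
#'
#' For each query, the normalized Hamming distance between the true molecule's
#' fingerprint and every candidate's fingerprint, aligned with the candidate
#' list. The entry at the true candidate is exactly 0.
#'
#' @param cands a [candidate_sets()].
#' @param fps a [fingerprint_table()] resolving every candidate and truth id.
#' @return named list (query id -> named numeric vector of Delta values).
#' @export
build_delta_table <- function(cands, fps) {
  stopifnot(inherits(cands, "candidate_sets"))
  validate_candidates(cands, fps)
  out <- lapply(names(cands$candidates), function(q) {
    ids <- cands$candidates[[q]]
    Fc <- fp_rows(fps, ids)
    ft <- fps$bits[cands$truth[[q]], ]
    d <- rowMeans(Fc != matrix(ft, nrow(Fc), length(ft), byrow = TRUE))
    names(d) <- ids
    d
  })
  names(out) <- names(cands$candidates)
  out
}

#' Structured Hinge loss for one query
#'
#' Margin-rescaled structured Hinge:
#' `l(w, x_i, y_i) = max_y Delta(y_i, y) - w'(s(x_i, y_i) - s(x_i, y))`,
#' the max taken over all candidates including the truth, whose term is
#' exactly 0 — hence the loss is always non-negative. Ties in the argmax go to
#' the lowest candidate index (deterministic).
#'
#' @param w length-K weight vector.
#' @param S `n_c x K` score matrix for the query.
#' @param delta length-`n_c` vector of structural losses.
#' @param true_idx index of the true candidate in `S`/`delta`.
#' @return list with `loss` (scalar, >= 0) and `argmax` (integer index).
#' @export
hinge_loss <- function(w, S, delta, true_idx) {
  S <- as.matrix(S)
  if (length(w) != ncol(S)) stopf("weight length %d vs %d models", length(w), ncol(S))
  if (length(delta) != nrow(S)) stopf("delta length mismatch")
  if (!is_count(true_idx) || true_idx > nrow(S)) stopf("invalid true candidate index")
  sw <- drop(S %*% w)
  v <- unname(delta - (sw[true_idx] - sw))
  j <- which.max(v)  # first index on ties
  list(loss = v[j], argmax = j)
}

#' Regularized fusion objective
#'
#' `J(w) = (lambda/2) ||w||^2 + (1/l) sum_i hinge_loss(w, x_i, y_i)`.
#' At `w = 0` the score term vanishes and `J(0)` equals the mean over queries
#' of the maximal structural loss.
#'
#' @param w length-K weight vector.
#' @param tensor a [score_tensor()].
#' @param deltas output of [build_delta_table()] covering the tensor's queries.
#' @param lambda non-negative regularization parameter.
#' @return scalar objective value.
#' @export
fusion_objective <- function(w, tensor, deltas, lambda) {
  stopifnot(inherits(tensor, "score_tensor"))
  if (lambda < 0) stopf("lambda must be non-negative")
  losses <- vapply(names(tensor$queries), function(q) {
    qq <- tensor$queries[[q]]
    hinge_loss(w, qq$scores, deltas[[q]], qq$true_idx)$loss
  }, numeric(1))
  lambda / 2 * sum(w^2) + mean(losses)
}

#' Learn fusion weights by mini-batch subgradient descent
#'
#' Minimizes [fusion_objective()] with Pegasos-style steps. Weights start at
#' zero; in each of `epochs` passes the queries are randomly permuted and cut
#' into contiguous batches of size `m` (last batch smaller if `l mod m != 0`).
#' For batch B at global iteration k (counting from 1), the update is
#' `w <- w - t_k * (lambda w + (1/|B|) sum_{i in B} g_i)` with learning rate
#' `t_k = 1/(lambda k)` and `g_i = -(s(x_i, y_i) - s(x_i, y*))` when the hinge
#' is active at a candidate `y*` other than the truth, else 0. No projection
#' or averaging step is applied. The per-epoch objective `J(w)` is recorded;
#' identical seeds give bit-identical weights.
#'
#' @param tensor a [score_tensor()] (the validation-fold queries, in the
#'   standard protocol).
#' @param deltas structural losses from [build_delta_table()].
#' @param lambda positive regularization parameter (the `1/(lambda k)`
#'   schedule requires it).
#' @param batch_size mini-batch size `m` (default 15, at most the number of
#'   queries).
#' @param epochs number of full passes (default 30).
#' @param seed integer RNG seed for the batch shuffles.
#' @return object of class `iokr_fusion`: weights `w` (named by model),
#'   hyperparameters, and `objective_trace` (per-epoch `J(w)`).
#' @export
iokr_fusion <- function(tensor, deltas, lambda, batch_size = 15L,
                        epochs = 30L, seed = 1L) {
  stopifnot(inherits(tensor, "score_tensor"))
  if (!is.numeric(lambda) || lambda <= 0) stopf("lambda must be positive")
  if (!is_count(batch_size)) stopf("batch_size must be a positive integer")
  if (!is_count(epochs)) stopf("epochs must be a positive integer")
  qids <- names(tensor$queries)
  l <- length(qids)
  m <- min(as.integer(batch_size), l)
  K <- length(tensor$model_names)
  w <- numeric(K)
  trace <- numeric(epochs)
  k <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(l)
      starts <- seq(1L, l, by = m)
      for (st in starts) {
        batch <- perm[st:min(st + m - 1L, l)]
        k <- k + 1L
        g <- lambda * w
        for (i in batch) {
          qq <- tensor$queries[[i]]
          hl <- hinge_loss(w, qq$scores, deltas[[qids[i]]], qq$true_idx)
          if (hl$loss > 0 && hl$argmax != qq$true_idx) {
            g <- g + (qq$scores[hl$argmax, ] - qq$scores[qq$true_idx, ]) / length(batch)
          }
        }
        w <- w - (1 / (lambda * k)) * g
      }
      trace[ep] <- fusion_objective(w, tensor, deltas, lambda)
    }
  })
  names(w) <- tensor$model_names
  structure(list(w = w, lambda = lambda, batch_size = m, epochs = epochs,
                 seed = seed, objective_trace = trace),
            class = "iokr_fusion")
}

#' @export
print.iokr_fusion <- function(x, ...) {
  cat(sprintf("iokr_fusion: %d models, lambda = %g, batch %d, %d epochs\n",
              length(x$w), x$lambda, x$batch_size, x$epochs))
  cat(sprintf("  J(w) after training: %.6f\n", utils::tail(x$objective_trace, 1)))
  print(round(x$w, 4))
  invisible(x)
}

#' @export
coef.iokr_fusion <- function(object, ...) object$w

#' Fused scores for each query
#'
#' Linear combination `sum_k w_k s_k(x, y)` of model scores.
#'
#' @param model an [iokr_fusion()] fit (or any list with element `w`).
#' @param tensor a [score_tensor()] with the same model set.
#' @return named list (query id -> named numeric vector of fused candidate
#'   scores).
#' @export
fuse_scores <- function(model, tensor) {
  stopifnot(inherits(tensor, "score_tensor"))
  w <- if (inherits(model, "iokr_fusion")) model$w else as.numeric(model)
  if (length(w) != length(tensor$model_names)) {
    stopf("weight length %d does not match %d models",
          length(w), length(tensor$model_names))
  }
  lapply(tensor$queries, function(qq) {
    s <- drop(qq$scores %*% w)
    names(s) <- qq$candidate_ids
    s
  })
}

#' @export
predict.iokr_fusion <- function(object, tensor, ...) fuse_scores(object, tensor)
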