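# Structure-grouped cross-validation and the end-to-end evaluation protocol:
# 5 folds, of which 3 train the kernel regression models, 1 (validation)
# trains the score aggregator and selects its regularization, and 1 is the
# test fold. All preprocessing statistics and hyperparameters are computed
# from train/validation data only.

#' Structure-grouped k-fold plan
#'
#' Spectra sharing a structure-group label are always assigned to the same
#' fold, so no test spectrum has a training spectrum of the same molecular
#' structure. Groups are shuffled with the seed and dealt round-robin to
#' folds. Each round designates one test fold, the next fold (cyclically) as
#' validation, and the rest as training folds; every fold is the test fold
#' exactly once.
#'
#' @param group_ids character vector of group labels (one per item, or the
#'   unique groups themselves).
#' @param n_folds number of folds (>= 2, default 5).
#' @param seed integer seed for the shuffle.
#' @return object of class `cv_plan`: `n_folds`, `fold_of_group` (named
#'   integer vector), `rounds` (list of `train_folds`, `validation_fold`,
#'   `test_fold`).
#' @export
grouped_kfold <- function(group_ids, n_folds = 5L, seed = 1L) {
  if (!is_count(n_folds) || n_folds < 2L) stopf("n_folds must be an integer >= 2")
  groups <- unique(as.character(group_ids))
  if (length(groups) < n_folds) {
    stopf("only %d distinct groups for %d folds", length(groups), n_folds)
  }
  shuffled <- with_seed(seed, sample(groups))
  fold_of_group <- stats::setNames(rep_len(seq_len(n_folds), length(shuffled)),
                                   shuffled)
  rounds <- lapply(seq_len(n_folds), function(r) {
    val <- r %% n_folds + 1L
    list(train_folds = setdiff(seq_len(n_folds), c(r, val)),
         validation_fold = val, test_fold = r)
  })
  structure(list(n_folds = as.integer(n_folds), fold_of_group = fold_of_group,
                 rounds = rounds, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Rank candidates for one query
#'
#' Candidates are sorted by descending score. The rank of the true molecule
#' is computed pessimistically: 1 + the number of candidates scoring strictly
#' higher than the truth + the number of non-truth candidates tied with it —
#' ties never favor the method, so constant scores yield rank `n_c`. If the
#' truth is absent from the candidate list the query is marked unscorable
#' (excluded from accuracy denominators downstream).
#'
#' @param scores numeric vector of candidate scores (higher is better).
#' @param candidate_ids character vector aligned with `scores`.
#' @param true_id the true molecule id.
#' @return list with `ranked_ids`, `rank_of_truth` (NA if unscorable),
#'   `unscorable`.
#' @export
rank_candidates <- function(scores, candidate_ids, true_id) {
  if (length(scores) != length(candidate_ids) || length(scores) == 0L) {
    stopf("scores and candidate ids must be non-empty and aligned")
  }
  ord <- order(scores, decreasing = TRUE)
  ranked <- candidate_ids[ord]
  ti <- match(true_id, candidate_ids)
  if (is.na(ti)) {
    iokr_log(sprintf("truth '%s' absent from candidate list; query unscorable",
                     true_id), level = "WARN")
    return(list(ranked_ids = ranked, rank_of_truth = NA_integer_,
                unscorable = TRUE))
  }
  st <- scores[ti]
  rank <- 1L + sum(scores > st) + sum(scores[-ti] == st)
  list(ranked_ids = ranked, rank_of_truth = rank, unscorable = FALSE)
}

#' Top-k accuracy over ranking results
#'
#' Percentage of scorable queries whose true molecule sits within the top k.
#' Monotone non-decreasing in k; unscorable queries are dropped from the
#' denominator with a logged count.
#'
#' @param results non-empty list of [rank_candidates()] results.
#' @param ks integer vector of cutoffs.
#' @return named numeric vector (percentages), names `top1`, `top5`, ...
#' @export
topk_accuracy <- function(results, ks = c(1L, 5L, 10L)) {
  if (length(results) == 0L) stopf("no ranking results")
  ranks <- vapply(results, `[[`, numeric(1), "rank_of_truth")
  bad <- sum(is.na(ranks))
  if (bad > 0L) {
    iokr_log(sprintf("%d unscorable query(ies) excluded from accuracy", bad),
             level = "WARN")
  }
  ranks <- ranks[!is.na(ranks)]
  if (length(ranks) == 0L) stopf("all queries unscorable")
  stats::setNames(vapply(ks, function(k) 100 * mean(ranks <= k), numeric(1)),
                  paste0("top", ks))
}

# ---------------------------------------------------------------------------
# Internal preprocessing helpers for the protocol.

# Slice, center and normalize an input Gram matrix computed over all spectra:
# training square block plus query-by-train cross block, all statistics from
# the training block only.
prep_input_kernel <- function(K_full_raw, train_ids, query_ids) {
  V <- km_values(K_full_raw)
  K_tr_raw <- kernel_matrix(V[train_ids, train_ids, drop = FALSE])
  K_tr <- normalize_kernel(center_train(K_tr_raw))
  cross_raw <- kernel_matrix(V[query_ids, train_ids, drop = FALSE],
                             row_ids = query_ids, col_ids = train_ids)
  cross <- normalize_kernel(center_cross(cross_raw, K_tr_raw,
                                         row_self_raw = diag(V)[query_ids]))
  list(train = K_tr, cross = cross)
}

output_kernel_raw <- function(type, A_bits, B_bits, gamma) {
  switch(type,
         linear = linear_fp_kernel(A_bits, B_bits),
         tanimoto = tanimoto_kernel(A_bits, B_bits),
         gaussian = gaussian_fp_kernel(A_bits, B_bits, gaussian_params(gamma)),
         gaussian_tanimoto = gaussian_tanimoto_kernel(A_bits, B_bits,
                                                      gaussian_params(gamma)),
         stopf("unknown output kernel type '%s'", type))
}

output_kernel_self <- function(type, bits) {
  if (type == "linear") rowSums(bits) else rep(1, nrow(bits))
}

# Training-block output kernel plus candidate-by-train cross block, centered
# and normalized with training statistics.
prep_output_kernel <- function(type, train_bits, cand_bits, gamma = NULL) {
  K_tr_raw <- output_kernel_raw(type, train_bits, train_bits, gamma)
  K_tr <- normalize_kernel(center_train(K_tr_raw))
  cross_raw <- output_kernel_raw(type, cand_bits, train_bits, gamma)
  cross <- normalize_kernel(center_cross(cross_raw, K_tr_raw,
                                         row_self_raw = output_kernel_self(type, cand_bits)))
  list(train = K_tr, cross = cross)
}

# Cosine scores of one fitted direction for a set of queries, as a named list
# aligned with each query's candidate order.
score_queries_forward <- function(model, kx_cross_q, ky_cross_cand, cands, qids) {
  A <- iokr_alpha(model, t(kx_cross_q$values[qids, , drop = FALSE]))
  A <- as.matrix(A)
  Ky_cand_cols <- t(ky_cross_cand$values)  # l x n_union
  out <- lapply(seq_along(qids), function(i) {
    ids <- cands$candidates[[qids[i]]]
    s <- cosine_scores(A[, i], model, Ky_cand_cols[, ids, drop = FALSE], 1)
    stats::setNames(s, ids)
  })
  names(out) <- qids
  out
}

score_queries_reverse <- function(model, kx_cross_q, ky_cross_cand, cands, qids) {
  B <- iokr_beta(model, t(ky_cross_cand$values))  # l x n_union
  colnames(B) <- ky_cross_cand$row_ids
  out <- lapply(qids, function(q) {
    ids <- cands$candidates[[q]]
    s <- reverse_cosine_scores(B[, ids, drop = FALSE], model,
                               kx_cross_q$values[q, ], 1)
    stats::setNames(s, ids)
  })
  names(out) <- qids
  out
}

# Build a score_tensor for a set of queries from per-model named score lists.
build_tensor <- function(model_scores, cands, qids) {
  model_names <- names(model_scores)
  mats <- lapply(qids, function(q) {
    ids <- cands$candidates[[q]]
    S <- vapply(model_names, function(m) model_scores[[m]][[q]][ids], numeric(length(ids)))
    S <- matrix(S, nrow = length(ids), dimnames = list(ids, model_names))
    S
  })
  names(mats) <- qids
  score_tensor(model_names, mats, cands$truth[qids])
}

# Select the fusion regularization by inner k-fold top-1 accuracy on the
# validation queries; ties break to the larger lambda.
fusion_select_lambda <- function(tensor, deltas, grid, n_folds = 4L,
                                 batch_size = 15L, epochs = 30L, seed = 1L) {
  grid <- sort(grid)
  qids <- names(tensor$queries)
  l <- length(qids)
  n_folds <- min(n_folds, l)
  if (n_folds < 2L || length(grid) == 1L) return(max(grid))
  fold <- with_seed(child_seed(seed, "fusion"), sample(rep_len(seq_len(n_folds), l)))
  top1 <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- qids[fold != f]; te <- qids[fold == f]
    sub_tr <- score_tensor(tensor$model_names,
                           lapply(tensor$queries[tr], `[[`, "scores"),
                           vapply(tensor$queries[tr], function(qq)
                             qq$candidate_ids[qq$true_idx], character(1)))
    sub_te <- tensor$queries[te]
    for (j in seq_along(grid)) {
      fit <- iokr_fusion(sub_tr, deltas, grid[j], batch_size = batch_size,
                         epochs = epochs, seed = seed + f)
      hits <- vapply(sub_te, function(qq) {
        s <- drop(qq$scores %*% fit$w)
        r <- rank_candidates(s, qq$candidate_ids, qq$candidate_ids[qq$true_idx])
        isTRUE(r$rank_of_truth == 1L)
      }, logical(1))
      top1[f, j] <- mean(hits)
    }
  }
  avg <- colMeans(top1)
  rev(grid)[which.max(rev(avg))]  # ties -> larger lambda
}

#' Run the full structure-grouped evaluation protocol
#'
#' For each of the `n_folds` cross-validation rounds: (1) every
#' (input kernel x output kernel x direction) model is fitted on the three
#' training folds, with its ridge parameter selected by inner-CV mean squared
#' error; (2) validation and test candidates are scored with the cosine
#' similarity; (3) the fusion weights are trained on the validation fold, the
#' fusion regularization selected by inner 4-fold top-1 accuracy on that
#' fold; (4) single models, uniform-MKL variants (equal-weight input-kernel
#' combination, forward direction) and the fused model are evaluated on the
#' test fold. Gaussian-family output-kernel bandwidths are selected per round
#' by entropy maximization on the training fold. All centering/normalization
#' statistics come from the training folds; nothing is learned from the test
#' fold.
#'
#' @param bench an [generate_benchmark()] result, or a list with the same
#'   fields (`views`, `fingerprints`, `candidates`, `groups`).
#' @param ppk [ppk_params()] for the input kernel on spectra (required; no
#'   hidden default).
#' @param output_kernels subset of
#'   `c("linear", "tanimoto", "gaussian", "gaussian_tanimoto")`.
#' @param lambda_grid ridge grid for both directions (decades
#'   `1e-5 ... 10` by default).
#' @param gamma_grid grid for the entropy-based bandwidth selection.
#' @param fusion list: `lambda_grid`, `batch_size` (15), `epochs` (30).
#' @param n_folds number of CV folds (default 5).
#' @param ks top-k cutoffs to report.
#' @param seed master seed (fold shuffle, inner CV, SGD batches).
#' @return object of class `iokr_protocol`: averaged `topk` matrix
#'   (methods x k), per-round details (`rounds`), averaged fusion `weights`,
#'   the `plan`, and bookkeeping.
#' @export
run_protocol <- function(bench, ppk, output_kernels = c("linear", "tanimoto"),
                         lambda_grid = 10^seq(-5, 1),
                         gamma_grid = 10^seq(-3, 1, length.out = 9),
                         fusion = list(lambda_grid = 10^seq(-3, 0),
                                       batch_size = 15L, epochs = 30L),
                         n_folds = 5L, ks = c(1L, 5L, 10L), seed = 1L) {
  output_kernels <- match.arg(output_kernels,
                              c("linear", "tanimoto", "gaussian",
                                "gaussian_tanimoto"), several.ok = TRUE)
  ppk <- ppk_params(ppk$sigma_m, ppk$sigma_i)
  views <- bench$views
  fps <- bench$fingerprints
  cands <- bench$candidates
  groups <- bench$groups
  mols <- names(groups)
  validate_candidates(cands, fps)
  plan <- grouped_kfold(groups[mols], n_folds = n_folds,
                        seed = child_seed(seed, "folds"))
  fold_of_mol <- plan$fold_of_group[groups[mols]]
  names(fold_of_mol) <- mols

  # raw input Grams over all spectra, once per view
  Kx_full <- lapply(views, function(specs) {
    specs <- specs[match(mols, vapply(specs, `[[`, character(1), "id"))]
    ppk_matrix(specs, specs, ppk)
  })

  deltas <- build_delta_table(cands, fps)
  directions <- c("forward", "reverse")
  single_names <- as.vector(outer(names(views), output_kernels,
                                  function(v, o) paste(v, o, sep = ".")))
  single_names <- as.vector(outer(single_names, directions, paste, sep = "."))

  rounds_out <- vector("list", plan$n_folds)
  for (r in seq_len(plan$n_folds)) {
    ro <- plan$rounds[[r]]
    train_m <- mols[fold_of_mol %in% ro$train_folds]
    val_m <- mols[fold_of_mol == ro$validation_fold]
    test_m <- mols[fold_of_mol == ro$test_fold]
    query_m <- c(val_m, test_m)
    cand_union <- unique(unlist(cands$candidates[query_m], use.names = FALSE))

    kx <- lapply(Kx_full, prep_input_kernel, train_ids = train_m,
                 query_ids = query_m)

    train_bits <- fp_rows(fps, train_m)
    cand_bits <- fp_rows(fps, cand_union)
    gammas <- list()
    ky <- lapply(output_kernels, function(o) {
      g <- NULL
      if (o %in% c("gaussian", "gaussian_tanimoto")) {
        sp <- if (o == "gaussian") "gaussian" else "gaussian_tanimoto"
        g <- select_gamma_by_entropy(fp_sq_distances(fingerprint_table(train_bits), sp),
                                     gamma_grid)$gamma
        gammas[[o]] <<- g
      }
      prep_output_kernel(o, train_bits, cand_bits, g)
    })
    names(ky) <- output_kernels

    val_scores <- list()
    test_scores <- list()
    lambdas <- list()
    midx <- 0L
    for (v in names(views)) {
      for (o in output_kernels) {
        for (dir in directions) {
          midx <- midx + 1L
          mname <- paste(v, o, dir, sep = ".")
          tune_seed <- child_seed(seed, "tuning", r * 1000L + midx)
          if (dir == "forward") {
            lam <- tune_lambda_by_mse(kx[[v]]$train, ky[[o]]$train,
                                      lambda_grid, 4L, tune_seed)
            fit <- iokr(kx[[v]]$train, ky[[o]]$train, lam)
            val_scores[[mname]] <- score_queries_forward(fit, kx[[v]]$cross,
                                                         ky[[o]]$cross, cands, val_m)
            test_scores[[mname]] <- score_queries_forward(fit, kx[[v]]$cross,
                                                          ky[[o]]$cross, cands, test_m)
          } else {
            lam <- tune_lambda_by_mse(ky[[o]]$train, kx[[v]]$train,
                                      lambda_grid, 4L, tune_seed)
            fit <- iokr_reverse(ky[[o]]$train, kx[[v]]$train, lam)
            val_scores[[mname]] <- score_queries_reverse(fit, kx[[v]]$cross,
                                                         ky[[o]]$cross, cands, val_m)
            test_scores[[mname]] <- score_queries_reverse(fit, kx[[v]]$cross,
                                                          ky[[o]]$cross, cands, test_m)
          }
          lambdas[[mname]] <- lam
        }
      }
    }

    # uniform multiple-kernel combination of the input views, forward models
    unimkl_scores <- list()
    if (length(views) > 1L) {
      Kx_uni_tr <- normalize_kernel(unimkl_combine(lapply(kx, `[[`, "train")))
      Kx_uni_cross <- normalize_kernel(unimkl_combine_cross(lapply(kx, `[[`, "cross")))
      kx_uni <- list(train = Kx_uni_tr, cross = Kx_uni_cross)
      for (o in output_kernels) {
        mname <- paste("unimkl", o, sep = ".")
        tune_seed <- child_seed(seed, "tuning", r * 1000L + 900L + match(o, output_kernels))
        lam <- tune_lambda_by_mse(kx_uni$train, ky[[o]]$train, lambda_grid,
                                  4L, tune_seed)
        fit <- iokr(kx_uni$train, ky[[o]]$train, lam)
        unimkl_scores[[mname]] <- score_queries_forward(fit, kx_uni$cross,
                                                        ky[[o]]$cross, cands, test_m)
        lambdas[[mname]] <- lam
      }
    }

    # late fusion trained on the validation fold
    tensor_val <- build_tensor(val_scores, cands, val_m)
    tensor_test <- build_tensor(test_scores, cands, test_m)
    fus_lambda <- fusion_select_lambda(tensor_val, deltas, fusion$lambda_grid,
                                       n_folds = 4L,
                                       batch_size = fusion$batch_size %||% 15L,
                                       epochs = fusion$epochs %||% 30L,
                                       seed = child_seed(seed, "fusion", r))
    fus <- iokr_fusion(tensor_val, deltas, fus_lambda,
                       batch_size = fusion$batch_size %||% 15L,
                       epochs = fusion$epochs %||% 30L,
                       seed = child_seed(seed, "fusion", 100L + r))
    fused_test <- fuse_scores(fus, tensor_test)

    # evaluate on the test fold
    eval_scores <- c(test_scores, unimkl_scores, list(fusion = fused_test))
    topk <- t(vapply(names(eval_scores), function(m) {
      res <- lapply(test_m, function(q) {
        rank_candidates(eval_scores[[m]][[q]], names(eval_scores[[m]][[q]]),
                        cands$truth[[q]])
      })
      topk_accuracy(res, ks)
    }, numeric(length(ks))))

    rounds_out[[r]] <- list(topk = topk, lambdas = lambdas, gammas = gammas,
                            fusion_lambda = fus_lambda, weights = fus$w,
                            objective_trace = fus$objective_trace,
                            n_test = length(test_m), n_val = length(val_m))
  }

  methods <- rownames(rounds_out[[1L]]$topk)
  topk_avg <- Reduce(`+`, lapply(rounds_out, `[[`, "topk")) / plan$n_folds
  W <- do.call(rbind, lapply(rounds_out, `[[`, "weights"))
  structure(list(topk = topk_avg, rounds = rounds_out,
                 weights = colMeans(W), weights_per_round = W,
                 model_names = single_names, methods = methods,
                 plan = plan, ks = ks, seed = seed),
            class = "iokr_protocol")
}

#' @export
print.iokr_protocol <- function(x, ...) {
  cat(sprintf("iokr_protocol: %d-fold structure-grouped CV\n", x$plan$n_folds))
  cat("Averaged top-k accuracy (%):\n")
  print(round(x$topk, 2))
  cat("Averaged fusion weights:\n")
  print(round(x$weights, 4))
  invisible(x)
}
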