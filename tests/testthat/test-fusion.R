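# Late fusion: Hamming structural loss, structured Hinge, the regularized
# objective, and the mini-batch subgradient learner.

make_toy_tensor <- function(n_query = 5, n_c = 4, K = 2, seed = 1,
                            informative = 1, noise_sd = 1) {
  set.seed(seed)
  scores <- list()
  truth <- character(0)
  for (q in seq_len(n_query)) {
    ids <- sprintf("q%d_c%d", q, seq_len(n_c))
    S <- matrix(rnorm(n_c * K, sd = noise_sd), n_c, K,
                dimnames = list(ids, paste0("mod", seq_len(K))))
    for (m in informative) {
      S[, m] <- 0
      S[1, m] <- 1  # informative model puts the truth on top with margin 1
    }
    scores[[paste0("q", q)]] <- S
    truth[paste0("q", q)] <- ids[1]
  }
  list(tensor = score_tensor(paste0("mod", seq_len(K)), scores, truth),
       deltas = lapply(stats::setNames(seq_len(n_query), names(scores)),
                       function(q) {
                         d <- c(0, runif(n_c - 1, 0.2, 0.8))
                         names(d) <- sprintf("q%d_c%d", q, seq_len(n_c))
                         d
                       }))
}

test_that("hamming_delta counts differing bit fractions", {
  expect_equal(hamming_delta(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(hamming_delta(c(1, 0), c(0, 1)), 1)
  expect_equal(hamming_delta(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_error(hamming_delta(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("build_delta_table aligns with candidates and zeroes the truth", {
  m <- rbind(t1 = c(1L, 1L, 0L, 0L), c1 = c(1L, 0L, 1L, 0L),
             c2 = c(0L, 0L, 1L, 1L))
  fps <- fingerprint_table(m)
  cs <- candidate_sets(list(q = c("c1", "t1", "c2")), c(q = "t1"))
  dt <- build_delta_table(cs, fps)
  expect_equal(dt$q[["t1"]], 0)
  for (cand in c("c1", "c2")) {
    expect_equal(dt$q[[cand]], hamming_delta(m["t1", ], m[cand, ]))
  }
  # missing fingerprint errors with the id
  cs2 <- candidate_sets(list(q = c("t1", "ghost")), c(q = "t1"))
  expect_error(build_delta_table(cs2, fps), "ghost")
})

test_that("hinge loss is the max over candidates, truth term included", {
  S <- matrix(c(0.9, 0.2, 0.5), 3, 1,
              dimnames = list(c("a", "b", "c"), "mod1"))
  delta <- c(0, 0.4, 0.7)

  # w = 0: loss = max Delta
  h0 <- hinge_loss(0, S, delta, true_idx = 1L)
  expect_equal(h0$loss, 0.7)
  expect_equal(h0$argmax, 3L)

  # single candidate (the truth): loss 0
  h1 <- hinge_loss(0.5, S[1, , drop = FALSE], 0, 1L)
  expect_equal(h1$loss, 0)
  expect_equal(h1$argmax, 1L)

  # brute-force oracle over candidates for a nontrivial w
  w <- 1.3
  vals <- vapply(1:3, function(j) delta[j] - w * (S[1, 1] - S[j, 1]), numeric(1))
  h <- hinge_loss(w, S, delta, 1L)
  expect_equal(h$loss, max(vals))
  expect_equal(h$argmax, which.max(vals))
  expect_gte(h$loss, 0)
})

test_that("hinge ties break to the lowest candidate index", {
  S <- matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "m"))
  h <- hinge_loss(0, S, c(0, 0.5, 0.5), 1L)
  expect_equal(h$argmax, 2L)
})

test_that("objective equals a direct summation oracle and J(0) = mean max delta", {
  toy <- make_toy_tensor(n_query = 5, n_c = 4, K = 2, seed = 3)
  tensor <- toy$tensor; deltas <- toy$deltas
  expect_equal(fusion_objective(c(0, 0), tensor, deltas, lambda = 0.1),
               mean(vapply(deltas, max, numeric(1))))

  w <- c(0.7, -0.3); lambda <- 0.25
  direct <- lambda / 2 * sum(w^2) + mean(vapply(names(tensor$queries), function(q) {
    qq <- tensor$queries[[q]]
    sw <- drop(qq$scores %*% w)
    max(deltas[[q]] - (sw[qq$true_idx] - sw))
  }, numeric(1)))
  expect_equal(fusion_objective(w, tensor, deltas, lambda), direct,
               tolerance = 1e-12)

  # all-zero deltas and w = 0 gives 0
  zero_d <- lapply(deltas, function(d) d * 0)
  expect_equal(fusion_objective(c(0, 0), tensor, zero_d, 0), 0)
})

test_that("the objective is convex in w", {
  toy <- make_toy_tensor(n_query = 6, n_c = 5, K = 3, seed = 4)
  set.seed(5)
  for (rep in 1:20) {
    w1 <- rnorm(3); w2 <- rnorm(3); t_ <- runif(1)
    J_mix <- fusion_objective(t_ * w1 + (1 - t_) * w2, toy$tensor, toy$deltas, 0.2)
    J_bound <- t_ * fusion_objective(w1, toy$tensor, toy$deltas, 0.2) +
      (1 - t_) * fusion_objective(w2, toy$tensor, toy$deltas, 0.2)
    expect_lte(J_mix, J_bound + 1e-10)
  }
})

test_that("subgradient descent is deterministic and decreases the objective", {
  toy <- make_toy_tensor(n_query = 12, n_c = 6, K = 3, seed = 6)
  f1 <- iokr_fusion(toy$tensor, toy$deltas, lambda = 0.1, batch_size = 4,
                    epochs = 20, seed = 42)
  f2 <- iokr_fusion(toy$tensor, toy$deltas, lambda = 0.1, batch_size = 4,
                    epochs = 20, seed = 42)
  expect_identical(f1$w, f2$w)  # bit-for-bit
  expect_identical(f1$objective_trace, f2$objective_trace)

  J0 <- fusion_objective(numeric(3), toy$tensor, toy$deltas, 0.1)
  expect_lte(tail(f1$objective_trace, 1), J0)
  expect_error(iokr_fusion(toy$tensor, toy$deltas, lambda = 0), "positive")
})

test_that("an informative model outweighs pure noise in every seeded run", {
  for (s in 1:5) {
    toy <- make_toy_tensor(n_query = 25, n_c = 8, K = 2, seed = 10 + s,
                           informative = 1)
    fit <- iokr_fusion(toy$tensor, toy$deltas, lambda = 0.05, batch_size = 5,
                       epochs = 30, seed = s)
    expect_gt(fit$w["mod1"], fit$w["mod2"])
  }
})

test_that("regularization alone never moves w off zero", {
  S <- matrix(0.3, 1, 2, dimnames = list("only", c("m1", "m2")))
  tensor <- score_tensor(c("m1", "m2"), list(q = S), c(q = "only"))
  fit <- iokr_fusion(tensor, list(q = c(only = 0)), lambda = 1,
                     batch_size = 1, epochs = 10, seed = 1)
  expect_lte(sqrt(sum(fit$w^2)), 1e-8)
})

test_that("fuse_scores is the advertised linear combination", {
  toy <- make_toy_tensor(n_query = 4, n_c = 5, K = 3, seed = 7)
  tensor <- toy$tensor

  f_e2 <- fuse_scores(c(0, 1, 0), tensor)
  for (q in names(tensor$queries)) {
    expect_equal(unname(f_e2[[q]]), unname(tensor$queries[[q]]$scores[, 2]))
  }
  f_0 <- fuse_scores(c(0, 0, 0), tensor)
  expect_true(all(unlist(f_0) == 0))

  set.seed(8)
  w <- rnorm(3)
  f_w <- fuse_scores(w, tensor)
  q1 <- tensor$queries[[1]]
  expect_equal(unname(f_w[[1]]), unname(drop(q1$scores %*% w)), tolerance = 1e-12)
  expect_error(fuse_scores(c(1, 2), tensor), "match")
})

test_that("fusing identical copies of one model preserves its ranking", {
  toy <- make_toy_tensor(n_query = 10, n_c = 6, K = 1, seed = 9, informative = 1)
  S3 <- lapply(toy$tensor$queries, function(qq) {
    S <- qq$scores[, c(1, 1, 1)]
    colnames(S) <- paste0("copy", 1:3)
    S
  })
  truth <- vapply(toy$tensor$queries, function(qq) qq$candidate_ids[qq$true_idx], "")
  tensor3 <- score_tensor(paste0("copy", 1:3), S3, truth)
  fit <- iokr_fusion(tensor3, toy$deltas, lambda = 0.1, batch_size = 5,
                     epochs = 30, seed = 2)
  fused <- fuse_scores(fit, tensor3)
  for (q in names(S3)) {
    r_f <- rank_candidates(fused[[q]], names(fused[[q]]), truth[[q]])
    r_s <- rank_candidates(S3[[q]][, 1], rownames(S3[[q]]), truth[[q]])
    expect_equal(r_f$rank_of_truth, r_s$rank_of_truth)
  }
})
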