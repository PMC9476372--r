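make_processed_kernel <- function(n, peaks = 5, seed = 1) {
  set.seed(seed)
  # well-separated spectra give a normalized Gram matrix that is strictly
  # positive definite (invertible), as the interpolation identity requires
  sp <- lapply(1:n, function(i) {
    ei_spectrum(sort(50 + 40 * i + runif(peaks, 0, 30)), runif(peaks, 1, 100))
  })
  normalize_kernel(kernel_matrix(sp))
}

test_that("near-zero ridge recovers training fingerprints (interpolation)", {
  K <- make_processed_kernel(10)
  set.seed(2)
  Y <- matrix(rbinom(10 * 40, 1, 0.4), nrow = 10)
  m <- iokr_fit(K, Y, lambda = 1e-10)
  for (i in c(1, 5, 10)) {
    pred <- iokr_predict_features(m, K[, i])
    expect_lt(max(abs(pred - Y[i, ])), 1e-6)
  }
})

test_that("prediction norm shrinks monotonically as lambda grows", {
  K <- make_processed_kernel(8)
  set.seed(3)
  Y <- matrix(rbinom(8 * 20, 1, 0.5), nrow = 8)
  k <- K[, 3]
  norms <- vapply(10^seq(-6, 3), function(l) {
    sqrt(sum(iokr_predict_features(iokr_fit(K, Y, l), k)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("two-point system matches hand-written normal equations", {
  # explicit 2x2 algebra: (K + lambda I)^-1 in closed form
  K <- matrix(c(1, 0.3, 0.3, 1), 2)
  Y <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 2)
  lambda <- 0.5
  a <- 1 + lambda; b <- 0.3
  inv <- matrix(c(a, -b, -b, a), 2) / (a^2 - b^2)
  kq <- c(0.9, 0.2)
  manual <- t(Y) %*% (inv %*% kq)
  m <- iokr_fit(K, Y, lambda)
  expect_equal(as.numeric(iokr_predict_features(m, kq)), as.numeric(manual),
               tolerance = 1e-12)
})

test_that("fit validates its inputs", {
  K <- make_processed_kernel(5)
  Y <- matrix(0, 4, 3)
  expect_error(iokr_fit(K, Y, 1), "rows")
  expect_error(iokr_fit(K, matrix(0, 5, 3), -1), "lambda")
  expect_error(iokr_fit(K[1:4, ], matrix(0, 4, 3), 1))
})

test_that("lambda selection minimizes an independently computed CV objective", {
  K <- make_processed_kernel(20, seed = 4)
  set.seed(5)
  Y <- matrix(rbinom(20 * 30, 1, 0.4), nrow = 20)
  grid <- 10^seq(-4, 0)
  sel <- select_lambda(K, Y, grid = grid, folds = 4, seed = 9)
  # independent oracle: same folds, plain solve() instead of the model path
  set.seed(9)
  fold_id <- sample(rep(1:4, length.out = 20))
  expect_equal(fold_id, sel$fold_id)
  mse <- sapply(grid, function(l) {
    mean(sapply(1:4, function(f) {
      tr <- fold_id != f; te <- !tr
      pred <- K[te, tr, drop = FALSE] %*%
        solve(K[tr, tr] + diag(l, sum(tr)), Y[tr, , drop = FALSE])
      mean((pred - Y[te, , drop = FALSE])^2)
    }))
  })
  expect_equal(unname(sel$cv_mse), unname(mse), tolerance = 1e-8)
  expect_equal(sel$lambda, grid[which.min(mse)])
})

test_that("lambda selection edge rules: single grid value and ties", {
  K <- make_processed_kernel(6)
  Y <- matrix(rbinom(6 * 5, 1, 0.5), nrow = 6)
  expect_equal(select_lambda(K, Y, grid = 0.37)$lambda, 0.37)
  # all-zero targets: identical loss across the grid -> smallest lambda
  sel <- select_lambda(K, matrix(0, 6, 5), grid = c(1, 0.01, 0.1), folds = 3)
  expect_equal(sel$lambda, 0.01)
  expect_error(select_lambda(K, Y, grid = c(1, 2), folds = 50), "folds")
})

test_that("candidate scoring follows the linear output kernel", {
  K <- make_processed_kernel(6)
  set.seed(6)
  Y <- matrix(rbinom(6 * 12, 1, 0.5), nrow = 6)
  m <- iokr_fit(K, Y, 0.1, mask_id = "m1")
  cs <- candidate_set("q", c("a", "b", "zero", "b2"),
                      rbind(Y[1, ], Y[2, ], 0, Y[2, ]),
                      true_id = "a", mask_id = "m1")
  sc <- predict_scores(m, K[, 1], cs)
  expect_equal(unname(sc["zero"]), 0)          # all-zero fingerprint
  expect_equal(unname(sc["b"]), unname(sc["b2"]))  # duplicated structures
  b <- iokr_predict_features(m, K[, 1])[1, ]
  expect_equal(unname(sc["a"]), sum(Y[1, ] * b), tolerance = 1e-12)
  # normalized variant divides by candidate norm
  scn <- predict_scores(m, K[, 1], cs, score = "normalized")
  expect_equal(unname(scn["a"]), unname(sc["a"]) / sqrt(sum(Y[1, ])),
               tolerance = 1e-12)
  # mask mismatch is an error
  cs2 <- candidate_set("q", "a", rbind(Y[1, ]), true_id = "a", mask_id = "other")
  expect_error(predict_scores(m, K[, 1], cs2), "mask")
})

test_that("ranking is deterministic, tie-aware and order-invariant", {
  sc <- c(b = 0.5, a = 0.5, c = 0.9, d = 0.1)
  r <- rank_candidates(sc, true_id = "a", query_id = "q")
  expect_equal(r$ids, c("c", "a", "b", "d"))      # ties broken by id
  expect_equal(r$rank_of_true, 2L)
  expect_equal(r$tie_groups, c(1L, 2L, 2L, 3L))
  # permuting the input changes nothing
  r2 <- rank_candidates(sc[c(3, 1, 4, 2)], true_id = "a", query_id = "q")
  expect_equal(r2$ids, r$ids)
  # single candidate = truth; missing truth
  expect_equal(rank_candidates(c(only = 1), true_id = "only")$rank_of_true, 1L)
  rm <- rank_candidates(sc, true_id = NA_character_)
  expect_true(rm$missing)
  expect_true(is.na(rm$rank_of_true))
  expect_error(rank_candidates(numeric(0)), "empty")
})

test_that("easy synthetic queries rank the truth strictly highest", {
  b <- small_bundle()
  res <- run_pipeline(b)
  ranks <- vapply(res$identify$rankings, function(r) r$rank_of_true, integer(1))
  expect_gte(mean(ranks == 1), 0.8)
  # repeated prediction is bit-identical
  res2 <- run_pipeline(b)
  expect_identical(res$identify$table$score, res2$identify$table$score)
})
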