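#' Fit an input-output kernel regression model
#'
#' Kernel ridge regression from the spectrum kernel to the linear kernel on
#' molecular fingerprints. The dual solution is the Cholesky factor of
#' `K_train + lambda I`; predicted output features for a query with kernel
#' column `k` are `t(Y) %*% solve(K_train + lambda I, k)`.
#'
#' @param K_train processed (centered+normalized) square training kernel.
#' @param Y numeric matrix of training output features, one row per training
#'   spectrum (masked fingerprint bits).
#' @param lambda ridge regularization strength (> 0).
#' @param mask_id identifier of the fingerprint mask used for `Y` (recorded
#'   so candidate fingerprints can be checked at prediction time).
#' @return an `iokr_model`.
#' @export
iokr_fit <- function(K_train, Y, lambda, mask_id = NA_character_) {
  stopifnot(is.matrix(K_train), nrow(K_train) == ncol(K_train))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(K_train)) stop("Y rows must match K_train")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  M <- K_train + diag(lambda, nrow(K_train))
  ch <- tryCatch(chol(M), error = function(e) {
    stop(sprintf("iokr_fit: K + lambda*I not positive definite at lambda=%g (rcond=%.3g)",
                 lambda, rcond(M)))
  })
  structure(list(chol = ch, Y = Y, lambda = lambda, n_train = nrow(K_train),
                 mask_id = mask_id),
            class = "iokr_model")
}

#' @export
print.iokr_model <- function(x, ...) {
  cat(sprintf("<iokr_model> n_train=%d, p=%d, lambda=%g\n",
              x$n_train, ncol(x$Y), x$lambda))
  invisible(x)
}

#' Predict output-feature vectors for query kernel columns
#'
#' @param model an `iokr_model`.
#' @param k_query numeric vector (one query) or matrix with one row per
#'   query and `n_train` columns, processed consistently with the training
#'   kernel.
#' @return matrix of predicted output features, one row per query.
#' @export
iokr_predict_features <- function(model, k_query) {
  if (is.null(dim(k_query))) k_query <- matrix(k_query, nrow = 1)
  stopifnot(ncol(k_query) == model$n_train)
  alpha <- backsolve(model$chol, forwardsolve(t(model$chol), t(k_query)))
  t(crossprod(model$Y, alpha))
}

#' Select the ridge strength by internal cross-validation
#'
#' Splits the training set into folds, fits on the complement of each fold
#' at every grid value, and measures the mean squared error between
#' predicted and true output-feature vectors on the held-out spectra. The
#' grid value with the lowest mean CV error wins; ties go to the smallest
#' lambda. Fold assignment is seeded and returned.
#'
#' @param K_train processed square training kernel.
#' @param Y training output-feature matrix.
#' @param grid non-empty numeric vector of candidate lambdas.
#' @param folds number of CV folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return list with `lambda` (the selection), `cv_mse` (named mean errors
#'   per grid value), and `fold_id`.
#' @export
select_lambda <- function(K_train, Y, grid = 10^seq(-4, 0, by = 1),
                          folds = 5, seed = 1) {
  stopifnot(length(grid) >= 1, all(grid > 0))
  Y <- as.matrix(Y)
  n <- nrow(K_train)
  if (length(grid) == 1) {
    return(list(lambda = grid, cv_mse = stats::setNames(NA_real_, grid),
                fold_id = NULL))
  }
  if (folds < 2 || folds > n) stop("folds must be in [2, n]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  err <- matrix(0, length(grid), folds)
  for (f in seq_len(folds)) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    if (!length(te) || !length(tr)) stop("degenerate CV fold")
    Ktr <- K_train[tr, tr, drop = FALSE]
    Kte <- K_train[te, tr, drop = FALSE]
    for (g in seq_along(grid)) {
      m <- iokr_fit(Ktr, Y[tr, , drop = FALSE], grid[g])
      pred <- iokr_predict_features(m, Kte)
      err[g, f] <- mean((pred - Y[te, , drop = FALSE])^2)
    }
  }
  mse <- rowMeans(err)
  best <- which(mse == min(mse))[1]  # ties -> smallest (grid sorted ascending)
  o <- order(grid)
  mse <- mse[o]; grid <- grid[o]
  best <- which(mse == min(mse))[1]
  list(lambda = grid[best], cv_mse = stats::setNames(mse, grid),
       fold_id = fold_id)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' A candidate set for one query spectrum
#'
#' @param query_id query identifier.
#' @param ids unique candidate identifiers.
#' @param fps matrix of candidate fingerprints, one row per candidate, in
#'   the model's masked layout.
#' @param true_id identifier of the correct candidate, or `NA` when the
#'   truth is absent from the set ("missing").
#' @param mask_id mask identifier of `fps`.
#' @return a `candidate_set`.
#' @export
candidate_set <- function(query_id, ids, fps, true_id = NA_character_,
                          mask_id = NA_character_) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("candidate identifiers must be unique")
  fps <- as.matrix(fps)
  if (nrow(fps) != length(ids)) stop("one fingerprint row per candidate required")
  if (!is.na(true_id) && !true_id %in% ids) {
    stop("true_id must be one of ids, or NA for a missing-truth set")
  }
  structure(list(query_id = as.character(query_id), ids = ids, fps = fps,
                 true_id = as.character(true_id),
                 contains_true = !is.na(true_id), mask_id = mask_id),
            class = "candidate_set")
}

#' Score a candidate set against a predicted output-feature vector
#'
#' The output kernel is linear on fingerprints, so each candidate's score is
#' the inner product of its (masked) fingerprint with the predicted feature
#' vector; higher is better. The `"normalized"` variant divides each score
#' by the candidate's fingerprint norm (equivalent to ranking by cosine in
#' output-feature space), which removes the bias toward candidates with
#' many set bits.
#'
#' @param model an `iokr_model`.
#' @param k_query processed kernel column of the query vs the training set.
#' @param cands a [candidate_set()] whose fingerprints share the model's
#'   mask.
#' @param score `"linear"` (default, the stated output kernel) or
#'   `"normalized"`.
#' @return named numeric vector of scores.
#' @export
predict_scores <- function(model, k_query, cands,
                           score = c("linear", "normalized")) {
  score <- match.arg(score)
  stopifnot(inherits(cands, "candidate_set"))
  if (!is.na(model$mask_id) && !is.na(cands$mask_id) &&
      model$mask_id != cands$mask_id) {
    stop("candidate fingerprints use a different mask than the model")
  }
  if (ncol(cands$fps) != ncol(model$Y)) {
    stop("candidate fingerprint length does not match model output layout")
  }
  b <- iokr_predict_features(model, k_query)
  sc <- as.numeric(cands$fps %*% b[1, ])
  if (score == "normalized") {
    sc <- sc / pmax(sqrt(rowSums(cands$fps^2)), .Machine$double.eps)
  }
  stats::setNames(sc, cands$ids)
}

#' Rank a scored candidate set
#'
#' Orders candidates by descending score, breaking ties deterministically by
#' lexicographic candidate identifier. Tie groups are recorded.
#'
#' @param scores named numeric score vector from [predict_scores()].
#' @param true_id the correct candidate id, or `NA` when the truth is
#'   missing from the set.
#' @param query_id query identifier carried into the result.
#' @return a `ranking_result`: list with `query_id`, `ids` (ordered),
#'   `scores` (ordered, non-increasing), `rank_of_true` (integer or `NA`
#'   for missing), `missing` (logical), `tie_groups` (integer group id per
#'   ordered candidate).
#' @export
rank_candidates <- function(scores, true_id = NA_character_,
                            query_id = NA_character_) {
  if (length(scores) == 0) stop("empty candidate set")
  if (is.null(names(scores))) stop("scores must be named by candidate id")
  o <- order(-scores, names(scores), method = "radix")
  ids <- names(scores)[o]; sc <- unname(scores[o])
  tie_groups <- cumsum(c(1L, diff(sc) != 0))
  missing <- is.na(true_id) || !true_id %in% ids
  rank_of_true <- if (missing) NA_integer_ else which(ids == true_id)
  structure(list(query_id = query_id, ids = ids, scores = sc,
                 rank_of_true = rank_of_true, missing = missing,
                 tie_groups = tie_groups),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %s: %d candidates, rank_of_true=%s\n",
              x$query_id, length(x$ids),
              if (x$missing) "missing" else x$rank_of_true))
  invisible(x)
}
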