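#' Train an identification model from curated (structure, spectrum) pairs
#'
#' End-to-end training stage: curates the training records, computes
#' fingerprints and the duplicate/constant column mask, builds the
#' probability product kernel Gram matrix, centers and normalizes it,
#' selects the ridge strength by internal cross-validation, and fits the
#' IOKR model. Every random choice is derived from `seed`.
#'
#' @param records list of `compound_record`s carrying spectra.
#' @param p a [ppk_params()] object.
#' @param lambda_grid candidate ridge strengths.
#' @param folds internal CV folds.
#' @param seed master seed for the CV fold assignment.
#' @param curate run the three-step curation first (default TRUE).
#' @param out_dir optional directory to persist the curation report and
#'   training summary as JSON/TSV.
#' @return a `tmsid_train` list: `model`, `mask`, `curation`, `spectra`
#'   (the curated training spectra, used to compute query kernel columns),
#'   `kernel_stats`, `lambda`, `cv`, `p`.
#' @export
run_train <- function(records, p = ppk_params(),
                      lambda_grid = 10^seq(-4, 0, by = 1), folds = 5,
                      seed = 1, curate = TRUE, out_dir = NULL) {
  stopifnot(is.list(records), length(records) >= 2)
  cur <- if (curate) run_curation(records) else {
    structure(list(n_input = length(records), n_output = length(records),
                   kept = records, per_step_removed = integer(0),
                   audit = data.frame()), class = "curation_report")
  }
  kept <- cur$kept
  if (length(kept) < 2) stop("fewer than 2 records survive curation")
  ids <- vapply(kept, function(r) r$id, "")
  spectra <- stats::setNames(lapply(kept, function(r) r$spectrum), ids)
  mols <- stats::setNames(lapply(kept, function(r) r$mol), ids)
  fps <- fingerprint_matrix(mols)
  mask <- build_mask(fps)
  Y <- apply_mask(fps, mask)
  K_raw <- kernel_matrix(spectra, p = p)
  proc <- process_kernel(K_raw)
  sel <- select_lambda(proc$train, Y, grid = lambda_grid, folds = folds,
                       seed = seed)
  model <- iokr_fit(proc$train, Y, sel$lambda, mask_id = mask$mask_id)
  out <- list(model = model, mask = mask, curation = cur, spectra = spectra,
              kernel_stats = proc$stats, K_raw = K_raw, lambda = sel$lambda,
              cv = sel, p = p)
  class(out) <- "tmsid_train"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(
      list(n_input = cur$n_input, n_output = cur$n_output,
           removed = as.list(cur$per_step_removed),
           lambda = sel$lambda, cv_mse = as.list(sel$cv_mse),
           mask_retained = length(mask$retained), mask_id = mask$mask_id,
           ppk = unclass(p)),
      file.path(out_dir, "training_report.json"), auto_unbox = TRUE)
    if (nrow(cur$audit)) {
      utils::write.table(cur$audit, file.path(out_dir, "curation_audit.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  out
}

# processed kernel column(s) of query spectra against the training set
.query_columns <- function(train, queries) {
  K_cross <- kernel_matrix(queries, unname(train$spectra), p = train$p)
  diag_test <- vapply(queries, function(s) ppk(s, s, train$p), numeric(1))
  proc <- process_kernel(train$K_raw, K_cross, diag_test)
  proc$cross
}

#' Identify query spectra against candidate sets
#'
#' Computes the processed kernel column of each query spectrum against the
#' training set, predicts output-feature vectors, scores each candidate by
#' the linear fingerprint kernel, and ranks.
#'
#' @param train a `tmsid_train` from [run_train()].
#' @param queries named list of query [ei_spectrum()]s; names are query
#'   ids.
#' @param candidates list of [candidate_set()]s, one per query, in the same
#'   order (fingerprints must be unmasked 6,214-bit rows or already in the
#'   model's mask; unmasked inputs are masked automatically).
#' @return list with `rankings` (one `ranking_result` per query) and
#'   `table` (long data.frame: query_id, candidate_id, score, rank,
#'   is_true).
#' @export
run_identify <- function(train, queries, candidates) {
  stopifnot(inherits(train, "tmsid_train"),
            length(queries) == length(candidates))
  Kq <- .query_columns(train, queries)
  rankings <- vector("list", length(queries))
  rows <- list()
  for (i in seq_along(queries)) {
    cs <- candidates[[i]]
    stopifnot(inherits(cs, "candidate_set"))
    if (ncol(cs$fps) == train$mask$n_total) {
      cs <- candidate_set(cs$query_id, cs$ids,
                          apply_mask(cs$fps, train$mask),
                          true_id = if (cs$contains_true) cs$true_id else NA_character_,
                          mask_id = train$mask$mask_id)
    }
    sc <- predict_scores(train$model, Kq[i, ], cs)
    rk <- rank_candidates(sc, true_id = if (cs$contains_true) cs$true_id else NA_character_,
                          query_id = cs$query_id)
    rankings[[i]] <- rk
    rows[[i]] <- data.frame(query_id = cs$query_id, candidate_id = rk$ids,
                            score = rk$scores, rank = seq_along(rk$ids),
                            is_true = !rk$missing & rk$ids == cs$true_id,
                            stringsAsFactors = FALSE)
  }
  names(rankings) <- vapply(rankings, function(r) r$query_id, "")
  list(rankings = rankings, table = do.call(rbind, rows))
}

#' Evaluate identification results
#'
#' @param rankings list of `ranking_result`s (from [run_identify()]).
#' @param groups optional named character vector mapping query ids to group
#'   labels (e.g. the presence-in-training flag, a structural class, or a
#'   spectral cluster).
#' @param ks top-k cut-offs.
#' @param out_dir optional directory for TSV/JSON export of the summary.
#' @return the summary data.frame from [summarize_rankings()].
#' @export
run_evaluate <- function(rankings, groups = NULL, ks = c(1, 10, 20),
                         out_dir = NULL) {
  summ <- summarize_rankings(rankings, groups = groups, ks = ks)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(summ, file.path(out_dir, "evaluation_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summ, file.path(out_dir, "evaluation_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  summ
}

#' Run the full pipeline on a synthetic benchmark bundle
#'
#' Convenience wrapper: train on the bundle's training records, identify its
#' test queries against their candidate sets, and evaluate with the
#' in-training grouping.
#'
#' @param bundle a `synthetic_bundle` from [make_benchmark()].
#' @param p a [ppk_params()] object.
#' @param lambda_grid,folds passed to [run_train()].
#' @param curate whether to curate the (already compliant) training records.
#' @param out_dir optional output directory for stage artifacts.
#' @return list with `train`, `identify`, `summary`.
#' @export
run_pipeline <- function(bundle, p = ppk_params(),
                         lambda_grid = 10^seq(-4, 0, by = 1), folds = 5,
                         curate = FALSE, out_dir = NULL) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  train <- run_train(bundle$train, p = p, lambda_grid = lambda_grid,
                     folds = folds, seed = bundle$cfg$master_seed,
                     curate = curate, out_dir = out_dir)
  queries <- stats::setNames(lapply(bundle$test, function(r) r$spectrum),
                             vapply(bundle$test, function(r) r$id, ""))
  res <- run_identify(train, queries, bundle$candidates[names(queries)])
  groups <- stats::setNames(
    ifelse(vapply(bundle$test, function(r) isTRUE(r$in_training), logical(1)),
           "Yes", "No"),
    names(queries))
  summ <- run_evaluate(res$rankings, groups = groups, out_dir = out_dir)
  list(train = train, identify = res, summary = summ)
}
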