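#' Absolute ranking position of the correct candidate
#'
#' The number of candidates scored strictly higher than the correct
#' candidate, plus one. Tied candidates are not "better", so ties do not
#' increase the ARP. Queries whose candidate set lacks the truth propagate
#' as `NA` ("missing").
#'
#' @param r a `ranking_result` from [rank_candidates()].
#' @return positive integer, or `NA_integer_` for a missing truth.
#' @export
arp <- function(r) {
  stopifnot(inherits(r, "ranking_result"))
  if (r$missing) return(NA_integer_)
  true_score <- r$scores[r$rank_of_true]
  sum(r$scores > true_score) + 1L
}

#' Relative ranking position
#'
#' \deqn{RRP = \frac{1}{2}\left(1 + \frac{BC - WC}{TC - 1}\right)}
#' where BC is the number of candidates scored better than the correct one,
#' WC the number scored worse, and TC the total count. RRP is 0 when the
#' correct candidate is ranked first and 1 when it is ranked last. The
#' degenerate single-candidate case (TC = 1, undefined by the formula) is
#' returned as 0 with a warning: the sole candidate is the correct one.
#'
#' @param bc,wc,tc better/worse/total candidate counts with
#'   `bc + wc = tc - 1` (ties, which are neither better nor worse, make the
#'   equality an inequality `bc + wc <= tc - 1`).
#' @return numeric in `[0, 1]`.
#' @export
rrp <- function(bc, wc, tc) {
  stopifnot(tc >= 1, bc >= 0, wc >= 0)
  if (bc + wc > tc - 1) stop("inconsistent counts: bc + wc must be <= tc - 1")
  if (tc == 1) {
    warning("RRP undefined for a single-candidate set; returning 0 by convention")
    return(0)
  }
  0.5 * (1 + (bc - wc) / (tc - 1))
}

#' RRP of a ranking result
#'
#' Computes better/worse counts from the scores (strict comparisons, so tied
#' candidates count as neither) and evaluates [rrp()].
#'
#' @param r a `ranking_result`.
#' @return numeric in `[0, 1]`, or `NA_real_` for a missing truth.
#' @export
rrp_of <- function(r) {
  stopifnot(inherits(r, "ranking_result"))
  if (r$missing) return(NA_real_)
  ts <- r$scores[r$rank_of_true]
  rrp(sum(r$scores > ts), sum(r$scores < ts), length(r$scores))
}

#' Top-k identification accuracy
#'
#' The percentage of queries whose correct candidate is ranked within the
#' top k. Queries with a missing truth stay in the denominator (they can
#' never be in the top k), matching the convention that accuracies are
#' reported over all test derivatives.
#'
#' @param results non-empty list of `ranking_result`s.
#' @param k rank cut-off (>= 1).
#' @return percentage in `[0, 100]`.
#' @export
topk <- function(results, k) {
  stopifnot(is.list(results), length(results) >= 1, k >= 1)
  ranks <- vapply(results, function(r) {
    if (r$missing) NA_integer_ else r$rank_of_true
  }, integer(1))
  100 * sum(!is.na(ranks) & ranks <= k) / length(ranks)
}

#' Summarize identification results
#'
#' Builds the per-group and merged summary table: query counts, missing
#' counts (truth absent from the candidate set), top-k accuracies, and the
#' mean absolute and relative ranking positions. Missing queries are counted
#' in the top-k denominators but excluded from the ARP/RRP means.
#'
#' @param results list of `ranking_result`s.
#' @param groups optional named character vector mapping every query id to
#'   a group label; when supplied, one summary row per group plus a
#'   `"Merged"` row is produced.
#' @param ks rank cut-offs for the top-k columns.
#' @return data.frame with one row per group (and `"Merged"`), columns
#'   `group`, `n`, `n_missing`, `pct_missing`, `top<k>_n`, `top<k>_pct`,
#'   `mean_arp`, `mean_rrp`.
#' @export
summarize_rankings <- function(results, groups = NULL, ks = c(1, 10, 20)) {
  stopifnot(is.list(results), length(results) >= 1)
  qids <- vapply(results, function(r) r$query_id, "")
  if (!is.null(groups)) {
    if (!all(qids %in% names(groups))) {
      stop("grouping does not cover all query ids: ",
           paste(setdiff(qids, names(groups)), collapse = ", "))
    }
    labels <- groups[qids]
  } else {
    labels <- rep("Merged", length(results))
  }
  one <- function(rs, label) {
    ranks <- vapply(rs, function(r) {
      if (r$missing) NA_integer_ else r$rank_of_true
    }, integer(1))
    arps <- vapply(rs, arp, integer(1))
    rrps <- vapply(rs, rrp_of, numeric(1))
    row <- data.frame(group = label, n = length(rs),
                      n_missing = sum(is.na(ranks)),
                      pct_missing = 100 * mean(is.na(ranks)))
    for (k in ks) {
      nk <- sum(!is.na(ranks) & ranks <= k)
      row[[paste0("top", k, "_n")]] <- nk
      row[[paste0("top", k, "_pct")]] <- 100 * nk / length(rs)
    }
    row$mean_arp <- if (all(is.na(arps))) NA_real_ else mean(arps, na.rm = TRUE)
    row$mean_rrp <- if (all(is.na(rrps))) NA_real_ else mean(rrps, na.rm = TRUE)
    row
  }
  out <- list()
  if (!is.null(groups)) {
    for (g in sort(unique(labels))) {
      out[[length(out) + 1L]] <- one(results[labels == g], g)
    }
  }
  out[[length(out) + 1L]] <- one(results, "Merged")
  do.call(rbind, out)
}
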