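#' Bin a spectrum onto a fixed-width m/z grid
#'
#' Assigns every peak to bin `floor(mz / bin_width)` (half-open bins
#' `[i*w, (i+1)*w)`) and stores, per bin, the *average* intensity of the
#' peaks that fall in it. Bins without peaks are zero.
#'
#' @param s an [ei_spectrum()].
#' @param bin_width bin width in Da (default 1.0).
#' @return a `binned_spectrum`: list with `bins` (integer indices),
#'   `values` (mean intensities), `bin_width`.
#' @export
bin_spectrum <- function(s, bin_width = 1.0) {
  stopifnot(inherits(s, "ei_spectrum"))
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  if (n_peaks(s) == 0) {
    return(structure(list(bins = integer(0), values = numeric(0),
                          bin_width = bin_width), class = "binned_spectrum"))
  }
  b <- as.integer(floor(s$peaks$mz / bin_width))
  f <- factor(b, levels = sort(unique(b)))
  vals <- as.numeric(tapply(s$peaks$intensity, f, mean))
  structure(list(bins = sort(unique(b)), values = vals, bin_width = bin_width),
            class = "binned_spectrum")
}

# dense numeric vector over bins 0..max for a list of binned spectra
.densify <- function(bs_list) {
  stopifnot(length(bs_list) >= 1)
  w <- unique(vapply(bs_list, function(b) b$bin_width, numeric(1)))
  if (length(w) != 1) stop("binned spectra have mismatched bin widths")
  maxb <- max(0L, unlist(lapply(bs_list, function(b) b$bins)))
  m <- matrix(0, nrow = length(bs_list), ncol = maxb + 1L)
  for (i in seq_along(bs_list)) {
    b <- bs_list[[i]]
    if (length(b$bins)) m[i, b$bins + 1L] <- b$values
  }
  m
}

#' Cosine similarity between two binned spectra
#'
#' The dot product of the two intensity vectors divided by the product of
#' their norms; for non-negative intensities the value lies in `[0, 1]`,
#' with 0 meaning no shared bins and 1 meaning identical (up to scale)
#' spectra.
#'
#' @param v,u `binned_spectrum` objects with equal `bin_width` (vectors are
#'   implicitly zero-padded to a common length).
#' @return numeric scalar in `[0, 1]`.
#' @export
cosine_similarity <- function(v, u) {
  stopifnot(inherits(v, "binned_spectrum"), inherits(u, "binned_spectrum"))
  if (v$bin_width != u$bin_width) stop("bin widths differ")
  nv <- sqrt(sum(v$values^2)); nu <- sqrt(sum(u$values^2))
  if (nv == 0 || nu == 0) {
    stop("cosine similarity undefined for an all-zero spectrum vector")
  }
  shared <- intersect(v$bins, u$bins)
  if (!length(shared)) return(0)
  dot <- sum(v$values[match(shared, v$bins)] * u$values[match(shared, u$bins)])
  min(1, dot / (nv * nu))
}

#' All-against-all cosine similarity matrix
#'
#' @param spectra list of [ei_spectrum()] objects (length >= 1); names are
#'   used as labels.
#' @param bin_width bin width in Da.
#' @return symmetric numeric matrix in `[0, 1]` with unit diagonal.
#' @export
similarity_matrix <- function(spectra, bin_width = 1.0) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  bs <- lapply(spectra, bin_spectrum, bin_width = bin_width)
  m <- .densify(bs)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cosine similarity undefined for an all-zero spectrum vector")
  mn <- m / nrm
  S <- tcrossprod(mn)
  S[S > 1] <- 1; S[S < 0] <- 0
  labs <- names(spectra)
  if (is.null(labs)) labs <- vapply(spectra, function(s) s$name, "")
  dimnames(S) <- list(labs, labs)
  S
}

#' Consensus spectrum of replicate acquisitions
#'
#' Each member spectrum is binned, max-normalized (so high-abundance runs do
#' not dominate), and the consensus is the per-bin mean of the normalized
#' member vectors.
#'
#' @param spectra non-empty list of [ei_spectrum()] replicates of one
#'   compound.
#' @param bin_width bin width in Da.
#' @return a `binned_spectrum`.
#' @export
consensus_spectrum <- function(spectra, bin_width = 1.0) {
  if (!is.list(spectra) || length(spectra) == 0) {
    stop("consensus_spectrum needs at least one spectrum")
  }
  bs <- lapply(spectra, bin_spectrum, bin_width = bin_width)
  m <- .densify(bs)
  mx <- apply(m, 1, max)
  if (any(mx == 0)) stop("consensus member with all-zero intensities")
  cons <- colMeans(m / mx)
  keep <- which(cons > 0)
  structure(list(bins = keep - 1L, values = cons[keep], bin_width = bin_width),
            class = "binned_spectrum")
}

#' Hierarchical clustering of consensus spectra
#'
#' Agglomerative clustering (average linkage by default) on the cosine
#' distance `1 - cosine` between consensus vectors. The cluster count `k`
#' is supplied by the user.
#'
#' @param consensus list of `binned_spectrum` objects (length >= 2 for a
#'   real clustering; a single vector yields one cluster with a warning).
#' @param k number of clusters to cut the dendrogram into.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `labels` (integer cluster id per input), `hclust`
#'   (the dendrogram, `NULL` in the degenerate single-vector case), and
#'   `distance` (the distance matrix used).
#' @export
cluster_consensus <- function(consensus, k = 2, linkage = "average") {
  stopifnot(is.list(consensus))
  n <- length(consensus)
  if (n < 2) {
    warning("fewer than 2 consensus spectra; returning a single cluster")
    return(list(labels = rep(1L, n), hclust = NULL, distance = NULL))
  }
  m <- .densify(consensus)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("all-zero consensus vector")
  S <- tcrossprod(m / nrm)
  D <- 1 - S
  D[D < 0] <- 0
  diag(D) <- 0
  labs <- names(consensus) %||% as.character(seq_len(n))
  dimnames(D) <- list(labs, labs)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  labels <- stats::cutree(hc, k = min(k, n))
  list(labels = labels, hclust = hc, distance = D)
}
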