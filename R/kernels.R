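#' Probability product kernel parameters
#'
#' Each peak of a spectrum is modelled as a bivariate normal distribution in
#' (m/z, intensity) with shared diagonal covariance
#' `diag(sigma_mz^2, sigma_int^2)`, and a spectrum as the equally weighted
#' mixture of its peak components. The kernel between two spectra is the
#' integral of the product of the two mixture densities. Bandwidths are not
#' dictated by the data and are exposed here: the defaults are 0.5 Da
#' (half a nominal-resolution mass unit) and 0.05 intensity units on
#' max-normalized (`[0, 1]`) intensities.
#'
#' @param sigma_mz peak-position bandwidth in Da (> 0).
#' @param sigma_int peak-intensity bandwidth (> 0), on the scale set by
#'   `intensity_scaling`.
#' @param intensity_scaling `"max"` (default) rescales every spectrum's
#'   intensities to max 1 before kernel evaluation; `"none"` uses raw
#'   abundances.
#' @return a `ppk_params` list.
#' @export
ppk_params <- function(sigma_mz = 0.5, sigma_int = 0.05,
                       intensity_scaling = c("max", "none")) {
  intensity_scaling <- match.arg(intensity_scaling)
  if (!is.numeric(sigma_mz) || sigma_mz <= 0) stop("sigma_mz must be > 0")
  if (!is.numeric(sigma_int) || sigma_int <= 0) stop("sigma_int must be > 0")
  structure(list(sigma_mz = sigma_mz, sigma_int = sigma_int,
                 intensity_scaling = intensity_scaling),
            class = "ppk_params")
}

.ppk_prep <- function(s, p) {
  if (n_peaks(s) == 0) stop("PPK undefined for an empty spectrum")
  I <- s$peaks$intensity
  if (p$intensity_scaling == "max") {
    mx <- max(I)
    if (mx == 0) stop("PPK undefined for an all-zero-intensity spectrum")
    I <- I / mx
  }
  list(m = s$peaks$mz, I = I)
}

#' Probability product kernel between two EI spectra
#'
#' Closed form of the Gaussian-mixture product integral with normalized
#' mixture weights (1/N per peak) and shared diagonal covariance:
#' \deqn{K(a,b) = \frac{1}{N_a N_b} \sum_{i \in a}\sum_{j \in b}
#'   \frac{1}{4\pi\sigma_m\sigma_I}
#'   \exp\!\left(-\frac{(m_i-m_j)^2}{4\sigma_m^2}
#'               -\frac{(I_i-I_j)^2}{4\sigma_I^2}\right)}
#'
#' @param a,b non-empty [ei_spectrum()] objects.
#' @param p a [ppk_params()] object.
#' @return non-negative numeric scalar.
#' @export
ppk <- function(a, b, p = ppk_params()) {
  stopifnot(inherits(p, "ppk_params"))
  pa <- .ppk_prep(a, p); pb <- .ppk_prep(b, p)
  const <- 1 / (4 * pi * p$sigma_mz * p$sigma_int)
  dm2 <- outer(pa$m, pb$m, "-")^2 / (4 * p$sigma_mz^2)
  di2 <- outer(pa$I, pb$I, "-")^2 / (4 * p$sigma_int^2)
  const * sum(exp(-(dm2 + di2))) / (length(pa$m) * length(pb$m))
}

#' PPK kernel matrix between two spectrum lists
#'
#' @param X,Y lists of [ei_spectrum()] objects; when `Y` is `NULL` the
#'   symmetric Gram matrix of `X` is computed (only the upper triangle is
#'   evaluated).
#' @param p a [ppk_params()] object.
#' @return numeric matrix `length(X)` x `length(Y)`, with attributes
#'   `state = "raw"` and `params`.
#' @export
kernel_matrix <- function(X, Y = NULL, p = ppk_params()) {
  stopifnot(is.list(X), length(X) >= 1)
  symmetric <- is.null(Y)
  if (symmetric) Y <- X
  px <- lapply(X, .ppk_prep, p = p)
  py <- if (symmetric) px else lapply(Y, .ppk_prep, p = p)
  const <- 1 / (4 * pi * p$sigma_mz * p$sigma_int)
  K <- matrix(0, length(X), length(Y))
  for (i in seq_along(X)) {
    jstart <- if (symmetric) i else 1L
    for (j in jstart:length(Y)) {
      dm2 <- outer(px[[i]]$m, py[[j]]$m, "-")^2 / (4 * p$sigma_mz^2)
      di2 <- outer(px[[i]]$I, py[[j]]$I, "-")^2 / (4 * p$sigma_int^2)
      K[i, j] <- const * sum(exp(-(dm2 + di2))) /
        (length(px[[i]]$m) * length(py[[j]]$m))
      if (symmetric && j > i) K[j, i] <- K[i, j]
    }
  }
  rownames(K) <- names(X); colnames(K) <- names(Y)
  attr(K, "state") <- "raw"
  attr(K, "params") <- p
  K
}

#' Center a kernel matrix in training feature space
#'
#' The training block is double-centered,
#' `Kc = K - 1K/n - K1/n + 1K1/n^2`. Cross blocks (rows = test points,
#' columns = training points) are centered with the *training* means, i.e.
#' the test points are centered in the training feature space. Centering is
#' idempotent.
#'
#' @param K_train square symmetric raw training kernel.
#' @param K_cross optional raw test-by-train kernel block.
#' @param diag_test optional raw self-similarities `k(x, x)` of the test
#'   points; when supplied, the centered test self-similarities are returned
#'   too (needed for normalization of cross blocks).
#' @return list with `train` (centered train block), `cross` (centered
#'   cross block or `NULL`), `diag_test` (centered test self-similarities or
#'   `NULL`), and `stats` (the training column means and grand mean).
#' @export
center_kernel <- function(K_train, K_cross = NULL, diag_test = NULL) {
  stopifnot(is.matrix(K_train), nrow(K_train) == ncol(K_train))
  n <- nrow(K_train)
  colmu <- colMeans(K_train)
  grand <- mean(K_train)
  Kc <- K_train - matrix(colmu, n, n, byrow = TRUE) -
    matrix(rowMeans(K_train), n, n) + grand
  out <- list(train = Kc, cross = NULL, diag_test = NULL,
              stats = list(colmu = colmu, grand = grand))
  if (!is.null(K_cross)) {
    stopifnot(ncol(K_cross) == n)
    rowmu <- rowMeans(K_cross)
    out$cross <- K_cross - matrix(colmu, nrow(K_cross), n, byrow = TRUE) -
      matrix(rowmu, nrow(K_cross), n) + grand
    if (!is.null(diag_test)) {
      stopifnot(length(diag_test) == nrow(K_cross))
      out$diag_test <- diag_test - 2 * rowmu + grand
    }
  }
  attr(out$train, "state") <- "centered"
  out
}

#' Cosine-normalize a kernel matrix
#'
#' `Kn(i, j) = K(i, j) / sqrt(K(i, i) K(j, j))`. For cross blocks the
#' column references are the training diagonal and the row references are
#' the test self-similarities in the same (e.g. centered) state.
#'
#' @param K kernel matrix (train block, or test-by-train cross block).
#' @param diag_row self-similarities for the rows (defaults to `diag(K)`
#'   for a square block).
#' @param diag_col self-similarities for the columns (defaults to
#'   `diag_row`).
#' @return normalized matrix with unit diagonal for a train block.
#' @export
normalize_kernel <- function(K, diag_row = NULL, diag_col = NULL) {
  stopifnot(is.matrix(K))
  if (is.null(diag_row)) {
    if (nrow(K) != ncol(K)) stop("diag_row required for non-square blocks")
    diag_row <- diag(K)
  }
  if (is.null(diag_col)) {
    if (nrow(K) != ncol(K)) stop("diag_col required for non-square blocks")
    diag_col <- diag_row
  }
  if (any(diag_row <= 0) || any(diag_col <= 0)) {
    stop("normalize_kernel: non-positive self-similarity (degenerate input)")
  }
  out <- K / sqrt(outer(diag_row, diag_col))
  attr(out, "state") <- paste0(attr(K, "state") %||% "raw", "+normalized")
  out
}

#' Center-then-normalize a training kernel and matching cross block
#'
#' Convenience wrapper applying [center_kernel()] followed by
#' [normalize_kernel()] (the order used throughout the pipeline) to the
#' training Gram matrix and, optionally, a test-by-train block.
#'
#' @param K_train raw training Gram matrix.
#' @param K_cross optional raw test-by-train block.
#' @param diag_test raw test self-similarities (required with `K_cross`).
#' @return list with processed `train`, `cross` (or `NULL`), and the
#'   centering/normalization references in `stats` for processing later
#'   queries.
#' @export
process_kernel <- function(K_train, K_cross = NULL, diag_test = NULL) {
  if (!is.null(K_cross) && is.null(diag_test)) {
    stop("diag_test is required to process a cross block")
  }
  ck <- center_kernel(K_train, K_cross, diag_test)
  dtr <- diag(ck$train)
  if (any(dtr <= 0)) {
    # duplicated training spectra have zero centered self-similarity;
    # guard with a tiny floor so normalization stays defined
    dtr <- pmax(dtr, 1e-12)
  }
  train <- ck$train / sqrt(outer(dtr, dtr))
  attr(train, "state") <- "centered+normalized"
  cross <- NULL
  if (!is.null(ck$cross)) {
    dte <- pmax(ck$diag_test, 1e-12)
    cross <- ck$cross / sqrt(outer(dte, dtr))
    attr(cross, "state") <- "centered+normalized"
  }
  list(train = train, cross = cross,
       stats = c(ck$stats, list(diag_train_centered = dtr)))
}
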