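#' Construct an EI mass spectrum
#'
#' The unit of all spectral computation: a peak list of (m/z, abundance)
#' pairs at nominal (unit) resolution, plus identity metadata as recorded in
#' NIST-style MSP exports. Peaks are sorted by ascending m/z; duplicate m/z
#' values within one record are merged by summing their intensities
#' (abundances are ion counts, so replicate entries of the same nominal mass
#' accumulate).
#'
#' @param mz numeric vector of mass-to-charge values (Da), all > 0.
#' @param intensity non-negative abundances, same length as `mz`.
#' @param name compound/record name.
#' @param inchikey,formula,cas,library_id optional text metadata
#'   (`NA` = absent; never invented).
#' @param mw,exact_mass optional molecular weight / exact mass in Da.
#' @param extra named list of unrecognized header fields carried through I/O.
#' @return an object of class `ei_spectrum`.
#' @export
ei_spectrum <- function(mz, intensity, name = NA_character_,
                        inchikey = NA_character_, formula = NA_character_,
                        mw = NA_real_, exact_mass = NA_real_,
                        cas = NA_character_, library_id = NA_character_,
                        extra = list()) {
  stopifnot(length(mz) == length(intensity))
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(mz <= 0)) stop("all m/z must be finite and > 0")
    if (any(!is.finite(intensity)) || any(intensity < 0)) {
      stop("all intensities must be finite and >= 0")
    }
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
      mz <- unique(mz)
    }
  }
  structure(list(
    peaks = data.frame(mz = mz, intensity = intensity),
    name = as.character(name), inchikey = as.character(inchikey),
    formula = as.character(formula), mw = as.numeric(mw),
    exact_mass = as.numeric(exact_mass), cas = as.character(cas),
    library_id = as.character(library_id), extra = extra
  ), class = "ei_spectrum")
}

#' @export
print.ei_spectrum <- function(x, ...) {
  cat(sprintf("<ei_spectrum> %s: %d peaks", ifelse(is.na(x$name), "(unnamed)", x$name),
              nrow(x$peaks)))
  if (!is.na(x$mw)) cat(sprintf(", MW %.2f", x$mw))
  cat("\n")
  invisible(x)
}

n_peaks <- function(s) nrow(s$peaks)

# header keys we map onto named fields; keys are matched after lowercasing
# and stripping spaces/hyphens/underscores
.MSP_FIELDS <- c(name = "name", inchikey = "inchikey", formula = "formula",
                 mf = "formula", mw = "mw", exactmass = "exact_mass",
                 casno = "cas", cas = "cas", "cas#" = "cas",
                 nistno = "library_id", nistid = "library_id",
                 dbid = "library_id", id = "library_id")

#' Read an MSP-format spectral library
#'
#' Parses NIST-style MSP text records (`Name:` ... `Num Peaks:` followed by
#' peak lines). Both `"mz intensity"` and `"mz<tab>intensity;"` peak-line
#' dialects are accepted; several peak pairs may share one line. Header keys
#' are case-insensitive; unknown keys are preserved in `$extra`. Duplicate
#' m/z within one record are merged by intensity sum and peaks are sorted
#' ascending.
#'
#' @param path file path.
#' @param on_error `"abort"` (default): stop at the first malformed record
#'   with file/line context; `"skip"`: drop malformed records with a warning.
#' @return list of [ei_spectrum()] objects.
#' @export
read_msp <- function(path, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # split into records on blank lines
  blank <- grepl("^\\s*$", lines)
  rec_id <- cumsum(c(TRUE, diff(!blank) == 1) & !blank)
  rec_id[blank] <- 0L
  specs <- list()
  for (r in setdiff(unique(rec_id), 0L)) {
    idx <- which(rec_id == r)
    res <- tryCatch(.parse_msp_record(lines[idx], path, idx[1]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "abort") stop(conditionMessage(res), call. = FALSE)
      warning(conditionMessage(res), call. = FALSE)
    } else {
      specs[[length(specs) + 1L]] <- res
    }
  }
  specs
}

.parse_msp_record <- function(rl, path, line0) {
  fields <- list(); extra <- list(); npk <- NA_integer_; pk_start <- NA_integer_
  for (i in seq_along(rl)) {
    ln <- rl[i]
    m <- regmatches(ln, regexec("^\\s*([^:]+?)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3 && !grepl("^[0-9.]", m[2])) {
      key <- tolower(gsub("[ -]", "_", m[2]))
      val <- m[3]
      if (key %in% c("num_peaks", "numpeaks")) {
        npk <- as.integer(val); pk_start <- i + 1L
        break
      }
      std <- unname(.MSP_FIELDS[gsub("_", "", key)])
      if (!is.na(std)) fields[[std]] <- val else extra[[key]] <- val
    }
  }
  if (is.na(npk)) {
    stop(sprintf("%s: record at line %d has no 'Num Peaks:' header", path, line0))
  }
  pk_lines <- if (pk_start <= length(rl)) rl[pk_start:length(rl)] else character(0)
  toks <- unlist(strsplit(paste(pk_lines, collapse = " "), "[;,]?[[:space:]]+|;"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals))) {
    stop(sprintf("%s: record '%s' at line %d has unparsable peak token '%s'",
                 path, fields$name %||% "?", line0, toks[which(is.na(vals))[1]]))
  }
  if (length(vals) %% 2 != 0 || length(vals) / 2 != npk) {
    stop(sprintf("%s: record '%s' at line %d lists %d peak values for 'Num Peaks: %d'",
                 path, fields$name %||% "?", line0, length(vals), npk))
  }
  mz <- vals[seq(1, length(vals), by = 2)]
  it <- vals[seq(2, length(vals), by = 2)]
  ei_spectrum(mz, it,
              name = fields$name %||% NA_character_,
              inchikey = fields$inchikey %||% NA_character_,
              formula = fields$formula %||% NA_character_,
              mw = as.numeric(fields$mw %||% NA),
              exact_mass = as.numeric(fields$exact_mass %||% NA),
              cas = fields$cas %||% NA_character_,
              library_id = fields$library_id %||% NA_character_,
              extra = extra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write spectra to an MSP file
#'
#' Emits NIST-style MSP records with a deterministic field order and peak
#' lines formatted as `"mz intensity"` with fixed 4-decimal precision, so
#' that a write/read round trip reproduces the peak list exactly at that
#' precision.
#'
#' @param spectra list of [ei_spectrum()] objects (may be empty).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_msp <- function(spectra, path) {
  stopifnot(is.list(spectra))
  con <- file(path, "w")
  on.exit(close(con))
  fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.4f", x))
  for (s in spectra) {
    stopifnot(inherits(s, "ei_spectrum"))
    wl <- function(key, val) {
      if (length(val) == 1 && !is.na(val)) {
        writeLines(paste0(key, ": ", val), con)
      }
    }
    wl("Name", s$name)
    wl("InChIKey", s$inchikey)
    wl("Formula", s$formula)
    if (!is.na(s$mw)) wl("MW", fmt_num(s$mw))
    if (!is.na(s$exact_mass)) wl("ExactMass", fmt_num(s$exact_mass))
    wl("CASNO", s$cas)
    wl("DB_ID", s$library_id)
    for (k in names(s$extra)) wl(k, s$extra[[k]])
    writeLines(paste0("Num Peaks: ", n_peaks(s)), con)
    if (n_peaks(s) > 0) {
      writeLines(paste(fmt_num(s$peaks$mz), fmt_num(s$peaks$intensity)), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Clamp a spectrum to an m/z acquisition window
#'
#' Retains peaks with `low <= mz <= high` (closed interval). The default
#' window is m/z 50 up to the molecular weight plus 10 Da, the final
#' modification applied to curated training spectra.
#'
#' @param s an [ei_spectrum()].
#' @param low lower bound in Da (default 50).
#' @param high upper bound in Da; defaults to `s$mw + 10`, which requires
#'   the spectrum's molecular weight to be known.
#' @return a copy of `s` with out-of-window peaks removed; metadata
#'   unchanged. Idempotent.
#' @export
clamp_mz_range <- function(s, low = 50, high = NULL) {
  stopifnot(inherits(s, "ei_spectrum"))
  if (is.null(high)) {
    if (is.na(s$mw)) stop("clamp_mz_range: spectrum has no MW and no explicit 'high'")
    high <- s$mw + 10
  }
  keep <- s$peaks$mz >= low & s$peaks$mz <= high
  s$peaks <- s$peaks[keep, , drop = FALSE]
  rownames(s$peaks) <- NULL
  s
}
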