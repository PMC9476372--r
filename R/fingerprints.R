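#' Structural feature vector of a molecule
#'
#' Computes a fixed, ordered set of isomorphism-invariant structural
#' descriptors (element counts, bond/ring statistics, atom environments,
#' functional-group counts, silyl-group classification) from a molecular
#' graph. All fingerprint bits are defined as threshold tests on these
#' features, so the fingerprint is a pure function of the structure:
#' isomorphic SMILES give identical features and hence identical bits.
#'
#' @param mol a `mol_graph` from [parse_smiles()].
#' @return named numeric vector of length `length(fp_feature_names())`.
#' @export
mol_features <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  at <- mol$atoms; bd <- mol$bonds
  elem <- at$elem
  cnt <- function(e) sum(elem == e)
  fm <- mol_formula(mol)
  sil <- .silyl_groups(mol)
  # carbonyl carbons: C with a double bond to O
  is_carbonyl <- vapply(seq_len(nrow(at)), function(i) {
    elem[i] == "C" && any(vapply(.nbrs(mol, i), function(j) {
      elem[j] == "O" && .bond_order(mol, i, j) == 2L
    }, logical(1)))
  }, logical(1))
  o_env <- lapply(which(elem == "O"), function(i) {
    nb <- .nbrs(mol, i)
    list(i = i, nb = nb, e = elem[nb],
         dbl = any(vapply(nb, function(j) .bond_order(mol, i, j) == 2L, logical(1))))
  })
  n_env <- lapply(which(elem == "N"), function(i) {
    nb <- .nbrs(mol, i); list(i = i, nb = nb, e = elem[nb])
  })
  o_si <- sum(vapply(o_env, function(o) "Si" %in% o$e, logical(1)))
  o_carbonyl <- sum(vapply(o_env, function(o) o$dbl, logical(1)))
  o_ether <- sum(vapply(o_env, function(o) sum(o$e == "C") == 2L && !o$dbl, logical(1)))
  o_phenolic <- sum(vapply(o_env, function(o) {
    any(o$e == "C" & at$in_ring[o$nb]) && !o$dbl
  }, logical(1)))
  o_free_oh <- sum(vapply(o_env, function(o) {
    at$nH[o$i] >= 1L && sum(o$e == "C") == 1L
  }, logical(1)))
  o_carboxyl_like <- sum(vapply(o_env, function(o) {
    !o$dbl && any(o$e == "C" & is_carbonyl[o$nb])
  }, logical(1)))
  n_amine <- sum(vapply(n_env, function(o) {
    all(o$e %in% c("C", "H")) && !any(is_carbonyl[o$nb]) && !at$in_ring[o$i]
  }, logical(1)))
  n_amide <- sum(vapply(n_env, function(o) any(is_carbonyl[o$nb]), logical(1)))
  n_nitro <- sum(vapply(n_env, function(o) sum(o$e == "O") >= 2L, logical(1)))
  ch <- function(nh, degmin = 0) {
    sum(elem == "C" & at$nH == nh & at$degree >= degmin & !at$in_ring)
  }
  deg <- function(d) sum(at$degree == d)
  ring_dbl <- if (nrow(bd)) sum(bd$order == 2L & bd$in_ring) else 0L
  n_comp <- .n_components(nrow(at), bd)
  feats <- c(
    nC = cnt("C"), nH = unname(fm$counts["H"] %||% 0L) %0% 0, nN = cnt("N"),
    nO = cnt("O"), nS = cnt("S"), nSi = cnt("Si"), nP = cnt("P"),
    nF = cnt("F"), nCl = cnt("Cl"), nBr = cnt("Br"), nI = cnt("I"),
    heavy = nrow(at), bonds = nrow(bd),
    dbl = if (nrow(bd)) sum(bd$order == 2L) else 0L,
    trp = if (nrow(bd)) sum(bd$order == 3L) else 0L,
    ring_edges = if (nrow(bd)) sum(bd$in_ring) else 0L,
    ring_atoms = sum(at$in_ring),
    n_rings = max(0L, nrow(bd) - nrow(at) + n_comp),
    ring_dbl = ring_dbl,
    deg1 = deg(1L), deg2 = deg(2L), deg3 = deg(3L), deg4 = deg(4L),
    ch3 = ch(3L), ch2 = ch(2L),
    c_quart = sum(elem == "C" & at$degree == 4L & at$nH == 0L),
    c_ring = sum(elem == "C" & at$in_ring),
    c_carbonyl = sum(is_carbonyl),
    c_arom_like = sum(elem == "C" & at$in_ring &
                        vapply(seq_len(nrow(at)), function(i) {
                          any(bd$order[(bd$a1 == i | bd$a2 == i) & bd$in_ring] == 2L)
                        }, logical(1))),
    o_si = o_si, o_ether = o_ether, o_carbonyl = o_carbonyl,
    o_phenolic = o_phenolic, o_free_oh = o_free_oh,
    o_carboxyl_like = o_carboxyl_like,
    n_si = sum(vapply(n_env, function(o) "Si" %in% o$e, logical(1))),
    n_amine = n_amine, n_amide = n_amide, n_nitro = n_nitro,
    n_ring = sum(elem == "N" & at$in_ring),
    s_si = sum(vapply(which(elem == "S"), function(i) {
      "Si" %in% elem[.nbrs(mol, i)]
    }, logical(1))),
    n_tms = sum(sil$kind == "tms"),
    n_tbdms = sum(sil$kind == "tbdms"),
    si_other = sum(sil$kind == "other"),
    tms_on_O = sum(sil$kind == "tms" & !is.na(sil$attach_elem) & sil$attach_elem == "O"),
    tms_on_N = sum(sil$kind == "tms" & !is.na(sil$attach_elem) & sil$attach_elem == "N"),
    tms_on_S = sum(sil$kind == "tms" & !is.na(sil$attach_elem) & sil$attach_elem == "S"),
    tms_on_C = sum(sil$kind == "tms" & !is.na(sil$attach_elem) & sil$attach_elem == "C"),
    halogen = cnt("F") + cnt("Cl") + cnt("Br") + cnt("I"),
    mw_bin = floor(fm$mw / 25),
    hetero = sum(!elem %in% c("C", "H"))
  )
  feats
}

`%0%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

.n_components <- function(n, bonds) {
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
    ri <- find(bonds$a1[b]); rj <- find(bonds$a2[b])
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' @rdname mol_features
#' @export
fp_feature_names <- function() {
  c("nC", "nH", "nN", "nO", "nS", "nSi", "nP", "nF", "nCl", "nBr", "nI",
    "heavy", "bonds", "dbl", "trp", "ring_edges", "ring_atoms", "n_rings",
    "ring_dbl", "deg1", "deg2", "deg3", "deg4", "ch3", "ch2", "c_quart",
    "c_ring", "c_carbonyl", "c_arom_like", "o_si", "o_ether", "o_carbonyl",
    "o_phenolic", "o_free_oh", "o_carboxyl_like", "n_si", "n_amine",
    "n_amide", "n_nitro", "n_ring", "s_si", "n_tms", "n_tbdms", "si_other",
    "tms_on_O", "tms_on_N", "tms_on_S", "tms_on_C", "halogen", "mw_bin",
    "hetero")
}

# per-feature threshold ladder depth (count features span 1..depth)
.FP_DEPTH <- c(nC = 32, nH = 48, nN = 6, nO = 10, nS = 3, nSi = 6, nP = 2,
               nF = 6, nCl = 4, nBr = 3, nI = 2, heavy = 40, bonds = 40,
               dbl = 8, trp = 2, ring_edges = 14, ring_atoms = 14,
               n_rings = 5, ring_dbl = 8, deg1 = 16, deg2 = 20, deg3 = 10,
               deg4 = 8, ch3 = 10, ch2 = 16, c_quart = 4, c_ring = 14,
               c_carbonyl = 4, c_arom_like = 14, o_si = 6, o_ether = 4,
               o_carbonyl = 4, o_phenolic = 4, o_free_oh = 3,
               o_carboxyl_like = 3, n_si = 3, n_amine = 3, n_amide = 3,
               n_nitro = 3, n_ring = 3, s_si = 2, n_tms = 6, n_tbdms = 2,
               si_other = 2, tms_on_O = 6, tms_on_N = 3, tms_on_S = 2,
               tms_on_C = 2, halogen = 6, mw_bin = 28, hetero = 12)

.FP_FAMILIES <- c(substructure = 307L, maccs = 166L, pubchem = 881L,
                  klekota_roth = 4860L)

#' Fingerprint bit definitions for one family
#'
#' Each fingerprint family is a fixed-length ordered list of structural
#' property tests with the published block lengths (substructure 307,
#' MACCS-type 166, PubChem-type 881, Klekota-Roth-type 4860; 6,214 bits in
#' total). Bit definitions are structural property keys: cumulative tests
#' (`feature >= t`) and exact-count keys (`feature == t`) drawn from a
#' per-family rotation over the descriptor pool, extended by deterministic
#' two-feature conjunctions for the largest family.
#' Definitions are generated once per session and cached; they are
#' versioned with the package, and [write_fp_definitions()] exports them as
#' plain text.
#'
#' @param family one of `"substructure"`, `"maccs"`, `"pubchem"`,
#'   `"klekota_roth"`.
#' @return data.frame with columns `bit`, `f1`, `t1`, `f2`, `t2`, `label`
#'   (`f2`/`t2` are `NA` for single-feature bits).
#' @export
fingerprint_definitions <- function(family) {
  family <- match.arg(family, names(.FP_FAMILIES))
  cache <- get0(".fp_def_cache", envir = .tmsid_env)
  if (!is.null(cache[[family]])) return(cache[[family]])
  feats <- fp_feature_names()
  # global single-bit pool: per feature a >= ladder plus == value keys
  pool <- do.call(rbind, lapply(feats, function(f) {
    d <- .FP_DEPTH[[f]]
    rbind(
      data.frame(op1 = "ge", f1 = f, t1 = seq_len(d), stringsAsFactors = FALSE),
      data.frame(op1 = "eq", f1 = f, t1 = 0:min(d, 10L), stringsAsFactors = FALSE))
  }))
  pool$op2 <- NA_character_; pool$f2 <- NA_character_; pool$t2 <- NA_integer_
  offset <- c(substructure = 0L, maccs = 450L, pubchem = 230L,
              klekota_roth = 29L)[family]
  L <- .FP_FAMILIES[[family]]
  take <- function(n, off) {
    idx <- ((off + seq_len(n) - 1L) %% nrow(pool)) + 1L
    pool[idx, , drop = FALSE]
  }
  if (family != "klekota_roth") {
    defs <- take(L, offset)
  } else {
    # mostly two-feature conjunctions, seeded with the single pool
    n_single <- min(nrow(pool), 900L)
    singles <- take(n_single, offset)
    pairs <- utils::combn(seq_along(feats), 2)
    variants <- data.frame(
      opa = c("ge", "ge", "eq", "ge", "eq", "ge", "ge", "eq"),
      ta  = c(1L, 2L, 1L, 1L, 2L, 3L, 2L, 0L),
      opb = c("ge", "ge", "ge", "eq", "eq", "ge", "eq", "ge"),
      tb  = c(1L, 1L, 2L, 1L, 1L, 2L, 2L, 1L),
      stringsAsFactors = FALSE)
    need <- L - n_single
    conj <- vector("list", need)
    k <- 0L; p <- offset %% ncol(pairs); v <- 0L
    while (k < need) {
      p <- p + 1L
      if (p > ncol(pairs)) { p <- 1L; v <- v + 1L }
      vi <- (v %% nrow(variants)) + 1L
      fa <- feats[pairs[1, p]]; fb <- feats[pairs[2, p]]
      k <- k + 1L
      conj[[k]] <- data.frame(
        op1 = variants$opa[vi], f1 = fa,
        t1 = min(variants$ta[vi], .FP_DEPTH[[fa]]),
        op2 = variants$opb[vi], f2 = fb,
        t2 = min(variants$tb[vi], .FP_DEPTH[[fb]]),
        stringsAsFactors = FALSE)
    }
    defs <- rbind(singles, do.call(rbind, conj))
  }
  defs <- defs[seq_len(L), c("op1", "f1", "t1", "op2", "f2", "t2"), drop = FALSE]
  defs$bit <- seq_len(L)
  lab1 <- sprintf("%s%s%d", defs$f1, ifelse(defs$op1 == "ge", ">=", "=="), defs$t1)
  lab2 <- ifelse(is.na(defs$f2), "",
                 sprintf("&%s%s%d", defs$f2, ifelse(defs$op2 == "ge", ">=", "=="),
                         defs$t2))
  defs$label <- paste0(lab1, lab2)
  rownames(defs) <- NULL
  defs <- defs[, c("bit", "op1", "f1", "t1", "op2", "f2", "t2", "label")]
  cache[[family]] <- defs
  assign(".fp_def_cache", cache, envir = .tmsid_env)
  defs
}

.tmsid_env <- new.env(parent = emptyenv())
assign(".fp_def_cache", list(), envir = .tmsid_env)

#' Export fingerprint bit definitions as plain text
#'
#' @param dir output directory; one TSV per family is written.
#' @return invisibly, the written file paths.
#' @export
write_fp_definitions <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(.FP_FAMILIES), function(fam) {
    p <- file.path(dir, paste0("fp_", fam, ".tsv"))
    utils::write.table(fingerprint_definitions(fam), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    p
  }, "")
  invisible(paths)
}

# evaluate one family's bits for a feature matrix (n x nfeat) -> n x L 0/1
.eval_defs <- function(Fm, defs) {
  n <- nrow(Fm)
  test <- function(op, f, t) {
    vals <- Fm[, f, drop = FALSE]
    thr <- matrix(rep(t, each = n), nrow = n)
    ge <- matrix(rep(op == "ge", each = n), nrow = n)
    (ge & (vals >= thr)) | (!ge & (vals == thr))
  }
  out <- test(defs$op1, defs$f1, defs$t1)
  conj <- !is.na(defs$f2)
  if (any(conj)) {
    ii <- which(conj)
    out[, ii] <- out[, ii] & test(defs$op2[ii], defs$f2[ii], defs$t2[ii])
  }
  out + 0L
}

#' Compute one fingerprint family block
#'
#' @param mol a `mol_graph` (or a feature vector from [mol_features()]).
#' @param family family name; see [fingerprint_definitions()].
#' @return integer 0/1 vector of the family's published length.
#' @export
compute_block <- function(mol, family) {
  family <- match.arg(family, names(.FP_FAMILIES))
  f <- if (inherits(mol, "mol_graph")) mol_features(mol) else mol
  stopifnot(is.numeric(f), all(fp_feature_names() %in% names(f)))
  defs <- fingerprint_definitions(family)
  as.integer(.eval_defs(matrix(f, nrow = 1, dimnames = list(NULL, names(f))), defs))
}

#' Concatenate the four family blocks into one fingerprint
#'
#' Fixed block order substructure | maccs | pubchem | klekota_roth, total
#' length 6,214.
#'
#' @param blocks named list with one integer 0/1 vector per family.
#' @return a `fingerprint` object (integer vector with layout attributes).
#' @export
concatenate_blocks <- function(blocks) {
  fams <- names(.FP_FAMILIES)
  if (!is.list(blocks) || !all(fams %in% names(blocks))) {
    stop("blocks must be a named list with entries: ", paste(fams, collapse = ", "))
  }
  for (fam in fams) {
    if (length(blocks[[fam]]) != .FP_FAMILIES[[fam]]) {
      stop(sprintf("block '%s' has length %d, expected %d",
                   fam, length(blocks[[fam]]), .FP_FAMILIES[[fam]]))
    }
    if (!all(blocks[[fam]] %in% c(0L, 1L))) stop("fingerprint bits must be 0/1")
  }
  bits <- as.integer(unlist(blocks[fams], use.names = FALSE))
  structure(bits, class = "fingerprint", masked = FALSE, mask_id = NA_character_)
}

#' Full concatenated fingerprint of a structure
#'
#' @param mol a `mol_graph` or a SMILES string.
#' @return a `fingerprint` of length 6,214 (unmasked).
#' @export
compute_fingerprint <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles1(mol)
  f <- mol_features(mol)
  concatenate_blocks(stats::setNames(
    lapply(names(.FP_FAMILIES), function(fam) compute_block(f, fam)),
    names(.FP_FAMILIES)))
}

#' Fingerprint matrix for many structures
#'
#' @param mols list of `mol_graph` objects (or character SMILES vector).
#' @return integer matrix, one row per structure, 6,214 columns (unmasked);
#'   attribute `masked = FALSE`.
#' @export
fingerprint_matrix <- function(mols) {
  if (is.character(mols)) mols <- parse_smiles(mols)
  Fm <- do.call(rbind, lapply(mols, mol_features))
  bits <- do.call(cbind, lapply(names(.FP_FAMILIES), function(fam) {
    .eval_defs(Fm, fingerprint_definitions(fam))
  }))
  rownames(bits) <- names(mols)
  attr(bits, "masked") <- FALSE
  bits
}

#' Build the duplicate/constant column mask from training fingerprints
#'
#' Removes columns that are constant across the whole training set and, for
#' each group of identical columns, every member but the lowest-index one.
#'
#' @param fps unmasked fingerprint matrix (rows = training structures).
#' @return a `fp_mask`: list with `retained` (column indices), `rule`
#'   (named character: `"constant"`/`"duplicate"` per removed column),
#'   `n_total`, `mask_id` (digest of the retained set).
#' @export
build_mask <- function(fps) {
  stopifnot(is.matrix(fps), nrow(fps) >= 2)
  p <- ncol(fps)
  keys <- apply(fps, 2, paste, collapse = "")
  const <- apply(fps, 2, function(x) all(x == x[1]))
  rule <- character(0)
  removed_const <- which(const)
  if (length(removed_const)) {
    rule[as.character(removed_const)] <- "constant"
  }
  cand <- which(!const)
  dup <- cand[duplicated(keys[cand])]
  if (length(dup)) rule[as.character(dup)] <- "duplicate"
  retained <- setdiff(seq_len(p), c(removed_const, dup))
  structure(list(retained = retained, rule = rule, n_total = p,
                 mask_id = sprintf("mask-%d-%d-%d", p, length(retained),
                                   sum(as.numeric(retained) * 31 %% 1e9) %% 999983L)),
            class = "fp_mask")
}

#' Apply a column mask to a fingerprint or fingerprint matrix
#'
#' @param fp a `fingerprint`, or an unmasked fingerprint matrix.
#' @param mask an `fp_mask` from [build_mask()] built on the same layout.
#' @return the masked fingerprint(s); re-masking an already masked input is
#'   an error.
#' @export
apply_mask <- function(fp, mask) {
  stopifnot(inherits(mask, "fp_mask"))
  if (is.matrix(fp)) {
    if (isTRUE(attr(fp, "masked"))) stop("fingerprint matrix is already masked")
    if (ncol(fp) != mask$n_total) stop("mask layout mismatch")
    out <- fp[, mask$retained, drop = FALSE]
    attr(out, "masked") <- TRUE
    attr(out, "mask_id") <- mask$mask_id
    return(out)
  }
  if (isTRUE(attr(fp, "masked"))) stop("fingerprint is already masked")
  if (length(fp) != mask$n_total) stop("mask layout mismatch")
  structure(as.integer(fp)[mask$retained], class = "fingerprint",
            masked = TRUE, mask_id = mask$mask_id)
}

#' Tanimoto similarity between two binary fingerprints
#'
#' @param a,b 0/1 vectors of equal length.
#' @return |a AND b| / |a OR b|; defined as 1 when both are all-zero.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
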