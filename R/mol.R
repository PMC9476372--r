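# Standard valences used to assign implicit hydrogens on neutral atoms.
.VALENCE <- c(C = 4, N = 3, O = 2, S = 2, Si = 4, P = 3,
              F = 1, Cl = 1, Br = 1, I = 1, B = 3, H = 1)

# IUPAC 2021 standard atomic weights (rounded) and monoisotopic masses.
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06,
                  Si = 28.085, P = 30.974, F = 18.998, Cl = 35.45,
                  Br = 79.904, I = 126.904, B = 10.81)
.MONO_MASS <- c(C = 12, H = 1.007825, N = 14.003074, O = 15.994915,
                S = 31.972071, Si = 27.976927, P = 30.973762, F = 18.998403,
                Cl = 34.968853, Br = 78.918338, I = 126.904473, B = 11.009305)

#' Parse SMILES strings into molecular graphs
#'
#' Parses one or more SMILES strings with OpenBabel (via ChemmineOB) and
#' converts each into a light molecular-graph representation: an atom table,
#' a bond table with Kekule bond orders, implicit hydrogen counts derived
#' from standard valences, and ring-membership flags. All downstream
#' structure logic (curation rules, fingerprints, molecular weight) operates
#' on this graph so that it is independent of any toolkit's aromaticity or
#' hydrogen model.
#'
#' @param smiles character vector of SMILES strings; names are kept as ids.
#' @param on_error `"abort"` (default) to stop on the first unparsable
#'   string, or `"na"` to return `NULL` for failed entries.
#' @return a list of `mol_graph` objects (or `NULL` entries under
#'   `on_error = "na"`). Each `mol_graph` has elements `atoms` (data.frame:
#'   `elem`, `nH`, `degree`, `in_ring`), `bonds` (data.frame: `a1`, `a2`,
#'   `order`, `in_ring`), and `smiles`.
#' @export
parse_smiles <- function(smiles, on_error = c("abort", "na")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(names(smiles))) names(smiles) <- paste0("mol", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ok <- ChemmineR::validSDF(sdf)
  if (any(!ok) && on_error == "abort") {
    stop("unparsable SMILES: ", paste(names(smiles)[!ok], collapse = ", "))
  }
  out <- vector("list", length(smiles))
  names(out) <- names(smiles)
  for (i in seq_along(smiles)) {
    if (!ok[i]) next
    out[[i]] <- .sdf_to_graph(sdf[[i]], smiles[[i]])
  }
  out
}

#' @rdname parse_smiles
#' @export
parse_smiles1 <- function(smiles) parse_smiles(smiles)[[1]]

.sdf_to_graph <- function(sdf, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(elem)
  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  # Drop explicit hydrogens into implicit counts so heavy-atom indices are
  # stable regardless of how the SMILES was written.
  expl_h <- which(elem == "H")
  nH <- integer(n)
  if (length(expl_h)) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[b]; a2 <- bonds$a2[b]
      if (elem[a1] == "H" && elem[a2] != "H") nH[a2] <- nH[a2] + 1L
      if (elem[a2] == "H" && elem[a1] != "H") nH[a1] <- nH[a1] + 1L
    }
    keep <- setdiff(seq_len(n), expl_h)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    bonds <- bonds[elem[bonds$a1] != "H" & elem[bonds$a2] != "H", , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    nH <- nH[keep]; elem <- elem[keep]; n <- length(elem)
  }
  bondsum <- integer(n); degree <- integer(n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      bondsum[bonds$a1[b]] <- bondsum[bonds$a1[b]] + bonds$order[b]
      bondsum[bonds$a2[b]] <- bondsum[bonds$a2[b]] + bonds$order[b]
      degree[bonds$a1[b]] <- degree[bonds$a1[b]] + 1L
      degree[bonds$a2[b]] <- degree[bonds$a2[b]] + 1L
    }
  }
  val <- .VALENCE[elem]
  val[is.na(val)] <- 0
  nH <- nH + pmax(0L, as.integer(val) - bondsum)
  ring_edge <- .ring_edges(n, bonds)
  in_ring <- rep(FALSE, n)
  if (any(ring_edge)) {
    in_ring[unique(c(bonds$a1[ring_edge], bonds$a2[ring_edge]))] <- TRUE
  }
  bonds$in_ring <- ring_edge
  structure(list(
    atoms = data.frame(elem = elem, nH = nH, degree = degree,
                       in_ring = in_ring, stringsAsFactors = FALSE),
    bonds = bonds,
    smiles = smiles
  ), class = "mol_graph")
}

# An edge lies on a ring iff its endpoints stay connected after its removal.
# Molecules here are small, so the quadratic scan is fine.
.ring_edges <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0) return(logical(0))
  adj <- vector("list", n)
  for (b in seq_len(m)) {
    adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], b)
    adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], b)
  }
  res <- logical(m)
  for (b in seq_len(m)) {
    src <- bonds$a1[b]; dst <- bonds$a2[b]
    seen <- logical(n); seen[src] <- TRUE
    stack <- src
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (e in adj[[v]]) {
        if (e == b) next
        w <- if (bonds$a1[e] == v) bonds$a2[e] else bonds$a1[e]
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    res[b] <- seen[dst]
  }
  res
}

#' Molecular formula, weight and exact mass from a molecular graph
#'
#' Computes element counts (including implicit hydrogens from standard
#' valences), the Hill-order molecular formula, the average molecular weight
#' and the monoisotopic exact mass.
#'
#' @param mol a `mol_graph` from [parse_smiles()].
#' @return list with `counts` (named integer), `formula` (character),
#'   `mw` (Da), `exact_mass` (Da).
#' @export
mol_formula <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  elems <- c(mol$atoms$elem, rep("H", sum(mol$atoms$nH)))
  counts <- table(factor(elems, levels = names(.ATOMIC_MASS)))
  counts <- counts[counts > 0]
  counts <- stats::setNames(as.integer(counts), names(counts))
  hill <- c("C", "H", sort(setdiff(names(counts), c("C", "H"))))
  hill <- hill[hill %in% names(counts)]
  formula <- paste0(vapply(hill, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, ""), collapse = "")
  list(counts = counts,
       formula = formula,
       mw = sum(.ATOMIC_MASS[names(counts)] * counts),
       exact_mass = sum(.MONO_MASS[names(counts)] * counts))
}

# neighbour atom indices of atom i
.nbrs <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# order of the bond between atoms i and j (0 if none)
.bond_order <- function(mol, i, j) {
  b <- mol$bonds
  hit <- (b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i)
  if (any(hit)) b$order[hit][1] else 0L
}

# Classify every silicon atom as an intact silyl group or not.
# Returns a data.frame with one row per Si atom:
#   idx, kind ("tms", "tbdms", "other"), attach (index of the non-methyl
#   substituent, NA if none), attach_elem.
.silyl_groups <- function(mol) {
  si <- which(mol$atoms$elem == "Si")
  if (!length(si)) {
    return(data.frame(idx = integer(0), kind = character(0),
                      attach = integer(0), attach_elem = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(si, function(i) {
    nb <- .nbrs(mol, i)
    is_me <- vapply(nb, function(j) {
      mol$atoms$elem[j] == "C" && mol$atoms$degree[j] == 1L &&
        mol$atoms$nH[j] == 3L && .bond_order(mol, i, j) == 1L
    }, logical(1))
    is_tbu <- vapply(nb, function(j) {
      if (mol$atoms$elem[j] != "C" || .bond_order(mol, i, j) != 1L) return(FALSE)
      jnb <- setdiff(.nbrs(mol, j), i)
      length(jnb) == 3L && all(vapply(jnb, function(k) {
        mol$atoms$elem[k] == "C" && mol$atoms$degree[k] == 1L &&
          mol$atoms$nH[k] == 3L
      }, logical(1)))
    }, logical(1))
    rest <- nb[!is_me & !is_tbu]
    kind <- "other"
    attach <- NA_integer_
    if (length(nb) == 4L) {
      if (sum(is_me) == 3L) {
        kind <- "tms"; attach <- nb[!is_me]
      } else if (sum(is_me) == 2L && sum(is_tbu) == 1L) {
        kind <- "tbdms"; attach <- rest
      }
    }
    data.frame(idx = i, kind = kind,
               attach = if (length(attach)) attach[1] else NA_integer_,
               attach_elem = if (!is.na(attach[1])) mol$atoms$elem[attach[1]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count intact trimethylsilyl groups in a structure
#'
#' A TMS group is a silicon atom carrying exactly three methyl carbons and
#' one further substituent. Counts every such silicon regardless of what the
#' fourth substituent is.
#'
#' @param mol a `mol_graph`.
#' @return integer count.
#' @export
count_tms <- function(mol) {
  sum(.silyl_groups(mol)$kind == "tms")
}
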