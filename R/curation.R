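#' A compound record: structure plus identity metadata
#'
#' @param id record identifier (unique within a library).
#' @param smiles structure as SMILES.
#' @param inchikey optional InChIKey (used for the name/structure
#'   consistency check; `NA` = absent).
#' @param mw molecular weight in Da; computed from the structure when `NA`.
#' @param spectrum optional [ei_spectrum()] linked to this record.
#' @param mol optional pre-parsed `mol_graph` (parsed from `smiles`
#'   otherwise).
#' @return a `compound_record`: list with `id`, `smiles`, `mol`,
#'   `inchikey`, `formula`, `mw`, `exact_mass`, `n_tms`, `spectrum`.
#' @export
compound_record <- function(id, smiles, inchikey = NA_character_,
                            mw = NA_real_, spectrum = NULL, mol = NULL) {
  if (is.null(mol)) mol <- parse_smiles1(smiles)
  fm <- mol_formula(mol)
  structure(list(
    id = as.character(id), smiles = smiles, mol = mol,
    inchikey = as.character(inchikey), formula = fm$formula,
    mw = if (is.na(mw)) fm$mw else as.numeric(mw),
    exact_mass = fm$exact_mass, n_tms = count_tms(mol),
    spectrum = spectrum
  ), class = "compound_record")
}

# Ordered exclusion categories (first match wins). Labels double as the
# rule names in curation reports.
.EXCLUSION_CATEGORIES <- c(
  "si_si", "c_si", "o_si_other", "n_si_other", "n_o_si_or_n_n_si",
  "s_si_other", "p_si", "rearrangement_tms", "tbdms", "mixed_tms_tbdms",
  "derivatization_agent", "inorganic", "heavy_metal")

#' Classify a structure for step-1 curation
#'
#' Applies the ordered structural exclusion categories for silylated library
#' entries: Si-Si bonds; C-Si bonds outside intact silyl groups; O-Si other
#' than hydroxyl/carboxyl-TMS; N-Si other than primary/secondary-amine TMS;
#' N-O-Si and N-N-Si chains; S-Si other than thiol-TMS; phosphorus-silyl
#' linkages; TMS on carbon (rearrangement products); TBDMS derivatives;
#' mixed TMS/TBDMS; derivatization agents; inorganic (no carbon skeleton
#' outside silyl groups); heavy-metal-containing. A structure matching none
#' of the categories is retained. Each category is an explicit graph rule on
#' the parsed structure; the first matching category is reported.
#'
#' A genuine TMS derivative carries C-Si bonds inside each trimethylsilyl
#' group, so the C-Si category fires only for silicon atoms that are not an
#' intact TMS/TBDMS group, or for silyl groups attached through carbon
#' (which the rearrangement category captures for intact TMS).
#'
#' @param x a `compound_record`, `mol_graph`, or SMILES string.
#' @return list with `keep` (logical) and `category` (`NA` when retained).
#' @export
classify_structure <- function(x) {
  mol <- if (inherits(x, "compound_record")) x$mol
         else if (inherits(x, "mol_graph")) x
         else parse_smiles1(x)
  at <- mol$atoms; bd <- mol$bonds
  elem <- at$elem
  sil <- .silyl_groups(mol)
  has_tms <- any(sil$kind == "tms")
  has_tbdms <- any(sil$kind == "tbdms")
  hit <- function(cat) list(keep = FALSE, category = cat)

  allowed_elems <- c("C", "H", "N", "O", "P", "S", "Br", "I", "F", "Cl", "Si")
  chain <- function(e1, e2, e3) {
    # any path a-b-c with elements e1-e2-e3
    any(vapply(which(elem == e2), function(b) {
      nb <- elem[.nbrs(mol, b)]
      any(nb == e1) && any(nb == e3) && (e1 != e3 || sum(nb == e1) >= 2)
    }, logical(1)))
  }

  # 1. Si-Si bonds
  if (nrow(bd) && any(elem[bd$a1] == "Si" & elem[bd$a2] == "Si")) {
    return(hit("si_si"))
  }
  # 2. C-Si bonds outside intact silyl groups
  if (any(sil$kind == "other")) return(hit("c_si"))
  for (g in which(!is.na(sil$attach))) {
    # 3-7: inspect what each intact silyl group is attached to
    a <- sil$attach[g]; ae <- sil$attach_elem[g]
    if (is.na(ae)) next
    if (ae == "O") {
      onb <- setdiff(.nbrs(mol, a), sil$idx[g])
      one <- elem[onb]
      if (any(one == "N")) return(hit("n_o_si_or_n_n_si"))
      if (any(one == "P")) return(hit("p_si"))
      if (any(one == "Si")) return(hit("o_si_other"))   # silyl ether chains
      if (length(onb) == 0) return(hit("o_si_other"))    # bare Si-OH ester
      if (!all(one == "C")) return(hit("o_si_other"))
    } else if (ae == "N") {
      nnb <- setdiff(.nbrs(mol, a), sil$idx[g])
      nne <- elem[nnb]
      if (any(nne == "N")) return(hit("n_o_si_or_n_n_si"))
      if (any(nne == "O")) return(hit("n_o_si_or_n_n_si"))
      if (any(nne == "P")) return(hit("p_si"))
      if (any(nne == "Si")) return(hit("n_si_other"))
      # primary/secondary amine-TMS only: remaining substituents are
      # non-carbonyl carbons, at most two of them, single-bonded
      is_carbonyl_c <- vapply(nnb, function(j) {
        elem[j] == "C" && any(vapply(.nbrs(mol, j), function(k) {
          elem[k] == "O" && .bond_order(mol, j, k) == 2L
        }, logical(1)))
      }, logical(1))
      dbl_on_n <- any(vapply(nnb, function(j) .bond_order(mol, a, j) > 1L, logical(1)))
      if (any(is_carbonyl_c) || dbl_on_n || length(nnb) > 2L) {
        return(hit("n_si_other"))
      }
    } else if (ae == "S") {
      snb <- setdiff(.nbrs(mol, a), sil$idx[g])
      sne <- elem[snb]
      if (any(sne == "P")) return(hit("p_si"))
      if (!all(sne == "C") || length(snb) != 1L) return(hit("s_si_other"))
    } else if (ae == "P") {
      return(hit("p_si"))
    }
  }
  # 7 (chain form): P-(O/N/S)-Si when not already caught
  if (any(elem == "P") && any(elem == "Si")) {
    if (chain("P", "O", "Si") || chain("P", "N", "Si") || chain("P", "S", "Si")) {
      return(hit("p_si"))
    }
  }
  # 8. TMS attached through carbon: rearrangement product
  if (any(sil$kind == "tms" & !is.na(sil$attach_elem) & sil$attach_elem == "C")) {
    return(hit("rearrangement_tms"))
  }
  # 9/10. TBDMS and mixed derivatives
  if (has_tbdms && !has_tms) return(hit("tbdms"))
  if (has_tbdms && has_tms) return(hit("mixed_tms_tbdms"))
  # 11. derivatization agents (chlorosilanes, silylamine reagents,
  #     N-silyl(halo)acetamides such as MSTFA/BSTFA)
  if (any(elem == "Si")) {
    si_cl <- nrow(bd) && any((elem[bd$a1] == "Si" & elem[bd$a2] == "Cl") |
                             (elem[bd$a2] == "Si" & elem[bd$a1] == "Cl"))
    si_n_si <- chain("Si", "N", "Si")
    amide_si <- any(vapply(which(elem == "N"), function(i) {
      nb <- .nbrs(mol, i)
      "Si" %in% elem[nb] && any(vapply(nb, function(j) {
        elem[j] == "C" && any(vapply(.nbrs(mol, j), function(k) {
          elem[k] == "O" && .bond_order(mol, j, k) == 2L
        }, logical(1)))
      }, logical(1)))
    }, logical(1)))
    if (si_cl || si_n_si || amide_si) return(hit("derivatization_agent"))
  }
  # 12. inorganic: no carbon outside silyl methyls
  silyl_c <- unlist(lapply(which(!is.na(sil$attach) | sil$kind != "other"), function(g) {
    setdiff(.nbrs(mol, sil$idx[g]), sil$attach[g])
  }))
  skeleton_c <- setdiff(which(elem == "C"), silyl_c)
  if (length(skeleton_c) == 0) return(hit("inorganic"))
  # 13. heavy metals / elements outside the organic set
  if (!all(elem %in% allowed_elems)) return(hit("heavy_metal"))
  list(keep = TRUE, category = NA_character_)
}

#' Remove high-mass records
#'
#' @param records list of `compound_record`s.
#' @param threshold mass cut-off in Da (default 1000).
#' @param mode `">"` (default) removes records with `mw > threshold`;
#'   `">="` removes `mw >= threshold`.
#' @return list with `kept`, `removed`, and `needs_review` (records with
#'   unknown MW, never silently kept).
#' @export
filter_high_mass <- function(records, threshold = 1000, mode = c(">", ">=")) {
  mode <- match.arg(mode)
  mw <- vapply(records, function(r) r$mw, numeric(1))
  review <- is.na(mw)
  over <- !review & if (mode == ">") mw > threshold else mw >= threshold
  list(kept = records[!over & !review], removed = records[over],
       needs_review = records[review])
}

#' Spectral quality criteria for a silylated-library entry
#'
#' Evaluates all four baseline quality criteria and reports every violation:
#' \enumerate{
#'   \item the spectrum extends to at least MW + 10 Da (proxied by the
#'     maximum observed peak m/z when no acquisition-range metadata exists);
#'   \item the molecular ion and its 13C isotope peak are present (peaks at
#'     nominal MW and MW + 1, each within +/- 0.5 Da);
#'   \item at least one TMS marker fragment is present among m/z 73, 147,
#'     221, 295 (one to four TMS groups); `strict_markers = TRUE` instead
#'     requires the marker corresponding to `min(n_tms, 4)` groups;
#'   \item at least five fragment-ion peaks besides the molecular-ion
#'     cluster.
#' }
#'
#' @param s an [ei_spectrum()].
#' @param mw molecular weight in Da (defaults to `s$mw`).
#' @param n_tms number of TMS groups (used by `strict_markers`).
#' @param strict_markers require the n_tms-specific marker instead of any.
#' @param tol m/z matching tolerance in Da (unit-resolution default 0.5).
#' @return list with `pass` (logical) and `violated` (character vector of
#'   criterion names, empty when passing).
#' @export
quality_filter <- function(s, mw = s$mw, n_tms = NA_integer_,
                           strict_markers = FALSE, tol = 0.5) {
  stopifnot(inherits(s, "ei_spectrum"))
  if (is.na(mw)) stop("quality_filter: MW must be known")
  mz <- s$peaks$mz
  violated <- character(0)
  has_peak <- function(target) any(abs(mz - target) <= tol)
  mw_nom <- round(mw)
  # acquisition range: use recorded scan-range metadata when available,
  # otherwise proxy with the maximum observed peak
  upper <- s$extra$upper_mz %||% if (length(mz)) max(mz) else 0
  if (upper < mw + 10 - tol) {
    violated <- c(violated, "acquisition_range")
  }
  if (!(has_peak(mw_nom) && has_peak(mw_nom + 1))) {
    violated <- c(violated, "molecular_ion")
  }
  markers <- c(73, 147, 221, 295)
  if (strict_markers && !is.na(n_tms) && n_tms >= 1) {
    need <- markers[min(n_tms, 4)]
    if (!has_peak(need)) violated <- c(violated, "tms_marker")
  } else {
    if (!any(vapply(markers, has_peak, logical(1)))) {
      violated <- c(violated, "tms_marker")
    }
  }
  frag <- mz[abs(mz - mw_nom) > 1 + tol]
  if (length(frag) < 5) violated <- c(violated, "fragment_count")
  list(pass = length(violated) == 0, violated = violated)
}

#' Run the three-step curation pipeline on a spectral library
#'
#' Step 1 removes structurally excluded entries ([classify_structure()]) and
#' erroneous entries whose stored InChIKey does not match the one computed
#' from the structure (skeleton block comparison; checked only when both are
#' available). Step 2 removes high-mass records ([filter_high_mass()]).
#' Step 3 removes records failing the spectral quality criteria
#' ([quality_filter()]). Finally each surviving spectrum is clamped to the
#' m/z window 50 to MW + 10 ([clamp_mz_range()]). Each removed record is
#' attributed to exactly one rule (first match wins); records with errors
#' are reported, never fatal for the whole run.
#'
#' @param records list of `compound_record`s, each carrying a spectrum.
#' @param mass_threshold,mass_mode see [filter_high_mass()].
#' @param strict_markers see [quality_filter()].
#' @param check_inchikey perform the stored-vs-computed InChIKey
#'   consistency check (requires OpenBabel via ChemmineOB).
#' @param clamp apply the final m/z-range clamp (default TRUE).
#' @return a `curation_report`: list with `n_input`, `n_output`, `kept`
#'   (curated records with clamped spectra), `per_step_removed` (named
#'   counts by rule), and `audit` (data.frame: id, status, rule).
#' @export
run_curation <- function(records, mass_threshold = 1000, mass_mode = ">",
                         strict_markers = FALSE, check_inchikey = TRUE,
                         clamp = TRUE) {
  stopifnot(is.list(records))
  n_input <- length(records)
  audit <- data.frame(id = vapply(records, function(r) r$id, ""),
                      status = rep("kept", n_input),
                      rule = rep(NA_character_, n_input),
                      stringsAsFactors = FALSE)
  removed <- stats::setNames(integer(0), character(0))
  bump <- function(rule) {
    cur <- if (rule %in% names(removed)) removed[[rule]] else 0L
    removed[rule] <<- cur + 1L
  }
  kept <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    rule <- NA_character_
    # step 1: structural exclusion
    cl <- tryCatch(classify_structure(r), error = function(e) e)
    if (inherits(cl, "error")) {
      rule <- "structure_error"
    } else if (!cl$keep) {
      rule <- cl$category
    } else if (check_inchikey && !is.na(r$inchikey)) {
      ik <- tryCatch(compute_inchikey(r$smiles), error = function(e) NA_character_)
      if (!is.na(ik) &&
          substr(ik, 1, 14) != substr(r$inchikey, 1, 14)) {
        rule <- "erroneous_entry"
      }
    }
    # step 2: high mass
    if (is.na(rule)) {
      if (is.na(r$mw)) {
        rule <- "needs_review_mw"
      } else if (if (mass_mode == ">") r$mw > mass_threshold else r$mw >= mass_threshold) {
        rule <- "high_mass"
      }
    }
    # step 3: spectral quality
    if (is.na(rule)) {
      if (is.null(r$spectrum)) {
        rule <- "missing_spectrum"
      } else {
        qf <- quality_filter(r$spectrum, mw = r$mw, n_tms = r$n_tms,
                             strict_markers = strict_markers)
        if (!qf$pass) rule <- paste0("quality_", qf$violated[1])
      }
    }
    if (is.na(rule)) {
      if (clamp) r$spectrum <- clamp_mz_range(r$spectrum, 50, r$mw + 10)
      kept[[length(kept) + 1L]] <- r
    } else {
      audit$status[i] <- "removed"
      audit$rule[i] <- rule
      bump(rule)
    }
  }
  structure(list(n_input = n_input, n_output = length(kept), kept = kept,
                 per_step_removed = removed, audit = audit),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> %d records in, %d kept, %d removed\n",
              x$n_input, x$n_output, x$n_input - x$n_output))
  if (length(x$per_step_removed)) {
    for (r in names(x$per_step_removed)) {
      cat(sprintf("  %-24s %d\n", r, x$per_step_removed[[r]]))
    }
  }
  invisible(x)
}

#' Compute an InChIKey from a SMILES string
#'
#' Thin wrapper over OpenBabel's InChI generation (via ChemmineOB), used by
#' the erroneous-entry consistency check.
#'
#' @param smiles a single SMILES string.
#' @return the InChIKey as a character scalar.
#' @export
compute_inchikey <- function(smiles) {
  out <- ChemmineOB::convertFormat("SMI", "INCHIKEY", smiles)
  trimws(strsplit(out, "\n")[[1]][1])
}
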