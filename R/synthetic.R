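#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the statistical structure the identification
#' pipeline assumes: TMS-derivatizable scaffolds with 1-5 silyl groups and
#' molecular weights in the test-set range 182-575 Da, EI spectra carrying
#' TMS marker fragments (m/z 73/147/221/295), a molecular ion with its 13C
#' isotope peak, fingerprint-determined fragment peaks in the instrument
#' scan range m/z 50-800, replicate-level multiplicative noise, peak
#' dropout, background clutter, and formula-free decoy candidate sets of
#' controlled structural (Tanimoto) similarity.
#'
#' @param n_train number of training (structure, spectrum) pairs.
#' @param n_test number of test queries.
#' @param overlap_fraction share of test compounds whose spectra also occur
#'   in the training set (the presence-in-training split).
#' @param n_tms_range integer range of silyl-group counts to admit.
#' @param mw_range admissible derivative molecular-weight window in Da.
#' @param fragment_map_seed seed of the deterministic bit-to-fragment map.
#' @param peaks_per_bit characteristic fragment positions per active bit.
#' @param fragment_map_density share of active fingerprint bits that emit
#'   fragment peaks (keeps spectra at a realistic few dozen peaks).
#' @param intensity_noise_sd sd of the multiplicative lognormal intensity
#'   noise.
#' @param peak_dropout_p per-peak dropout probability (diagnostic peaks -
#'   molecular ion, isotope, TMS markers - are never dropped).
#' @param background_peaks number of uniform clutter peaks per spectrum.
#' @param candidates_per_query candidate-set size (including the truth when
#'   present).
#' @param decoy_similarity_range Tanimoto interval (on masked fingerprints
#'   when a mask is supplied) from which decoys are drawn.
#' @param p_missing probability that a query's candidate set omits the
#'   truth.
#' @param n_decoy_pool extra compounds generated only to serve as decoys.
#' @param n_replicates replicate spectra per test compound in the bundle.
#' @param master_seed master seed; identical config + seed gives
#'   bit-identical output.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_train = 300, n_test = 50,
                             overlap_fraction = 0.6,
                             n_tms_range = c(1, 5),
                             mw_range = c(182, 575),
                             fragment_map_seed = 42,
                             peaks_per_bit = 1,
                             fragment_map_density = 0.08,
                             intensity_noise_sd = 0.05,
                             peak_dropout_p = 0.02,
                             background_peaks = 3,
                             candidates_per_query = 50,
                             decoy_similarity_range = c(0, 0.4),
                             p_missing = 0,
                             n_decoy_pool = 250,
                             n_replicates = 3,
                             master_seed = 1) {
  cfg <- list(n_train = n_train, n_test = n_test,
              overlap_fraction = overlap_fraction,
              n_tms_range = n_tms_range, mw_range = mw_range,
              fragment_map_seed = fragment_map_seed,
              peaks_per_bit = peaks_per_bit,
              fragment_map_density = fragment_map_density,
              intensity_noise_sd = intensity_noise_sd,
              peak_dropout_p = peak_dropout_p,
              background_peaks = background_peaks,
              candidates_per_query = candidates_per_query,
              decoy_similarity_range = decoy_similarity_range,
              p_missing = p_missing, n_decoy_pool = n_decoy_pool,
              n_replicates = n_replicates, master_seed = master_seed)
  stopifnot(cfg$n_train >= 0, cfg$n_test >= 0,
            cfg$overlap_fraction >= 0, cfg$overlap_fraction <= 1,
            cfg$peak_dropout_p >= 0, cfg$peak_dropout_p <= 1,
            cfg$p_missing >= 0, cfg$p_missing <= 1,
            cfg$fragment_map_density > 0, cfg$fragment_map_density <= 1,
            cfg$intensity_noise_sd >= 0, cfg$background_peaks >= 0,
            cfg$candidates_per_query >= 1,
            length(cfg$decoy_similarity_range) == 2,
            cfg$decoy_similarity_range[1] <= cfg$decoy_similarity_range[2])
  structure(cfg, class = "generator_config")
}

# Deterministic 31-bit integer hash (Lehmer-style scramble); stays exact in
# double arithmetic.
.hash_int <- function(x, seed = 0) {
  y <- ((x + 1) * 2654435761 + (seed + 1) * 40503) %% 2147483647
  (y * 48271) %% 2147483647
}

# ---- scaffold template grammar ---------------------------------------------
# Each template is a SMILES string with site tokens:
#   {O}  hydroxyl       -> O[Si](C)(C)C
#   {N}  primary amine  -> N[Si](C)(C)C
#   {S}  thiol          -> S[Si](C)(C)C
#   {A}  carboxyl       -> C(=O)O[Si](C)(C)C
# Tokens are placed so that plain textual expansion yields valid SMILES
# (trailing position or inside explicit parentheses).
.expand_template <- function(tpl) {
  s <- gsub("{O}", "O[Si](C)(C)C", tpl, fixed = TRUE)
  s <- gsub("{N}", "N[Si](C)(C)C", s, fixed = TRUE)
  s <- gsub("{S}", "S[Si](C)(C)C", s, fixed = TRUE)
  gsub("{A}", "C(=O)O[Si](C)(C)C", s, fixed = TRUE)
}

.n_sites <- function(tpl) {
  lengths(regmatches(tpl, gregexpr("\\{[ONSA]\\}", tpl)))
}

#' Scaffold template universe of TMS-derivatizable structures
#'
#' Enumerates the built-in grammar of derivatizable scaffolds (aliphatic
#' alcohols and diols, phenols and diphenols, aliphatic and aromatic acids,
#' alicyclic alcohols, amines, bisphenols, amino acids and other poly-silyl
#' scaffolds), fully derivatized at every active site. Structural classes
#' mirror the six attachment-moiety classes used for grouped evaluation.
#'
#' @return data.frame with `template`, `smiles` (derivatized), `n_sites`,
#'   `class`, `family` (scaffold family id used as the designed cluster
#'   label).
#' @export
tms_template_universe <- function() {
  alkyl <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC",
             "CCCCCCCC", "CC(C)C", "CC(C)(C)C", "CCCCCCCCCC")
  rsub <- c(alkyl, "F", "Cl", "Br", "OC", "N(=O)=O", "C(F)(F)F")
  tpl <- list()
  add <- function(template, class, family) {
    tpl[[length(tpl) + 1L]] <<- data.frame(template = template, class = class,
                                           family = family,
                                           stringsAsFactors = FALSE)
  }
  # aliphatic alcohols: primary chains, secondary, branched, diols
  for (a in alkyl[3:11]) add(paste0("C", a, "{O}"), "aliphatic_O", "alkanol")
  for (a in alkyl[4:11]) add(paste0("CC(", a, "){O}"), "aliphatic_O", "alkanol")
  for (a in alkyl[4:10]) add(paste0("CC(C)(", a, "){O}"), "aliphatic_O", "alkanol")
  for (a in alkyl) {
    add(paste0("CC(C", a, "C{O})C{O}"), "poly", "diol")
    add(paste0("C(", a, ")(C{O})C{O}"), "poly", "diol")
  }
  # phenols: mono- and di-substituted rings
  for (r in rsub) add(paste0("c1cc(", r, ")ccc1{O}"), "phenyl_O", "phenol")
  for (r1 in rsub) for (r2 in c("C", "CC", "CCC", "CC(C)C", "Cl", "F", "OC",
                                "N(=O)=O")) {
    add(paste0("c1c(", r1, ")cc(", r2, ")cc1{O}"), "phenyl_O", "phenol")
  }
  for (r in rsub) add(paste0("c1ccc(", r, ")cc1C{O}"), "aliphatic_O", "benzylalcohol")
  for (r1 in rsub) for (r2 in c("C", "Cl", "OC", "CC")) {
    add(paste0("c1cc(", r1, ")cc(", r2, ")c1C{O}"), "aliphatic_O", "benzylalcohol")
  }
  add("c1ccc2cc({O})ccc2c1", "phenyl_O", "phenol")          # naphthol-like
  add("c1ccc2c({O})cccc2c1", "phenyl_O", "phenol")
  # diphenols (hydroquinone/catechol-like) -> poly
  for (r in rsub) {
    add(paste0("c1cc({O})c(", r, ")cc1{O}"), "poly", "diphenol")
    add(paste0("c1c(", r, ")cc({O})cc1{O}"), "poly", "diphenol")
  }
  # carboxylic acids: aliphatic and aromatic; salicylic-like 2-site
  for (a in alkyl[3:11]) add(paste0("C", a, "{A}"), "aliphatic_O", "alkanoic")
  for (a in alkyl[4:10]) add(paste0("CC(", a, "){A}"), "aliphatic_O", "alkanoic")
  for (r in rsub) add(paste0("c1cc(", r, ")ccc1{A}"), "phenyl_O", "benzoic")
  for (r1 in rsub) for (r2 in c("C", "Cl", "OC", "F")) {
    add(paste0("c1c(", r1, ")cc(", r2, ")cc1{A}"), "phenyl_O", "benzoic")
  }
  for (r in rsub) add(paste0("c1cc(", r, ")cc({O})c1{A}"), "poly", "salicylic")
  # alicyclic alcohols
  for (r in c("", "C", "CC", "CCC", "CC(C)C", "CCCC", "CCCCC", "CCCCCC",
              "c2ccccc2")) {
    ring5 <- if (nzchar(r)) paste0("C1CC(", r, ")CC1{O}") else "C1CCCC1{O}"
    ring6 <- if (nzchar(r)) paste0("C1CCC(", r, ")CC1{O}") else "C1CCCCC1{O}"
    add(ring5, "ring_O", "cycloalkanol")
    add(ring6, "ring_O", "cycloalkanol")
  }
  for (r in c("C", "CC", "CCC", "CCCC", "CC(C)C", "CCCCC", "c2ccccc2")) {
    add(paste0("CC1CCC(", r, ")CC1{O}"), "ring_O", "cycloalkanol")
    add(paste0("CC1CC(", r, ")CCC1{O}"), "ring_O", "cycloalkanol")
  }
  # amines: primary and phenalkyl
  for (a in alkyl[4:11]) add(paste0("C", a, "{N}"), "mono_N", "alkylamine")
  for (a in alkyl[5:10]) add(paste0("CC(", a, "){N}"), "mono_N", "alkylamine")
  for (r in c("", "C", "CC", "CCC", "CCCC", "CC(C)C", "OC", "Cl", "F",
              "C(F)(F)F")) {
    pre <- if (nzchar(r)) paste0("c1cc(", r, ")ccc1") else "c1ccccc1"
    add(paste0(pre, "C{N}"), "mono_N", "benzylamine")
    add(paste0(pre, "CC{N}"), "mono_N", "phenethylamine")
    add(paste0(pre, "CC(C){N}"), "mono_N", "phenethylamine")
    add(paste0(pre, "CC(CC){N}"), "mono_N", "phenethylamine")
  }
  # thiols
  for (a in alkyl[5:11]) add(paste0("C", a, "{S}"), "poly", "thiol")
  # bisphenols: two phenol-TMS rings joined by a bridge
  bridges <- c("C(C)(C)", "C", "C(C)(CC)", "S(=O)(=O)", "C(CC)(CC)",
               "C(C)(CCC)", "C(C)(CCCC)", "C1(CCCCC1)")
  for (b in bridges) for (r in c("", "C", "CC", "Cl", "OC", "CCC")) {
    ring2 <- if (nzchar(r)) paste0("c1ccc({O})c(", r, ")c1") else "c1ccc({O})cc1"
    add(paste0("c1cc({O})ccc1", b, ring2), "bisphenol", "bisphenol")
  }
  # amino acids and mixed N,O poly scaffolds
  for (a in c("C", "CC", "CC(C)C", "CCC", "CCCC", "CC(C)CC", "Cc1ccccc1",
              "CCc1ccccc1")) {
    add(paste0("C(", a, ")({N}){A}"), "poly", "aminoacid")
  }
  add("C(C{O})({N}){A}", "poly", "aminoacid")               # serine-like
  add("C(Cc1ccc({O})cc1)({N}){A}", "poly", "aminoacid")     # tyrosine-like
  add("C(CC{O})({N}){A}", "poly", "aminoacid")
  add("C(CS(C))({N}){A}", "poly", "aminoacid")              # methionine-like
  for (r in alkyl) {
    add(paste0("c1cc({O})cc({O})c1C", r, "{O}"), "poly", "triol")
  }
  for (r in rsub[1:8]) {
    add(paste0("c1c({O})cc({O})cc1C(=O)", r), "poly", "diphenol")
  }
  out <- do.call(rbind, tpl)
  out$smiles <- .expand_template(out$template)
  out$n_sites <- .n_sites(out$template)
  out
}

#' Generate synthetic TMS-derivative compound records
#'
#' Deterministically samples distinct structures from the template universe,
#' restricted to the configured silyl-count and molecular-weight windows.
#'
#' @param cfg a [generator_config()].
#' @param n number of compounds (defaults to `n_train`).
#' @param seed sampling seed (defaults to `master_seed`).
#' @return list of `compound_record`s with `class` and `family` attributes
#'   attached; `NULL`-free, length `n`.
#' @export
generate_compounds <- function(cfg = generator_config(), n = cfg$n_train,
                               seed = cfg$master_seed) {
  stopifnot(inherits(cfg, "generator_config"), n >= 0)
  if (n == 0) return(list())
  uni <- .generator_universe(cfg)
  if (n > nrow(uni)) {
    stop(sprintf("template universe has only %d structures in range; %d requested",
                 nrow(uni), n))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647)
  pick <- sort(sample.int(nrow(uni), n))
  .records_from_universe(uni[pick, , drop = FALSE])
}

# expanded, MW/TMS-filtered, parsed universe (cached per config window)
.generator_universe <- function(cfg) {
  key <- paste(cfg$n_tms_range, collapse = "-")
  key <- paste0(key, "|", paste(cfg$mw_range, collapse = "-"))
  cache <- get0(".universe_cache", envir = .tmsid_env) %||% list()
  if (!is.null(cache[[key]])) return(cache[[key]])
  uni <- tms_template_universe()
  uni <- uni[uni$n_sites >= cfg$n_tms_range[1] &
               uni$n_sites <= cfg$n_tms_range[2], , drop = FALSE]
  mols <- parse_smiles(stats::setNames(uni$smiles, paste0("u", seq_len(nrow(uni)))),
                       on_error = "na")
  parsed <- !vapply(mols, is.null, logical(1))
  uni <- uni[parsed, , drop = FALSE]; mols <- mols[parsed]
  mw <- vapply(mols, function(m) mol_formula(m)$mw, numeric(1))
  keep <- mw >= cfg$mw_range[1] & mw <= cfg$mw_range[2]
  uni <- uni[keep, , drop = FALSE]
  uni$mw <- mw[keep]
  uni$mol <- I(mols[keep])
  uni <- uni[!duplicated(uni$smiles), , drop = FALSE]
  rownames(uni) <- NULL
  cache[[key]] <- uni
  assign(".universe_cache", cache, envir = .tmsid_env)
  uni
}

.records_from_universe <- function(uni) {
  recs <- lapply(seq_len(nrow(uni)), function(i) {
    r <- compound_record(id = sprintf("SYN%04d", i),
                         smiles = uni$smiles[i], mol = uni$mol[[i]])
    r$class <- uni$class[i]
    r$family <- uni$family[i]
    r
  })
  # ids must be unique and stable across subsets: derive from row content
  for (i in seq_along(recs)) {
    recs[[i]]$id <- sprintf("SYN%05d", .hash_int(i, nchar(uni$smiles[i])) %% 89989L)
  }
  # guard against hash collisions
  ids <- vapply(recs, function(r) r$id, "")
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))
    for (i in dup) recs[[i]]$id <- sprintf("%s_%d", recs[[i]]$id, i)
  }
  names(recs) <- vapply(recs, function(r) r$id, "")
  recs
}

#' Simulate an EI spectrum for a synthetic compound
#'
#' The deterministic core maps each active fingerprint bit through a hashed
#' fragment map to a characteristic m/z in the scan range 50-800 (capped at
#' the molecular ion: fragments cannot exceed the molecular mass), adds TMS
#' marker peaks for `min(n_tms, 4)` markers, the molecular ion at nominal
#' MW and its 13C isotope at MW + 1 with carbon-count-scaled intensity.
#' On top of that, seeded randomness applies multiplicative lognormal
#' intensity noise, per-peak dropout (diagnostic peaks exempt) and uniform
#' background clutter.
#'
#' @param record a `compound_record`.
#' @param cfg a [generator_config()].
#' @param seed integer seed for the stochastic components.
#' @param fp optional precomputed unmasked fingerprint of the structure.
#' @return an [ei_spectrum()] with MW metadata and the acquisition range
#'   recorded in `$extra$upper_mz`.
#' @export
simulate_spectrum <- function(record, cfg = generator_config(), seed = 0,
                              fp = NULL) {
  stopifnot(inherits(record, "compound_record"))
  if (is.null(fp)) fp <- compute_fingerprint(record$mol)
  mw_nom <- round(record$mw)
  active <- which(as.integer(fp) == 1L)
  h_gate <- .hash_int(active, cfg$fragment_map_seed) %% 1000
  frag_bits <- active[h_gate < 1000 * cfg$fragment_map_density]
  frag <- list(mz = numeric(0), int = numeric(0))
  if (length(frag_bits) && cfg$peaks_per_bit >= 1) {
    for (k in seq_len(cfg$peaks_per_bit)) {
      hk <- .hash_int(frag_bits * 7L + k, cfg$fragment_map_seed + 13 * k)
      frag$mz <- c(frag$mz, 50 + (hk %% 751))
      frag$int <- c(frag$int, 5 + (.hash_int(frag_bits * 11L + k,
                                             cfg$fragment_map_seed + 29 * k) %% 95))
    }
  }
  keep <- frag$mz <= mw_nom - 2  # fragments sit below the molecular ion
  frag$mz <- frag$mz[keep]; frag$int <- frag$int[keep]
  markers <- c(73, 147, 221, 295)
  marker_int <- c(999, 400, 150, 60)
  nm <- min(max(record$n_tms, 0L), 4L)
  nC <- unname(mol_formula(record$mol)$counts["C"])
  diag_mz <- c(if (nm >= 1) markers[seq_len(nm)], mw_nom, mw_nom + 1)
  diag_int <- c(if (nm >= 1) marker_int[seq_len(nm)], 30,
                max(1, 30 * 0.011 * nC))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647)
  n_frag <- length(frag$mz)
  if (cfg$peak_dropout_p > 0 && n_frag > 0) {
    drop <- stats::runif(n_frag) < cfg$peak_dropout_p
    frag$mz <- frag$mz[!drop]; frag$int <- frag$int[!drop]
  }
  mz <- c(frag$mz, diag_mz)
  int <- c(frag$int, diag_int)
  if (cfg$intensity_noise_sd > 0) {
    int <- int * exp(stats::rnorm(length(int), 0, cfg$intensity_noise_sd))
  }
  if (cfg$background_peaks > 0) {
    mz <- c(mz, 50 + floor(stats::runif(cfg$background_peaks) * 751))
    int <- c(int, 1 + stats::runif(cfg$background_peaks) * 19)
  }
  ei_spectrum(mz, int, name = record$id, inchikey = record$inchikey,
              formula = record$formula, mw = record$mw,
              exact_mass = record$exact_mass,
              extra = list(upper_mz = 800))
}

#' Replicate spectra of one compound
#'
#' @param record a `compound_record`.
#' @param n number of replicates (>= 1).
#' @param cfg a [generator_config()].
#' @param seed base seed; replicate i uses a seed derived from `seed` and i.
#' @return list of `n` [ei_spectrum()] objects.
#' @export
make_replicates <- function(record, n, cfg = generator_config(),
                            seed = cfg$master_seed) {
  stopifnot(n >= 1)
  fp <- compute_fingerprint(record$mol)
  lapply(seq_len(n), function(i) {
    simulate_spectrum(record, cfg, seed = .hash_int(i, seed), fp = fp)
  })
}

#' Assemble a decoy candidate set for one query
#'
#' Decoys are drawn from the pool at Tanimoto similarity to the truth inside
#' `cfg$decoy_similarity_range`; the truth itself is omitted with
#' probability `cfg$p_missing`.
#'
#' @param truth the true `compound_record`.
#' @param pool list of `compound_record`s to draw decoys from.
#' @param cfg a [generator_config()].
#' @param seed sampling seed.
#' @param fps fingerprint matrix with one named row per pool member and a
#'   row for the truth (computed on the fly if absent); masked rows are
#'   used as-is for the similarity screen.
#' @return a [candidate_set()] (fingerprints in the layout of `fps`).
#' @export
make_candidate_set <- function(truth, pool, cfg = generator_config(),
                               seed = cfg$master_seed, fps = NULL) {
  stopifnot(inherits(truth, "compound_record"))
  pool_ids <- vapply(pool, function(r) r$id, "")
  if (is.null(fps)) {
    mols <- c(stats::setNames(list(truth$mol), truth$id),
              stats::setNames(lapply(pool, function(r) r$mol), pool_ids))
    fps <- fingerprint_matrix(mols)
  }
  if (!truth$id %in% rownames(fps)) stop("fps must contain a row for the truth")
  tfp <- fps[truth$id, ]
  cand_ids <- setdiff(pool_ids, truth$id)
  sims <- vapply(cand_ids, function(id) tanimoto(tfp, fps[id, ]), numeric(1))
  lo <- cfg$decoy_similarity_range[1]; hi <- cfg$decoy_similarity_range[2]
  eligible <- cand_ids[sims >= lo & sims <= hi]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647)
  include_truth <- stats::runif(1) >= cfg$p_missing
  n_decoys <- cfg$candidates_per_query - as.integer(include_truth)
  if (length(eligible) < n_decoys) {
    stop(sprintf(paste0("decoy similarity range [%.2f, %.2f] infeasible: only %d ",
                        "of %d pool compounds eligible (achieved range [%.2f, %.2f]), ",
                        "%d needed"),
                 lo, hi, length(eligible), length(cand_ids),
                 if (length(sims)) min(sims) else NA,
                 if (length(sims)) max(sims) else NA, n_decoys))
  }
  decoys <- sample(eligible, n_decoys)
  ids <- c(if (include_truth) truth$id, decoys)
  candidate_set(query_id = truth$id, ids = ids,
                fps = fps[ids, , drop = FALSE],
                true_id = if (include_truth) truth$id else NA_character_,
                mask_id = attr(fps, "mask_id") %||% NA_character_)
}

#' Generate a full synthetic benchmark bundle
#'
#' Produces the complete train/test design: training (structure, spectrum)
#' pairs, test queries with `overlap_fraction` of their compounds also
#' present in training (with independently drawn spectra), replicate
#' spectra, per-query candidate sets, and ground-truth labels (structural
#' class, scaffold-family cluster label, in-training flag).
#'
#' @param cfg a [generator_config()].
#' @return a `synthetic_bundle`: list with `train` (records with spectra),
#'   `test` (records with `$spectrum`, `$replicates`, `$in_training`),
#'   `candidates` (list of [candidate_set()]s keyed by query id), `fps`
#'   (unmasked fingerprint matrix over all compounds), `labels` (data.frame
#'   id/class/family), `cfg`.
#' @export
make_benchmark <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  n_overlap <- round(cfg$overlap_fraction * cfg$n_test)
  n_new <- cfg$n_test - n_overlap
  n_all <- cfg$n_train + n_new + cfg$n_decoy_pool
  all_rec <- generate_compounds(cfg, n = n_all, seed = cfg$master_seed)
  train_rec <- all_rec[seq_len(cfg$n_train)]
  new_rec <- all_rec[cfg$n_train + seq_len(n_new)]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$master_seed %% 2147483647)
  overlap_idx <- if (n_overlap > 0) sort(sample.int(cfg$n_train, n_overlap)) else integer(0)
  fps <- fingerprint_matrix(stats::setNames(lapply(all_rec, function(r) r$mol),
                                            names(all_rec)))
  for (i in seq_along(train_rec)) {
    train_rec[[i]]$spectrum <- simulate_spectrum(
      train_rec[[i]], cfg, seed = .hash_int(i, cfg$master_seed + 1000),
      fp = fps[train_rec[[i]]$id, ])
  }
  test_rec <- c(train_rec[overlap_idx], new_rec)
  for (i in seq_along(test_rec)) {
    r <- test_rec[[i]]
    r$in_training <- r$id %in% names(train_rec)[overlap_idx]
    r$spectrum <- simulate_spectrum(r, cfg,
                                    seed = .hash_int(i, cfg$master_seed + 2000),
                                    fp = fps[r$id, ])
    if (cfg$n_replicates > 0) {
      r$replicates <- lapply(seq_len(cfg$n_replicates), function(j) {
        simulate_spectrum(r, cfg, seed = .hash_int(i * 131 + j,
                                                   cfg$master_seed + 3000),
                          fp = fps[r$id, ])
      })
    }
    test_rec[[i]] <- r
  }
  # decoy similarity is screened in the masked fingerprint space of the
  # training set: that is the space in which candidates are scored, so the
  # configured Tanimoto range controls the actual ranking difficulty
  mask <- build_mask(fps[names(train_rec), , drop = FALSE])
  fps_masked <- apply_mask(fps, mask)
  rownames(fps_masked) <- rownames(fps)
  cands <- lapply(seq_along(test_rec), function(i) {
    make_candidate_set(test_rec[[i]], all_rec, cfg,
                       seed = .hash_int(i, cfg$master_seed + 4000),
                       fps = fps_masked)
  })
  names(cands) <- vapply(test_rec, function(r) r$id, "")
  labels <- data.frame(
    id = names(all_rec),
    class = vapply(all_rec, function(r) r$class, ""),
    family = vapply(all_rec, function(r) r$family, ""),
    stringsAsFactors = FALSE)
  structure(list(train = train_rec, test = test_rec, candidates = cands,
                 fps = fps, labels = labels, cfg = cfg),
            class = "synthetic_bundle")
}

#' Build a small library with planted curation violations
#'
#' For curation-report testing: generates `n_valid` compliant records and
#' injects records violating specific rules in known numbers.
#'
#' @param n_valid number of compliant records.
#' @param plan named integer vector of planted violations; supported names:
#'   `siloxane` (Si-Si structures), `tbdms`, `high_mass` (MW > 1000),
#'   `few_peaks` (spectra with 4 peaks), `no_marker` (spectra lacking all
#'   TMS marker ions), `erroneous` (scrambled InChIKey).
#' @param cfg a [generator_config()].
#' @param seed seed for the valid part.
#' @return list with `records` and the echoed `plan`.
#' @export
make_planted_library <- function(n_valid = 5,
                                 plan = c(siloxane = 2, high_mass = 1,
                                          few_peaks = 2),
                                 cfg = generator_config(), seed = cfg$master_seed) {
  recs <- generate_compounds(cfg, n = n_valid, seed = seed)
  for (i in seq_along(recs)) {
    recs[[i]]$spectrum <- simulate_spectrum(recs[[i]], cfg,
                                            seed = .hash_int(i, seed),
                                            fp = NULL)
  }
  mk <- function(id, smiles, spectrum = NULL, inchikey = NA_character_) {
    r <- compound_record(id, smiles, inchikey = inchikey)
    r$class <- "planted"; r$family <- "planted"
    r$spectrum <- if (is.null(spectrum)) {
      simulate_spectrum(r, cfg, seed = .hash_int(nchar(id), seed))
    } else spectrum
    r
  }
  k <- 0L
  for (rule in names(plan)) {
    for (j in seq_len(plan[[rule]])) {
      k <- k + 1L
      id <- sprintf("PLANT%02d_%s", k, rule)
      r <- switch(rule,
        siloxane = mk(id, "C[Si](C)(C)[Si](C)(C)C"),
        tbdms = mk(id, paste0("CC(C)(C)[Si](C)(C)Oc1ccc(",
                              strrep("C", j), ")cc1")),
        high_mass = mk(id, paste0("C", strrep("C", 75 + j), "O[Si](C)(C)C")),
        few_peaks = {
          base <- generate_compounds(cfg, n = 20, seed = seed + 7)[[10 + j]]
          base$id <- id
          base$spectrum <- ei_spectrum(c(73, 147, round(base$mw),
                                         round(base$mw) + 1),
                                       c(999, 400, 30, 5), name = id,
                                       mw = base$mw,
                                       extra = list(upper_mz = 800))
          base
        },
        no_marker = {
          base <- generate_compounds(cfg, n = 20, seed = seed + 7)[[15 + j]]
          base$id <- id
          sp <- simulate_spectrum(base, cfg, seed = .hash_int(k, seed))
          keep <- !round(sp$peaks$mz) %in% c(73, 147, 221, 295)
          sp$peaks <- sp$peaks[keep, , drop = FALSE]
          base$spectrum <- sp
          base
        },
        erroneous = {
          base <- generate_compounds(cfg, n = 20, seed = seed + 7)[[j]]
          base$id <- id
          base$inchikey <- "XXXXXXXXXXXXXX-UHFFFAOYSA-N"
          base$spectrum <- simulate_spectrum(base, cfg, seed = .hash_int(k, seed))
          base
        },
        stop("unknown planted rule: ", rule))
      recs[[length(recs) + 1L]] <- r
    }
  }
  names(recs) <- vapply(recs, function(r) r$id, "")
  list(records = recs, plan = plan)
}
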