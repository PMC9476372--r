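test_that("family blocks have the published lengths and binary values", {
  mol <- parse_smiles1("C[Si](C)(C)Oc1ccccc1")
  lens <- c(substructure = 307L, maccs = 166L, pubchem = 881L,
            klekota_roth = 4860L)
  for (fam in names(lens)) {
    blk <- compute_block(mol, fam)
    expect_length(blk, lens[[fam]])
    expect_true(all(blk %in% c(0L, 1L)))
  }
  expect_error(compute_block(mol, "circular"))
  expect_error(parse_smiles1("C("), "unparsable")
})

test_that("fingerprints are canonicalization-stable pure functions", {
  pairs <- list(c("OCC", "CCO"),
                c("c1ccccc1O[Si](C)(C)C", "C[Si](C)(C)Oc1ccccc1"),
                c("C1=CC=CC=C1", "c1ccccc1"))
  for (p in pairs) {
    f1 <- compute_fingerprint(p[1])
    f2 <- compute_fingerprint(p[2])
    expect_equal(as.integer(f1), as.integer(f2), info = paste(p, collapse = " vs "))
  }
  # repeated calls bit-identical
  expect_identical(as.integer(compute_fingerprint("CCCCO[Si](C)(C)C")),
                   as.integer(compute_fingerprint("CCCCO[Si](C)(C)C")))
})

test_that("concatenation enforces block order and total length 6214", {
  mol <- parse_smiles1("CCCCO[Si](C)(C)C")
  blocks <- lapply(stats::setNames(nm = c("substructure", "maccs", "pubchem",
                                          "klekota_roth")),
                   function(f) compute_block(mol, f))
  fp <- concatenate_blocks(blocks)
  expect_length(fp, 307 + 166 + 881 + 4860)
  expect_equal(as.integer(fp[1:307]), blocks$substructure)
  expect_equal(as.integer(fp[307 + seq_len(166)]), blocks$maccs)
  expect_error(concatenate_blocks(blocks[-1]), "named list")
  short <- blocks; short$maccs <- short$maccs[-1]
  expect_error(concatenate_blocks(short), "length")
  zeros <- lapply(c(substructure = 307, maccs = 166, pubchem = 881,
                    klekota_roth = 4860), function(n) integer(n))
  expect_equal(sum(concatenate_blocks(zeros)), 0)
})

test_that("mask removes constant and duplicate columns, keeping lowest index", {
  m <- rbind(c(1, 0, 1, 0, 1, 1),
             c(1, 1, 1, 0, 0, 1),
             c(1, 0, 1, 1, 1, 0),
             c(1, 1, 1, 0, 0, 1))
  # col1 constant; col3 == col1 (constant dup); col5 == col2? no: c2=(0,1,0,1), c5=(1,0,1,0)
  mask <- build_mask(m)
  expect_true(1 %in% as.integer(names(mask$rule)[mask$rule == "constant"]))
  expect_equal(sort(mask$retained), setdiff(1:6, c(1, 3)))
  expect_equal(unname(mask$rule["3"]), "constant")
  # all distinct, non-constant -> identity mask
  m2 <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0))
  expect_equal(build_mask(m2)$retained, 1:3)
  # duplicate non-constant columns keep the first
  m3 <- cbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0))
  mk3 <- build_mask(m3)
  expect_equal(mk3$retained, c(1, 3))
  expect_equal(unname(mk3$rule["2"]), "duplicate")
})

test_that("masking applied to a training set leaves no constant/duplicate columns", {
  recs <- generate_compounds(generator_config(), n = 30, seed = 13)
  fps <- fingerprint_matrix(stats::setNames(lapply(recs, function(r) r$mol),
                                            names(recs)))
  mask <- build_mask(fps)
  mf <- apply_mask(fps, mask)
  expect_false(any(apply(mf, 2, function(x) all(x == x[1]))))
  expect_false(anyDuplicated(apply(mf, 2, paste, collapse = "")) > 0)
  expect_equal(length(mask$retained) + length(mask$rule), ncol(fps))
})

test_that("apply_mask is layout-checked and rejects double masking", {
  fp <- compute_fingerprint("CCCCCCO[Si](C)(C)C")
  n <- length(fp)
  idmask <- structure(list(retained = seq_len(n), rule = character(0),
                           n_total = n, mask_id = "id"), class = "fp_mask")
  m1 <- apply_mask(fp, idmask)
  expect_equal(as.integer(m1), as.integer(fp))
  expect_true(attr(m1, "masked"))
  expect_error(apply_mask(m1, idmask), "already masked")
  toy <- structure(list(retained = c(1L, 3L), rule = c(`2` = "duplicate"),
                        n_total = 4L, mask_id = "toy"), class = "fp_mask")
  expect_equal(as.integer(apply_mask(structure(c(1L, 0L, 1L, 1L),
                                               class = "fingerprint",
                                               masked = FALSE), toy)),
               c(1L, 1L))
  expect_error(apply_mask(fp, toy), "layout mismatch")
})

test_that("tanimoto is 1 for identical structures and bounded in [0,1]", {
  a <- compute_fingerprint("CCCCO[Si](C)(C)C")
  b <- compute_fingerprint("c1ccccc1O[Si](C)(C)C")
  expect_equal(tanimoto(a, a), 1)
  t <- tanimoto(a, b)
  expect_gte(t, 0); expect_lt(t, 1)
  expect_equal(tanimoto(integer(5), integer(5)), 1)
})

test_that("bit definitions are deterministic and exportable as text", {
  d1 <- fingerprint_definitions("maccs")
  d2 <- fingerprint_definitions("maccs")
  expect_identical(d1, d2)
  expect_equal(nrow(fingerprint_definitions("klekota_roth")), 4860)
  dir <- withr::local_tempdir()
  paths <- write_fp_definitions(dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.delim(file.path(dir, "fp_substructure.tsv"))
  expect_equal(nrow(back), 307)
})
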