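test_that("structural exclusion categories fire on canonical examples", {
  cases <- list(
    list("C[Si](C)(C)[Si](C)(C)C", "si_si"),              # disilane
    list("CC[Si](C)(C)CC", "c_si"),                       # alkylsilane
    list("CC(C)=NO[Si](C)(C)C", "n_o_si_or_n_n_si"),      # oxime-TMS
    list("CC(C)=N[Si](C)(C)C", "n_si_other"),             # imine-TMS
    list("CC(=O)N(C)[Si](C)(C)C", "n_si_other"),          # amide-TMS (MSTFA-like)
    list("C[Si](C)(C)OP(=O)(O)O", "p_si"),                # phosphate-TMS
    list("C[Si](C)(C)CC(=O)O", "rearrangement_tms"),      # C-attached TMS
    list("CC(C)(C)[Si](C)(C)OCC", "tbdms"),               # TBDMS ether
    list("CC(C)(C)[Si](C)(C)Oc1ccc(O[Si](C)(C)C)cc1", "mixed_tms_tbdms"),
    list("Cl[Si](C)(C)C", "derivatization_agent"),        # TMCS
    list("C[Si](C)(C)O[Si](C)(C)C", "o_si_other")         # disiloxane
  )
  for (cs in cases) {
    got <- classify_structure(cs[[1]])
    expect_false(got$keep, info = cs[[1]])
    expect_equal(got$category, cs[[2]], info = cs[[1]])
  }
})

test_that("legitimate TMS derivatives are always retained", {
  keepers <- c(
    "C[Si](C)(C)Oc1ccccc1",            # phenol-TMS
    "CCCCCCO[Si](C)(C)C",              # hexanol-TMS
    "CCCC(=O)O[Si](C)(C)C",            # butanoate-TMS
    "C[Si](C)(C)NCCc1ccccc1",          # phenethylamine-TMS
    "CCCCS[Si](C)(C)C",                # thiol-TMS
    "C[Si](C)(C)Oc1ccc(C(C)(C)c2ccc(O[Si](C)(C)C)cc2)cc1")  # bisphenol-2TMS
  for (smi in keepers) {
    expect_true(classify_structure(smi)$keep, info = smi)
  }
  # every structure in the generator universe is a valid TMS derivative
  recs <- generate_compounds(generator_config(), n = 40, seed = 21)
  for (r in recs) expect_true(classify_structure(r)$keep, info = r$smiles)
})

test_that("graph rules agree with an independent SMARTS matcher", {
  # cross-check the classifier's bond-environment logic against OpenBabel
  # SMARTS matching on a mixed set of keep/exclude structures
  smis <- c("C[Si](C)(C)[Si](C)(C)C", "C[Si](C)(C)Oc1ccccc1",
            "CC(C)(C)[Si](C)(C)OCC", "CCCCS[Si](C)(C)C",
            "C[Si](C)(C)O[Si](C)(C)C", "CC[Si](C)(C)CC")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smis, seq_along(smis))))
  sisi <- ChemmineR::smartsSearchOB(sdf, "[Si][Si]", uniqueMatches = FALSE) > 0
  siosi <- ChemmineR::smartsSearchOB(sdf, "[Si][OX2][Si]", uniqueMatches = FALSE) > 0
  tbdms <- ChemmineR::smartsSearchOB(sdf, "[Si](C)(C)C(C)(C)C", uniqueMatches = FALSE) > 0
  cls <- vapply(smis, function(s) {
    cat <- classify_structure(s)$category
    if (is.na(cat)) "keep" else cat
  }, "")
  expect_equal(unname(cls == "si_si"), unname(sisi))
  expect_equal(unname(cls == "o_si_other"), unname(siosi))
  expect_equal(unname(cls == "tbdms"), unname(tbdms))
})

test_that("high-mass filtering honours the comparison mode", {
  cfg <- generator_config()
  recs <- generate_compounds(cfg, n = 3, seed = 2)
  recs[[1]]$mw <- 1050; recs[[2]]$mw <- 575; recs[[3]]$mw <- 1000
  gt <- filter_high_mass(recs, 1000, ">")
  expect_length(gt$removed, 1)
  expect_equal(gt$removed[[1]]$mw, 1050)
  ge <- filter_high_mass(recs, 1000, ">=")
  expect_length(ge$removed, 2)
  recs[[2]]$mw <- NA_real_
  fr <- filter_high_mass(recs, 1000)
  expect_length(fr$needs_review, 1)
  expect_length(fr$kept, 1)
})

test_that("quality criteria are evaluated jointly and report all violations", {
  # 4 peaks only: too few fragment ions
  s4 <- ei_spectrum(c(73, 147, 230, 231), c(99, 40, 30, 4), mw = 230,
                    extra = list(upper_mz = 800))
  qf <- quality_filter(s4, mw = 230)
  expect_false(qf$pass)
  expect_equal(qf$violated, "fragment_count")
  # no TMS marker
  sm <- ei_spectrum(c(60, 91, 105, 119, 133, 230, 231),
                    c(10, 20, 30, 40, 50, 30, 4), mw = 230,
                    extra = list(upper_mz = 800))
  expect_true("tms_marker" %in% quality_filter(sm, mw = 230)$violated)
  # constructed to satisfy all four
  ok <- ei_spectrum(c(73, 147, 91, 105, 119, 133, 60, 230, 231),
                    c(99, 40, 10, 10, 10, 10, 10, 30, 4), mw = 230,
                    extra = list(upper_mz = 800))
  expect_true(quality_filter(ok, mw = 230)$pass)
  # molecular-ion cluster required (both M and M+1)
  noiso <- ei_spectrum(c(73, 147, 91, 105, 119, 133, 60, 230),
                       c(99, 40, 10, 10, 10, 10, 10, 30), mw = 230,
                       extra = list(upper_mz = 800))
  expect_true("molecular_ion" %in% quality_filter(noiso, mw = 230)$violated)
  # acquisition range proxied by max peak when no metadata
  shallow <- ei_spectrum(c(73, 147, 91, 105, 119, 133, 230, 231),
                         c(99, 40, 10, 10, 10, 10, 30, 4), mw = 230)
  expect_true("acquisition_range" %in% quality_filter(shallow, mw = 230)$violated)
  # strict marker mode requires the n_tms-specific marker
  s1 <- ei_spectrum(c(73, 91, 105, 119, 133, 60, 230, 231),
                    c(99, 10, 10, 10, 10, 10, 30, 4), mw = 230,
                    extra = list(upper_mz = 800))
  expect_true(quality_filter(s1, mw = 230, n_tms = 1, strict_markers = TRUE)$pass)
  expect_false(quality_filter(s1, mw = 230, n_tms = 2, strict_markers = TRUE)$pass)
  expect_error(quality_filter(s1, mw = NA), "MW")
})

test_that("curation removes exactly the planted violations and conserves counts", {
  plan <- c(siloxane = 2, high_mass = 1, few_peaks = 2)
  pl <- make_planted_library(n_valid = 10, plan = plan)
  rep <- run_curation(pl$records)
  expect_equal(rep$n_input, 15)
  expect_equal(rep$n_output, 10)
  expect_equal(unname(rep$per_step_removed["si_si"]), 2L)
  expect_equal(unname(rep$per_step_removed["high_mass"]), 1L)
  expect_equal(unname(rep$per_step_removed["quality_fragment_count"]), 2L)
  expect_equal(rep$n_input, rep$n_output + sum(rep$per_step_removed))
  expect_equal(sum(rep$audit$status == "removed"), 5)
  # every removed record names exactly one rule
  expect_true(all(!is.na(rep$audit$rule[rep$audit$status == "removed"])))
  expect_true(all(is.na(rep$audit$rule[rep$audit$status == "kept"])))
})

test_that("curation of its own output is a no-op, and empty input works", {
  pl <- make_planted_library(n_valid = 6, plan = c(siloxane = 1))
  rep1 <- run_curation(pl$records)
  rep2 <- run_curation(rep1$kept)
  expect_equal(rep2$n_input, rep2$n_output)
  expect_length(rep2$per_step_removed, 0)
  rep0 <- run_curation(list())
  expect_equal(rep0$n_input, 0)
  expect_equal(rep0$n_output, 0)
})

test_that("erroneous entries are caught by InChIKey consistency", {
  recs <- generate_compounds(generator_config(), n = 2, seed = 9)
  recs[[1]]$inchikey <- compute_inchikey(recs[[1]]$smiles)   # consistent
  recs[[2]]$inchikey <- "QQQQQQQQQQQQQQ-UHFFFAOYSA-N"        # scrambled
  for (i in 1:2) {
    recs[[i]]$spectrum <- simulate_spectrum(recs[[i]], generator_config(),
                                            seed = i)
  }
  rep <- run_curation(recs)
  expect_equal(rep$n_output, 1)
  expect_equal(unname(rep$per_step_removed["erroneous_entry"]), 1L)
})
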