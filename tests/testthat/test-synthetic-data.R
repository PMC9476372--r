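test_that("compound generation is deterministic, bounded and TMS-correct", {
  cfg <- generator_config()
  r1 <- generate_compounds(cfg, n = 25, seed = 17)
  r2 <- generate_compounds(cfg, n = 25, seed = 17)
  expect_identical(vapply(r1, function(r) r$smiles, ""),
                   vapply(r2, function(r) r$smiles, ""))
  expect_length(generate_compounds(cfg, n = 0), 0)
  mws <- vapply(r1, function(r) r$mw, numeric(1))
  expect_true(all(mws >= cfg$mw_range[1] & mws <= cfg$mw_range[2]))
  tms <- vapply(r1, function(r) r$n_tms, integer(1))
  expect_true(all(tms >= cfg$n_tms_range[1] & tms <= cfg$n_tms_range[2]))
  expect_false(anyDuplicated(vapply(r1, function(r) r$id, "")) > 0)
  expect_error(generate_compounds(cfg, n = 1e6), "universe")
})

test_that("the deterministic spectrum core ignores the seed when noise is off", {
  cfg <- generator_config(intensity_noise_sd = 0, peak_dropout_p = 0,
                          background_peaks = 0)
  rec <- generate_compounds(cfg, n = 1, seed = 23)[[1]]
  s1 <- simulate_spectrum(rec, cfg, seed = 1)
  s2 <- simulate_spectrum(rec, cfg, seed = 999)
  expect_identical(s1$peaks, s2$peaks)
})

test_that("simulated spectra carry the diagnostic structure of TMS derivatives", {
  cfg <- generator_config()
  recs <- generate_compounds(cfg, n = 15, seed = 29)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    s <- simulate_spectrum(r, cfg, seed = i)
    mz <- s$peaks$mz
    expect_true(all(mz >= 50 & mz <= 800))
    expect_true(any(abs(mz - 73) <= 0.5))                 # first TMS marker
    expect_true(any(abs(mz - round(r$mw)) <= 0.5))        # molecular ion
    expect_true(any(abs(mz - round(r$mw) - 1) <= 0.5))    # 13C isotope
    expect_equal(s$extra$upper_mz, 800)
    expect_true(quality_filter(s, mw = r$mw, n_tms = r$n_tms)$pass)
  }
})

test_that("replicate similarity mirrors acquisition reproducibility", {
  cfg <- generator_config()
  rec <- generate_compounds(cfg, n = 5, seed = 31)
  for (r in rec[1:3]) {
    reps <- make_replicates(r, 6, cfg, seed = 41)
    S <- similarity_matrix(reps)
    expect_gt(min(S[lower.tri(S)]), 0.95)
  }
  # heavy noise pushes replicate pairs under the 0.50 QC threshold
  noisy <- generator_config(intensity_noise_sd = 3, peak_dropout_p = 0.6,
                            background_peaks = 40)
  lows <- vapply(rec, function(r) {
    S <- similarity_matrix(make_replicates(r, 8, noisy, seed = 43))
    min(S[lower.tri(S)])
  }, numeric(1))
  expect_true(any(lows < 0.5))
})

test_that("candidate sets respect the similarity screen and missing rate", {
  cfg <- generator_config(candidates_per_query = 10)
  pool <- generate_compounds(cfg, n = 60, seed = 37)
  fps <- fingerprint_matrix(stats::setNames(lapply(pool, function(r) r$mol),
                                            names(pool)))
  truth <- pool[[1]]
  cs <- make_candidate_set(truth, pool, cfg, seed = 3, fps = fps)
  expect_length(cs$ids, 10)
  expect_true(cs$contains_true)
  expect_equal(cs$true_id, truth$id)
  sims <- vapply(setdiff(cs$ids, truth$id), function(id) {
    tanimoto(fps[truth$id, ], fps[id, ])
  }, numeric(1))
  expect_true(all(sims >= cfg$decoy_similarity_range[1] &
                    sims <= cfg$decoy_similarity_range[2]))
  # p_missing = 1: truth omitted from every set
  cfg_m <- generator_config(candidates_per_query = 10, p_missing = 1)
  cs_m <- make_candidate_set(truth, pool, cfg_m, seed = 3, fps = fps)
  expect_false(cs_m$contains_true)
  expect_false(truth$id %in% cs_m$ids)
  # infeasible request errors with an achieved-range report
  cfg_bad <- generator_config(candidates_per_query = 50,
                              decoy_similarity_range = c(0.99, 1))
  expect_error(make_candidate_set(truth, pool, cfg_bad, seed = 3, fps = fps),
               "infeasible")
})

test_that("benchmark bundles are reproducible and honour the overlap design", {
  b <- small_bundle()
  cfg <- b$cfg
  b2 <- make_benchmark(cfg)
  expect_identical(b$fps, b2$fps)
  expect_identical(vapply(b$test, function(r) r$id, ""),
                   vapply(b2$test, function(r) r$id, ""))
  expect_identical(b$train[[1]]$spectrum$peaks, b2$train[[1]]$spectrum$peaks)
  n_in <- sum(vapply(b$test, function(r) r$in_training, logical(1)))
  expect_equal(n_in, round(cfg$overlap_fraction * cfg$n_test))
  train_ids <- vapply(b$train, function(r) r$id, "")
  for (r in b$test) {
    expect_equal(r$id %in% train_ids, r$in_training)
    expect_true(r$id %in% names(b$candidates))
  }
  expect_equal(nrow(b$labels), cfg$n_train +
                 (cfg$n_test - n_in) + cfg$n_decoy_pool)
  expect_true(all(c("class", "family") %in% names(b$labels)))
})

test_that("identifiability improves as noise and decoy similarity drop", {
  run_at <- function(...) {
    cfg <- generator_config(n_train = 60, n_test = 15, n_decoy_pool = 120,
                            candidates_per_query = 15, n_replicates = 0,
                            master_seed = 5, ...)
    res <- run_pipeline(make_benchmark(cfg))
    res$summary[res$summary$group == "Merged", "top1_pct"]
  }
  easy <- run_at()
  mid <- run_at(decoy_similarity_range = c(0.3, 1))
  hard <- run_at(decoy_similarity_range = c(0.3, 1), intensity_noise_sd = 0.5,
                 peak_dropout_p = 0.3, background_peaks = 10)
  expect_gte(easy, mid)
  expect_gte(mid, hard)
  expect_gte(easy, 80)
})
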