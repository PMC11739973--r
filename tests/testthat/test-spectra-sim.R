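# Synthetic sample and run generator: abundance structure, determinism,
# shift sampling and truth-table integrity.

test_that("two-protein sample splits abundance as requested", {
  s <- build_sample(2, dominant_fraction = 0.9, seed = 1, n_true = 2)
  expect_equal(s$proteins$abundance, c(0.9, 0.1))
  expect_equal(s$planted_true, s$proteins$gene)
})

test_that("sample generation is seed-deterministic", {
  a <- build_sample(20, 0.5, seed = 5)
  b <- build_sample(20, 0.5, seed = 5)
  d <- build_sample(20, 0.5, seed = 6)
  expect_identical(a$proteins, b$proteins)
  expect_false(identical(a$proteins$sequence, d$proteins$sequence))
})

test_that("dominant fraction outside (0,1) is rejected", {
  expect_error(build_sample(5, dominant_fraction = 0), "dominant_fraction")
  expect_error(build_sample(5, dominant_fraction = 1), "dominant_fraction")
})

test_that("generated sequences follow the configured residue frequencies", {
  s <- build_sample(500, 0.5, seed = 21, n_true = 100)
  aa <- strsplit(paste(s$proteins$sequence, collapse = ""), "")[[1]]
  freq <- table(factor(aa, levels = names(ionextract:::.IE_AA_FREQ)))
  freq <- as.numeric(freq) / length(aa)
  expect_lt(max(abs(freq - ionextract:::.IE_AA_FREQ)), 0.02)
})

test_that("without isotopes or H-loss all deltas concentrate at zero", {
  run <- simulate_run(fix_sample(), run_parameters(
    300, seed = 3, isotope_sampling = FALSE,
    hloss_probs = c("-1" = 0, "-2" = 0, "-3" = 0),
    precursor_jitter_sd = 0.02, spurious_rate = 0))
  obs_mh <- run$spectra$charge * run$spectra$precursor_mz -
    (run$spectra$charge - 1) * proton_mass()
  delta <- obs_mh - run$truth$theoretical_mh[
    match(run$spectra$id, run$truth$spectrum_id)]
  expect_equal(run$truth$shift, rep(0L, nrow(run$truth)))
  expect_lt(max(abs(delta)), 5 * 0.02)
})

test_that("zero jitter makes observed deltas exactly integer", {
  run <- fix_clean_run()
  obs_mh <- run$spectra$charge * run$spectra$precursor_mz -
    (run$spectra$charge - 1) * proton_mass()
  ti <- match(run$spectra$id, run$truth$spectrum_id)
  delta <- obs_mh - run$truth$theoretical_mh[ti]
  expect_equal(delta, as.numeric(run$truth$shift[ti]), tolerance = 1e-9)
})

test_that("truth covers every non-spurious spectrum exactly once", {
  run <- fix_run()
  expect_equal(anyDuplicated(run$truth$spectrum_id), 0L)
  expect_true(all(run$truth$spectrum_id %in% run$spectra$id))
  # spurious fraction near its configured rate
  expect_equal(1 - nrow(run$truth) / nrow(run$spectra), 0.10,
               tolerance = 0.35)
})

test_that("empirical shift frequencies match the mixing distribution", {
  # single-peptide sample makes the mixture explicit
  pep <- "LVNEVTEFAK"
  s <- structure(list(
    proteins = data.frame(accession = "P1", gene = "ALBL",
                          sequence = paste0(pep, "AAAAAK"),
                          abundance = 1, stringsAsFactors = FALSE),
    planted_true = "ALBL", seed = 1L), class = "synthetic_sample")
  params <- run_parameters(8000, seed = 17, spurious_rate = 0,
                           max_missed = 0)
  run <- simulate_run(s, params)
  tab <- run$truth[run$truth$sequence == pep, ]
  sp <- ionextract:::.ie_shift_probs(pep, params)
  counts <- table(factor(tab$shift, levels = sp$shifts))
  n <- nrow(tab)
  for (k in seq_along(sp$shifts)) {
    expected <- n * sp$probs[k]
    sdev <- sqrt(n * sp$probs[k] * (1 - sp$probs[k]))
    expect_lt(abs(as.numeric(counts[k]) - expected),
              3 * sdev + 3)  # +3 guards the near-zero cells
  }
})

test_that("heavy peptides mostly leave the monoisotopic peak", {
  run <- fix_run()
  big <- run$truth[run$truth$theoretical_mh > 1945, ]
  expect_gt(nrow(big), 50)
  expect_lt(mean(big$shift == 0), 0.5)
})

test_that("blank runs are reproducible, sized, and signal-free", {
  p <- run_parameters(50, seed = 9)
  expect_identical(simulate_blank(p), simulate_blank(p))
  expect_equal(nrow(simulate_blank(run_parameters(0, seed = 1))), 0L)
  b <- simulate_blank(p)
  expect_equal(nrow(b), 50L)
  expect_true(all(vapply(b$peaks, nrow, integer(1)) >= 2L))
})

test_that("blank-run matches show no protein enrichment", {
  s <- build_sample(40, 0.3, seed = 5, n_true = 40,
                    length_range = c(300, 300))
  lib <- build_peptide_library(s$proteins, max_missed = 2)
  bl <- simulate_blank(run_parameters(10000, seed = 6))
  pb <- bfps(search_run(bl, lib, source = "blank"))
  expect_gt(nrow(pb), 30)
  hits <- table(factor(unlist(strsplit(pb$genes, ";")),
                       levels = s$proteins$gene))
  # expected hit share is each protein's share of library peptides
  share <- table(factor(unlist(strsplit(lib$genes, ";")),
                        levels = s$proteins$gene))
  p_exp <- as.vector(share) / sum(share)
  set.seed(1)
  chi <- stats::chisq.test(as.vector(hits), p = p_exp,
                           simulate.p.value = TRUE, B = 2000)
  expect_gt(chi$p.value, 0.01)
})
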