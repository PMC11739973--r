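# Control correction, protein aggregation, cumulative p-values, BH
# q-values and type I/II error arithmetic.

make_counts <- function(n_exp, n_blank = 0L, n_random = 0L,
                        depth = c(experimental = 1000, blank = 1000,
                                  random = 1000)) {
  k <- length(n_exp)
  out <- data.frame(
    sequence = sprintf("PEP%03d", seq_len(k)), charge = 2L,
    genes = "G1", shared = FALSE,
    n_experimental = as.integer(n_exp),
    n_blank = as.integer(rep_len(n_blank, k)),
    n_random = as.integer(rep_len(n_random, k)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_spectra") <- depth
  class(out) <- c("observation_counts", "data.frame")
  out
}

test_that("chi-square correction accepts clear excesses only", {
  cc <- correct_counts(make_counts(c(10, 3)), chi_min = 9, pseudo = 0.5)
  # O=10 vs E=0.5 -> chi = 180.5, accepted
  expect_equal(cc$chi_sq[1], (10 - 0.5)^2 / 0.5)
  expect_true(cc$accepted[1])
  # O=3 vs scaled E=3 -> chi = 0, rejected
  cc2 <- correct_counts(make_counts(3, n_blank = 3))
  expect_equal(cc2$chi_sq, 0)
  expect_false(cc2$accepted)
})

test_that("control scaling follows the relative search depths", {
  cc <- correct_counts(make_counts(20, n_blank = 2, n_random = 10,
                                   depth = c(experimental = 1000,
                                             blank = 500, random = 10000)))
  expect_equal(cc$expected, 2 * 2 + 10 * 0.1)  # 4 + 1
  expect_equal(cc$chi_sq, (20 - 5)^2 / 5)
})

test_that("acceptance matches a brute-force recomputation", {
  set.seed(20)
  n <- 1000
  counts <- make_counts(sample(0:30, n, replace = TRUE),
                        n_blank = sample(0:5, n, replace = TRUE),
                        n_random = sample(0:50, n, replace = TRUE),
                        depth = c(experimental = 2000, blank = 700,
                                  random = 30000))
  cc <- correct_counts(counts, chi_min = 9, pseudo = 0.5)
  brute <- vapply(seq_len(n), function(i) {
    e <- max(0.5, counts$n_blank[i] * 2000 / 700 +
               counts$n_random[i] * 2000 / 30000)
    o <- counts$n_experimental[i]
    o > e && (o - e)^2 / e >= 9
  }, logical(1))
  expect_equal(cc$accepted, brute)
})

test_that("protein aggregation applies the n >= 3 rule", {
  psms <- make_psms(spectrum_id = sprintf("S%d", 1:5),
                    sequence = c("PA", "PA", "PB", "PC", "PC"),
                    genes = c("G1", "G1", "G1", "G2", "G2"))
  agg <- aggregate_proteins(psms)
  expect_equal(agg$n_observations[agg$gene == "G1"], 3L)
  expect_true(agg$flagged[agg$gene == "G1"])
  expect_false(agg$flagged[agg$gene == "G2"])
  expect_equal(agg$distinct_peptides[agg$gene == "G1"], 2L)
})

test_that("shared peptides count toward every parent symbol", {
  psms <- make_psms(spectrum_id = sprintf("S%d", 1:3),
                    sequence = c("PA", "PA", "PA"),
                    genes = "G1;G2", shared = TRUE)
  agg <- aggregate_proteins(psms)
  expect_setequal(agg$gene, c("G1", "G2"))
  expect_equal(agg$n_observations, c(3L, 3L))
  expect_equal(agg$n_unique_observations, c(0L, 0L))
})

test_that("aggregation counts match the generator truth", {
  run <- fix_clean_run()
  psm <- bfps(search_run(run$spectra, fix_library()))
  agg <- aggregate_proteins(psm)
  # brute-force recount from the PSM table itself
  expected <- table(unlist(strsplit(psm$genes, ";")))
  expect_equal(agg$n_observations[match(names(expected), agg$gene)],
               as.integer(expected))
})

test_that("cumulative p-values follow the log-space product", {
  expect_equal(cumulative_p(0.000038, 1), 0.000038)
  expect_equal(cumulative_p(0.5, 0), 1)
  expect_equal(cumulative_p(0.001848, 21), 0.001848^21, tolerance = 1e-12)
  set.seed(21)
  ps <- runif(30, 1e-6, 1)
  gm <- 10^mean(log10(ps))
  expect_equal(cumulative_p_from_values(ps),
               cumulative_p(gm, length(ps)), tolerance = 1e-9)
  expect_equal(cumulative_p_from_values(numeric(0)), 1)
})

test_that("BH q-values agree with a hand step-up computation", {
  expect_equal(bh_q(0.01), 0.01)
  expect_equal(bh_q(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # independent step-up oracle
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    out <- numeric(m); out[o] <- pmin(q, 1)
    out
  }
  set.seed(22)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_q(p), bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bh_q(p) >= p))  # q >= p at every rank
  }
})

test_that("type II error arithmetic reproduces the ratio formula", {
  expect_equal(type2_protein(302, 2784), 89)
  expect_equal(type2_protein(382, 2784), 86)
  expect_equal(type2_protein(963, 2784), 65)
  expect_equal(type2_protein(2784, 2784), 0)
  expect_equal(type2_peptide(21, 84), 75)
  expect_equal(type2_peptide(47, 84), 44)
  expect_equal(type2_peptide(84, 84), 0)
  expect_error(type2_protein(3000, 2784), "benchmark")
  expect_error(type2_peptide(90, 84), "total")
})

test_that("treatment sweeps match a brute-force per-treatment recount", {
  run <- fix_run()
  psm <- fix_psms()
  counts <- observation_counts(psm, n_experimental = nrow(run$spectra))
  counts <- correct_counts(counts)
  ladders <- list(window_set("mono", 0.05), window_set("mono", 0.2),
                  window_set("all", 0.1), window_set("all", 0.5))
  sweep <- treatment_sweep(psm, counts, ladders)
  # brute force: filter accepted peptides, window, regroup, recount
  acc <- counts[counts$accepted, ]
  key <- paste(psm$sequence, psm$charge)
  corrected <- psm[key %in% paste(acc$sequence, acc$charge), ]
  for (k in seq_along(ladders)) {
    ws <- ladders[[k]]
    keep <- vapply(corrected$delta_mass, function(d)
      any(abs(d - ws$centers) <= ws$tolerance), logical(1))
    sub <- corrected[keep, ]
    agg <- aggregate_proteins(sub)
    expect_equal(sweep$msms_count[k], nrow(sub), label = ws$name)
    expect_equal(sweep$proteins_n3[k],
                 sum(agg$flagged & agg$q_value <= 0.01), label = ws$name)
  }
  bench <- sweep[sweep$treatment == "All MS/MS corrected", ]
  expect_equal(bench$type2_percent, 0)
  uncorr <- sweep[sweep$treatment == "All MS/MS not corrected", ]
  expect_true(is.na(uncorr$type2_percent))
  expect_equal(uncorr$msms_count, nrow(psm))
})
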