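# Peptide composition, mass, digestion and isotope-envelope arithmetic.

test_that("residue compositions sum with one water", {
  g <- peptide_composition("G")
  expect_equal(unclass(g)[c("C", "H", "N", "O", "S")],
               c(C = 2, H = 5, N = 1, O = 2, S = 0))
  # additivity: GG equals G + G minus one water
  gg <- peptide_composition("GG")
  expect_equal(unclass(gg)[["H"]], 2 * unclass(g)[["H"]] - 2)
  expect_equal(unclass(gg)[["O"]], 2 * unclass(g)[["O"]] - 1)
  expect_equal(unclass(gg)[["C"]], 2 * unclass(g)[["C"]])
  # frozen from an independent residue-table summation (pyteomics)
  alb <- peptide_composition("EQLKAVMDDFAAFVEK")
  expect_equal(unclass(alb)[c("C", "H", "N", "O", "S")],
               c(C = 83, H = 129, N = 19, O = 26, S = 1))
})

test_that("unknown residues are rejected with the offending character", {
  expect_error(peptide_composition("ABZ"), "B")
  expect_error(peptide_composition("AXA"), "X")
})

test_that("monoisotopic masses match textbook values", {
  expect_equal(monoisotopic_mass(elemental_composition(H = 2, O = 1)),
               18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(peptide_composition("G")),
               75.03203, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(elemental_composition()), 0)
  # frozen from pyteomics: neutral mono mass of the reference ALB peptide
  expect_equal(peptide_mass("EQLKAVMDDFAAFVEK", fixed_cys = FALSE),
               1839.907686, tolerance = 1e-5)
  expect_equal(peptide_mh("EQLKAVMDDFAAFVEK"),
               1840.914962, tolerance = 1e-5)
})

test_that("modifications add formula atoms or carried mass", {
  ox <- peptide_composition("M", mods = list(list(formula = c(O = 1L))))
  expect_equal(unclass(ox)[["O"]],
               unclass(peptide_composition("M"))[["O"]] + 1)
  lab <- peptide_composition("M", mods = list(list(delta = 4.0)))
  expect_equal(monoisotopic_mass(lab),
               monoisotopic_mass(peptide_composition("M")) + 4.0)
  # every standard modification's formula reproduces its stated delta
  mods <- standard_modifications()
  for (i in seq_len(nrow(mods))) {
    f <- mods$formula[[i]]
    m <- sum(f * c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069)[names(f)])
    expect_equal(m, mods$delta[i], tolerance = 1e-5,
                 label = mods$name[i])
  }
})

test_that("tryptic digestion follows [RK] cleavage with missed cleavages", {
  expect_setequal(digest_protein("AAKGGRCC", max_missed = 0)$sequence,
                  c("AAK", "GGR", "CC"))
  d2 <- digest_protein("AAKGGRCC", max_missed = 2)
  expect_setequal(d2$sequence,
                  c("AAK", "GGR", "CC", "AAKGGR", "GGRCC", "AAKGGRCC"))
  expect_equal(d2$missed_cleavages[d2$sequence == "AAKGGRCC"], 2L)
  # brute-force enumeration oracle: every contiguous fragment run
  frags <- c("AAK", "GGR", "CC")
  runs <- unlist(lapply(1:3, function(i)
    lapply(i:min(3, i + 2), function(j)
      paste(frags[i:j], collapse = ""))))
  expect_setequal(d2$sequence, runs)
  # KKK: positional duplicates are emitted, dedup is the library's job
  dk <- digest_protein("KKK", max_missed = 1)
  expect_setequal(unique(dk$sequence), c("K", "KK"))
  expect_equal(sum(dk$sequence == "KK"), 2L)
})

test_that("digestion without K/R returns the whole protein at any depth", {
  for (mm in c(0, 1, 3, 5))
    expect_equal(digest_protein("ACDEFGHILM", max_missed = mm)$sequence,
                 "ACDEFGHILM")
})

test_that("isotope envelopes reproduce per-element abundances", {
  c1 <- isotope_envelope(elemental_composition(C = 1), max_shift = 1,
                         renormalize = FALSE)
  expect_equal(unname(c1), c(0.9893, 0.0107), tolerance = 1e-12)
  empty <- isotope_envelope(elemental_composition(), max_shift = 5)
  expect_equal(unname(empty), c(1, 0, 0, 0, 0, 0))
  s1 <- isotope_envelope(elemental_composition(S = 1), max_shift = 4,
                         renormalize = FALSE)
  expect_equal(unname(s1), c(0.9499, 0.0075, 0.0425, 0, 0.0001),
               tolerance = 1e-12)
})

test_that("envelopes are normalised and convolve additively", {
  set.seed(42)
  for (i in 1:100) {
    comp <- random_composition()
    env <- isotope_envelope(comp, max_shift = 40, renormalize = FALSE)
    expect_lt(abs(sum(env) - 1), 1e-9)
  }
  # envelope of A+B equals the convolution of the envelopes of A and B
  for (i in 1:25) {
    a <- random_composition()
    b <- random_composition()
    ab <- elemental_composition(C = a[["C"]] + b[["C"]],
                                H = a[["H"]] + b[["H"]],
                                N = a[["N"]] + b[["N"]],
                                O = a[["O"]] + b[["O"]],
                                S = a[["S"]] + b[["S"]])
    ea <- isotope_envelope(a, max_shift = 30, renormalize = FALSE)
    eb <- isotope_envelope(b, max_shift = 30, renormalize = FALSE)
    eab <- isotope_envelope(ab, max_shift = 30, renormalize = FALSE)
    conv <- stats::convolve(ea, rev(eb), type = "open")[1:31]
    expect_lt(max(abs(eab - conv)), 1e-9)
  }
})

test_that("+1/monoisotopic ratio grows with homopolymer length", {
  ratio <- vapply(c(5, 10, 20, 40, 80), function(n) {
    env <- isotope_envelope(
      peptide_composition(strrep("G", n)), max_shift = 1,
      renormalize = FALSE)
    env[["1"]] / env[["0"]]
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
})

test_that("crossover mass agrees with a brute-force homopolymer scan", {
  # brute force: evaluate poly-G envelopes length by length
  n <- 1
  repeat {
    env <- isotope_envelope(peptide_composition(strrep("G", n)),
                            max_shift = 1, renormalize = FALSE)
    if (env[["1"]] > env[["0"]]) break
    n <- n + 1
    if (n > 100) fail("no crossover found for poly-G")
  }
  brute_mass <- peptide_mass(strrep("G", n), fixed_cys = FALSE)
  scan_mass <- plus1_crossover_mass(homopolymer_model("G"),
                                    mass_range = c(500, 4000))
  expect_lt(abs(scan_mass - brute_mass), 60)  # within one residue step
  expect_error(plus1_crossover_mass(model = NULL), "composition_model")
})
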