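# Shared fixtures, built once per test run and memoised. All randomness
# is seed-fixed so the suite is deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small plasma-like sample + simulated run + search library
fix_sample <- function() fixture("sample", function() {
  build_sample(30, dominant_fraction = 0.4, seed = 7, n_true = 10)
})

fix_library <- function() fixture("library", function() {
  build_peptide_library(fix_sample()$proteins, max_missed = 2)
})

fix_run <- function() fixture("run", function() {
  simulate_run(fix_sample(), run_parameters(1500, seed = 11))
})

fix_psms <- function() fixture("psms", function() {
  bfps(search_run(fix_run()$spectra, fix_library()))
})

# a noise-free, jitter-free run where every spectrum is exactly its
# generating peptide at its planted shift
fix_clean_run <- function() fixture("clean_run", function() {
  simulate_run(fix_sample(), run_parameters(
    400, seed = 13, precursor_jitter_sd = 0, fragment_jitter_sd = 0,
    noise_peaks_lambda = 0, spurious_rate = 0))
})

# random elemental composition of peptide-like size
random_composition <- function() {
  elemental_composition(
    C = sample(1:120, 1), H = sample(1:200, 1), N = sample(0:40, 1),
    O = sample(0:40, 1), S = sample(0:4, 1)
  )
}

# a synthetic spectrum data frame row set from explicit components
make_spectra <- function(mh, charge, intensity, peaks) {
  out <- data.frame(
    id = sprintf("TST%03d", seq_along(mh)),
    precursor_mz = (mh + (charge - 1) * proton_mass()) / charge,
    charge = as.integer(charge),
    precursor_intensity = intensity,
    stringsAsFactors = FALSE
  )
  out$peaks <- peaks
  out
}

# minimal PSM table builder for unit tests
make_psms <- function(spectrum_id, sequence, charge = 2L, p_value = 1e-4,
                      delta_mass = 0, genes = "G1", shared = FALSE,
                      source = "experimental") {
  n <- max(lengths(list(spectrum_id, sequence, charge, p_value,
                        delta_mass, genes)))
  data.frame(
    spectrum_id = rep_len(spectrum_id, n),
    sequence = rep_len(sequence, n),
    mods = "",
    charge = rep_len(as.integer(charge), n),
    observed_mh = 1000 + rep_len(delta_mass, n),
    theoretical_mh = 1000,
    delta_mass = rep_len(delta_mass, n),
    matched = 10L,
    p_value = rep_len(p_value, n),
    source = rep_len(source, n),
    genes = rep_len(genes, n),
    shared = rep_len(shared, n),
    stringsAsFactors = FALSE
  )
}
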