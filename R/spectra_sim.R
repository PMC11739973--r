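# Synthetic ground truth: plasma-like protein mixtures and simulated
# LC-MS/MS runs with isotope-envelope and hydrogen-loss precursor sampling,
# plus blank (noise-only) runs. Every downstream stage of the package is
# testable against the truth tables these functions emit.

#' Build a plasma-like synthetic protein sample
#'
#' Generates a protein mixture with the abundance skew typical of human
#' plasma: one dominant albumin-like protein holding `dominant_fraction`
#' of the total abundance, a set of "planted true" proteins whose
#' abundances decay as a power law, and a pool of trace background
#' proteins. Sequences are random with human-average residue frequencies
#' unless a FASTA file is supplied.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param dominant_fraction Fraction of total abundance held by the
#'   dominant protein, in (0,1). Default 0.5, the order of magnitude of
#'   albumin's share of plasma protein.
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @param source_fasta Optional FASTA path; its first `n_proteins` records
#'   are used instead of random sequences.
#' @param n_true Number of planted-true proteins (including the dominant
#'   one); these receive abundances high enough to be detectable.
#' @param background_fraction Total abundance shared by the remaining
#'   background proteins. Default 0.02.
#' @param abundance_exponent Power-law exponent of the planted abundance
#'   decay. Default 1 (Zipf-like).
#' @param length_range Length range of random protein sequences.
#' @return A `synthetic_sample`: list with `proteins` (data frame:
#'   `accession`, `gene`, `sequence`, `abundance`) and `planted_true`
#'   (character vector of gene symbols).
#' @export
build_sample <- function(n_proteins, dominant_fraction = 0.5, seed = 1,
                         source_fasta = NULL,
                         n_true = min(100L, n_proteins),
                         background_fraction = 0.02,
                         abundance_exponent = 1,
                         length_range = c(150, 600)) {
  n_proteins <- as.integer(n_proteins)
  if (n_proteins < 2L) stop("n_proteins must be >= 2")
  if (!(dominant_fraction > 0 && dominant_fraction < 1))
    stop("dominant_fraction must be in (0, 1)")
  n_true <- min(as.integer(n_true), n_proteins)
  set.seed(as.integer(seed))

  if (!is.null(source_fasta)) {
    prot <- read_fasta(source_fasta)
    if (nrow(prot) < n_proteins)
      stop("FASTA holds fewer than n_proteins records")
    prot <- prot[seq_len(n_proteins), c("accession", "gene", "sequence")]
  } else {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(.IE_AA_FREQ), L, replace = TRUE,
                   prob = .IE_AA_FREQ), collapse = "")
    }, character(1))
    prot <- data.frame(
      accession = sprintf("SYNP%04d", seq_len(n_proteins)),
      gene = sprintf("GS%04d", seq_len(n_proteins)),
      sequence = seqs,
      stringsAsFactors = FALSE
    )
  }

  n_bg <- n_proteins - n_true
  bg_frac <- if (n_bg > 0) background_fraction else 0
  planted_frac <- 1 - dominant_fraction - bg_frac
  if (planted_frac <= 0) stop("dominant + background fractions exceed 1")
  ab <- numeric(n_proteins)
  ab[1] <- dominant_fraction
  if (n_true > 1L) {
    w <- (seq_len(n_true - 1L))^(-abundance_exponent)
    ab[2:n_true] <- planted_frac * w / sum(w)
  } else {
    ab[1] <- ab[1] + planted_frac
  }
  if (n_bg > 0) ab[(n_true + 1L):n_proteins] <- bg_frac / n_bg
  prot$abundance <- ab

  structure(
    list(proteins = prot, planted_true = prot$gene[seq_len(n_true)],
         seed = as.integer(seed)),
    class = "synthetic_sample"
  )
}

#' Parameters of a simulated LC-MS/MS run
#'
#' @param n_spectra Number of MS/MS spectra to emit (>= 1).
#' @param seed Integer seed for all randomness in the run.
#' @param isotope_sampling Draw the non-negative part of the precursor
#'   shift from each peptide's isotope envelope (default `TRUE`). When
#'   off, all non-hydrogen-loss precursors sit at shift 0.
#' @param hloss_probs Named probabilities of hydrogen-loss satellites at
#'   -1/-2/-3 Da. Defaults (0.05, 0.02, 0.01); these are phenomenological
#'   rates, not measured chemistry, and are deliberately configurable.
#' @param precursor_jitter_sd Gaussian jitter (Da) added to the observed
#'   MH; default 0.02 Da, an orbital-trap-like per-ion accuracy.
#' @param fragment_jitter_sd Gaussian jitter (Da) on fragment m/z,
#'   default 0.05 Da.
#' @param noise_peaks_lambda Poisson mean of spurious fragment peaks added
#'   to each true spectrum, default 8.
#' @param noise_fragment_lambda Poisson mean of fragment peaks in purely
#'   spurious/blank spectra, default 30.
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of
#'   precursor intensity (arbitrary counts), defaults log(5e4) and 1.2.
#' @param spurious_rate Fraction of spectra with no generating peptide,
#'   default 0.10.
#' @param fragment_mz_range m/z range of retained fragments, default
#'   (150, 2000).
#' @param charge_probs Named sampling weights for precursor charges 2+ and
#'   3+ (renormalised over the charges feasible for each peptide).
#' @param flyability_shape Gamma shape of per-peptide ionisation
#'   propensities within a protein; small values concentrate a protein's
#'   signal in a few proteotypic peptides. Default 0.15.
#' @param max_missed Missed cleavages allowed for generated peptides,
#'   default 1.
#' @param max_shift Largest heavy-isotope shift sampled, default +5.
#' @return A `run_parameters` list.
#' @export
run_parameters <- function(n_spectra, seed = 1, isotope_sampling = TRUE,
                           hloss_probs = c("-1" = 0.05, "-2" = 0.02,
                                           "-3" = 0.01),
                           precursor_jitter_sd = 0.02,
                           fragment_jitter_sd = 0.05,
                           noise_peaks_lambda = 8,
                           noise_fragment_lambda = 30,
                           intensity_meanlog = log(5e4),
                           intensity_sdlog = 1.2,
                           spurious_rate = 0.10,
                           fragment_mz_range = c(150, 2000),
                           charge_probs = c("2" = 0.7, "3" = 0.3),
                           flyability_shape = 0.15,
                           max_missed = 1,
                           max_shift = 5) {
  n_spectra <- as.integer(n_spectra)
  if (n_spectra < 0L) stop("n_spectra must be >= 0")
  hl <- hloss_probs[c("-1", "-2", "-3")]
  hl[is.na(hl)] <- 0
  names(hl) <- c("-1", "-2", "-3")
  if (any(hl < 0) || sum(hl) >= 1)
    stop("hydrogen-loss probabilities must be in [0,1) and sum below 1")
  stopifnot(precursor_jitter_sd >= 0, fragment_jitter_sd >= 0,
            spurious_rate >= 0, spurious_rate < 1)
  structure(
    list(n_spectra = n_spectra, seed = as.integer(seed),
         isotope_sampling = isotope_sampling, hloss_probs = hl,
         precursor_jitter_sd = precursor_jitter_sd,
         fragment_jitter_sd = fragment_jitter_sd,
         noise_peaks_lambda = noise_peaks_lambda,
         noise_fragment_lambda = noise_fragment_lambda,
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog,
         spurious_rate = spurious_rate,
         fragment_mz_range = fragment_mz_range,
         charge_probs = charge_probs,
         flyability_shape = flyability_shape,
         max_missed = as.integer(max_missed),
         max_shift = as.integer(max_shift)),
    class = "run_parameters"
  )
}

# Feasible charges (among 2,3) putting a precursor of protonated mass mh
# within the instrument m/z window.
.ie_feasible_charges <- function(mh, mz_range = c(500, 2000)) {
  z <- c(2L, 3L)
  mz <- (mh + (z - 1) * .IE_PROTON) / z
  z[mz > mz_range[1] & mz < mz_range[2]]
}

# Eligible peptide pool for a sample: digested, mass-computed, restricted
# to masses reachable at charge 2+ or 3+, with per-peptide sampling
# weights (protein abundance x flyability).
.ie_peptide_pool <- function(sample, params) {
  prot <- sample$proteins
  pools <- lapply(seq_len(nrow(prot)), function(i) {
    pep <- digest_protein(prot$sequence[i], max_missed = params$max_missed)
    pep <- pep[!duplicated(pep$sequence), , drop = FALSE]
    pep$mh <- vapply(pep$sequence, peptide_mh, numeric(1), USE.NAMES = FALSE)
    pep <- pep[pep$mh > 999 & pep$mh < 5990, , drop = FALSE]
    pep <- pep[vapply(pep$mh, function(m)
      length(.ie_feasible_charges(m)) > 0, logical(1)), , drop = FALSE]
    if (!nrow(pep)) return(NULL)
    fly <- stats::rgamma(nrow(pep), shape = params$flyability_shape, rate = 1)
    if (sum(fly) == 0) fly <- rep(1, nrow(pep))
    pep$weight <- prot$abundance[i] * fly / sum(fly)
    pep$gene <- prot$gene[i]
    pep
  })
  do.call(rbind, pools[!vapply(pools, is.null, logical(1))])
}

# Mixture over integer precursor shifts for one peptide: hydrogen-loss
# satellites at -1/-2/-3 plus the isotope envelope on 0..max_shift.
.ie_shift_probs <- function(sequence, params) {
  hl <- params$hloss_probs
  if (params$isotope_sampling) {
    env <- isotope_envelope(peptide_composition(sequence, fixed_cys = TRUE),
                            max_shift = params$max_shift)
    pos <- (1 - sum(hl)) * env
  } else {
    pos <- c("0" = 1 - sum(hl),
             stats::setNames(numeric(params$max_shift),
                             as.character(seq_len(params$max_shift))))
  }
  shifts <- c(-3L, -2L, -1L, 0L:params$max_shift)
  probs <- c(hl[["-3"]], hl[["-2"]], hl[["-1"]], unname(pos))
  list(shifts = shifts, probs = probs)
}

# One noise fragment peak set
.ie_noise_peaks <- function(n, params) {
  if (n <= 0) return(cbind(mz = numeric(0), intensity = numeric(0)))
  mz <- stats::runif(n, params$fragment_mz_range[1], params$fragment_mz_range[2])
  cbind(mz = mz, intensity = stats::rlnorm(n, meanlog = log(500), sdlog = 1))
}

#' Simulate an LC-MS/MS run from a synthetic sample
#'
#' For each non-spurious spectrum: a peptide is drawn proportional to
#' protein abundance times peptide flyability; a charge (2+ or 3+) is
#' drawn among the feasible ones; an integer precursor shift k is drawn
#' from the peptide's isotope envelope mixed with the hydrogen-loss
#' probabilities (k in -3..+5); the observed MH is the theoretical MH plus
#' k plus Gaussian jitter; fragments are the b/y ladder with jitter plus
#' Poisson noise peaks. Spurious spectra carry noise only. The truth table
#' records the generating peptide, gene and shift of every non-spurious
#' spectrum.
#'
#' @param sample A `synthetic_sample` from [build_sample()].
#' @param params A `run_parameters` object.
#' @return A `simulated_run`: list with `spectra` (data frame: `id`,
#'   `precursor_mz`, `charge`, `precursor_intensity`, list-column `peaks`
#'   of two-column matrices sorted by m/z) and `truth` (data frame:
#'   `spectrum_id`, `sequence`, `gene`, `shift`, `theoretical_mh`).
#' @export
simulate_run <- function(sample, params) {
  stopifnot(inherits(sample, "synthetic_sample"),
            inherits(params, "run_parameters"))
  set.seed(params$seed)
  n <- params$n_spectra
  if (n == 0L)
    return(structure(list(spectra = .ie_empty_spectra(),
                          truth = .ie_empty_truth()),
                     class = "simulated_run"))

  pool <- .ie_peptide_pool(sample, params)
  if (is.null(pool) || !nrow(pool)) stop("no eligible peptides in sample")

  spurious <- stats::runif(n) < params$spurious_rate
  idx <- integer(n)
  idx[!spurious] <- sample.int(nrow(pool), sum(!spurious), replace = TRUE,
                               prob = pool$weight)

  # per-peptide shift distributions, computed once per distinct peptide
  shift <- integer(n)
  by_pep <- split(which(!spurious), idx[!spurious])
  for (u in names(by_pep)) {
    sel <- by_pep[[u]]
    sp <- .ie_shift_probs(pool$sequence[as.integer(u)], params)
    shift[sel] <- sample(sp$shifts, length(sel), replace = TRUE,
                         prob = sp$probs)
  }

  ids <- sprintf("SIM%06d", seq_len(n))
  precursor_mz <- numeric(n)
  charge <- integer(n)
  intensity <- stats::rlnorm(n, params$intensity_meanlog,
                             params$intensity_sdlog)
  peaks <- vector("list", n)
  rng <- params$fragment_mz_range

  for (i in seq_len(n)) {
    if (spurious[i]) {
      mh <- stats::runif(1, 1000, 4000)
      z <- sample(c(2L, 3L), 1)
      np <- max(2L, stats::rpois(1, params$noise_fragment_lambda))
      pk <- .ie_noise_peaks(np, params)
    } else {
      u <- idx[i]
      mh_theor <- pool$mh[u]
      feas <- .ie_feasible_charges(mh_theor + shift[i])
      if (!length(feas)) feas <- .ie_feasible_charges(mh_theor)
      w <- params$charge_probs[as.character(feas)]
      w[is.na(w)] <- 1e-6
      z <- if (length(feas) == 1L) feas else
        sample(feas, 1, prob = w)
      mh <- mh_theor + shift[i] +
        stats::rnorm(1, 0, params$precursor_jitter_sd)
      lad <- fragment_ladder(pool$sequence[u], charge = z)
      fmz <- lad + stats::rnorm(length(lad), 0, params$fragment_jitter_sd)
      keep <- fmz >= rng[1] & fmz <= rng[2]
      tr <- cbind(mz = fmz[keep],
                  intensity = stats::rlnorm(sum(keep), log(5e3), 1))
      nn <- stats::rpois(1, params$noise_peaks_lambda)
      pk <- rbind(tr, .ie_noise_peaks(nn, params))
      if (nrow(pk) < 2L) pk <- rbind(pk, .ie_noise_peaks(2L, params))
    }
    pk <- pk[order(pk[, 1L]), , drop = FALSE]
    peaks[[i]] <- pk
    charge[i] <- z
    precursor_mz[i] <- (mh + (z - 1) * .IE_PROTON) / z
  }

  spectra <- data.frame(id = ids, precursor_mz = precursor_mz,
                        charge = charge, precursor_intensity = intensity,
                        stringsAsFactors = FALSE)
  spectra$peaks <- peaks

  tr_sel <- which(!spurious)
  truth <- data.frame(
    spectrum_id = ids[tr_sel],
    sequence = pool$sequence[idx[tr_sel]],
    gene = pool$gene[idx[tr_sel]],
    shift = shift[tr_sel],
    theoretical_mh = pool$mh[idx[tr_sel]],
    stringsAsFactors = FALSE
  )
  structure(list(spectra = spectra, truth = truth), class = "simulated_run")
}

.ie_empty_spectra <- function() {
  out <- data.frame(id = character(0), precursor_mz = numeric(0),
                    charge = integer(0), precursor_intensity = numeric(0),
                    stringsAsFactors = FALSE)
  out$peaks <- list()
  out
}

.ie_empty_truth <- function() {
  data.frame(spectrum_id = character(0), sequence = character(0),
             gene = character(0), shift = integer(0),
             theoretical_mh = numeric(0), stringsAsFactors = FALSE)
}

#' Simulate a blank (noise-only) run
#'
#' Spectra carry no planted peptide signal: precursor masses and fragment
#' peaks are drawn from the noise model only. Blank runs stand in for
#' solvent-only injections and serve as the analytical control when
#' correcting observation frequencies.
#'
#' @param params A `run_parameters` object; `n_spectra`, `seed` and the
#'   noise-model fields are used.
#' @return A data frame of spectra shaped like `simulate_run()$spectra`,
#'   with ids `BLK000001`, ...
#' @export
simulate_blank <- function(params) {
  stopifnot(inherits(params, "run_parameters"))
  set.seed(params$seed)
  n <- params$n_spectra
  if (n == 0L) return(.ie_empty_spectra())
  ids <- sprintf("BLK%06d", seq_len(n))
  mh <- stats::rlnorm(n, log(1800), 0.35)
  mh <- pmin(pmax(mh, 1010), 3980)
  z <- sample(c(2L, 3L), n, replace = TRUE)
  feas2 <- (mh + .IE_PROTON) / 2
  z[feas2 >= 2000] <- 3L
  intensity <- stats::rlnorm(n, params$intensity_meanlog,
                             params$intensity_sdlog)
  peaks <- lapply(seq_len(n), function(i) {
    np <- max(2L, stats::rpois(1, params$noise_fragment_lambda))
    pk <- .ie_noise_peaks(np, params)
    pk[order(pk[, 1L]), , drop = FALSE]
  })
  out <- data.frame(id = ids,
                    precursor_mz = (mh + (z - 1) * .IE_PROTON) / z,
                    charge = z, precursor_intensity = intensity,
                    stringsAsFactors = FALSE)
  out$peaks <- peaks
  out
}
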