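# Peptide mass/composition arithmetic, tryptic digestion, modifications
# and isotopic-envelope computation.

#' Elemental composition of a peptide
#'
#' Sums the standard residue compositions of `sequence` and adds one water
#' (peptides are residue chains plus H2O). Modifications with a known
#' elemental formula add their atoms to the composition; mass-only
#' modifications are carried separately in the `extra_mass` attribute so
#' that [monoisotopic_mass()] still returns the full mass.
#'
#' @param sequence Peptide sequence using the 20 standard one-letter codes.
#' @param mods Optional list of modifications, each a list with elements
#'   `delta` (monoisotopic mass shift, Da) and optionally `formula`
#'   (named integer vector over C,H,N,O,S). A `position` element is allowed
#'   and ignored here (composition is position-independent).
#' @param fixed_cys Add the carbamidomethyl formula (C2H3NO) for every
#'   cysteine. Default `FALSE` so that the bare residue-sum identity holds.
#' @return An object of class `elemental_composition`: a named integer
#'   vector with elements C, H, N, O, S and attribute `extra_mass` (Da).
#' @examples
#' peptide_composition("G")   # C2 H5 N1 O2
#' @export
peptide_composition <- function(sequence, mods = NULL, fixed_cys = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(aa, rownames(.IE_RESIDUE_COMP))
  if (anyNA(idx)) {
    bad <- unique(aa[is.na(idx)])
    stop("unknown residue(s) in sequence: ", paste(bad, collapse = ", "))
  }
  counts <- colSums(.IE_RESIDUE_COMP[idx, , drop = FALSE])
  counts[["H"]] <- counts[["H"]] + 2L
  counts[["O"]] <- counts[["O"]] + 1L
  if (fixed_cys) {
    ncys <- sum(aa == "C")
    counts[["C"]] <- counts[["C"]] + 2L * ncys
    counts[["H"]] <- counts[["H"]] + 3L * ncys
    counts[["N"]] <- counts[["N"]] + ncys
    counts[["O"]] <- counts[["O"]] + ncys
  }
  extra <- 0
  for (m in mods) {
    if (!is.null(m$formula)) {
      f <- m$formula
      counts[names(f)] <- counts[names(f)] + f
    } else if (!is.null(m$delta)) {
      if (!is.finite(m$delta)) stop("modification delta must be finite")
      extra <- extra + m$delta
    }
  }
  if (any(counts < 0)) stop("modification removes more atoms than present")
  structure(round(counts), extra_mass = extra,
            class = "elemental_composition")
}

#' Bare elemental composition from atom counts
#'
#' @param C,H,N,O,S Non-negative atom counts.
#' @param extra_mass Additional mass (Da) not described by a formula.
#' @return An `elemental_composition` object.
#' @export
elemental_composition <- function(C = 0, H = 0, N = 0, O = 0, S = 0,
                                  extra_mass = 0) {
  counts <- c(C = C, H = H, N = N, O = O, S = S)
  if (any(counts < 0)) stop("atom counts must be non-negative")
  structure(round(counts), extra_mass = extra_mass,
            class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  cat(paste0(names(nz), unclass(nz), collapse = " "),
      if (attr(x, "extra_mass") != 0)
        sprintf("(+%.6f Da non-elemental)", attr(x, "extra_mass")),
      "\n")
  invisible(x)
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp An `elemental_composition`.
#' @return Mass in Da: sum of atom counts times lightest-isotope masses,
#'   plus any mass-only modification carried in `extra_mass`.
#' @examples
#' monoisotopic_mass(elemental_composition(H = 2, O = 1)) # 18.010565
#' @export
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  sum(unclass(comp) * .IE_ATOMS[names(comp)]) +
    (attr(comp, "extra_mass") %||% 0)
}

#' Neutral monoisotopic mass and MH of a peptide
#'
#' @inheritParams peptide_composition
#' @param fixed_cys Apply the fixed carbamidomethyl modification
#'   (+57.021464 Da) to every cysteine. Default `TRUE`, matching the
#'   standard alkylation protocol.
#' @return `peptide_mass()` returns the neutral monoisotopic mass (Da);
#'   `peptide_mh()` adds one proton.
#' @export
peptide_mass <- function(sequence, mods = NULL, fixed_cys = TRUE) {
  monoisotopic_mass(peptide_composition(sequence, mods, fixed_cys = fixed_cys))
}

#' @rdname peptide_mass
#' @export
peptide_mh <- function(sequence, mods = NULL, fixed_cys = TRUE) {
  peptide_mass(sequence, mods, fixed_cys) + .IE_PROTON
}

#' In-silico tryptic digestion
#'
#' Cleaves after every K or R (rule `[RK]|[X]`, i.e. no proline exception)
#' and emits every contiguous run of 1 to `max_missed + 1` fragments,
#' annotated with its missed-cleavage count and position. Peptides arising
#' at several positions are all returned; deduplication by sequence is the
#' caller's concern (see [build_peptide_library()]).
#'
#' @param protein Protein sequence (one-letter codes; non-empty).
#' @param max_missed Maximum number of missed cleavages, default 3.
#' @return A data frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`.
#' @examples
#' digest_protein("AAKGGRCC", max_missed = 0)$sequence # AAK GGR CC
#' @export
digest_protein <- function(protein, max_missed = 3) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  max_missed <- as.integer(max_missed)
  stopifnot(max_missed >= 0L)
  n <- nchar(protein)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  k <- length(starts)
  out_start <- integer(0); out_end <- integer(0); out_mc <- integer(0)
  for (i in seq_len(k)) {
    jmax <- min(k, i + max_missed)
    js <- i:jmax
    out_start <- c(out_start, rep.int(starts[i], length(js)))
    out_end <- c(out_end, ends[js])
    out_mc <- c(out_mc, js - i)
  }
  data.frame(
    sequence = substring(protein, out_start, out_end),
    start = out_start,
    end = out_end,
    missed_cleavages = out_mc,
    stringsAsFactors = FALSE
  )
}

# Truncated linear convolution of two probability vectors (index 0-based
# mass shifts), keeping at most `cap` entries.
.ie_conv <- function(a, b, cap = 64L) {
  out <- stats::convolve(a, rev(b), type = "open")
  out[out < 0] <- 0  # FFT round-off
  if (length(out) > cap) out <- out[seq_len(cap)]
  out
}

# abundance vector raised to the n-th convolution power
.ie_conv_pow <- function(v, n, cap = 64L) {
  result <- 1
  base <- v
  while (n > 0L) {
    if (n %% 2L == 1L) result <- .ie_conv(result, base, cap)
    n <- n %/% 2L
    if (n > 0L) base <- .ie_conv(base, base, cap)
  }
  result
}

#' Nominal-mass isotope envelope of a composition
#'
#' Iterated convolution of the per-element isotope-abundance vectors
#' (C/H/N at +0/+1; O at +0/+1/+2; S at +0/+1/+2/+4). The envelope gives
#' the probability that the molecule carries a total nominal mass shift of
#' k Da relative to the all-light-isotope species.
#'
#' @param comp An `elemental_composition`.
#' @param max_shift Largest shift retained (default 5 Da).
#' @param renormalize Rescale the truncated envelope to sum to one
#'   (default `TRUE`). With `renormalize = FALSE` the vector keeps the raw
#'   probabilities, whose sum approaches 1 as `max_shift` grows.
#' @return Named numeric vector `p0 ... p<max_shift>` (names `"0"`,
#'   `"1"`, ...).
#' @examples
#' isotope_envelope(elemental_composition(C = 1), max_shift = 1,
#'                  renormalize = FALSE)  # 0.9893, 0.0107
#' @export
isotope_envelope <- function(comp, max_shift = 5, renormalize = TRUE) {
  stopifnot(inherits(comp, "elemental_composition"))
  cap <- max(64L, as.integer(max_shift) + 1L)
  env <- 1
  for (el in names(.IE_ISOTOPES)) {
    n <- unclass(comp)[[el]]
    if (n > 0) env <- .ie_conv(env, .ie_conv_pow(.IE_ISOTOPES[[el]], n, cap), cap)
  }
  k <- as.integer(max_shift) + 1L
  if (length(env) < k) env <- c(env, numeric(k - length(env)))
  out <- env[seq_len(k)]
  if (renormalize) out <- out / sum(env)
  names(out) <- as.character(seq_len(k) - 1L)
  out
}

#' Mass-to-composition scaling models
#'
#' `averagine_model()` scales the averagine mean peptide composition
#' (C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per 111.1254 Da) to a target
#' mass; `homopolymer_model()` builds poly-residue compositions (residue
#' repeats plus one water), useful as an independent check.
#'
#' @param residue One-letter residue code for `homopolymer_model()`.
#' @return A `composition_model` object: a function of mass (Da) returning
#'   an `elemental_composition` with rounded atom counts.
#' @export
averagine_model <- function() {
  f <- function(mass) {
    counts <- round(.IE_AVERAGINE * mass)
    elemental_composition(C = counts[["C"]], H = counts[["H"]],
                          N = counts[["N"]], O = counts[["O"]],
                          S = counts[["S"]])
  }
  structure(f, class = c("composition_model", "function"))
}

#' @rdname averagine_model
#' @export
homopolymer_model <- function(residue = "G") {
  rc <- .IE_RESIDUE_COMP[residue, ]
  rm <- .IE_RESIDUE_MASS[[residue]]
  f <- function(mass) {
    n <- max(1L, round((mass - .IE_WATER) / rm))
    elemental_composition(C = n * rc[["C"]], H = n * rc[["H"]] + 2,
                          N = n * rc[["N"]], O = n * rc[["O"]] + 1,
                          S = n * rc[["S"]])
  }
  structure(f, class = c("composition_model", "function"))
}

#' Mass at which the +1 isotope peak overtakes the monoisotopic peak
#'
#' Scans peptide masses under a mass-to-composition scaling model,
#' evaluates the isotope envelope at each mass, and returns the smallest
#' mass at which p(+1) exceeds p(0). For natural-composition peptides this
#' crossover falls between 1000 and 2000 Da, which is why restricting a
#' search to the monoisotopic peak discards most of the signal from large
#' peptides.
#'
#' @param model A `composition_model` (default [averagine_model()]).
#' @param mass_range Masses scanned, Da.
#' @param coarse_step,fine_step Scan resolutions, Da.
#' @return Crossover mass in Da (numeric), or `NA` if p1 never exceeds p0
#'   in `mass_range`.
#' @export
plus1_crossover_mass <- function(model = averagine_model(),
                                 mass_range = c(500, 3000),
                                 coarse_step = 20, fine_step = 1) {
  if (is.null(model) || !inherits(model, "composition_model"))
    stop("a composition_model is required")
  p1_gt_p0 <- function(mass) {
    env <- isotope_envelope(model(mass), max_shift = 2, renormalize = FALSE)
    env[["1"]] > env[["0"]]
  }
  grid <- seq(mass_range[1], mass_range[2], by = coarse_step)
  hit <- which(vapply(grid, p1_gt_p0, logical(1)))
  if (!length(hit)) return(NA_real_)
  lo <- if (hit[1] == 1L) grid[1] else grid[hit[1] - 1L]
  fine <- seq(lo, grid[hit[1]], by = fine_step)
  fine[which(vapply(fine, p1_gt_p0, logical(1)))[1]]
}

#' Standard peptide modifications
#'
#' The fixed cysteine carbamidomethylation plus the usual variable
#' modifications considered in wide-window plasma searches: oxidation and
#' dioxidation of M/W, deamidation of N/Q, a C-terminal hydroxyl and an
#' N-terminal proton. The N-terminal proton is as much a charge
#' bookkeeping device as a chemical modification and is disabled by
#' default.
#'
#' @return A data frame with columns `name`, `targets` (residue letters,
#'   or `"nterm"`/`"cterm"`), `delta` (Da), `fixed`, `enabled` and a
#'   list-column `formula`.
#' @export
standard_modifications <- function() {
  data.frame(
    name = c("carbamidomethyl", "oxidation", "dioxidation",
             "deamidation", "cterm_hydroxyl", "nterm_proton"),
    targets = c("C", "M,W", "M,W", "N,Q", "cterm", "nterm"),
    delta = c(57.021464, 15.994915, 31.98983, 0.984016,
              17.002735, 1.007825),
    fixed = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    enabled = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    formula = I(list(
      c(C = 2L, H = 3L, N = 1L, O = 1L),
      c(O = 1L),
      c(O = 2L),
      c(H = -1L, N = -1L, O = 1L),
      c(H = 1L, O = 1L),
      c(H = 1L)
    )),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
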