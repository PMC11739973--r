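# A defined, simplified goodness-of-fit peptide-spectrum matcher.
# The scorer is a declared stand-in for full database-search engines:
# greedy b/y fragment matching with a binomial-tail p-value. External
# search results can be ingested as PSM tables instead (see
# read_psm_tsv()), so all downstream modules are scorer-agnostic.

#' Search configuration
#'
#' Precursor and scoring filters of a wide-window search: 2+/3+ precursors
#' from 500 to 2000 m/z, delta-mass window -3.0 to +5.0 Da, fragments
#' matched at +/-0.5 Da, a minimum precursor intensity of 1000 counts and
#' a maximum accepted p-value of 0.01.
#'
#' @param precursor_mz_range Precursor m/z window, default c(500, 2000).
#' @param charges Accepted precursor charges, default c(2, 3).
#' @param delta_window Precursor delta-mass window in Da, default
#'   c(-3, 5).
#' @param fragment_tol Fragment matching tolerance (one side), Da.
#' @param min_precursor_intensity Minimum precursor intensity counts.
#' @param max_p Maximum accepted PSM p-value.
#' @return A `search_config` list.
#' @export
search_config <- function(precursor_mz_range = c(500, 2000),
                          charges = c(2L, 3L),
                          delta_window = c(-3, 5),
                          fragment_tol = 0.5,
                          min_precursor_intensity = 1000,
                          max_p = 0.01) {
  stopifnot(delta_window[1] < delta_window[2], fragment_tol > 0,
            max_p > 0, max_p <= 1)
  structure(
    list(precursor_mz_range = precursor_mz_range,
         charges = as.integer(charges), delta_window = delta_window,
         fragment_tol = fragment_tol,
         min_precursor_intensity = min_precursor_intensity,
         max_p = max_p),
    class = "search_config"
  )
}

#' b/y fragment-ion ladder of a peptide
#'
#' Singly charged b and y ions at every peptide-bond cleavage position;
#' doubly charged b/y ions are added when the precursor charge is 3+.
#'
#' @param sequence Peptide sequence (length >= 2).
#' @param charge Precursor charge (2 or 3).
#' @param mod_positions,mod_deltas Optional parallel vectors of modified
#'   residue positions and their mass deltas (Da).
#' @param fixed_cys Apply carbamidomethyl to cysteines, default `TRUE`.
#' @return Ascending numeric vector of fragment m/z values.
#' @export
fragment_ladder <- function(sequence, charge = 2L, mod_positions = NULL,
                            mod_deltas = NULL, fixed_cys = TRUE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(aa)
  if (L < 2L) stop("peptide must have length >= 2")
  res <- .IE_RESIDUE_MASS[aa]
  if (anyNA(res)) stop("unknown residue in sequence")
  if (fixed_cys) res[aa == "C"] <- res[aa == "C"] + 57.021464
  if (length(mod_positions))
    res[mod_positions] <- res[mod_positions] + mod_deltas
  cs <- cumsum(res)
  total <- cs[L]
  bi <- cs[seq_len(L - 1L)]                 # neutral b fragment masses
  yi <- total - cs[seq_len(L - 1L)]         # neutral y minus water
  out <- c(bi + .IE_PROTON, yi + .IE_WATER + .IE_PROTON)
  if (charge >= 3L)
    out <- c(out, (bi + 2 * .IE_PROTON) / 2,
             (yi + .IE_WATER + 2 * .IE_PROTON) / 2)
  sort(unname(out))
}

# binomial-tail p-value of a matched count given ladder size and
# per-trial probability q, clamped away from zero
.ie_binom_p <- function(matched, trials, q) {
  p <- stats::pbinom(matched - 1L, trials, q, lower.tail = FALSE)
  pmax(pmin(p, 1), 1e-300)
}

#' Score one spectrum against one peptide
#'
#' Counts ladder ions matched within the fragment tolerance (each
#' observed peak consumed at most once, greedily in ascending m/z) and
#' converts the count to a binomial upper-tail p-value with per-trial
#' probability `q = min(1, n_peaks * 2 * tol / spanned m/z range)`.
#'
#' @param spectrum A one-row spectrum (list or data-frame row) with
#'   elements `peaks` (two-column matrix, m/z ascending) and `charge`.
#' @param sequence Peptide sequence.
#' @param config A [search_config()].
#' @param mod_positions,mod_deltas Optional modification vectors passed to
#'   [fragment_ladder()].
#' @return List with `matched` (count) and `p` (probability).
#' @export
score_match <- function(spectrum, sequence, config = search_config(),
                        mod_positions = NULL, mod_deltas = NULL) {
  pk <- spectrum$peaks
  if (is.list(pk) && !is.matrix(pk)) pk <- pk[[1]]
  lad <- fragment_ladder(sequence, charge = spectrum$charge[[1]],
                         mod_positions = mod_positions,
                         mod_deltas = mod_deltas)
  if (is.null(pk) || nrow(pk) == 0L)
    return(list(matched = 0L, p = 1))
  mz <- pk[, 1L]
  if (is.unsorted(mz)) mz <- sort(mz)
  span <- mz[length(mz)] - mz[1L]
  if (span <= 0) stop("spectrum spans zero m/z range")
  matched <- ie_match_count(lad, mz, config$fragment_tol)
  q <- min(1, length(mz) * 2 * config$fragment_tol / span)
  list(matched = matched, p = .ie_binom_p(matched, length(lad), q))
}

#' Build a peptide search library from proteins
#'
#' Digests every protein ([RK] cleavage, up to `max_missed` missed
#' cleavages), deduplicates by sequence (recording all parent gene
#' symbols; peptides shared across symbols are flagged), optionally
#' expands variable modifications (at most `max_variable` per peptide),
#' and computes theoretical MH values with fixed cysteine
#' carbamidomethylation.
#'
#' @param proteins Data frame with columns `accession`, `gene`,
#'   `sequence` (e.g. `build_sample()$proteins` or [read_fasta()] output).
#' @param max_missed Missed cleavages, default 3.
#' @param variable_mods Optional subset of [standard_modifications()]
#'   rows (`fixed == FALSE`) to expand combinatorially.
#' @param max_variable Cap on simultaneous variable modifications per
#'   peptide, default 2.
#' @param mh_range Retain peptides with theoretical MH in this range.
#' @param min_length Minimum peptide length, default 5.
#' @return A `peptide_library` data frame sorted by `mh`, with columns
#'   `sequence`, `mods`, `genes`, `shared`, `missed_cleavages`, `mh` and
#'   list-columns `mod_positions`, `mod_deltas`.
#' @export
build_peptide_library <- function(proteins, max_missed = 3,
                                  variable_mods = NULL, max_variable = 2,
                                  mh_range = c(600, 6100),
                                  min_length = 5) {
  stopifnot(all(c("gene", "sequence") %in% names(proteins)))
  digs <- lapply(seq_len(nrow(proteins)), function(i) {
    d <- digest_protein(proteins$sequence[i], max_missed = max_missed)
    d <- d[nchar(d$sequence) >= min_length, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    d$gene <- proteins$gene[i]
    d
  })
  digs <- do.call(rbind, digs[!vapply(digs, is.null, logical(1))])
  if (is.null(digs) || !nrow(digs)) stop("no peptides produced by digestion")

  # deduplicate by sequence, collapse parent genes
  gene_map <- tapply(digs$gene, digs$sequence,
                     function(g) sort(unique(g)), simplify = FALSE)
  first <- digs[!duplicated(digs$sequence), , drop = FALSE]
  mc_min <- tapply(digs$missed_cleavages, digs$sequence, min)
  lib <- data.frame(
    sequence = first$sequence,
    mods = "",
    stringsAsFactors = FALSE
  )
  genes <- gene_map[lib$sequence]
  lib$genes <- vapply(genes, paste, character(1), collapse = ";")
  lib$shared <- lengths(genes) > 1L
  lib$missed_cleavages <- as.integer(mc_min[lib$sequence])
  lib$mod_positions <- rep(list(integer(0)), nrow(lib))
  lib$mod_deltas <- rep(list(numeric(0)), nrow(lib))

  if (!is.null(variable_mods) && nrow(variable_mods)) {
    lib <- .ie_expand_mods(lib, variable_mods, max_variable)
  }

  base_mh <- vapply(lib$sequence, peptide_mh, numeric(1), USE.NAMES = FALSE)
  lib$mh <- base_mh + vapply(lib$mod_deltas, sum, numeric(1))
  lib <- lib[lib$mh >= mh_range[1] & lib$mh <= mh_range[2], , drop = FALSE]
  lib <- lib[order(lib$mh), , drop = FALSE]
  rownames(lib) <- NULL
  class(lib) <- c("peptide_library", "data.frame")
  lib
}

# combinatorial expansion of variable modifications, capped at
# max_variable simultaneous sites per peptide
.ie_expand_mods <- function(lib, variable_mods, max_variable) {
  rows <- vector("list", nrow(lib))
  for (i in seq_len(nrow(lib))) {
    base <- lib[i, , drop = FALSE]
    aa <- strsplit(base$sequence, "", fixed = TRUE)[[1]]
    sites <- list()
    for (j in seq_len(nrow(variable_mods))) {
      m <- variable_mods[j, ]
      tg <- strsplit(m$targets, ",", fixed = TRUE)[[1]]
      pos <- if (identical(tg, "nterm")) 1L
             else if (identical(tg, "cterm")) length(aa)
             else which(aa %in% tg)
      for (p in pos)
        sites[[length(sites) + 1L]] <- list(pos = p, delta = m$delta,
                                            name = m$name)
    }
    combos <- list(list())
    if (length(sites)) {
      for (k in seq_len(min(max_variable, length(sites)))) {
        cmb <- utils::combn(length(sites), k, simplify = FALSE)
        for (cc in cmb) {
          sel <- sites[cc]
          if (anyDuplicated(vapply(sel, `[[`, integer(1), "pos"))) next
          combos[[length(combos) + 1L]] <- sel
        }
      }
    }
    rows[[i]] <- do.call(rbind, lapply(combos, function(sel) {
      r <- base
      if (length(sel)) {
        ord <- order(vapply(sel, `[[`, integer(1), "pos"))
        sel <- sel[ord]
        r$mod_positions <- list(vapply(sel, `[[`, integer(1), "pos"))
        r$mod_deltas <- list(vapply(sel, `[[`, numeric(1), "delta"))
        r$mods <- paste(vapply(sel, function(s)
          sprintf("%d:%s", s$pos, s$name), character(1)), collapse = ";")
      }
      r
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Search a run against a peptide library
#'
#' For each eligible spectrum (charge in `config$charges`, precursor
#' intensity >= `config$min_precursor_intensity`, precursor m/z in range)
#' the observed MH is computed as `z * m/z - (z-1) * proton`, every
#' library peptide whose theoretical MH lies within the delta window of
#' the observed MH is scored, and matches with `p <= config$max_p` are
#' returned.
#'
#' @param spectra Spectrum data frame (`id`, `precursor_mz`, `charge`,
#'   `precursor_intensity`, list-column `peaks`), e.g. from
#'   [simulate_run()], [simulate_blank()], [generate_random_spectra()] or
#'   [read_mgf()].
#' @param library A [build_peptide_library()] result.
#' @param config A [search_config()].
#' @param source Label stored in the `source` column of the output
#'   (`"experimental"`, `"blank"` or `"random"`).
#' @return A PSM data frame with columns `spectrum_id`, `sequence`,
#'   `mods`, `charge`, `observed_mh`, `theoretical_mh`, `delta_mass`,
#'   `matched`, `p_value`, `source`, `genes`, `shared`. The attribute
#'   `n_scored` counts all (spectrum, candidate) pairs evaluated.
#' @export
search_run <- function(spectra, library, config = search_config(),
                       source = "experimental") {
  stopifnot(inherits(library, "peptide_library"))
  n <- nrow(spectra)
  w <- config$delta_window
  eligible <- spectra$charge %in% config$charges &
    spectra$precursor_intensity >= config$min_precursor_intensity &
    spectra$precursor_mz > config$precursor_mz_range[1] &
    spectra$precursor_mz < config$precursor_mz_range[2]

  obs_mh <- spectra$charge * spectra$precursor_mz -
    (spectra$charge - 1) * .IE_PROTON

  # candidate index ranges over the mh-sorted library
  lo <- findInterval(obs_mh - w[2], library$mh) + 1L
  hi <- findInterval(obs_mh - w[1], library$mh)

  # pre-computed fragment ladders per library row and charge
  lad2 <- vector("list", nrow(library))
  lad3 <- vector("list", nrow(library))
  get_ladders <- function(idx, z) {
    cache <- if (z >= 3L) lad3 else lad2
    miss <- idx[vapply(cache[idx], is.null, logical(1))]
    for (u in miss) {
      cache[[u]] <- fragment_ladder(library$sequence[u], charge = z,
                                    mod_positions = library$mod_positions[[u]],
                                    mod_deltas = library$mod_deltas[[u]])
    }
    if (z >= 3L) lad3 <<- cache else lad2 <<- cache
    cache[idx]
  }

  acc <- vector("list", n)
  n_scored <- 0
  for (i in seq_len(n)) {
    if (!eligible[i] || hi[i] < lo[i]) next
    idx <- lo[i]:hi[i]
    pk <- spectra$peaks[[i]]
    if (is.null(pk) || nrow(pk) < 2L) next
    mz <- pk[, 1L]
    if (is.unsorted(mz)) mz <- sort(mz)
    span <- mz[length(mz)] - mz[1L]
    if (span <= 0) next
    z <- spectra$charge[i]
    lads <- get_ladders(idx, z)
    matched <- ie_score_spectrum(mz, lads, config$fragment_tol)
    n_scored <- n_scored + length(idx)
    trials <- lengths(lads)
    q <- min(1, length(mz) * 2 * config$fragment_tol / span)
    p <- .ie_binom_p(matched, trials, q)
    keep <- which(p <= config$max_p)
    if (!length(keep)) next
    acc[[i]] <- list(i = rep.int(i, length(keep)), lib = idx[keep],
                     matched = matched[keep], p = p[keep])
  }

  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc)) {
    out <- .ie_empty_psm(source)
    attr(out, "n_scored") <- n_scored
    return(out)
  }
  si <- unlist(lapply(acc, `[[`, "i"))
  li <- unlist(lapply(acc, `[[`, "lib"))
  out <- data.frame(
    spectrum_id = spectra$id[si],
    sequence = library$sequence[li],
    mods = library$mods[li],
    charge = spectra$charge[si],
    observed_mh = obs_mh[si],
    theoretical_mh = library$mh[li],
    delta_mass = obs_mh[si] - library$mh[li],
    matched = unlist(lapply(acc, `[[`, "matched")),
    p_value = unlist(lapply(acc, `[[`, "p")),
    source = source,
    genes = library$genes[li],
    shared = library$shared[li],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_scored") <- n_scored
  out
}

.ie_empty_psm <- function(source = character(0)) {
  data.frame(spectrum_id = character(0), sequence = character(0),
             mods = character(0), charge = integer(0),
             observed_mh = numeric(0), theoretical_mh = numeric(0),
             delta_mass = numeric(0), matched = integer(0),
             p_value = numeric(0),
             source = if (length(source)) character(0) else character(0),
             genes = character(0), shared = logical(0),
             stringsAsFactors = FALSE)
}

#' Best fit per spectrum (BFPS)
#'
#' Non-redundancy rule: each MS/MS spectrum contributes at most one
#' peptide-spectrum match, the one with the lowest p-value. Ties are
#' broken deterministically by lexicographic peptide sequence, then
#' modification string, then charge.
#'
#' @param psms A PSM data frame from [search_run()] or [read_psm_tsv()].
#' @return The PSM subset with one row per `spectrum_id`.
#' @export
bfps <- function(psms) {
  if (!nrow(psms)) return(psms)
  ord <- order(psms$spectrum_id, psms$p_value, psms$sequence,
               psms$mods, psms$charge)
  out <- psms[ord, , drop = FALSE]
  out <- out[!duplicated(out$spectrum_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
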