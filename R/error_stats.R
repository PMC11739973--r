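# Observation-frequency correction against blank and random controls,
# protein aggregation, p/q-value computation and type I/II error
# reporting across extraction treatments.

#' Tabulate peptide observation counts across sources
#'
#' Counts best-fit-per-spectrum PSMs per (sequence, charge) in the
#' experimental, blank and random sources, and records the search depth
#' (spectra searched) of each source so control counts can be scaled.
#'
#' @param experimental,blank,random PSM data frames (apply [bfps()]
#'   first). `blank` and `random` may be empty.
#' @param n_experimental,n_blank,n_random Spectra searched per source;
#'   defaults are the number of distinct spectrum ids present, but the
#'   true search depths should be supplied whenever known.
#' @return An `observation_counts` data frame with columns `sequence`,
#'   `charge`, `genes`, `shared`, `n_experimental`, `n_blank`,
#'   `n_random`, and attributes `n_spectra` (named numeric) recording the
#'   search depths.
#' @export
observation_counts <- function(experimental, blank = NULL, random = NULL,
                               n_experimental = NULL, n_blank = NULL,
                               n_random = NULL) {
  count_src <- function(psms) {
    if (is.null(psms) || !nrow(psms))
      return(stats::setNames(integer(0), character(0)))
    key <- paste(psms$sequence, psms$charge, sep = "\r")
    table(key)
  }
  ce <- count_src(experimental)
  cb <- count_src(blank)
  cr <- count_src(random)
  keys <- unique(c(names(ce), names(cb), names(cr)))
  if (!length(keys))
    stop("no PSMs supplied")
  parts <- strsplit(keys, "\r", fixed = TRUE)
  seqs <- vapply(parts, `[[`, character(1), 1L)
  chg <- as.integer(vapply(parts, `[[`, character(1), 2L))
  # gene annotation from whichever source carries the peptide
  ann <- rbind(
    if (!is.null(experimental) && nrow(experimental))
      experimental[, c("sequence", "genes", "shared")],
    if (!is.null(blank) && nrow(blank)) blank[, c("sequence", "genes", "shared")],
    if (!is.null(random) && nrow(random)) random[, c("sequence", "genes", "shared")]
  )
  ann <- ann[!duplicated(ann$sequence), , drop = FALSE]
  gi <- match(seqs, ann$sequence)
  out <- data.frame(
    sequence = seqs, charge = chg,
    genes = ann$genes[gi], shared = ann$shared[gi],
    n_experimental = as.integer(ifelse(is.na(ce[keys]), 0L, ce[keys])),
    n_blank = as.integer(ifelse(is.na(cb[keys]), 0L, cb[keys])),
    n_random = as.integer(ifelse(is.na(cr[keys]), 0L, cr[keys])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  depth <- c(
    experimental = n_experimental %||%
      length(unique(experimental$spectrum_id)),
    blank = n_blank %||%
      (if (is.null(blank)) 0 else length(unique(blank$spectrum_id))),
    random = n_random %||%
      (if (is.null(random)) 0 else length(unique(random$spectrum_id)))
  )
  attr(out, "n_spectra") <- depth
  class(out) <- c("observation_counts", "data.frame")
  out
}

#' Correct observation counts against blank and random controls
#'
#' For each peptide the expected control count is
#' `E = max(pseudo, n_blank * s_b + n_random * s_r)` where each control
#' count is scaled by the ratio of experimental to control search depth.
#' A peptide is accepted iff its experimental count exceeds E and the
#' one-cell chi-square statistic `(O - E)^2 / E` reaches `chi_min`.
#' Rejected peptides (those with control-like observation frequencies)
#' are removed before protein aggregation.
#'
#' @param counts An [observation_counts()] data frame.
#' @param chi_min Chi-square acceptance threshold, default 9.
#' @param pseudo Pseudo-count floor for E when controls are empty,
#'   default 0.5.
#' @return `counts` with added columns `expected`, `chi_sq`, `accepted`.
#' @export
correct_counts <- function(counts, chi_min = 9, pseudo = 0.5) {
  stopifnot(inherits(counts, "observation_counts"))
  depth <- attr(counts, "n_spectra")
  if (depth[["experimental"]] <= 0) stop("experimental search depth must be > 0")
  sb <- if (depth[["blank"]] > 0) depth[["experimental"]] / depth[["blank"]] else 0
  sr <- if (depth[["random"]] > 0) depth[["experimental"]] / depth[["random"]] else 0
  e_ctrl <- counts$n_blank * sb + counts$n_random * sr
  e <- pmax(pseudo, e_ctrl)
  chi <- (counts$n_experimental - e)^2 / e
  counts$expected <- e
  counts$chi_sq <- chi
  counts$accepted <- counts$n_experimental > e & chi >= chi_min
  counts
}

#' Aggregate accepted PSMs to protein summaries
#'
#' Groups (optionally correction-filtered) best-fit PSMs by gene symbol.
#' `n_observations` counts peptide observations (PSMs), and a symbol is
#' flagged when supported by three or more. The protein-level p-value is
#' the product of the best p-value of each distinct peptide, floored at
#' 1e-300, and is corrected across proteins to a Benjamini-Hochberg
#' q-value. Peptides shared across gene symbols count towards all of
#' them and are flagged; unique-peptide tallies are reported alongside.
#'
#' @param psms Best-fit PSM data frame (after [bfps()]).
#' @param accepted Optional accepted-peptide table: either a corrected
#'   [observation_counts()] data frame (its `accepted` rows are used) or
#'   a data frame with `sequence` and `charge` columns.
#' @param n_min Observation threshold for the `flagged` column, default 3.
#' @return A data frame with columns `gene`, `n_observations`,
#'   `distinct_peptides`, `n_unique_observations`,
#'   `distinct_unique_peptides`, `cumulative_p`, `q_value`, `flagged`.
#' @export
aggregate_proteins <- function(psms, accepted = NULL, n_min = 3L) {
  if (!is.null(accepted)) {
    if (inherits(accepted, "observation_counts")) {
      if (!"accepted" %in% names(accepted))
        stop("run correct_counts() before aggregation")
      accepted <- accepted[accepted$accepted, c("sequence", "charge")]
    }
    key <- paste(psms$sequence, psms$charge, sep = "\r")
    ok <- key %in% paste(accepted$sequence, accepted$charge, sep = "\r")
    psms <- psms[ok, , drop = FALSE]
  }
  if (!nrow(psms))
    return(data.frame(gene = character(0), n_observations = integer(0),
                      distinct_peptides = integer(0),
                      n_unique_observations = integer(0),
                      distinct_unique_peptides = integer(0),
                      cumulative_p = numeric(0), q_value = numeric(0),
                      flagged = logical(0)))
  glist <- strsplit(psms$genes, ";", fixed = TRUE)
  reps <- lengths(glist)
  long <- psms[rep.int(seq_len(nrow(psms)), reps), , drop = FALSE]
  long$gene <- unlist(glist)
  sp <- split(long, long$gene)
  out <- do.call(rbind, lapply(sp, function(g) {
    best <- tapply(g$p_value, g$sequence, min)
    lp <- sum(log10(best))
    data.frame(
      gene = g$gene[1L],
      n_observations = nrow(g),
      distinct_peptides = length(best),
      n_unique_observations = sum(!g$shared),
      distinct_unique_peptides = length(unique(g$sequence[!g$shared])),
      cumulative_p = max(10^lp, 1e-300),
      stringsAsFactors = FALSE
    )
  }))
  out$q_value <- bh_q(out$cumulative_p)
  out$flagged <- out$n_observations >= n_min
  out <- out[order(-out$n_observations, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative p-value of repeated peptide observations
#'
#' The product of n per-observation p-values at the geometric-mean
#' p-value, computed in log10 space: `10^(n * log10(mean_p))`. With
#' `n = 0` the empty product is 1.
#'
#' @param mean_p Geometric-mean p-value, in (0, 1].
#' @param n Number of observations (>= 0).
#' @return The cumulative p-value.
#' @examples
#' cumulative_p(0.001848, 21)   # ~4e-58
#' @export
cumulative_p <- function(mean_p, n) {
  stopifnot(all(mean_p > 0), all(mean_p <= 1), all(n >= 0))
  10^(n * log10(mean_p))
}

#' @rdname cumulative_p
#' @param p_values Explicit vector of per-observation p-values whose
#'   product is returned (log-space).
#' @export
cumulative_p_from_values <- function(p_values) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  if (!length(p_values)) return(1)
  10^sum(log10(p_values))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (cumulative minimum from the largest rank), as implemented by
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_q <- function(p_values) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Protein-level type II (false negative) error of a treatment
#'
#' @param detected_n3 Proteins at n >= 3 detected under the treatment.
#' @param benchmark_n3 Proteins at n >= 3 in the corrected benchmark
#'   (all windows, +/-0.5 Da).
#' @return Integer percent: `round(100 * (1 - detected/benchmark))`.
#' @examples
#' type2_protein(302, 2784)  # 89
#' @export
type2_protein <- function(detected_n3, benchmark_n3) {
  stopifnot(benchmark_n3 > 0)
  if (any(detected_n3 < 0) || any(detected_n3 > benchmark_n3))
    stop("detected count must lie in [0, benchmark]")
  round(100 * (1 - detected_n3 / benchmark_n3))
}

#' Peptide-level type II error of a window
#'
#' @param n_window Identifications inside the window(s).
#' @param n_total Total identifications of the peptide.
#' @return Integer percent: `round(100 * (1 - n_window/n_total))`.
#' @examples
#' type2_peptide(21, 84)  # 75
#' @export
type2_peptide <- function(n_window, n_total) {
  stopifnot(n_total > 0)
  if (any(n_window < 0) || any(n_window > n_total))
    stop("window count must lie in [0, total]")
  round(100 * (1 - n_window / n_total))
}

#' Sweep extraction treatments and report type I/II errors
#'
#' Applies each window set to the corrected best-fit PSMs and reports,
#' per treatment, the number of protein gene symbols at n >= 3 with
#' q <= `q_max`, the retained MS/MS count, the worst q-value among those
#' proteins, and the protein-level type II error relative to the
#' benchmark (all centers, +/-0.5 Da, which retains every PSM of a
#' -3..+5 search). Rows for the corrected and uncorrected full data are
#' appended.
#'
#' @param psms Best-fit PSM data frame (after [bfps()]).
#' @param accepted Accepted-peptide table from [correct_counts()] (or
#'   `NULL` to skip correction).
#' @param window_sets List of [window_set()] objects.
#' @param q_max q-value threshold for counting proteins, default 0.01.
#' @param n_min Peptide-observation threshold, default 3.
#' @return A data frame with columns `treatment`, `proteins_n3`, `fdr_q`,
#'   `msms_count`, `type2_percent`.
#' @export
treatment_sweep <- function(psms, accepted, window_sets, q_max = 0.01,
                            n_min = 3L) {
  corrected <- if (is.null(accepted)) psms else {
    acc <- if (inherits(accepted, "observation_counts"))
      accepted[accepted$accepted, c("sequence", "charge")] else accepted
    key <- paste(psms$sequence, psms$charge, sep = "\r")
    psms[key %in% paste(acc$sequence, acc$charge, sep = "\r"), ,
         drop = FALSE]
  }
  bench_ws <- window_set("all", 0.5, name = "All MS/MS corrected")
  bench <- extract_ions(corrected, bench_ws)
  count_row <- function(sub, name, benchmark_n3 = NULL) {
    agg <- aggregate_proteins(sub, accepted = NULL, n_min = n_min)
    hit <- agg$flagged & agg$q_value <= q_max
    n3 <- sum(hit)
    data.frame(
      treatment = name,
      proteins_n3 = n3,
      fdr_q = if (n3) max(agg$q_value[hit]) else NA_real_,
      msms_count = nrow(sub),
      type2_percent = if (is.null(benchmark_n3)) NA_integer_
                      else type2_protein(min(n3, benchmark_n3), benchmark_n3),
      stringsAsFactors = FALSE
    )
  }
  bench_row <- count_row(bench, "All MS/MS corrected")
  bench_n3 <- bench_row$proteins_n3
  rows <- lapply(window_sets, function(ws)
    count_row(extract_ions(corrected, ws), ws$name, bench_n3))
  bench_row$type2_percent <- type2_protein(bench_n3, max(bench_n3, 1L))
  uncorr <- count_row(psms, "All MS/MS not corrected")
  out <- rbind(do.call(rbind, rows), bench_row, uncorr)
  rownames(out) <- NULL
  out
}
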