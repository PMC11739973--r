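# File formats: FASTA protein libraries, MGF spectrum interchange and
# the package's versioned PSM TSV. All writers stamp provenance header
# comments; readers reject malformed records with line numbers.

.IE_PSM_COLUMNS <- c("spectrum_id", "sequence", "mods", "charge",
                     "observed_mh", "theoretical_mh", "delta_mass",
                     "matched", "p_value", "source", "genes", "shared")

.ie_provenance <- function(extra = character(0)) {
  v <- tryCatch(as.character(utils::packageVersion("ionextract")),
                error = function(e) "dev")
  c(sprintf("# ionextract %s", v), extra)
}

#' Read a protein FASTA file
#'
#' Accepts plain headers (first token used as accession and gene) and
#' UniProt-style headers (`>sp|P02768|ALBU_HUMAN ... GN=ALB ...`), from
#' which the accession and the `GN=` gene symbol are parsed.
#'
#' @param path FASTA file path.
#' @return Data frame with columns `accession`, `gene`, `sequence`,
#'   `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) stop("empty FASTA: ", path)
  headers <- names(ss)
  acc <- vapply(headers, function(h) {
    tok <- strsplit(h, "[ \t]")[[1]][1]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) parts[2] else tok
  }, character(1), USE.NAMES = FALSE)
  gene <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("GN=[^ ]+", h))
    if (length(m)) sub("^GN=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  gene[is.na(gene)] <- acc[is.na(gene)]
  data.frame(accession = acc, gene = gene,
             sequence = toupper(as.character(ss)),
             description = headers, stringsAsFactors = FALSE)
}

#' Write a protein FASTA file
#'
#' @param proteins Data frame with `accession`, `gene`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  ss <- Biostrings::AAStringSet(proteins$sequence)
  names(ss) <- sprintf("%s GN=%s", proteins$accession, proteins$gene)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write spectra to MGF
#'
#' @param spectra Spectrum data frame (`id`, `precursor_mz`, `charge`,
#'   `precursor_intensity`, list-column `peaks`).
#' @param path Output path.
#' @param header Extra provenance comment lines.
#' @export
write_mgf <- function(spectra, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.ie_provenance(header), con)
  for (i in seq_len(nrow(spectra))) {
    pk <- spectra$peaks[[i]]
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=%s", spectra$id[i]),
      sprintf("PEPMASS=%.6f %.4f", spectra$precursor_mz[i],
              spectra$precursor_intensity[i]),
      sprintf("CHARGE=%d+", spectra$charge[i]),
      sprintf("%.6f %.4f", pk[, 1L], pk[, 2L]),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read an MGF file
#'
#' @param path MGF file path.
#' @return Spectrum data frame shaped like `simulate_run()$spectra`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty MGF: ", path)
  ids <- character(0); mzs <- numeric(0); zs <- integer(0)
  ints <- numeric(0); peaks <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, "#") || !nzchar(trimws(ln))) { i <- i + 1L; next }
    if (ln != "BEGIN IONS")
      stop("malformed MGF at line ", i, ": expected BEGIN IONS")
    id <- NA_character_; pm <- NA_real_; pint <- 0; z <- NA_integer_
    pmz <- numeric(0); pin <- numeric(0)
    i <- i + 1L
    while (i <= n && lines[i] != "END IONS") {
      ln <- lines[i]
      if (startsWith(ln, "TITLE=")) {
        id <- sub("^TITLE=", "", ln)
      } else if (startsWith(ln, "PEPMASS=")) {
        v <- strsplit(sub("^PEPMASS=", "", ln), "[ \t]+")[[1]]
        pm <- as.numeric(v[1])
        if (length(v) > 1L) pint <- as.numeric(v[2])
        if (is.na(pm)) stop("malformed PEPMASS at line ", i)
      } else if (startsWith(ln, "CHARGE=")) {
        z <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        if (is.na(z)) stop("malformed CHARGE at line ", i)
      } else if (grepl("^[0-9]", ln)) {
        v <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
        if (length(v) < 2L || anyNA(v))
          stop("malformed peak at line ", i)
        pmz <- c(pmz, v[1]); pin <- c(pin, v[2])
      }
      i <- i + 1L
    }
    if (i > n) stop("unterminated spectrum block starting near line ", i)
    if (is.na(pm) || is.na(z))
      stop("spectrum ending at line ", i, " lacks PEPMASS or CHARGE")
    ids <- c(ids, id); mzs <- c(mzs, pm); zs <- c(zs, z)
    ints <- c(ints, pint)
    ord <- order(pmz)
    peaks[[length(peaks) + 1L]] <- cbind(mz = pmz[ord], intensity = pin[ord])
    i <- i + 1L
  }
  out <- data.frame(id = ids, precursor_mz = mzs, charge = zs,
                    precursor_intensity = ints, stringsAsFactors = FALSE)
  out$peaks <- peaks
  out
}

#' Write and read PSM TSV tables
#'
#' The TSV carries a versioned schema in its provenance header. On read,
#' the invariant `delta_mass = observed_mh - theoretical_mh` is checked
#' and violating rows are rejected with their line numbers.
#'
#' @param psms PSM data frame.
#' @param path TSV path.
#' @param header Extra provenance comment lines.
#' @param tol Tolerance for the delta-mass invariant on read, Da.
#' @export
write_psm_tsv <- function(psms, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.ie_provenance(c("# psm-schema 1", header)), con)
  out <- psms[, .IE_PSM_COLUMNS, drop = FALSE]
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path, tol = 1e-4) {
  if (!file.exists(path)) stop("PSM TSV not found: ", path)
  lines <- readLines(path)
  skip <- 0L
  while (skip < length(lines) && startsWith(lines[skip + 1L], "#"))
    skip <- skip + 1L
  if (skip >= length(lines)) stop("PSM TSV has no data: ", path)
  df <- utils::read.table(text = lines[(skip + 1L):length(lines)],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(mods = "character",
                                         genes = "character"))
  missing <- setdiff(.IE_PSM_COLUMNS, names(df))
  if (length(missing))
    stop("PSM TSV missing column(s): ", paste(missing, collapse = ", "))
  df$mods[is.na(df$mods)] <- ""
  bad <- which(abs(df$delta_mass -
                     (df$observed_mh - df$theoretical_mh)) > tol)
  if (length(bad)) {
    file_lines <- bad + skip + 1L  # +1 for the column header line
    stop("delta_mass != observed_mh - theoretical_mh at line(s): ",
         paste(utils::head(file_lines, 10L), collapse = ", "))
  }
  df
}

#' Write treatment reports
#'
#' Writes the treatment-sweep TSV (one row per extraction treatment, the
#' shape of the package's protein-count tables) and a JSON file with the
#' full per-protein detail.
#'
#' @param sweep A [treatment_sweep()] data frame.
#' @param proteins An [aggregate_proteins()] data frame.
#' @param dir Output directory (created if needed).
#' @param header Extra provenance comment lines.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(sweep, proteins, dir, header = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sweep_path <- file.path(dir, "treatment_sweep.tsv")
  con <- file(sweep_path, "w")
  writeLines(.ie_provenance(header), con)
  utils::write.table(sweep, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  prot_path <- file.path(dir, "proteins.json")
  jsonlite::write_json(proteins, prot_path, digits = NA)
  invisible(c(sweep_path, prot_path))
}
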