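# Monte-Carlo random MS/MS spectrum generator calibrated to an
# experimental run: the statistical control against which observation
# frequencies are corrected.

#' Profile an MS/MS run
#'
#' Summarises a run so that random control spectra can be generated to
#' match it: intensity-weighted mean (and sd) of the precursor protonated
#' mass, its empirical range, the empirical fragment-count distribution,
#' a fragment m/z histogram over the instrument range, the precursor
#' charge proportions and a log-normal fit of precursor intensities.
#'
#' @param spectra Spectrum data frame (>= 1 row) with `precursor_mz`,
#'   `charge`, `precursor_intensity` and list-column `peaks`.
#' @param mz_bin Fragment m/z histogram bin width, Da. Default 10.
#' @param precursor_bin Precursor mass histogram bin width, Da.
#'   Default 10.
#' @param fragment_mz_range Fragment histogram support, default
#'   (150, 2000).
#' @return A `spectrum_profile` object.
#' @export
spectrum_profile <- function(spectra, mz_bin = 10, precursor_bin = 10,
                             fragment_mz_range = c(150, 2000)) {
  if (is.null(spectra) || nrow(spectra) == 0L)
    stop("at least one spectrum is required to build a profile")
  mh <- spectra$charge * spectra$precursor_mz -
    (spectra$charge - 1) * .IE_PROTON
  w <- spectra$precursor_intensity
  if (all(w == 0)) w <- rep(1, length(w))
  mean_mh <- sum(w * mh) / sum(w)
  sd_mh <- sqrt(sum(w * (mh - mean_mh)^2) / sum(w))
  # intensity-weighted precursor mass histogram; sampling from it
  # reproduces the weighted mean and the empirical mass distribution
  pb <- seq(floor(min(mh)), ceiling(max(mh)) + precursor_bin,
            by = precursor_bin)
  pbin <- pmin(pmax(findInterval(mh, pb, rightmost.closed = TRUE), 1L),
               length(pb) - 1L)
  pw <- vapply(split(w, factor(pbin, levels = seq_len(length(pb) - 1L))),
               sum, numeric(1))
  pw <- pw / sum(pw)
  counts <- vapply(spectra$peaks, nrow, integer(1))
  all_mz <- unlist(lapply(spectra$peaks, function(p) p[, 1L]))
  all_mz <- all_mz[all_mz >= fragment_mz_range[1] &
                     all_mz <= fragment_mz_range[2]]
  breaks <- seq(fragment_mz_range[1], fragment_mz_range[2], by = mz_bin)
  if (breaks[length(breaks)] < fragment_mz_range[2])
    breaks <- c(breaks, fragment_mz_range[2])
  nbin <- length(breaks) - 1L
  bin_counts <- if (length(all_mz)) {
    tabulate(pmin(pmax(findInterval(all_mz, breaks,
                                    rightmost.closed = TRUE), 1L), nbin),
             nbins = nbin)
  } else rep(1L, nbin)
  probs <- bin_counts / sum(bin_counts)
  max_int <- max(c(1, unlist(lapply(spectra$peaks, function(p)
    if (nrow(p)) max(p[, 2L]) else NA_real_))), na.rm = TRUE)
  li <- log(pmax(spectra$precursor_intensity, 1))
  structure(
    list(precursor_mean = mean_mh, precursor_sd = max(sd_mh, 1e-9),
         precursor_min = min(mh), precursor_max = max(mh),
         precursor_breaks = pb, precursor_probs = as.numeric(pw),
         fragment_counts = as.integer(counts),
         fragment_breaks = breaks, fragment_probs = probs,
         charge_levels = as.integer(names(table(spectra$charge))),
         charge_probs = as.numeric(prop.table(table(spectra$charge))),
         intensity_meanlog = mean(li),
         intensity_sdlog = max(stats::sd(li), 1e-9),
         max_fragment_intensity = max_int,
         fragment_mz_range = fragment_mz_range),
    class = "spectrum_profile"
  )
}

#' Generate random MS/MS control spectra
#'
#' Each spectrum draws its precursor mass (from the profile's
#' intensity-weighted mass histogram, so the weighted average, range and
#' mass distribution match the experimental run), charge, fragment count
#' and fragment m/z values independently from the profile distributions;
#' every fragment lies in the profile's m/z range. Fragment intensities are uniform on (0, 1]
#' times the profile maximum (the control constrains mass structure, not
#' intensity structure).
#'
#' @param profile A [spectrum_profile()].
#' @param n Number of spectra (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A spectrum data frame shaped like `simulate_run()$spectra`,
#'   with ids `RND0000001`, ...
#' @export
generate_random_spectra <- function(profile, n, seed = 1) {
  stopifnot(inherits(profile, "spectrum_profile"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  set.seed(as.integer(seed))
  pb <- profile$precursor_breaks
  pbin <- sample.int(length(pb) - 1L, n, replace = TRUE,
                     prob = profile$precursor_probs)
  mh <- stats::runif(n, pb[pbin], pb[pbin + 1L])
  z <- if (length(profile$charge_levels) == 1L)
    rep(profile$charge_levels, n)
  else sample(profile$charge_levels, n, replace = TRUE,
              prob = profile$charge_probs)
  counts <- sample(profile$fragment_counts, n, replace = TRUE)
  counts <- pmax(counts, 2L)
  brk <- profile$fragment_breaks
  nbin <- length(brk) - 1L
  total <- sum(counts)
  bins <- sample.int(nbin, total, replace = TRUE,
                     prob = profile$fragment_probs)
  frag_mz <- stats::runif(total, brk[bins], brk[bins + 1L])
  frag_int <- stats::runif(total) * profile$max_fragment_intensity
  idx <- rep.int(seq_len(n), counts)
  peaks <- vector("list", n)
  mz_split <- split(frag_mz, idx)
  int_split <- split(frag_int, idx)
  for (i in seq_len(n)) {
    ord <- order(mz_split[[i]])
    peaks[[i]] <- cbind(mz = mz_split[[i]][ord],
                        intensity = int_split[[i]][ord])
  }
  out <- data.frame(
    id = sprintf("RND%07d", seq_len(n)),
    precursor_mz = (mh + (z - 1) * .IE_PROTON) / z,
    charge = z,
    precursor_intensity = stats::rlnorm(n, profile$intensity_meanlog,
                                        profile$intensity_sdlog),
    stringsAsFactors = FALSE
  )
  out$peaks <- peaks
  out
}

#' Serialize or restore a spectrum profile
#'
#' @param profile A `spectrum_profile`.
#' @param path JSON file path.
#' @return `read_profile_json()` returns a `spectrum_profile`.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "spectrum_profile"))
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$fragment_counts <- as.integer(x$fragment_counts)
  x$charge_levels <- as.integer(x$charge_levels)
  structure(x, class = "spectrum_profile")
}
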