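# Delta-mass analysis: Gaussian kernel density estimation of precursor
# delta masses, topographic detection of the integer peaks from heavy
# isotopes and hydrogen loss, and selected-ion extraction under window
# sets.

#' Precursor delta mass
#'
#' @param observed_mh,theoretical_mh Protonated masses, Da (> 0).
#' @return `observed_mh - theoretical_mh`, Da.
#' @export
delta_mass <- function(observed_mh, theoretical_mh) {
  if (any(observed_mh <= 0) || any(theoretical_mh <= 0))
    stop("masses must be positive")
  observed_mh - theoretical_mh
}

#' Delta-mass window set
#'
#' Integer extraction centers with a common tolerance. The predefined
#' treatments are `"mono"` (center 0 only) and `"all"` (-3 .. +5).
#'
#' @param centers `"mono"`, `"all"`, or a numeric subset of -3..+5.
#' @param tolerance Half-width of each window, Da (> 0).
#' @param name Optional treatment label.
#' @return A `window_set` list with `centers`, `tolerance`, `name`.
#' @export
window_set <- function(centers = "all", tolerance = 0.1, name = NULL) {
  if (is.character(centers)) {
    centers <- switch(match.arg(centers, c("mono", "all")),
                      mono = 0L, all = -3L:5L)
  }
  centers <- sort(unique(as.integer(centers)))
  if (!all(centers %in% -3L:5L))
    stop("centers must lie in -3 .. +5")
  if (!(tolerance > 0)) stop("tolerance must be positive")
  if (is.null(name)) {
    lab <- if (identical(centers, 0L)) "Monoisotopic"
           else if (identical(centers, -3L:5L)) "Hydrogen and Isotopes"
           else paste(centers, collapse = ",")
    name <- sprintf("%s ±%g Da", lab, tolerance)
  }
  structure(list(centers = centers, tolerance = tolerance, name = name),
            class = "window_set")
}

#' Gaussian kernel density of delta masses
#'
#' Kernel density estimate on a uniform grid over (-3.5, +5.5) Da with
#' the Gaussian kernel and, by default, Silverman's rule-of-thumb
#' bandwidth (the default of R's `density()`). The profile is
#' renormalised so its trapezoidal integral over the grid is one.
#'
#' @param deltas Numeric vector of delta masses (>= 2 values).
#' @param bandwidth Optional kernel bandwidth in Da; default
#'   `stats::bw.nrd0(deltas)`.
#' @param from,to Grid limits, Da.
#' @param spacing Grid spacing, Da. Default 0.005.
#' @return A `density_profile`: list with `grid`, `density`, `bandwidth`.
#' @export
density_profile <- function(deltas, bandwidth = NULL, from = -3.5,
                            to = 5.5, spacing = 0.005) {
  if (length(deltas) < 2L) stop("at least two delta-mass values required")
  bw <- bandwidth %||% stats::bw.nrd0(deltas)
  npt <- round((to - from) / spacing) + 1L
  d <- stats::density(deltas, bw = bw, kernel = "gaussian",
                      from = from, to = to, n = npt)
  area <- .ie_trapz(d$x, d$y)
  structure(list(grid = d$x, density = d$y / area, bandwidth = d$bw),
            class = "density_profile")
}

.ie_trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Detect integer delta-mass peaks
#'
#' Finds local maxima of a density profile lying within +/-0.25 Da of the
#' integer candidates -3..+5 and retains those whose topographic
#' prominence (height above the highest saddle separating the peak from
#' taller terrain) is at least `prominence_frac` times the global maximum
#' density. A flat (structureless) profile therefore yields no peaks.
#'
#' @param profile A [density_profile()].
#' @param prominence_frac Fraction of the global maximum density required
#'   as prominence. Default 0.01, low enough to resolve satellite
#'   components down to roughly one percent of the modal peak while
#'   rejecting kernel-estimate wiggles.
#' @return Data frame with columns `center` (integer Da), `position`
#'   (grid location of the maximum, Da) and `height`.
#' @export
detect_integer_peaks <- function(profile, prominence_frac = 0.01) {
  stopifnot(inherits(profile, "density_profile"))
  y <- profile$density
  x <- profile$grid
  n <- length(y)
  mid <- 2:(n - 1L)
  is_max <- mid[y[mid] > y[mid - 1L] & y[mid] >= y[mid + 1L]]
  # topographic prominence of each local maximum
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1L)]
    right <- y[seq((i + 1L), n)]
    saddle <- -Inf
    hl <- which(left >= h)
    sl <- if (length(hl)) min(y[(max(hl)):(i - 1L)]) else -Inf
    hr <- which(right >= h)
    sr <- if (length(hr)) min(y[(i + 1L):(i + min(hr))]) else -Inf
    saddle <- max(sl, sr)
    if (!is.finite(saddle)) h else h - saddle
  }, numeric(1))
  gmax <- max(y)
  keep <- is_max[prom >= prominence_frac * gmax]
  if (!length(keep))
    return(data.frame(center = integer(0), position = numeric(0),
                      height = numeric(0)))
  cand <- round(x[keep])
  ok <- abs(x[keep] - cand) <= 0.25 & cand >= -3 & cand <= 5
  keep <- keep[ok]; cand <- cand[ok]
  if (!length(keep))
    return(data.frame(center = integer(0), position = numeric(0),
                      height = numeric(0)))
  out <- data.frame(center = as.integer(cand), position = x[keep],
                    height = y[keep])
  # tallest maximum per integer
  out <- out[order(out$center, -out$height), , drop = FALSE]
  out <- out[!duplicated(out$center), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Selected-ion extraction of PSMs
#'
#' Retains PSMs whose delta mass lies within `tolerance` of at least one
#' window center (closed intervals). Apply [bfps()] first so counts are
#' per-spectrum non-redundant.
#'
#' @param psms PSM data frame with a `delta_mass` column.
#' @param windows A [window_set()].
#' @return The retained PSM subset.
#' @export
extract_ions <- function(psms, windows) {
  stopifnot(inherits(windows, "window_set"))
  if (windows$tolerance > 0.5)
    message("window tolerance ", windows$tolerance,
            " Da > 0.5 Da: adjacent integer windows overlap")
  if (!nrow(psms)) return(psms)
  d <- psms$delta_mass
  dist <- do.call(pmin, lapply(windows$centers, function(cc) abs(d - cc)))
  out <- psms[dist <= windows$tolerance, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window delta-mass residual summary
#'
#' For each window center, the mean and standard deviation of the
#' residual `delta_mass - center` among retained PSMs: a compact report
#' of the per-Dalton scatter of precursor errors.
#'
#' @inheritParams extract_ions
#' @return Data frame with `center`, `n`, `mean_residual`, `sd_residual`.
#' @export
window_residual_summary <- function(psms, windows) {
  stopifnot(inherits(windows, "window_set"))
  do.call(rbind, lapply(windows$centers, function(cc) {
    r <- psms$delta_mass - cc
    r <- r[abs(r) <= windows$tolerance]
    data.frame(center = cc, n = length(r),
               mean_residual = if (length(r)) mean(r) else NA_real_,
               sd_residual = if (length(r) > 1L) stats::sd(r) else NA_real_)
  }))
}
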