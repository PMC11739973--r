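# Physical constants and residue tables used throughout the package.
# Atomic masses are lightest-isotope (monoisotopic) values; isotope
# abundances are IUPAC representative terrestrial values.

# Monoisotopic atomic masses, Da
.IE_ATOMS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Proton mass used for MH and m/z arithmetic, Da
.IE_PROTON <- 1.007276

# One water, Da (2 H + O)
.IE_WATER <- 2 * .IE_ATOMS[["H"]] + .IE_ATOMS[["O"]]

# Nominal-mass isotope abundance vectors per element, indexed by mass shift
# starting at 0 (e.g. S has isotopes at +0, +1, +2 and +4 Da).
.IE_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
)

# Elemental composition (C, H, N, O, S) of the 20 standard amino-acid
# residues (i.e. amino acid minus one water).
.IE_RESIDUE_COMP <- matrix(
  c(
    # C  H  N  O  S
    3,  5, 1, 1, 0,  # A
    6, 12, 4, 1, 0,  # R
    4,  6, 2, 2, 0,  # N
    4,  5, 1, 3, 0,  # D
    3,  5, 1, 1, 1,  # C
    5,  8, 2, 2, 0,  # Q
    5,  7, 1, 3, 0,  # E
    2,  3, 1, 1, 0,  # G
    6,  7, 3, 1, 0,  # H
    6, 11, 1, 1, 0,  # I
    6, 11, 1, 1, 0,  # L
    6, 12, 2, 1, 0,  # K
    5,  9, 1, 1, 1,  # M
    9,  9, 1, 1, 0,  # F
    5,  7, 1, 1, 0,  # P
    3,  5, 1, 2, 0,  # S
    4,  7, 1, 2, 0,  # T
    11, 10, 2, 1, 0, # W
    9,  9, 1, 2, 0,  # Y
    5,  9, 1, 1, 0   # V
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    c("C", "H", "N", "O", "S")
  )
)

# Monoisotopic residue masses, Da
.IE_RESIDUE_MASS <- drop(.IE_RESIDUE_COMP %*% .IE_ATOMS)

# Average residue frequencies of human proteins, used when generating
# synthetic protein sequences (normalised at load time).
.IE_AA_FREQ <- local({
  f <- c(
    A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
    G = 6.6, H = 2.6, I = 4.3, L = 9.9, K = 5.7, M = 2.1, F = 3.7,
    P = 6.3, S = 8.3, T = 5.3, W = 1.2, Y = 2.7, V = 6.0
  )
  f / sum(f)
})

# Averagine-like mean elemental composition of peptides, atoms per Dalton.
.IE_AVERAGINE <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773,
                   S = 0.0417) / 111.1254

#' Proton mass used by the package
#'
#' Monoisotopic proton mass (Da) used to convert between neutral mass,
#' protonated mass (MH) and m/z.
#'
#' @return A length-one numeric, 1.007276 Da.
#' @export
proton_mass <- function() .IE_PROTON
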