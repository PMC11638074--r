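# Physical constants for intact-protein mass computation.
#
# Residue (i.e. water-free amino-acid) masses in Da; `average` uses IUPAC
# standard atomic weights, `mono` the principal-isotope masses. Nitrogen
# counts per residue include the backbone amide nitrogen, so a protein's
# nitrogen total is the sum over its residue composition.

AA_MASS_AVG <- c(
  G = 57.05140, A = 71.07802, S = 87.07742, P = 97.11537, V = 99.13125,
  T = 101.10404, C = 103.14281, L = 113.15787, I = 113.15787, N = 114.10280,
  D = 115.08757, Q = 128.12942, K = 128.17252, E = 129.11418, M = 131.19604,
  H = 137.13952, F = 147.17420, R = 156.18592, Y = 163.17360, W = 186.21031
)

AA_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00918, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04048,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# nitrogen atoms per residue (backbone + side chain)
AA_NITROGEN <- c(
  G = 1L, A = 1L, S = 1L, P = 1L, V = 1L, T = 1L, C = 1L, L = 1L, I = 1L,
  N = 2L, D = 1L, Q = 2L, K = 2L, E = 1L, M = 1L, H = 3L, F = 1L, R = 4L,
  Y = 1L, W = 2L
)

MASS_WATER_AVG <- 18.01529
MASS_WATER_MONO <- 18.01056
MASS_PROTON <- 1.00728

# Uniform 15N labelling: mass added per nitrogen atom. In average mode the
# baseline is the natural-abundance average atomic weight of nitrogen; in
# monoisotopic mode it is the 14N mass.
N15_SHIFT_AVG <- 15.0001089 - 14.0067
N15_SHIFT_MONO <- 15.0001089 - 14.0030740

#' Canonical human ubiquitin sequence
#'
#' The 76-residue sequence (UniProt P0CG48 monomer). Lysines sit at
#' positions 6, 11, 27, 29, 33, 48 and 63; the C-terminal G76 forms the
#' isopeptide bond of a distal moiety.
#'
#' @format Character scalar (one-letter codes).
#' @export
UB_SEQUENCE <- paste0(
  "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYNIQKESTLHLVLRLRGG"
)

# residue sequences of supported appended tags
UB_TAG_SEQUENCES <- c(AVI = "GLNDIFEAQKIEWHE")

#' Empirical m/z of the uniformly 15N-labelled ubiquitin calibrant
#'
#' The singly protonated position at which the heavy-ubiquitin internal
#' standard is observed and to which spectra are internally calibrated
#' (8,669.470 m/z). The computed average \[M+H\]+ of uniform-15N ubiquitin
#' is ~0.6 Da higher; the calibrant value is the instrument-calibrated
#' convention and the pipeline treats it as the reference.
#'
#' @format Numeric scalar (m/z).
#' @export
UB15N_CALIBRANT_MZ <- 8669.470
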