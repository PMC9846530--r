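# Amino-acid code tables and embedded chemical-shift reference data.

#: one-letter <-> three-letter residue code maps (20 standard amino acids)
AA_131 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_113 <- stats::setNames(names(AA_131), AA_131)

#' Convert residue codes between one- and three-letter forms
#'
#' @param x character vector of residue codes (three-letter codes are
#'   case-insensitive).
#' @return character vector of the converted codes; unknown codes give `NA`.
#' @examples
#' aa_three_to_one(c("ALA", "Gly"))
#' aa_one_to_three("P")
#' @export
aa_three_to_one <- function(x) unname(AA_131[toupper(x)])

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) unname(AA_113[toupper(x)])

# Backbone random-coil chemical shifts (ppm) per residue type, used as the
# deterministic baseline by the synthetic generator. Values are near the
# standard empirical random-coil tables; absolute levels are immaterial
# downstream because every statistic in the pipeline is a difference.
RANDOM_COIL <- data.frame(
  residue_type = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  H  = c(8.24, 8.23, 8.40, 8.34, 8.32, 8.32, 8.42, 8.33, 8.42, 8.00,
         8.16, 8.29, 8.28, 8.30, NA,   8.31, 8.15, 8.25, 8.28, 8.03),
  N  = c(123.8, 120.5, 118.7, 120.4, 118.8, 119.8, 120.2, 108.8, 118.2, 119.9,
         121.8, 120.4, 119.6, 120.3, NA,    115.7, 113.6, 121.3, 120.3, 119.2),
  CA = c(52.5, 56.0, 53.1, 54.2, 58.2, 55.7, 56.6, 45.1, 55.0, 61.1,
         55.1, 56.2, 55.4, 57.7, 63.3, 58.3, 61.8, 57.5, 57.9, 62.2),
  CB = c(19.1, 30.9, 38.9, 41.1, 28.0, 29.4, 29.9, NA,   29.0, 38.8,
         42.4, 33.1, 32.9, 39.6, 32.1, 63.8, 69.8, 29.6, 38.8, 32.9),
  C  = c(177.8, 176.3, 175.2, 176.3, 174.6, 176.0, 176.6, 174.9, 174.1, 176.4,
         177.6, 176.6, 176.3, 175.8, 177.3, 174.6, 174.7, 176.1, 175.9, 176.3),
  stringsAsFactors = FALSE
)

# Secondary-shift offsets (ppm) applied inside helical segments by the
# synthetic generator; signs follow the usual helix secondary-shift pattern
# (CA/CO downfield, HN/N/CB upfield).
HELIX_OFFSETS <- c(H = -0.25, N = -1.5, CA = 2.8, CB = -0.5, C = 1.8)

# Nuclei the pipeline recognizes; carbonyl carbon is stored as "C"
# (readers also accept the label "CO").
NUCLEI <- c("H", "N", "CA", "CB", "C")

#' Histone H3 sequence
#'
#' The 135-residue Xenopus laevis histone H3 sequence (H3.2-type, Ser96),
#' numbered 1-135. Residues ~44-132 form the structured core domain; the
#' prolines at 66 and 121 are the only prolines in that range.
#'
#' @return single one-letter amino-acid string of length 135.
#' @examples
#' nchar(h3_sequence())
#' @export
h3_sequence <- function() {
  paste0(
    "ARTKQTARKSTGGKAPRKQLATKAARKSAP",
    "ATGGVKKPHRYRPGTVALREIRRYQKSTEL",
    "LIRKLPFQRLVREIAQDFKTDLRFQSSAVM",
    "ALQEASEAYLVGLFEDTNLCAIHAKRVTIM",
    "PKDIQLARRIRGERA"
  )
}
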