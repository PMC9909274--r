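#' @include AllClasses.R
NULL

## Fixed alphabet: the 20 canonical amino acids in alphabetical
## one-letter order. All alphabet-indexed features (rows of the chain
## matrix) use this order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GEOM_PROPERTIES <- c("ASA", "RASA", "ECA", "ICA", "EVA")

PHYSCHEM_PROPERTIES <- c("hydrophobicity", "polarizability", "polarity",
                         "secondary_structure", "codon_diversity")

## canonical three-letter -> one-letter map; anything else becomes "X"
AA_321 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

#' The amino-acid alphabet used by the package
#'
#' @return The 20 canonical one-letter amino-acid codes in alphabetical
#'   order; this fixed order indexes the rows of all chain matrices.
#' @export
aminoAcidAlphabet <- function() AA_ALPHABET

## circular sequence index: position j shifted by `by` on a length-L
## cycle (head-to-tail connection), 1-based
circIndex <- function(j, by, L) ((j - 1L + by) %% L) + 1L

#' Names of the six unordered chain pairs
#'
#' @param ids character vector of four chain identifiers.
#' @return Character vector of six pair names in fixed order 1-2, 1-3,
#'   1-4, 2-3, 2-4, 3-4 (e.g. `"A:B"`), the order in which per-complex
#'   samples and NPIRP components are reported.
#' @export
chainPairNames <- function(ids) {
  stopifnot(length(ids) == 4L)
  idx <- chainPairIndex()
  paste(ids[idx[, 1L]], ids[idx[, 2L]], sep = ":")
}

## 6 x 2 matrix of chain positions forming the unordered pairs
chainPairIndex <- function() {
  cbind(c(1L, 1L, 1L, 2L, 2L, 3L), c(2L, 3L, 4L, 3L, 4L, 4L))
}

## squared-distance matrix between two coordinate sets (n x 3, m x 3)
crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
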