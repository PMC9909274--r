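#' @include utils.R
NULL

#' Default physicochemical scale table
#'
#' A ready-to-use 20 x 5 table of the five amino-acid physicochemical
#' properties consumed by the sequence descriptors: hydrophobicity
#' (Kyte-Doolittle hydropathy), polarizability (Charton-Charton),
#' polarity (Grantham), secondary-structure propensity (Chou-Fasman
#' helix propensity) and codon diversity (number of synonymous codons).
#' These are standard published scales; any other table can be supplied
#' via [readPhyschemTable()] or [PhyschemTable()] — every descriptor is
#' computed relative to whatever table is passed in.
#'
#' @return A [PhyschemTable-class] object.
#' @examples
#' featureMatrix(defaultPhyschemTable())["A", ]
#' @export
defaultPhyschemTable <- function() {
  values <- matrix(c(
    ## hydropathy, polarizability, polarity, helix propensity, codons
     1.8, 0.046,  8.1, 1.42, 4,   # A
     2.5, 0.128,  5.5, 0.70, 2,   # C
    -3.5, 0.105, 13.0, 1.01, 2,   # D
    -3.5, 0.151, 12.3, 1.51, 2,   # E
     2.8, 0.290,  5.2, 1.13, 2,   # F
    -0.4, 0.000,  9.0, 0.57, 4,   # G
    -3.2, 0.230, 10.4, 1.00, 2,   # H
     4.5, 0.186,  5.2, 1.08, 3,   # I
    -3.9, 0.219, 11.3, 1.16, 2,   # K
     3.8, 0.186,  4.9, 1.21, 6,   # L
     1.9, 0.221,  5.7, 1.45, 1,   # M
    -3.5, 0.134, 11.6, 0.67, 2,   # N
    -1.6, 0.131,  8.0, 0.57, 4,   # P
    -3.5, 0.180, 10.5, 1.11, 2,   # Q
    -4.5, 0.291, 10.5, 0.98, 6,   # R
    -0.8, 0.062,  9.2, 0.77, 6,   # S
    -0.7, 0.108,  8.6, 0.83, 4,   # T
     4.2, 0.140,  5.9, 1.06, 4,   # V
    -0.9, 0.409,  5.4, 1.08, 1,   # W
    -1.3, 0.298,  6.2, 0.69, 2),  # Y
    nrow = 20, byrow = TRUE,
    dimnames = list(AA_ALPHABET, PHYSCHEM_PROPERTIES))
  PhyschemTable(values)
}

## maximum ASA per residue type (A^2, theoretical tripeptide values),
## used only by the synthetic generator to derive RASA from ASA
MAX_ASA <- c(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104,
             H = 224, I = 197, K = 236, L = 201, M = 224, N = 195,
             P = 159, Q = 225, R = 274, S = 155, T = 172, V = 174,
             W = 285, Y = 263, X = 200)
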