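#' @include structures-io.R
NULL

## names of the 24 per-amino-acid chain-matrix columns: four position
## statistics, then mean/min/max/ratio for each of the five geometric
## properties
chainMatrixColnames <- function() {
  c("F", "A", "B", "M",
    as.vector(vapply(GEOM_PROPERTIES, function(p)
      paste0(c("A_", "B_", "M_", "R_"), p), character(4))))
}

#' Map a chain to its five geometric number sequences
#'
#' Returns, for each geometric property, the per-residue value sequence
#' aligned with the chain (identity mapping from the profile columns).
#'
#' @param chain a [ChainRecord-class].
#' @param profile the aligned [GeometricProfile-class].
#' @return Named list of five numeric vectors (`ASA`, `RASA`, `ECA`,
#'   `ICA`, `EVA`), each of length L.
#' @export
numberSequences <- function(chain, profile) {
  vals <- profileValues(profile)
  if (nrow(vals) != nchar(chainSeq(chain)))
    stop("profile rows do not match chain length")
  lapply(stats::setNames(GEOM_PROPERTIES, GEOM_PROPERTIES),
         function(p) unname(vals[, p]))
}

#' Same-type amino-acid change sequences
#'
#' For one amino-acid letter `x` occurring n times in the chain at
#' 1-based positions a_1 < ... < a_n, the position change sequence is
#' the successive differences a_{t+1} - a_t (length n-1); each geometry
#' change sequence is the successive differences of the property values
#' at those positions. Degenerate cases: for n = 1 the single value is
#' the occurrence position (or property value) minus the chain mean of
#' all positions 1..L (or of the whole property sequence); for n = 0 the
#' sequence is the single value 0.
#'
#' @param chain a [ChainRecord-class].
#' @param profile the aligned [GeometricProfile-class].
#' @param x single amino-acid letter from [aminoAcidAlphabet()].
#' @return List with elements `positions` (the a_t), `n` (occurrence
#'   count), `f` (position change sequence) and `fGeom` (named list of
#'   the five geometry change sequences).
#' @examples
#' ch <- ChainRecord("A", "ACAGAHHAALKAYAW", matrix(0, 15, 3))
#' asa <- c(6, 4, 7, 5, 7, 8, 2, 8, 9, 3, 7, 11, 10, 14, 15)
#' prof <- GeometricProfile("A", matrix(rep(asa, 5), ncol = 5,
#'   dimnames = list(NULL, c("ASA", "RASA", "ECA", "ICA", "EVA"))))
#' changeSequences(ch, prof, "A")$f   # 2 2 3 1 3 2
#' @export
changeSequences <- function(chain, profile, x) {
  if (!x %in% AA_ALPHABET)
    stop("x must be one of the 20 canonical amino-acid letters")
  seqChars <- strsplit(chainSeq(chain), "")[[1]]
  L <- length(seqChars)
  vals <- profileValues(profile)
  if (nrow(vals) != L) stop("profile rows do not match chain length")
  pos <- which(seqChars == x)
  n <- length(pos)
  if (n > 1L) {
    f <- diff(pos)
    fGeom <- lapply(stats::setNames(GEOM_PROPERTIES, GEOM_PROPERTIES),
                    function(p) diff(vals[pos, p]))
  } else if (n == 1L) {
    f <- pos - mean(seq_len(L))
    fGeom <- lapply(stats::setNames(GEOM_PROPERTIES, GEOM_PROPERTIES),
                    function(p) vals[pos, p] - mean(vals[, p]))
  } else {
    f <- 0
    fGeom <- lapply(stats::setNames(GEOM_PROPERTIES, GEOM_PROPERTIES),
                    function(p) 0)
  }
  list(letter = x, positions = pos, n = n, f = as.numeric(f),
       fGeom = lapply(fGeom, as.numeric))
}

#' Position statistics of a change sequence
#'
#' The four statistics of the position change sequence: frequency
#' F = n / L, arithmetic mean A (sum of the change sequence divided by
#' the occurrence count n; the single value itself for n = 1), minimum B
#' and maximum M (both 0 for n = 0).
#'
#' @param cs result of [changeSequences()].
#' @param L chain length.
#' @return Named numeric vector `c(F, A, B, M)`.
#' @export
positionStats <- function(cs, L) {
  n <- cs$n
  if (n == 0L) return(c(F = 0, A = 0, B = 0, M = 0))
  A <- if (n == 1L) cs$f[1L] else sum(cs$f) / n
  c(F = n / L, A = A, B = min(cs$f), M = max(cs$f))
}

#' Geometry statistics of a change sequence
#'
#' Mean A^i (sum of the geometry change sequence divided by the
#' occurrence count n), minimum B^i, maximum M^i, and the ratio
#' R^i = A^i / A of the geometry mean to the position mean (0 when
#' A = 0 or n = 0).
#'
#' @param cs result of [changeSequences()].
#' @param property one of `ASA`, `RASA`, `ECA`, `ICA`, `EVA` (or its
#'   1..5 index).
#' @return Named numeric vector `c(A, B, M, R)`.
#' @export
geometryStats <- function(cs, property) {
  if (is.numeric(property)) property <- GEOM_PROPERTIES[property]
  fg <- cs$fGeom[[property]]
  n <- cs$n
  if (n == 0L) return(c(A = 0, B = 0, M = 0, R = 0))
  A <- sum(fg) / n
  Apos <- if (n == 1L) cs$f[1L] else sum(cs$f) / n
  R <- if (Apos == 0) 0 else A / Apos
  c(A = A, B = min(fg), M = max(fg), R = R)
}

#' Chain matrix Q: 20 amino acids x 24 change-sequence statistics
#'
#' Builds the 20 x 24 matrix describing one chain: one row per
#' amino-acid letter (alphabetical, see [aminoAcidAlphabet()]), columns
#' `F, A, B, M` followed, for each geometric property, by
#' `A_p, B_p, M_p, R_p`. Rows of letters absent from the chain are all
#' zero.
#'
#' @param chain a [ChainRecord-class].
#' @param profile the aligned [GeometricProfile-class].
#' @return Numeric 20 x 24 matrix with amino-acid row names.
#' @export
chainMatrix <- function(chain, profile) {
  L <- nchar(chainSeq(chain))
  Q <- matrix(0, 20L, 24L,
              dimnames = list(AA_ALPHABET, chainMatrixColnames()))
  for (x in AA_ALPHABET) {
    cs <- changeSequences(chain, profile, x)
    if (cs$n == 0L) next
    row <- positionStats(cs, L)
    for (p in GEOM_PROPERTIES) row <- c(row, geometryStats(cs, p))
    Q[x, ] <- row
  }
  Q
}

#' Standardised chain-pair feature map
#'
#' The sample matrix of a chain pair is the element-wise absolute
#' difference of the two chain matrices, standardised over all 480
#' entries to zero mean and unit population standard deviation. A
#' constant difference matrix (sigma = 0) standardises to all zeros.
#' The map is symmetric in the two chains.
#'
#' @param qa,qb 20 x 24 chain matrices from [chainMatrix()].
#' @param complexId,chainPair,label optional sample metadata.
#' @param standardize set `FALSE` to keep the raw absolute-difference
#'   matrix.
#' @return A [FeatureMap-class] object.
#' @export
pairFeatureMap <- function(qa, qb, complexId = NA_character_,
                           chainPair = NA_character_, label = NA_integer_,
                           standardize = TRUE) {
  stopifnot(all(dim(qa) == c(20L, 24L)), all(dim(qb) == c(20L, 24L)))
  s <- abs(qa - qb)
  if (standardize) {
    mu <- mean(s)
    sigma <- sqrt(mean((s - mu)^2))   # population sigma over 480 entries
    s <- if (sigma > 0) (s - mu) / sigma else s * 0
  }
  new("FeatureMap", map = unname(s), complexId = as.character(complexId),
      chainPair = as.character(chainPair), label = as.integer(label))
}

#' Feature maps for all six chain pairs of a complex
#'
#' @param complex a [TetramerComplex-class].
#' @param profiles named list of four [GeometricProfile-class] objects
#'   (names = chain ids).
#' @param labels optional [InterfaceLabels-class]; when given, each map
#'   carries its interaction label.
#' @return Named list of six [FeatureMap-class] objects in fixed pair
#'   order.
#' @examples
#' sim <- simulateComplex(simulationConfig(seed = 5))
#' maps <- complexFeatureMaps(sim$complex, sim$profiles, sim$labels)
#' vapply(maps, sampleLabel, integer(1))
#' @export
complexFeatureMaps <- function(complex, profiles, labels = NULL) {
  ids <- chainIds(complex)
  qs <- lapply(ids, function(cid)
    chainMatrix(chains(complex)[[cid]], profiles[[cid]]))
  names(qs) <- ids
  idx <- chainPairIndex()
  pn <- chainPairNames(ids)
  flags <- if (is.null(labels)) rep(NA_integer_, 6L) else
    as.integer(interacting(labels))
  maps <- lapply(seq_len(6L), function(z)
    pairFeatureMap(qs[[idx[z, 1L]]], qs[[idx[z, 2L]]],
                   complexId = complex@complexId, chainPair = pn[z],
                   label = flags[z]))
  stats::setNames(maps, pn)
}
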