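#' @include AllGenerics.R
NULL

## Central data containers. All residue indexing inside the package is
## 1-based sequential over the retained residues of a chain; author
## numbering is kept alongside for reporting only.

#' Single protein chain (C-alpha representation)
#'
#' Holds one chain of a tetramer: its one-letter sequence, the C-alpha
#' coordinates and the author residue numbering. Residues whose
#' three-letter name falls outside the canonical 20 are stored as `X`;
#' they keep their position (and coordinates) but contribute nothing to
#' alphabet-indexed features.
#'
#' @slot chainId single-character chain identifier.
#' @slot sequence one-letter amino-acid string of length L.
#' @slot caCoords numeric L x 3 coordinate matrix (Angstrom).
#' @slot residueIds integer vector of author residue numbers (length L).
#'
#' @seealso [ChainRecord()] for the user constructor.
#' @export
setClass("ChainRecord",
  representation(chainId = "character", sequence = "character",
                 caCoords = "matrix", residueIds = "integer"))

setValidity("ChainRecord", function(object) {
  L <- nchar(object@sequence)
  msg <- character()
  if (length(object@chainId) != 1L || !nzchar(object@chainId))
    msg <- c(msg, "chainId must be a single non-empty string")
  if (length(object@sequence) != 1L)
    msg <- c(msg, "sequence must be a single string")
  if (nrow(object@caCoords) != L)
    msg <- c(msg, sprintf("coordinate rows (%d) != sequence length (%d)",
                          nrow(object@caCoords), L))
  if (ncol(object@caCoords) != 3L)
    msg <- c(msg, "caCoords must have 3 columns")
  if (length(object@residueIds) != L)
    msg <- c(msg, "residueIds length != sequence length")
  bad <- setdiff(strsplit(object@sequence, "")[[1]], c(AA_ALPHABET, "X"))
  if (length(bad))
    msg <- c(msg, paste0("sequence letters outside alphabet: ",
                         paste(unique(bad), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a ChainRecord
#'
#' @param chainId single-character chain identifier.
#' @param sequence one-letter amino-acid string.
#' @param caCoords numeric L x 3 matrix of C-alpha coordinates (Angstrom).
#' @param residueIds optional integer author numbering; defaults to `1:L`.
#' @return A [ChainRecord-class] object. Chains shorter than 20 or longer
#'   than 500 residues trigger a warning (the method targets that range)
#'   but are accepted.
#' @examples
#' ch <- ChainRecord("A", "ACDEFGHIKLMNPQRSTVWY",
#'                   matrix(rnorm(60), ncol = 3))
#' chainSeq(ch)
#' @export
ChainRecord <- function(chainId, sequence, caCoords,
                        residueIds = seq_len(nchar(sequence))) {
  caCoords <- as.matrix(caCoords)
  storage.mode(caCoords) <- "double"
  L <- nchar(sequence)
  if (L < 20L || L > 500L)
    warning(sprintf("chain %s has %d residues; the method targets 20-500",
                    chainId, L))
  new("ChainRecord", chainId = as.character(chainId),
      sequence = toupper(sequence), caCoords = caCoords,
      residueIds = as.integer(residueIds))
}

#' Four-chain protein complex
#'
#' @slot complexId PDB-style identifier of the complex.
#' @slot chains named list of exactly four [ChainRecord-class] objects
#'   with unique chain identifiers; yields exactly six unordered chain
#'   pairs.
#' @export
setClass("TetramerComplex",
  representation(complexId = "character", chains = "list"))

setValidity("TetramerComplex", function(object) {
  msg <- character()
  if (length(object@chains) != 4L)
    msg <- c(msg, sprintf("complex must have 4 chains, got %d",
                          length(object@chains)))
  if (!all(vapply(object@chains, is, logical(1), "ChainRecord")))
    msg <- c(msg, "all chains must be ChainRecord objects")
  else {
    ids <- vapply(object@chains, function(ch) ch@chainId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "chain ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TetramerComplex
#'
#' @param complexId identifier for the complex.
#' @param chains list of four [ChainRecord-class] objects.
#' @return A [TetramerComplex-class] object.
#' @export
TetramerComplex <- function(complexId, chains) {
  names(chains) <- vapply(chains, function(ch) ch@chainId, character(1))
  new("TetramerComplex", complexId = as.character(complexId),
      chains = chains)
}

#' Per-residue geometric property profile
#'
#' Five per-residue geometric properties for one chain: accessible
#' surface area (ASA, A^2), relative ASA (fraction), exterior contact
#' area (ECA), interior contact area (ICA) and exterior void area
#' (EVA, A^2). Rows are aligned with the chain's retained residues.
#'
#' @slot chainId chain identifier the profile belongs to.
#' @slot values numeric L x 5 matrix, columns `ASA, RASA, ECA, ICA, EVA`.
#' @export
setClass("GeometricProfile",
  representation(chainId = "character", values = "matrix"))

setValidity("GeometricProfile", function(object) {
  msg <- character()
  if (!identical(colnames(object@values), GEOM_PROPERTIES))
    msg <- c(msg, paste0("columns must be ",
                         paste(GEOM_PROPERTIES, collapse = ", ")))
  else {
    if (any(!is.finite(object@values)))
      msg <- c(msg, "all property values must be finite")
    else {
      if (any(object@values[, "ASA"] < 0)) msg <- c(msg, "ASA must be >= 0")
      if (any(object@values[, "RASA"] < 0)) msg <- c(msg, "RASA must be >= 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeometricProfile
#'
#' @param chainId chain identifier.
#' @param values numeric L x 5 matrix (columns ASA, RASA, ECA, ICA, EVA).
#' @return A [GeometricProfile-class] object.
#' @export
GeometricProfile <- function(chainId, values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  colnames(values) <- colnames(values)
  new("GeometricProfile", chainId = as.character(chainId), values = values)
}

#' Amino-acid physicochemical scale table
#'
#' Values of five physicochemical properties (hydrophobicity,
#' polarizability, polarity, secondary-structure propensity, codon
#' diversity) for each of the 20 canonical amino acids.
#'
#' @slot values numeric 20 x 5 matrix; row names are the amino-acid
#'   letters in alphabetical order, all values finite.
#' @seealso [defaultPhyschemTable()], [readPhyschemTable()].
#' @export
setClass("PhyschemTable", representation(values = "matrix"))

setValidity("PhyschemTable", function(object) {
  msg <- character()
  if (!setequal(rownames(object@values), AA_ALPHABET) ||
      nrow(object@values) != 20L)
    msg <- c(msg, "all 20 amino-acid letters must be present exactly once")
  if (ncol(object@values) != 5L)
    msg <- c(msg, "exactly 5 property columns required")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a PhyschemTable
#'
#' @param values numeric 20 x 5 matrix with amino-acid letters as row
#'   names and five property columns.
#' @return A [PhyschemTable-class] object (rows reordered alphabetically).
#' @export
PhyschemTable <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  obj <- new("PhyschemTable", values = values)
  obj@values <- obj@values[AA_ALPHABET, , drop = FALSE]
  obj
}

#' Interaction and interface labels of a complex
#'
#' For each of the six unordered chain pairs: whether the two chains
#' interact, and the set of residue-index pairs labelled as interface.
#' A chain pair is interacting if and only if its interface set is
#' non-empty.
#'
#' @slot pairNames the six chain-pair names (`"A:B"` style) in fixed
#'   order: 1-2, 1-3, 1-4, 2-3, 2-4, 3-4 by chain position.
#' @slot interactionFlags named logical vector of length 6.
#' @slot interfacePairs named list of two-column integer matrices
#'   (1-based residue indices on the first/second chain of the pair).
#' @slot cutoff distance cutoff (Angstrom) used for labelling.
#' @export
setClass("InterfaceLabels",
  representation(pairNames = "character", interactionFlags = "logical",
                 interfacePairs = "list", cutoff = "numeric"))

setValidity("InterfaceLabels", function(object) {
  msg <- character()
  if (length(object@pairNames) != 6L ||
      length(object@interactionFlags) != 6L ||
      length(object@interfacePairs) != 6L)
    msg <- c(msg, "exactly 6 chain pairs required")
  nonEmpty <- vapply(object@interfacePairs,
                     function(m) nrow(m) > 0L, logical(1))
  if (!identical(unname(nonEmpty), unname(object@interactionFlags)))
    msg <- c(msg, "interaction flag must equal non-emptiness of interface set")
  if (length(msg)) msg else TRUE
})

#' Standardised chain-pair feature map
#'
#' The 20 x 24 absolute-difference matrix of two chain matrices after
#' per-sample standardisation (zero mean, unit population standard
#' deviation over the 480 entries; a constant matrix standardises to all
#' zeros). This is the input sample of the chain-interaction CNN.
#'
#' @slot map numeric 20 x 24 matrix.
#' @slot complexId complex the sample comes from.
#' @slot chainPair chain-pair name (`"A:B"`).
#' @slot label integer class label (1 interacting, 0 not, NA unknown).
#' @export
setClass("FeatureMap",
  representation(map = "matrix", complexId = "character",
                 chainPair = "character", label = "integer"))

setValidity("FeatureMap", function(object) {
  if (!all(dim(object@map) == c(20L, 24L)))
    return(sprintf("map must be 20 x 24, got %d x %d",
                   nrow(object@map), ncol(object@map)))
  TRUE
})

#' Fitted chain-interaction CNN
#'
#' @slot weights list of layer weights (conv1, conv2, fully connected).
#' @slot config the [cnnConfig()] list used for training.
#' @slot history data.frame of per-epoch training (and validation) loss.
#' @export
setClass("CnnModel",
  representation(weights = "list", config = "list", history = "data.frame"))

#' Fitted under-sampled SVM ensemble
#'
#' @slot models list of fitted member SVMs (e1071, RBF kernel,
#'   probability outputs).
#' @slot center,scale feature standardisation statistics fitted on the
#'   union of the positives and all sampled negatives.
#' @slot config the [ensembleConfig()] list used for training.
#' @export
setClass("SvmEnsemble",
  representation(models = "list", center = "numeric", scale = "numeric",
                 config = "list"))

## ---- accessors ----

#' @rdname chainIds
#' @export
setMethod("chainIds", "TetramerComplex", function(x)
  vapply(x@chains, function(ch) ch@chainId, character(1), USE.NAMES = FALSE))

#' @rdname chains
#' @export
setMethod("chains", "TetramerComplex", function(x) x@chains)

#' @rdname chainSeq
#' @export
setMethod("chainSeq", "ChainRecord", function(x) x@sequence)

#' @rdname caCoords
#' @export
setMethod("caCoords", "ChainRecord", function(x) x@caCoords)

#' @rdname residueIds
#' @export
setMethod("residueIds", "ChainRecord", function(x) x@residueIds)

#' @rdname profileValues
#' @export
setMethod("profileValues", "GeometricProfile", function(x) x@values)

#' @rdname interacting
#' @export
setMethod("interacting", "InterfaceLabels", function(x)
  stats::setNames(x@interactionFlags, x@pairNames))

#' @rdname interfacePairs
#' @export
setMethod("interfacePairs", "InterfaceLabels", function(x)
  stats::setNames(x@interfacePairs, x@pairNames))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "FeatureMap", function(x) x@map)

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "PhyschemTable", function(x) x@values)

#' @rdname sampleLabel
#' @export
setMethod("sampleLabel", "FeatureMap", function(x) x@label)

## ---- show methods ----

setMethod("show", "ChainRecord", function(object) {
  cat(sprintf("ChainRecord %s: %d residues\n", object@chainId,
              nchar(object@sequence)))
  s <- object@sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
})

setMethod("show", "TetramerComplex", function(object) {
  cat(sprintf("TetramerComplex %s\n", object@complexId))
  for (ch in object@chains)
    cat(sprintf("  chain %s: %d residues\n", ch@chainId,
                nchar(ch@sequence)))
})

setMethod("show", "GeometricProfile", function(object) {
  cat(sprintf("GeometricProfile for chain %s: %d residues x 5 properties\n",
              object@chainId, nrow(object@values)))
})

setMethod("show", "PhyschemTable", function(object) {
  cat("PhyschemTable: 20 amino acids x 5 properties\n")
  cat("  properties:", paste(colnames(object@values), collapse = ", "), "\n")
})

setMethod("show", "InterfaceLabels", function(object) {
  n <- vapply(object@interfacePairs, nrow, integer(1))
  cat(sprintf("InterfaceLabels (cutoff %.1f A): %d of 6 chain pairs interacting\n",
              object@cutoff, sum(object@interactionFlags)))
  for (z in seq_len(6))
    cat(sprintf("  %s: %s (%d interface pairs)\n", object@pairNames[z],
                if (object@interactionFlags[z]) "interacting" else "-", n[z]))
})

setMethod("show", "FeatureMap", function(object) {
  cat(sprintf("FeatureMap %s %s (label %s), 20 x 24\n", object@complexId,
              object@chainPair, ifelse(is.na(object@label), "NA",
                                       object@label)))
})

setMethod("show", "CnnModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "CnnModel: conv %dx(3x3) -> conv %dx(2x2) -> maxpool -> fc(2)\n",
    cfg$kernelsConv1, cfg$kernelsConv2))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                max(object@history$epoch),
                object@history$loss[nrow(object@history)]))
})

setMethod("show", "SvmEnsemble", function(object) {
  cat(sprintf("SvmEnsemble: %d RBF members (C = %g, gamma = %g)\n",
              length(object@models), object@config$cost,
              object@config$gamma))
})
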