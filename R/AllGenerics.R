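#' Chain identifiers of a complex
#'
#' @param x a [TetramerComplex-class] object.
#' @return Character vector of the four chain identifiers.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' List of chains in a complex
#'
#' @param x a [TetramerComplex-class] object.
#' @return Named list of [ChainRecord-class] objects.
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' One-letter amino-acid sequence of a chain
#'
#' @param x a [ChainRecord-class] object.
#' @return Single character string over the 20-letter alphabet plus `X`.
#' @export
setGeneric("chainSeq", function(x) standardGeneric("chainSeq"))

#' C-alpha coordinates of a chain
#'
#' @param x a [ChainRecord-class] object.
#' @return Numeric L x 3 matrix of coordinates in Angstrom.
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' Author residue numbering of a chain
#'
#' @param x a [ChainRecord-class] object.
#' @return Integer vector of author residue numbers.
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' Per-residue geometric property matrix
#'
#' @param x a [GeometricProfile-class] object.
#' @return Numeric L x 5 matrix with columns ASA, RASA, ECA, ICA, EVA.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Chain-pair interaction indicators
#'
#' @param x an [InterfaceLabels-class] object.
#' @return Named logical vector over the six unordered chain pairs.
#' @export
setGeneric("interacting", function(x) standardGeneric("interacting"))

#' Interface residue pairs per chain pair
#'
#' @param x an [InterfaceLabels-class] object.
#' @return Named list of two-column integer matrices (residue indices on
#'   the first and second chain of the pair).
#' @export
setGeneric("interfacePairs", function(x) standardGeneric("interfacePairs"))

#' Feature matrix of a feature map or table
#'
#' @param x a [FeatureMap-class] or [PhyschemTable-class] object.
#' @return The underlying numeric matrix.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Class label attached to a sample
#'
#' @param x a [FeatureMap-class] object.
#' @return Integer label (1 interacting, 0 not, `NA` unknown).
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))
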