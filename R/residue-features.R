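#' @include cnn.R
NULL

## Stage-two featurisation: 155 circular sequence descriptors over five
## physicochemical scales plus 305 spatial-neighbour descriptors over
## the five geometric properties, per residue; residue pairs are the
## concatenation of the two 460-vectors (chain-1 residue first).

N_SEQ_FEATURES <- 155L
N_STRUCT_FEATURES <- 305L
N_RESIDUE_FEATURES <- 460L
N_STRUCT_NEIGHBORS <- 20L   # spatial descriptors use the 20 nearest residues

#' Physicochemical number sequences of a chain
#'
#' Maps the chain sequence through a physicochemical table, one value
#' sequence per property.
#'
#' @param chain a [ChainRecord-class].
#' @param table a [PhyschemTable-class].
#' @return Numeric L x 5 matrix (columns = properties).
#' @export
physchemSequences <- function(chain, table) {
  stopifnot(is(table, "PhyschemTable"))
  letters1 <- strsplit(chainSeq(chain), "")[[1]]
  unknown <- setdiff(unique(letters1), rownames(featureMatrix(table)))
  if (length(unknown))
    stop("chain contains letter(s) absent from the physicochemical ",
         "table: ", paste(unknown, collapse = ", "))
  featureMatrix(table)[letters1, , drop = FALSE]
}

#' Amino-acid k-interval product factors (circular)
#'
#' Forward factor: value at the central position times the value k
#' positions before it, divided by k; backward factor: same with the
#' position k after it. The sequence is treated as a cycle (head-to-tail
#' connection), so offsets wrap around.
#'
#' @param values numeric value sequence of one property.
#' @param j central position (1-based).
#' @param k offset, 1..10.
#' @return Named numeric vector `c(forward, backward)`.
#' @export
aaipf <- function(values, j, k) {
  L <- length(values)
  if (k < 1L || k > 10L) stop("k must be in 1..10")
  c(forward = values[j] * values[circIndex(j, -k, L)] / k,
    backward = values[j] * values[circIndex(j, k, L)] / k)
}

#' Amino-acid k-average cumulation factor (circular)
#'
#' Mean of the 2k+1 circularly indexed values centred at the given
#' position.
#'
#' @inheritParams aaipf
#' @return Single numeric value.
#' @export
aaacf <- function(values, j, k) {
  L <- length(values)
  if (k < 1L || k > 10L) stop("k must be in 1..10")
  mean(values[circIndex(j, -k:k, L)])
}

#' Distance-ranked neighbour order of a residue
#'
#' All other residues of the chain sorted by ascending Euclidean
#' C-alpha distance to the central residue; equidistant residues are
#' ordered by ascending sequence position (stable tie-break).
#'
#' @param chain a [ChainRecord-class] with at least 22 residues (the
#'   spatial descriptors need 21 ranked neighbours).
#' @param j central residue position (1-based).
#' @return List with `order` (positions lambda_1..lambda_{L-1}) and
#'   `dist` (the matching non-decreasing distances, Angstrom).
#' @export
neighborOrder <- function(chain, j) {
  xyz <- caCoords(chain)
  L <- nrow(xyz)
  if (L - 1L < 21L)
    stop("structure descriptors need at least 21 neighbouring residues; ",
         "chain has ", L - 1L)
  d <- sqrt(colSums((t(xyz) - xyz[j, ])^2))
  others <- seq_len(L)[-j]
  o <- order(d[others])          # order() is stable: position tie-break
  list(order = others[o], dist = unname(d[others][o]))
}

#' Residue k-interval product factor
#'
#' Geometric value of the central residue times the value of its k-th
#' nearest spatial neighbour, divided by k.
#'
#' @param values numeric per-residue value sequence of one geometric
#'   property.
#' @param j central residue position.
#' @param ord a [neighborOrder()] result for residue `j`.
#' @param k neighbour rank, 1..20.
#' @return Single numeric value.
#' @export
ripf <- function(values, j, ord, k) {
  if (k < 1L || k > N_STRUCT_NEIGHBORS) stop("k must be in 1..20")
  values[j] * values[ord$order[k]] / k
}

#' Residue k-average cumulation factor
#'
#' Mean of the central residue's value and its k nearest neighbours'
#' values (division by k+1).
#'
#' @inheritParams ripf
#' @return Single numeric value.
#' @export
racf <- function(values, j, ord, k) {
  if (k < 1L || k > N_STRUCT_NEIGHBORS) stop("k must be in 1..20")
  (values[j] + sum(values[ord$order[seq_len(k)]])) / (k + 1)
}

#' Exponential distance weights of the nearest neighbours
#'
#' Weight of the xi-th nearest neighbour:
#' `exp(-d_xi^2 * (k+1) / sum(d_1^2 .. d_{k+1}^2))`. The normalising sum
#' runs over the k+1 nearest neighbours of the central residue, so with
#' all distances equal every weight is `exp(-1)`. The scale-invariant
#' normalisation keeps the exponent O(1) at protein scale.
#'
#' @param ord a [neighborOrder()] result.
#' @param k whole size parameter; the spatial feature layout uses 20.
#' @param literal use the unnormalised literal form
#'   `exp(-d^2) * (k+1) / sum(d^2)` instead (underflows at protein
#'   scale; provided for comparison).
#' @return Numeric vector of k+1 weights.
#' @export
neighborWeights <- function(ord, k = N_STRUCT_NEIGHBORS,
                            literal = FALSE) {
  d <- ord$dist[seq_len(k + 1L)]
  if (any(d <= 0))
    stop("duplicate coordinates: zero neighbour distance")
  if (literal) return(exp(-d^2) * (k + 1) / sum(d^2))
  exp(-d^2 * (k + 1) / sum(d^2))
}

#' Weighted neighbour factors rho
#'
#' The weight of each of the 20 nearest neighbours times its geometric
#' value.
#'
#' @inheritParams ripf
#' @param k whole size parameter (default 20).
#' @return Numeric vector of k values.
#' @export
rhoFactors <- function(values, ord, k = N_STRUCT_NEIGHBORS) {
  w <- neighborWeights(ord, k)[seq_len(k)]
  w * values[ord$order[seq_len(k)]]
}

## column names of the 460-feature residue vector, fixed layout
residueFeatureNames <- function() {
  seqBlock <- as.vector(vapply(PHYSCHEM_PROPERTIES, function(p) {
    c(as.vector(rbind(paste0("AAFIPF", 1:10, "_", p),
                      paste0("AABIPF", 1:10, "_", p))),
      paste0("AAACF", 1:10, "_", p))
  }, character(30)))
  structBlock <- as.vector(vapply(GEOM_PROPERTIES, function(p) {
    c(paste0("RIPF", 1:20, "_", p), paste0("RACF", 1:20, "_", p),
      paste0("RHO", 1:20, "_", p))
  }, character(60)))
  c(seqBlock, paste0("raw_", PHYSCHEM_PROPERTIES),
    structBlock, paste0("raw_", GEOM_PROPERTIES))
}

#' All residue feature vectors of a chain
#'
#' Computes the full L x 460 residue descriptor matrix of a chain in
#' one vectorised pass: for each physicochemical property the 10
#' forward/backward circular interval-product factors and 10 circular
#' window means, the 5 raw physicochemical values; for each geometric
#' property the 20 neighbour product factors, 20 neighbour cumulation
#' factors and 20 exponential-weight factors over the distance-ranked
#' C-alpha neighbours, and the 5 raw geometric values.
#'
#' @param chain a [ChainRecord-class] (>= 22 residues).
#' @param physchemTable a [PhyschemTable-class].
#' @param profile the aligned [GeometricProfile-class].
#' @return Numeric L x 460 matrix with the documented fixed column
#'   order (sequence block first, then structure block).
#' @export
chainResidueFeatures <- function(chain, physchemTable, profile) {
  phy <- physchemSequences(chain, physchemTable)
  geo <- profileValues(profile)
  L <- nrow(phy)
  if (nrow(geo) != L) stop("profile rows do not match chain length")
  js <- seq_len(L)

  ## sequence block: 5 x (20 + 10) + 5 = 155
  seqCols <- matrix(0, L, 150L)
  col <- 0L
  for (i in seq_len(5L)) {
    v <- phy[, i]
    for (k in 1:10) {
      seqCols[, col + 1L] <- v * v[circIndex(js, -k, L)] / k
      seqCols[, col + 2L] <- v * v[circIndex(js, k, L)] / k
      col <- col + 2L
    }
    for (k in 1:10) {
      acc <- numeric(L)
      for (delta in -k:k) acc <- acc + v[circIndex(js, delta, L)]
      col <- col + 1L
      seqCols[, col] <- acc / (2 * k + 1)
    }
  }

  ## spatial neighbour ranking for every residue
  if (L - 1L < 21L)
    stop("structure descriptors need at least 21 neighbouring residues; ",
         "chain has ", L - 1L)
  d2full <- crossDist2(caCoords(chain), caCoords(chain))
  diag(d2full) <- Inf
  lambda <- matrix(0L, L, 21L)
  for (j in js) lambda[j, ] <- order(d2full[j, ])[1:21]
  d2rank <- matrix(d2full[cbind(rep(js, 21L), as.vector(lambda))], L, 21L)
  if (any(d2rank <= 0))
    stop("duplicate coordinates: zero neighbour distance")
  w <- exp(-d2rank * 21 / rowSums(d2rank))   # L x 21 weights

  ## structure block: 5 x (20 + 20 + 20) + 5 = 305
  structCols <- matrix(0, L, 300L)
  col <- 0L
  for (i in seq_len(5L)) {
    g <- geo[, i]
    gLambda <- matrix(g[as.vector(lambda[, 1:20])], L, 20L)
    structCols[, col + 1:20] <- g * gLambda / rep(1:20, each = L)
    cum <- t(apply(gLambda, 1L, cumsum))
    structCols[, col + 21:40] <- (g + cum) / rep(2:21, each = L)
    structCols[, col + 41:60] <- w[, 1:20] * gLambda
    col <- col + 60L
  }

  out <- cbind(seqCols, phy, structCols, geo)
  dimnames(out) <- list(NULL, residueFeatureNames())
  out
}

#' Feature vector of a single residue
#'
#' @inheritParams chainResidueFeatures
#' @param j residue position (1-based).
#' @return Named numeric vector of length 460.
#' @export
residueVector <- function(chain, physchemTable, profile, j) {
  chainResidueFeatures(chain, physchemTable, profile)[j, ]
}

#' Residue-pair feature vector
#'
#' Concatenation of two residue vectors, the chain-1 residue first; the
#' representation is order-sensitive by construction.
#'
#' @param u1,u2 residue feature vectors of length 460.
#' @param label optional 0/1 interface label, stored as attribute.
#' @return Numeric vector of length 920, names prefixed `c1_` / `c2_`.
#' @export
pairVector <- function(u1, u2, label = NA_integer_) {
  stopifnot(length(u1) == N_RESIDUE_FEATURES,
            length(u2) == N_RESIDUE_FEATURES)
  out <- c(u1, u2)
  names(out) <- c(paste0("c1_", names(u1) %||% seq_along(u1)),
                  paste0("c2_", names(u2) %||% seq_along(u2)))
  attr(out, "label") <- as.integer(label)
  out
}

#' Assemble a labelled residue-pair dataset from complexes
#'
#' Convenience builder for ensemble training and evaluation tables:
#' featurises every chain of each complex, then collects residue-pair
#' vectors for all six chain pairs with their interface labels,
#' optionally subsampling each chain pair's positives and negatives to
#' keep the table tractable.
#'
#' @param sims list of complex bundles as returned by
#'   [simulateComplex()] (elements `complex`, `profiles`, `physchem`,
#'   `labels`); equivalent hand-built lists work the same way.
#' @param maxPositives,maxNegatives per chain pair, the maximum number
#'   of interface / non-interface pairs retained (`Inf` keeps all);
#'   subsampling is seeded.
#' @param seed RNG seed for the subsampling.
#' @return List with `x` (pair-feature matrix, 920 columns), `y`
#'   (0/1 interface labels) and `meta` (data.frame: complex, chain
#'   pair, residue indices).
#' @export
residuePairDataset <- function(sims, maxPositives = Inf,
                               maxNegatives = 200L, seed = 1L) {
  set.seed(seed)
  xs <- list(); ys <- list(); metas <- list()
  for (s in sims) {
    ids <- chainIds(s$complex)
    U <- lapply(stats::setNames(ids, ids), function(cid)
      chainResidueFeatures(chains(s$complex)[[cid]], s$physchem,
                           s$profiles[[cid]]))
    idx <- chainPairIndex()
    truthAll <- interfacePairs(s$labels)
    for (z in seq_len(6L)) {
      u1 <- U[[ids[idx[z, 1L]]]]; u2 <- U[[ids[idx[z, 2L]]]]
      truth <- truthAll[[z]]
      key <- paste(truth[, 1L], truth[, 2L])
      all <- cbind(rep(seq_len(nrow(u1)), times = nrow(u2)),
                   rep(seq_len(nrow(u2)), each = nrow(u1)))
      isPos <- paste(all[, 1L], all[, 2L]) %in% key
      pos <- which(isPos); neg <- which(!isPos)
      if (length(pos) > maxPositives)
        pos <- sort(sample(pos, maxPositives))
      if (length(neg) > maxNegatives)
        neg <- sort(sample(neg, maxNegatives))
      keep <- c(pos, neg)
      xs[[length(xs) + 1L]] <- chainPairVectors(u1, u2,
                                                all[keep, , drop = FALSE])
      ys[[length(ys) + 1L]] <- as.integer(isPos[keep])
      metas[[length(metas) + 1L]] <- data.frame(
        complex = s$complex@complexId,
        chainPair = names(truthAll)[z],
        res1 = all[keep, 1L], res2 = all[keep, 2L])
    }
  }
  list(x = do.call(rbind, xs), y = unlist(ys),
       meta = do.call(rbind, metas))
}

#' Residue-pair feature matrix for selected pairs of a chain pair
#'
#' @param u1,u2 residue feature matrices of the two chains from
#'   [chainResidueFeatures()].
#' @param pairs two-column integer matrix of (chain-1 residue, chain-2
#'   residue) indices; defaults to all L1 x L2 candidate pairs.
#' @return Numeric `nrow(pairs)` x 920 matrix; attribute `pairs` holds
#'   the index matrix.
#' @export
chainPairVectors <- function(u1, u2, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- cbind(rep(seq_len(nrow(u1)), times = nrow(u2)),
                   rep(seq_len(nrow(u2)), each = nrow(u1)))
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  out <- cbind(u1[pairs[, 1L], , drop = FALSE],
               u2[pairs[, 2L], , drop = FALSE])
  colnames(out) <- c(paste0("c1_", colnames(u1)), paste0("c2_", colnames(u2)))
  attr(out, "pairs") <- pairs
  out
}
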