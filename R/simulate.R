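#' @include evaluation.R
NULL

## Synthetic tetramer generator. Each complex is four compact
## self-avoiding C-alpha walks placed so that designated chain pairs
## touch (some residue pair within the label cutoff) and the others
## stay far apart. Interaction structure is planted through a latent
## per-chain divergence coordinate: chains of an interacting pair are
## close homologs, the mostly homo-oligomeric character of real
## tetramer sets, and through the geometry-derived property tables
## (cross-chain packing raises exterior contact area). Labels are
## always recomputed from coordinates by labelContacts(), never
## asserted.

## composition poles of the divergence axis: buried/hydrophobic-rich
## versus surface/polar-rich chains
COMP_CORE <- c(A = 0.09, C = 0.03, D = 0.02, E = 0.02, F = 0.08,
               G = 0.07, H = 0.02, I = 0.09, K = 0.02, L = 0.11,
               M = 0.05, N = 0.02, P = 0.03, Q = 0.02, R = 0.02,
               S = 0.04, T = 0.04, V = 0.10, W = 0.05, Y = 0.08)
COMP_SURF <- c(A = 0.04, C = 0.01, D = 0.08, E = 0.09, F = 0.02,
               G = 0.06, H = 0.04, I = 0.03, K = 0.09, L = 0.05,
               M = 0.02, N = 0.07, P = 0.05, Q = 0.07, R = 0.08,
               S = 0.09, T = 0.08, V = 0.04, W = 0.01, Y = 0.03)

#' Synthetic-data configuration
#'
#' Defaults describe the study conditions the generator emulates:
#' tetramers with 25-60 residues per chain, about one in five chain
#' pairs non-interacting (mirroring the sparse non-interactions of real
#' tetramer sets), at least one planted interface pair per interacting
#' chain pair, and moderate measurement noise on the geometric
#' properties.
#'
#' @param nComplexes number of complexes (for [simulateDataset()]).
#' @param lengthRange inclusive chain-length range; one length is drawn
#'   per complex and shared by its four homologous chains. Default
#'   `c(25, 60)` (the lower end leaves the 21 ranked neighbours the
#'   spatial descriptors need).
#' @param nonInteractingFraction target fraction of non-interacting
#'   chain pairs, in [0, 1]; default 0.2.
#' @param minInterfacePairs minimum interface residue pairs per
#'   interacting chain pair; default 1.
#' @param propertyNoise multiplier on the Gaussian noise of the
#'   property tables; default 1.
#' @param burialCoupling strength of the burial-to-ASA coupling
#'   (neighbour count lowering accessible area); default 1.
#' @param contactCutoff labelling cutoff in Angstrom (C-alpha); 8.
#' @param maxRetries geometry retries before giving up; default 40.
#' @param seed integer RNG seed.
#' @return A list of class `simulationConfig`.
#' @export
simulationConfig <- function(nComplexes = 12L, lengthRange = c(25L, 60L),
                             nonInteractingFraction = 0.2,
                             minInterfacePairs = 1L, propertyNoise = 1,
                             burialCoupling = 1, contactCutoff = 8,
                             maxRetries = 40L, seed = 1L) {
  stopifnot(nComplexes >= 1L, length(lengthRange) == 2L,
            lengthRange[1] >= 20L, lengthRange[2] <= 500L,
            lengthRange[1] <= lengthRange[2],
            nonInteractingFraction >= 0, nonInteractingFraction <= 1,
            minInterfacePairs >= 1L, propertyNoise >= 0,
            contactCutoff > 0)
  structure(list(nComplexes = as.integer(nComplexes),
                 lengthRange = as.integer(lengthRange),
                 nonInteractingFraction = nonInteractingFraction,
                 minInterfacePairs = as.integer(minInterfacePairs),
                 propertyNoise = propertyNoise,
                 burialCoupling = burialCoupling,
                 contactCutoff = contactCutoff,
                 maxRetries = as.integer(maxRetries),
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

## latent composition coordinates: pairs with |u_i - u_j| <= theta are
## designated interacting; resampled until every pair clears the
## ambiguity margin around theta
drawLatent <- function(fraction, margin = 0.08, maxTries = 500L) {
  theta <- 1 - sqrt(fraction)
  for (try in seq_len(maxTries)) {
    u <- stats::runif(4)
    gaps <- abs(u[chainPairIndex()[, 1L]] - u[chainPairIndex()[, 2L]])
    if (all(abs(gaps - theta) > margin))
      return(list(u = u, interact = gaps <= theta))
  }
  stop("could not draw a margin-separated latent configuration")
}

## compact self-avoiding-ish CA walk confined to a sphere
chainWalk <- function(L, center, radius, step = 3.8, minSep = 3.2) {
  xyz <- matrix(0, L, 3L)
  xyz[1L, ] <- center + stats::rnorm(3, sd = 0.5)
  for (i in seq_len(L - 1L)) {
    placed <- FALSE
    for (try in seq_len(25L)) {
      dir <- stats::rnorm(3)
      cand <- xyz[i, ] + step * dir / sqrt(sum(dir^2))
      if (sqrt(sum((cand - center)^2)) > radius) next
      prev <- xyz[seq_len(max(1L, i - 1L)), , drop = FALSE]
      if (min(sqrt(rowSums((prev - rep(cand, each = nrow(prev)))^2))) <
          minSep) next
      placed <- TRUE
      break
    }
    if (!placed) {   # pull back toward the centre and accept
      dir <- center - xyz[i, ] + stats::rnorm(3, sd = 1)
      cand <- xyz[i, ] + step * dir / sqrt(sum(dir^2))
    }
    xyz[i + 1L, ] <- cand
  }
  xyz
}

## place 4 chain centres approximately realising the target distances
placeCenters <- function(target) {
  centers <- matrix(stats::rnorm(12, sd = mean(target) / 3), 4L, 3L)
  for (iter in seq_len(300L)) {
    for (z in seq_len(6L)) {
      i <- chainPairIndex()[z, 1L]; j <- chainPairIndex()[z, 2L]
      v <- centers[i, ] - centers[j, ]
      dd <- sqrt(sum(v^2))
      if (dd < 1e-6) { v <- stats::rnorm(3); dd <- sqrt(sum(v^2)) }
      adj <- 0.25 * (dd - target[i, j]) * v / dd
      centers[i, ] <- centers[i, ] - adj
      centers[j, ] <- centers[j, ] + adj
    }
  }
  centers
}

#' Simulate one tetramer complex
#'
#' Generates four chains (sequences, C-alpha coordinates and geometric
#' property tables) with a planted interaction pattern, and labels it
#' with [labelContacts()]. Deterministic given the seed.
#'
#' @param config a [simulationConfig()].
#' @param complexId identifier for the complex.
#' @param seed RNG seed; defaults to the config seed.
#' @return List with elements `complex` ([TetramerComplex-class]),
#'   `profiles` (named list of four [GeometricProfile-class]),
#'   `physchem` (the default [PhyschemTable-class]) and `labels`
#'   ([InterfaceLabels-class], recomputed from the coordinates).
#' @examples
#' sim <- simulateComplex(simulationConfig(seed = 11))
#' sum(interacting(sim$labels))
#' @export
simulateComplex <- function(config = simulationConfig(),
                            complexId = "SIM001", seed = config$seed) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(seed)
  ids <- c("A", "B", "C", "D")
  Ls <- sample(config$lengthRange[1L]:config$lengthRange[2L], 4L,
               replace = TRUE)
  lat <- drawLatent(config$nonInteractingFraction)

  ## sequences sampled from the latent composition blend: chains close
  ## on the divergence axis (interacting pairs) have similar
  ## composition, distant ones differ systematically
  seqs <- vapply(seq_len(4L), function(c) {
    p <- (1 - lat$u[c]) * COMP_CORE + lat$u[c] * COMP_SURF
    paste(sample(AA_ALPHABET, Ls[c], replace = TRUE, prob = p),
          collapse = "")
  }, character(1))

  ## geometry: retried until the realised contact labels match the
  ## designated pattern with the required interface size
  ## near pairs overlap enough to touch; far pairs sit just outside
  ## contact range, as non-interacting chains of a real tetramer do
  radii <- 3.6 * Ls^(1/3)
  idx <- chainPairIndex()
  target <- matrix(0, 4L, 4L)
  for (z in seq_len(6L)) {
    i <- idx[z, 1L]; j <- idx[z, 2L]
    target[i, j] <- target[j, i] <-
      if (lat$interact[z]) 0.78 * (radii[i] + radii[j])
      else radii[i] + radii[j] + 6
  }
  cx <- NULL; labels <- NULL
  for (attempt in seq_len(config$maxRetries)) {
    centers <- placeCenters(target)
    chainList <- lapply(seq_len(4L), function(c)
      ChainRecord(ids[c], seqs[c],
                  chainWalk(Ls[c], centers[c, ], radii[c])))
    cand <- TetramerComplex(complexId, chainList)
    lab <- labelContacts(cand, cutoff = config$contactCutoff)
    sizes <- vapply(interfacePairs(lab), nrow, integer(1))
    okPattern <- identical(unname(interacting(lab)), lat$interact)
    okSize <- all(sizes[lat$interact] >= config$minInterfacePairs)
    if (okPattern && okSize) { cx <- cand; labels <- lab; break }
  }
  if (is.null(cx))
    stop("infeasible geometry for complex ", complexId, " after ",
         config$maxRetries, " retries")

  ## property tables from the realised geometry
  allXyz <- do.call(rbind, lapply(chains(cx), caCoords))
  chainOf <- rep(seq_len(4L), times = Ls)
  d2 <- crossDist2(allXyz, allXyz)
  within10 <- d2 <= 100 & d2 > 0
  profiles <- lapply(seq_len(4L), function(c) {
    rows <- which(chainOf == c)
    same <- rowSums(within10[rows, rows, drop = FALSE])
    cross <- rowSums(within10[rows, chainOf != c, drop = FALSE])
    L <- length(rows)
    ## surface-like chains (high divergence coordinate) are both more
    ## exposed on average and more variable in their exposure
    noise <- function(sd) stats::rnorm(L, sd = sd * config$propertyNoise *
                                         (0.5 + lat$u[c]))
    asa <- pmax(0, 115 + 50 * lat$u[c] -
                  9 * config$burialCoupling * same + noise(8))
    letters1 <- strsplit(seqs[c], "")[[1]]
    rasa <- pmin(1, asa / MAX_ASA[letters1])
    eca <- pmax(0, 12 * cross + noise(4))
    ica <- pmax(0, 14 * same + noise(5))
    eva <- pmax(0, 40 + 40 * lat$u[c] - 4 * cross + noise(6))
    GeometricProfile(ids[c], cbind(ASA = asa, RASA = unname(rasa),
                                   ECA = eca, ICA = ica, EVA = eva))
  })
  names(profiles) <- ids
  list(complex = cx, profiles = profiles,
       physchem = defaultPhyschemTable(), labels = labels)
}

#' Simulate a dataset on disk
#'
#' Writes `nComplexes` complexes (C-alpha PDB plus one property TSV per
#' chain) into a directory with a manifest, split 3:1 into train and
#' test in id order.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return The manifest data.frame, invisibly; the manifest file is
#'   `manifest.tsv` inside `dir`.
#' @export
simulateDataset <- function(config = simulationConfig(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$nComplexes
  nTrain <- floor(n * 3 / 4)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("SIM%03d", i)
    sim <- simulateComplex(config, complexId = id,
                           seed = config$seed * 1000L + i)
    pdbPath <- file.path(dir, paste0(id, ".pdb"))
    writeComplexPdb(sim$complex, pdbPath)
    profPaths <- vapply(chainIds(sim$complex), function(cid) {
      p <- file.path(dir, sprintf("%s_%s.tsv", id, cid))
      writePropertyTable(sim$profiles[[cid]],
                         chains(sim$complex)[[cid]], p)
      p
    }, character(1))
    rows[[i]] <- data.frame(
      complex_id = id,
      split = if (i <= nTrain) "train" else "test",
      pdb = basename(pdbPath),
      profiles = paste(basename(profPaths), collapse = ","))
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
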