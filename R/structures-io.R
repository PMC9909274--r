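#' @include physchem.R
NULL

#' Read a tetramer complex from a PDB file
#'
#' Parses a PDB file (first model only) and extracts four chains as
#' C-alpha records. Residues without a C-alpha atom are dropped with a
#' warning; for alternate locations the first one is kept and occupancy
#' is ignored. Three-letter residue names outside the canonical 20 map
#' to `X`.
#'
#' @param path path to a PDB file.
#' @param chainIds optional character vector of four chain identifiers to
#'   select. Required when the file contains more than four chains.
#' @param complexId identifier to store; defaults to the file name
#'   without extension.
#' @return A [TetramerComplex-class] object.
#' @examples
#' sim <- simulateComplex(simulationConfig(seed = 7))
#' tmp <- tempfile(fileext = ".pdb")
#' writeComplexPdb(sim$complex, tmp)
#' cx <- readComplex(tmp)
#' chainIds(cx)
#' @export
readComplex <- function(path, chainIds = NULL, complexId = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("could not parse PDB file ", path, ": ",
                         conditionMessage(e)))
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (!nrow(atoms)) stop("no ATOM records in ", path)
  ## first altloc only
  atoms <- atoms[is.na(atoms$alt) | atoms$alt %in% c("", "A"), , drop = FALSE]
  present <- unique(atoms$chain)
  if (is.null(chainIds)) {
    if (length(present) > 4L)
      stop("complex has ", length(present),
           " chains; supply an explicit 4-chain selection via 'chainIds'")
    chainIds <- present
  } else {
    missing <- setdiff(chainIds, present)
    if (length(missing))
      stop("requested chains not in file: ", paste(missing, collapse = ", "))
  }
  if (length(chainIds) != 4L)
    stop("complex must have 4 chains, got ", length(chainIds))

  mkChain <- function(cid) {
    ca <- atoms[atoms$chain == cid & atoms$elety == "CA", , drop = FALSE]
    resKeyAll <- unique(paste(atoms$resno[atoms$chain == cid],
                              atoms$insert[atoms$chain == cid]))
    ## one CA per residue (first wins)
    key <- paste(ca$resno, ca$insert)
    ca <- ca[!duplicated(key), , drop = FALSE]
    nDropped <- length(resKeyAll) - nrow(ca)
    if (nDropped > 0L)
      warning(sprintf("chain %s: dropped %d residue(s) without a CA atom",
                      cid, nDropped))
    if (!nrow(ca)) stop("chain ", cid, " has no CA atoms")
    letters1 <- unname(AA_321[ca$resid])
    letters1[is.na(letters1)] <- "X"
    ChainRecord(cid, paste(letters1, collapse = ""),
                cbind(ca$x, ca$y, ca$z), residueIds = ca$resno)
  }
  cx <- TetramerComplex(complexId %||%
                          sub("\\.[^.]*$", "", basename(path)),
                        lapply(chainIds, mkChain))
  cx
}

#' Read a per-residue geometric property table
#'
#' Reads a tab-separated table with columns `residue_index`, `aa`,
#' `ASA`, `RASA`, `ECA`, `ICA`, `EVA` (one row per residue, `#`
#' comments allowed) and aligns it to a chain.
#'
#' @param path path to the TSV file.
#' @param chain the [ChainRecord-class] the table describes; row count,
#'   residue indices and amino-acid letters must match.
#' @return A [GeometricProfile-class] object aligned with `chain`.
#' @export
readPropertyTable <- function(path, chain) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("residue_index", "aa", GEOM_PROPERTIES)
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("property table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(tab)) stop("property table ", path, " is empty")
  for (cc in GEOM_PROPERTIES)
    if (!is.numeric(tab[[cc]]))
      stop("non-numeric values in column ", cc, " of ", path)
  L <- nchar(chainSeq(chain))
  if (nrow(tab) != L)
    stop(sprintf("property table has %d rows but chain %s has %d residues",
                 nrow(tab), chain@chainId, L))
  badIdx <- which(tab$residue_index != residueIds(chain))
  badAa <- which(tab$aa != strsplit(chainSeq(chain), "")[[1]])
  bad <- sort(unique(c(badIdx, badAa)))
  if (length(bad))
    stop("property table rows disagree with chain ", chain@chainId,
         " at row(s): ", paste(utils::head(bad, 10), collapse = ", "))
  vals <- as.matrix(tab[, GEOM_PROPERTIES])
  colnames(vals) <- GEOM_PROPERTIES
  GeometricProfile(chain@chainId, vals)
}

#' Write a per-residue geometric property table
#'
#' Inverse of [readPropertyTable()].
#'
#' @param profile a [GeometricProfile-class].
#' @param chain the matching [ChainRecord-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePropertyTable <- function(profile, chain, path) {
  vals <- profileValues(profile)
  df <- data.frame(residue_index = residueIds(chain),
                   aa = strsplit(chainSeq(chain), "")[[1]],
                   vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a physicochemical scale table
#'
#' Tab-separated file with a column `aa` plus five numeric property
#' columns, one row per canonical amino acid.
#'
#' @param path path to the TSV file.
#' @return A [PhyschemTable-class] object.
#' @export
readPhyschemTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!"aa" %in% names(tab)) stop("physchem table lacks an 'aa' column")
  vals <- as.matrix(tab[, setdiff(names(tab), "aa"), drop = FALSE])
  rownames(vals) <- tab$aa
  PhyschemTable(vals)
}

#' Label chain-pair contacts and interface residue pairs
#'
#' Residue pair (i on one chain, j on another) is labelled as interface
#' when the C-alpha distance is at or below `cutoff`; a chain pair is
#' interacting when it has at least one interface pair. This
#' distance rule is the standard surrogate for a Voronoi contact-area
#' criterion.
#'
#' @param complex a [TetramerComplex-class].
#' @param cutoff distance cutoff in Angstrom (> 0); default 8.0,
#'   appropriate for C-alpha-only coordinates.
#' @return An [InterfaceLabels-class] object over the six chain pairs.
#' @examples
#' sim <- simulateComplex(simulationConfig(seed = 3))
#' interacting(labelContacts(sim$complex))
#' @export
labelContacts <- function(complex, cutoff = 8) {
  stopifnot(is(complex, "TetramerComplex"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number")
  coords <- lapply(chains(complex), caCoords)
  if (any(!vapply(coords, function(m) all(is.finite(m)), logical(1))))
    stop("non-finite coordinates in complex ", complex@complexId)
  idx <- chainPairIndex()
  pairs <- vector("list", 6L)
  flags <- logical(6L)
  for (z in seq_len(6L)) {
    d2 <- crossDist2(coords[[idx[z, 1L]]], coords[[idx[z, 2L]]])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    dimnames(hit) <- list(NULL, c("res1", "res2"))
    storage.mode(hit) <- "integer"
    pairs[[z]] <- hit
    flags[z] <- nrow(hit) > 0L
  }
  pn <- chainPairNames(chainIds(complex))
  new("InterfaceLabels", pairNames = pn,
      interactionFlags = stats::setNames(flags, pn),
      interfacePairs = stats::setNames(pairs, pn), cutoff = cutoff)
}

#' Read a dataset manifest
#'
#' Flat tab-separated file with one complex per line and columns
#' `complex_id`, `split` (train/validation/test), `pdb` and `profiles`
#' (comma-separated per-chain property-table paths). Paths are resolved
#' relative to the manifest's directory when not absolute.
#'
#' @param path manifest file path.
#' @return A data.frame with the columns above, paths made absolute.
#' @export
readManifest <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("complex_id", "split", "pdb", "profiles")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  tab$pdb <- resolve(tab$pdb)
  tab$profiles <- vapply(strsplit(tab$profiles, ","), function(ps)
    paste(resolve(ps), collapse = ","), character(1))
  allFiles <- c(tab$pdb, unlist(strsplit(tab$profiles, ",")))
  absent <- allFiles[!file.exists(allFiles)]
  if (length(absent))
    stop("manifest references missing file(s): ",
         paste(utils::head(absent, 5), collapse = ", "))
  if (anyDuplicated(tab$complex_id))
    stop("duplicate complex ids in manifest")
  tab
}

#' Write a dataset manifest
#'
#' @param manifest data.frame with columns `complex_id`, `split`, `pdb`,
#'   `profiles`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a complex as a C-alpha-only PDB file
#'
#' Emits standard fixed-width `ATOM` records (one CA per residue, chains
#' separated by `TER`), parseable by any PDB reader including
#' [readComplex()].
#'
#' @param complex a [TetramerComplex-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeComplexPdb <- function(complex, path) {
  rev321 <- stats::setNames(names(AA_321), unname(AA_321))
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in chains(complex)) {
    letters1 <- strsplit(chainSeq(ch), "")[[1]]
    res3 <- rev321[letters1]
    res3[is.na(res3)] <- "UNK"
    xyz <- caCoords(ch)
    for (i in seq_along(letters1)) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, res3[i], ch@chainId, residueIds(ch)[i],
        xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, "C"), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}
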