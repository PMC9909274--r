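test_that("PDB round trip preserves chains, sequences and coordinates", {
  sim <- simulateComplex(simulationConfig(seed = 21), complexId = "RT01")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeComplexPdb(sim$complex, tmp)
  cx <- readComplex(tmp)
  expect_s4_class(cx, "TetramerComplex")
  expect_identical(chainIds(cx), chainIds(sim$complex))
  for (cid in chainIds(cx)) {
    expect_identical(chainSeq(chains(cx)[[cid]]),
                     chainSeq(chains(sim$complex)[[cid]]))
    expect_equal(caCoords(chains(cx)[[cid]]),
                 caCoords(chains(sim$complex)[[cid]]), tolerance = 1e-3)
  }
})

test_that("residues without a CA atom are dropped with a warning", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  mkAtom <- function(serial, name, res, chain, resno, x) {
    pad <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, pad, res, chain, resno, x, 0, 0, 1, 0,
            substr(name, 1, 1))
  }
  lines <- character()
  s <- 0
  for (ch in c("A", "B", "C", "D")) {
    for (r in 1:20) { s <- s + 1
      lines <- c(lines, mkAtom(s, "CA", "ALA", ch, r, r * 3.8)) }
    # residue 21 of chain A has a backbone N but no CA
    if (ch == "A") { s <- s + 1
      lines <- c(lines, mkAtom(s, "N", "GLY", ch, 21, 90)) }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), tmp)
  expect_warning(cx <- readComplex(tmp), "without a CA atom")
  expect_identical(nchar(chainSeq(chains(cx)[["A"]])), 20L)
})

test_that("wrong chain counts are rejected", {
  sim <- simulateComplex(simulationConfig(seed = 22))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeComplexPdb(sim$complex, tmp)
  # keep only three chains
  lines <- readLines(tmp)
  keep <- !(startsWith(lines, "ATOM") & substr(lines, 22, 22) == "D")
  tmp3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[keep], tmp3)
  expect_error(readComplex(tmp3), "4 chains")
  # explicit selection of a missing chain
  expect_error(readComplex(tmp, chainIds = c("A", "B", "C", "Z")),
               "not in file")
})

test_that("nonstandard residue names map to X", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  lines <- character(); s <- 0
  for (ch in c("A", "B", "C", "D")) {
    for (r in 1:4) { s <- s + 1
      res <- if (ch == "A" && r == 2) "MSE" else "ALA"
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        s, res, ch, r, r * 3.8, 0, 0, 1, 0, "C")) }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), tmp)
  cx <- suppressWarnings(readComplex(tmp))
  expect_identical(chainSeq(chains(cx)[["A"]]), "AXAA")
})

test_that("property tables align with the chain and reject bad input", {
  sim <- simulateComplex(simulationConfig(seed = 23))
  ch <- chains(sim$complex)[[1]]
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writePropertyTable(sim$profiles[[1]], ch, tmp)
  prof <- readPropertyTable(tmp, ch)
  expect_equal(profileValues(prof), profileValues(sim$profiles[[1]]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # the published worked-example ASA column survives a round trip
  wch <- workedExampleChain()
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writePropertyTable(workedExampleProfile(), wch, tmp2)
  expect_identical(unname(profileValues(readPropertyTable(tmp2, wch))[, "ASA"]),
                   workedExampleAsa)

  # missing column
  tab <- read.table(tmp, header = TRUE, sep = "\t")
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[, -3], tmp3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPropertyTable(tmp3, ch), "lacks column")
  # row-count mismatch
  tmp4 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[-1, ], tmp4, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPropertyTable(tmp4, ch), "rows but chain")
  # disagreeing amino-acid letters name offending rows
  tab2 <- tab; tab2$aa[3] <- if (tab2$aa[3] == "G") "P" else "G"
  tmp5 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab2, tmp5, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPropertyTable(tmp5, ch), "row\\(s\\): 3")
  # empty file
  tmp6 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("residue_index\taa\tASA\tRASA\tECA\tICA\tEVA", tmp6)
  expect_error(readPropertyTable(tmp6, ch), "empty")
})

test_that("contact labelling matches geometry and the definitions", {
  mkChain <- function(id, offset) {
    suppressWarnings(ChainRecord(id, strrep("A", 25),
                                 cbind(seq_len(25) * 3.8 + offset[1],
                                       offset[2], offset[3])))
  }
  # all chains far apart -> nothing interacts
  far <- TetramerComplex("FAR", list(mkChain("A", c(0, 0, 0)),
                                     mkChain("B", c(0, 200, 0)),
                                     mkChain("C", c(0, 0, 200)),
                                     mkChain("D", c(0, 200, 200))))
  lab <- labelContacts(far, cutoff = 8)
  expect_false(any(interacting(lab)))
  expect_identical(sum(vapply(interfacePairs(lab), nrow, integer(1))), 0L)

  # one residue pair at 3 A -> with a 3.5 A cutoff exactly that pair
  # is positive and the chains interact
  a <- mkChain("A", c(0, 0, 0))
  bxyz <- cbind(seq_len(25) * 3.8, 60, 0)
  bxyz[10, ] <- caCoords(a)[5, ] + c(0, 3, 0)
  b <- suppressWarnings(ChainRecord("B", strrep("A", 25), bxyz))
  cx <- TetramerComplex("ONE", list(a, b, mkChain("C", c(0, 300, 0)),
                                    mkChain("D", c(0, 0, 300))))
  lab <- labelContacts(cx, cutoff = 3.5)
  expect_true(interacting(lab)[["A:B"]])
  expect_identical(interfacePairs(lab)[["A:B"]],
                   matrix(c(5L, 10L), 1, 2,
                          dimnames = list(NULL, c("res1", "res2"))))

  expect_error(labelContacts(cx, cutoff = -1), "positive")
})

test_that("vectorised labeller equals the brute-force all-pairs oracle", {
  for (seed in c(31, 32, 33)) {
    sim <- simulateComplex(simulationConfig(seed = seed,
                                            lengthRange = c(25L, 40L)))
    lab <- labelContacts(sim$complex, cutoff = 8)
    oracle <- bruteContacts(sim$complex, 8)
    for (z in seq_len(6))
      expect_equal(unname(interfacePairs(lab)[[z]]),
                   unname(oracle[[z]]), ignore_attr = TRUE)
  }
})

test_that("complex invariants hold: 6 pairs, L1*L2 candidates, flag consistency", {
  sim <- simulateComplex(simulationConfig(seed = 40))
  expect_length(chainPairNames(chainIds(sim$complex)), 6L)
  lab <- sim$labels
  sets <- interfacePairs(lab)
  expect_identical(unname(vapply(sets, nrow, integer(1)) > 0L),
                   unname(interacting(lab)))
  idx <- tetraPPI:::chainPairIndex()
  Ls <- vapply(chains(sim$complex), function(ch) nchar(chainSeq(ch)),
               integer(1))
  for (z in seq_len(6)) {
    nCand <- Ls[idx[z, 1]] * Ls[idx[z, 2]]
    expect_lte(nrow(sets[[z]]), nCand)
    if (nrow(sets[[z]])) {
      expect_true(all(sets[[z]][, 1] <= Ls[idx[z, 1]]))
      expect_true(all(sets[[z]][, 2] <= Ls[idx[z, 2]]))
    }
  }
})

test_that("manifest round trip resolves files and flags missing ones", {
  dir <- withr::local_tempdir()
  manifest <- simulateDataset(simulationConfig(nComplexes = 4L, seed = 3),
                              dir)
  got <- readManifest(file.path(dir, "manifest.tsv"))
  expect_identical(got$complex_id, manifest$complex_id)
  expect_identical(got$split, c("train", "train", "train", "test"))
  expect_true(all(file.exists(got$pdb)))
  file.remove(got$pdb[1])
  expect_error(readManifest(file.path(dir, "manifest.tsv")), "missing file")
})
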