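mkTable <- function(seed = 1) {
  set.seed(seed)
  vals <- matrix(round(runif(100, -2, 2), 3), 20, 5,
                 dimnames = list(aminoAcidAlphabet(),
                                 c("hydrophobicity", "polarizability",
                                   "polarity", "secondary_structure",
                                   "codon_diversity")))
  PhyschemTable(vals)
}

test_that("physicochemical sequences are table lookups and reject unknowns", {
  tab <- defaultPhyschemTable()
  ch <- suppressWarnings(ChainRecord("A", strrep("A", 22),
                                     matrix(rnorm(66), 22, 3)))
  phy <- physchemSequences(ch, tab)
  expect_identical(dim(phy), c(22L, 5L))
  expect_true(all(phy[, "hydrophobicity"] == 1.8))

  chX <- suppressWarnings(ChainRecord("B", paste0(strrep("A", 21), "X"),
                                      matrix(rnorm(66), 22, 3)))
  expect_error(physchemSequences(chX, tab), "X")
})

test_that("interval product factors follow the circular definition", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(aaipf(v, j = 3, k = 2),
               c(forward = 3 * 1 / 2, backward = 3 * 5 / 2))
  # wrap: two after position 5 is position 2
  expect_equal(aaipf(v, j = 5, k = 2)[["backward"]], 5 * 2 / 2)
  # constant sequence closed form
  cv <- rep(4, 9)
  for (k in c(1, 5, 10))
    expect_equal(unname(aaipf(cv, 3, k)), rep(16 / k, 2))
  expect_error(aaipf(v, 1, 11), "1..10")
})

test_that("window means follow the circular definition", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(aaacf(v, j = 3, k = 1), 3)
  expect_equal(aaacf(v, j = 1, k = 1), (5 + 1 + 2) / 3)
  expect_equal(aaacf(rep(7, 6), 2, 10), 7)   # constant, even when wrapping
})

test_that("circular features match the wrap oracle exhaustively on short sequences", {
  for (L in c(5, 8, 12)) {
    set.seed(L)
    v <- round(runif(L, -3, 3), 3)
    for (j in seq_len(L)) for (k in 1:10) {
      expect_equal(aaipf(v, j, k)[["forward"]],
                   v[j] * v[bruteWrap(j, -k, L)] / k)
      expect_equal(aaipf(v, j, k)[["backward"]],
                   v[j] * v[bruteWrap(j, k, L)] / k)
      expect_equal(aaacf(v, j, k),
                   mean(v[vapply(-k:k, function(d) bruteWrap(j, d, L),
                                 integer(1))]))
    }
  }
})

test_that("neighbour order sorts by distance with stable position tie-break", {
  # collinear chain with growing gaps: spatial order equals position order
  x <- cumsum(c(0, seq(2, 2 + 23 * 0.5, by = 0.5)))
  ch <- ChainRecord("A", strrep("A", 25), cbind(x, 0, 0))
  ord <- neighborOrder(ch, 1)
  expect_identical(ord$order, 2:25)
  expect_equal(ord$dist, x[2:25])
  expect_true(all(diff(ord$dist) >= 0))

  # equidistant neighbours: the lower sequence position comes first
  xyz <- cbind(c(0, -4, 4, x[4:25] + 10), 0, 0)
  ch2 <- ChainRecord("B", strrep("A", 25), xyz)
  ord2 <- neighborOrder(ch2, 1)
  expect_identical(ord2$order[1:2], c(2L, 3L))

  small <- suppressWarnings(ChainRecord("C", strrep("A", 10),
                                        matrix(rnorm(30), 10, 3)))
  expect_error(neighborOrder(small, 1), "21 neighbouring")
})

test_that("neighbour order matches an exhaustive sort oracle on random structures", {
  for (seed in 1:50) {
    ch <- randomChain(25, seed + 600)
    j <- (seed %% 25) + 1
    ord <- neighborOrder(ch, j)
    d <- apply(caCoords(ch), 1, function(p)
      sqrt(sum((p - caCoords(ch)[j, ])^2)))
    oracle <- setdiff(order(d), j)
    expect_identical(ord$order, oracle[seq_along(ord$order)])
  }
})

test_that("spatial product, cumulation and weight factors follow their formulas", {
  ch <- randomChain(30, 71)
  set.seed(72)
  phi <- runif(30, 0, 10)
  j <- 4
  ord <- neighborOrder(ch, j)
  expect_equal(ripf(phi, j, ord, 3), phi[j] * phi[ord$order[3]] / 3)
  expect_equal(racf(phi, j, ord, 2),
               (phi[j] + phi[ord$order[1]] + phi[ord$order[2]]) / 3)
  # cumulation factor is the mean over {central} U k nearest
  for (k in c(1, 7, 20))
    expect_equal(racf(phi, j, ord, k),
                 mean(c(phi[j], phi[ord$order[seq_len(k)]])))
  # constant profile closed forms
  cphi <- rep(3, 30)
  expect_equal(ripf(cphi, j, ord, 5), 9 / 5)
  expect_equal(racf(cphi, j, ord, 20), 3)

  w <- neighborWeights(ord, 20)
  expect_length(w, 21L)
  # weights decrease with distance (same normaliser)
  expect_true(all(diff(w) <= 0))
  expect_equal(rhoFactors(phi, ord, 20),
               w[1:20] * phi[ord$order[1:20]])
})

test_that("equal neighbour distances give the exp(-1) weight", {
  # central residue surrounded by 21 points on a sphere, rest far away
  set.seed(80)
  dirs <- matrix(rnorm(63), 21, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyz <- rbind(c(0, 0, 0), dirs * 5,
               matrix(rnorm(9, mean = 40), 3, 3))
  ch <- ChainRecord("A", strrep("A", 25), xyz)
  ord <- neighborOrder(ch, 1)
  w <- neighborWeights(ord, 20)
  expect_equal(w, rep(exp(-1), 21))
  expect_equal(rhoFactors(rep(2, 25), ord, 20), rep(2 * exp(-1), 20))

  dup <- ChainRecord("B", strrep("A", 25),
                     rbind(c(0, 0, 0), c(0, 0, 0),
                           matrix(rnorm(69, sd = 10), 23, 3)))
  expect_error(neighborWeights(neighborOrder(dup, 1), 20), "duplicate")
})

test_that("residue vectors have the 155 + 305 layout and compose into 920-d pairs", {
  tab <- mkTable(5)
  ch <- randomChain(26, 90)
  prof <- randomProfile(ch, 91)
  U <- chainResidueFeatures(ch, tab, prof)
  expect_identical(dim(U), c(26L, 460L))
  nm <- colnames(U)
  seqBlock <- grepl("^(AAFIPF|AABIPF|AAACF|raw_(hyd|polariz|polarity|sec|codon))",
                    nm)
  expect_identical(sum(grepl("^(AAFIPF|AABIPF|AAACF)", nm)), 150L)
  expect_identical(sum(grepl("^(RIPF|RACF|RHO)", nm)), 300L)
  expect_identical(sum(grepl("^raw_", nm)), 10L)

  u <- residueVector(ch, tab, prof, 3)
  expect_length(u, 460L)
  pv <- pairVector(U[1, ], U[2, ], label = 1L)
  expect_length(pv, 920L)
  expect_identical(attr(pv, "label"), 1L)
  # order-sensitive: chain-1 residue comes first
  expect_false(isTRUE(all.equal(unname(pv),
                                unname(pairVector(U[2, ], U[1, ])))))
  expect_equal(unname(pv[1:460]), unname(U[1, ]))
})

test_that("vectorised residue features match the scalar factor functions", {
  tab <- mkTable(6)
  ch <- randomChain(24, 95)
  prof <- randomProfile(ch, 96)
  U <- chainResidueFeatures(ch, tab, prof)
  phy <- physchemSequences(ch, tab)
  geo <- profileValues(prof)
  for (j in c(1L, 9L, 24L)) {
    ord <- neighborOrder(ch, j)
    manual <- numeric(0)
    for (i in 1:5) {
      blk <- numeric(0)
      for (k in 1:10) blk <- c(blk, aaipf(phy[, i], j, k))
      for (k in 1:10) blk <- c(blk, aaacf(phy[, i], j, k))
      manual <- c(manual, blk)
    }
    manual <- c(manual, phy[j, ])
    for (i in 1:5) {
      blk <- c(vapply(1:20, function(k) ripf(geo[, i], j, ord, k),
                      numeric(1)),
               vapply(1:20, function(k) racf(geo[, i], j, ord, k),
                      numeric(1)),
               rhoFactors(geo[, i], ord, 20))
      manual <- c(manual, blk)
    }
    manual <- c(manual, geo[j, ])
    expect_equal(unname(U[j, ]), unname(manual), tolerance = 1e-12)
  }
})

test_that("structure features are invariant under rigid motion", {
  tab <- mkTable(7)
  ch <- randomChain(28, 97)
  prof <- randomProfile(ch, 98)
  U <- chainResidueFeatures(ch, tab, prof)
  set.seed(99)
  qr_ <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(qr_) < 0) qr_[, 1] <- -qr_[, 1]
  moved <- ChainRecord(ch@chainId, chainSeq(ch),
                       caCoords(ch) %*% qr_ +
                         matrix(rep(c(5, -12, 40), each = 28), 28, 3),
                       residueIds(ch))
  U2 <- chainResidueFeatures(moved, tab, prof)
  expect_equal(U, U2, tolerance = 1e-9)
})

test_that("pair datasets carry labels consistent with the contact labeller", {
  sims <- list(simulateComplex(simulationConfig(seed = 121,
                                                lengthRange = c(25L, 35L))))
  ds <- residuePairDataset(sims, maxPositives = 10, maxNegatives = 20,
                           seed = 1)
  expect_identical(ncol(ds$x), 920L)
  expect_identical(nrow(ds$x), length(ds$y))
  expect_identical(nrow(ds$meta), length(ds$y))
  truth <- interfacePairs(sims[[1]]$labels)
  for (r in sample(nrow(ds$meta), 25)) {
    tp <- truth[[ds$meta$chainPair[r]]]
    isPos <- paste(ds$meta$res1[r], ds$meta$res2[r]) %in%
      paste(tp[, 1], tp[, 2])
    expect_identical(ds$y[r], as.integer(isPos))
  }
})
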