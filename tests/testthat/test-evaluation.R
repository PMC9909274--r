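test_that("confusion metrics follow their closed forms", {
  m <- confusionMetrics(3, 1, 2, 4)
  expect_equal(m[["recall"]], 0.75)
  expect_equal(m[["specificity"]], 2 / 3)
  expect_equal(m[["precision"]], 0.6)
  expect_equal(m[["f1"]], 6 / 9)
  expect_equal(m[["accuracy"]], 0.7)
  expect_equal(m[["mcc"]], (3 * 4 - 2 * 1) / sqrt(5 * 4 * 6 * 5))

  perfect <- confusionMetrics(7, 0, 0, 5)
  expect_true(all(perfect == 1))

  w <- capture_warnings(deg <- confusionMetrics(3, 0, 0, 0))
  expect_true(any(grepl("MCC", w)))        # undefined MCC warns ...
  expect_true(any(grepl("specificity", w)))  # ... as does specificity
  expect_true(is.nan(deg[["mcc"]]))
  expect_true(is.nan(deg[["specificity"]]))
  expect_error(confusionMetrics(0, 0, 0, 0), "zero")
})

test_that("confusion metrics agree with independent formulas on random counts", {
  set.seed(42)
  for (i in 1:1000) {
    cts <- rpois(4, 6) + 1   # keep every denominator positive
    m <- confusionMetrics(cts[1], cts[2], cts[3], cts[4])
    tp <- cts[1]; fn <- cts[2]; fp <- cts[3]; tn <- cts[4]
    expect_equal(unname(m), c(
      tp / (tp + fn), tn / (tn + fp), tp / (tp + fp),
      2 * tp / (2 * tp + fp + fn),
      (tp * tn - fp * fn) /
        sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
      (tp + tn) / sum(cts)))
  }
})

test_that("rank AUC is exact on separations and matches the pairwise oracle", {
  expect_equal(aucScore(c(.9, .8, .4, .2), c(1, 1, 0, 0)), 1)
  expect_error(aucScore(c(.1, .2), c(1, 1)), "both classes")

  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(aucScore(scores, labels), bruteAuc(scores, labels))
  }

  set.seed(8)
  scores <- runif(4000); labels <- rbinom(4000, 1, 0.5)
  expect_lt(abs(aucScore(scores, labels) - 0.5), 0.05)
})

test_that("PT vectors count correct interactions and non-interactions", {
  expect_equal(ptNorm(c(1, 1, 0, 0, 0, 0), c(1, 1, 1, 1, 1, 0)),
               c(a = 2, b = 1, norm = 3))   # the published 1DD3 bookkeeping
  expect_equal(ptNorm(rep(1, 6), c(1, 1, 1, 1, 1, 0)),
               c(a = 5, b = 0, norm = 5))
  expect_equal(ptNorm(c(1, 1, 1, 1, 1, 0), c(1, 1, 1, 1, 1, 0)),
               c(a = 5, b = 1, norm = 6))
  expect_equal(ptNorm(c(0, 0, 0, 0, 0, 1), c(1, 1, 1, 1, 1, 0)),
               c(a = 0, b = 0, norm = 0))
  expect_error(ptNorm(rep(1, 5), rep(1, 6)), "6 chain pairs")
})

test_that("NPIRP vectors count true pairs in the top-t per interface", {
  mkRank <- function(truth, nCand, nHitsInTop, t) {
    # candidates with the first nHitsInTop truths scored highest
    res <- cbind(rep(1:10, each = 10), rep(1:10, times = 10))[1:nCand, ]
    scores <- seq(1, 0.01, length.out = nCand)
    truthM <- res[seq_len(nHitsInTop), , drop = FALSE]
    list(rank = data.frame(res1 = res[, 1], res2 = res[, 2],
                           score = scores),
         truth = truthM)
  }
  r1 <- mkRank(nCand = 40, nHitsInTop = 2, t = 10)
  r2 <- mkRank(nCand = 40, nHitsInTop = 1, t = 10)
  empty <- list(rank = data.frame(res1 = 1:5, res2 = 1:5,
                                  score = seq(0.5, 0.1, length.out = 5)),
                truth = matrix(integer(), 0, 2))
  rankings <- list(r1$rank, r2$rank, empty$rank, empty$rank, empty$rank,
                   empty$rank)
  truths <- list(r1$truth, r2$truth, empty$truth, empty$truth,
                 empty$truth, empty$truth)
  out <- npirp(rankings, truths, t = 10)
  expect_identical(unname(out$n), c(2L, 1L, 0L, 0L, 0L, 0L))
  expect_identical(out$l0, 2L)
  expect_identical(out$l1, 3L)

  # nothing ranked anywhere -> all zero
  out0 <- npirp(rep(list(empty$rank), 6), rep(list(empty$truth), 6), 10)
  expect_identical(c(out0$l0, out0$l1), c(0L, 0L))

  # t beyond the candidates with a perfect ranking retrieves every pair
  allTruth <- lapply(1:6, function(z)
    cbind(rep(1:3, each = 2), rep(1:2, times = 3)))
  allRank <- lapply(1:6, function(z)
    data.frame(res1 = rep(1:3, each = 2), res2 = rep(1:2, times = 3),
               score = seq(1, 0.5, length.out = 6)))
  outAll <- suppressWarnings(npirp(allRank, allTruth, t = 50))
  expect_identical(outAll$l1, 36L)
  expect_identical(outAll$l0, 6L)
})

test_that("Accuracy4t counts complexes by interfaces hit over eligible complexes", {
  expect_equal(accuracy4t(c(2, 0, 6), c(5, 6, 6), z = 1), 100 * 2 / 3)
  expect_equal(accuracy4t(rep(6, 5), rep(6, 5), z = 4), 100)
  expect_error(accuracy4t(c(1, 1), c(2, 2), z = 3), "at least 3")
})

test_that("published test-set tables aggregate to the published accuracies", {
  t3 <- read.table(system.file("extdata", "table3.tsv",
                               package = "tetraPPI"),
                   header = TRUE, sep = "\t", comment.char = "#")
  expect_identical(nrow(t3), 28L)
  expect_identical(sum(t3$a), 139L)
  expect_identical(t3$a + t3$b, t3$pt_l1)

  t5 <- read.table(system.file("extdata", "table5.tsv",
                               package = "tetraPPI"),
                   header = TRUE, sep = "\t", comment.char = "#")
  expect_identical(nrow(t5), 28L)
  native <- rep(6L, 28)   # every complex has >= 2 native interfaces
  expect_equal(round(accuracy4t(t5$l0_t10, native, z = 1), 2), 82.14)
  expect_equal(round(accuracy4t(t5$l0_t10, native, z = 2), 2), 71.43)
  expect_equal(round(accuracy4t(t5$l0_t20, native, z = 2), 2), 89.29)

  # monotonicity: non-increasing in z at fixed t, non-decreasing in t
  for (col in c("l0_t10", "l0_t15", "l0_t20", "l0_t30")) {
    acc <- vapply(1:6, function(z) accuracy4t(t5[[col]], native, z),
                  numeric(1))
    expect_true(all(diff(acc) <= 0))
  }
  for (z in 1:2) {
    accT <- vapply(c("l0_t10", "l0_t15", "l0_t20", "l0_t30"),
                   function(col) accuracy4t(t5[[col]], native, z),
                   numeric(1))
    expect_true(all(diff(accT) >= 0))
  }

  # norms are internally consistent: l1 >= l0, l0 <= 6, l1 <= 6t
  for (t in c(10, 15, 20, 30)) {
    l0 <- t5[[paste0("l0_t", t)]]; l1 <- t5[[paste0("l1_t", t)]]
    expect_true(all(l0 >= 0 & l0 <= 6))
    expect_true(all(l1 >= l0))
    expect_true(all(l1 <= 6 * t))
  }
})
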