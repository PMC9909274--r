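# shared fixtures and independent oracles

# worked-example chain: P = ACAGAHHAALKAYAW with the published ASA
# number sequence (other properties filled with distinct dummies)
workedExampleAsa <- c(6, 4, 7, 5, 7, 8, 2, 8, 9, 3, 7, 11, 10, 14, 15)

workedExampleChain <- function() {
  suppressWarnings(ChainRecord("A", "ACAGAHHAALKAYAW",
                               matrix(seq_len(45), 15, 3)))
}

workedExampleProfile <- function() {
  vals <- cbind(ASA = workedExampleAsa,
                RASA = workedExampleAsa / 20,
                ECA = rev(workedExampleAsa),
                ICA = workedExampleAsa * 2,
                EVA = workedExampleAsa + 1)
  GeometricProfile("A", vals)
}

randomChain <- function(L, seed, chainId = "A") {
  set.seed(seed)
  seqs <- paste(sample(aminoAcidAlphabet(), L, replace = TRUE),
                collapse = "")
  coords <- cbind(cumsum(rnorm(L, 1.5, 2)), rnorm(L, sd = 4),
                  rnorm(L, sd = 4))
  suppressWarnings(ChainRecord(chainId, seqs, coords))
}

randomProfile <- function(chain, seed) {
  set.seed(seed)
  L <- nchar(chainSeq(chain))
  GeometricProfile(chain@chainId,
                   cbind(ASA = runif(L, 0, 150), RASA = runif(L),
                         ECA = runif(L, 0, 60), ICA = runif(L, 0, 80),
                         EVA = runif(L, 0, 50)))
}

# brute-force all-pairs contact labelling (independent of the
# vectorised implementation)
bruteContacts <- function(complex, cutoff) {
  chs <- chains(complex)
  idx <- tetraPPI:::chainPairIndex()
  lapply(seq_len(6), function(z) {
    a <- caCoords(chs[[idx[z, 1]]]); b <- caCoords(chs[[idx[z, 2]]])
    hits <- NULL
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      if (sqrt(sum((a[i, ] - b[j, ])^2)) <= cutoff)
        hits <- rbind(hits, c(i, j))
    if (is.null(hits)) matrix(integer(), 0, 2) else hits
  })
}

# exhaustive pairwise-comparison AUC oracle (ties count 1/2)
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# circular index oracle using explicit repeated wrapping
bruteWrap <- function(j, off, L) {
  p <- j + off
  while (p < 1) p <- p + L
  while (p > L) p <- p - L
  as.integer(p)
}
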