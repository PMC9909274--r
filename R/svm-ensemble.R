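#' @include residue-features.R
NULL

#' SVM ensemble configuration
#'
#' @param nModels number of ensemble members (default 10).
#' @param negativesPerSet negatives sampled per balanced set; defaults
#'   to the number of positives at training time.
#' @param cost C-classification regularisation parameter (default 1).
#' @param gamma RBF kernel width; `NULL` (default) uses the median
#'   heuristic 1 / (2 * median squared pairwise distance) computed on
#'   the standardised training union.
#' @param disjointSets sample the negative subsets without replacement
#'   across sets (default `FALSE`: sets are drawn independently and may
#'   overlap).
#' @param seed integer RNG seed for sampling and member training.
#' @return A list of class `ensembleConfig`.
#' @export
ensembleConfig <- function(nModels = 10L, negativesPerSet = NULL,
                           cost = 1, gamma = NULL, disjointSets = FALSE,
                           seed = 1L) {
  stopifnot(nModels >= 1L, is.null(negativesPerSet) || negativesPerSet >= 1L,
            cost > 0)
  structure(list(nModels = as.integer(nModels),
                 negativesPerSet = if (is.null(negativesPerSet)) NULL
                   else as.integer(negativesPerSet),
                 cost = cost, gamma = gamma,
                 disjointSets = isTRUE(disjointSets),
                 seed = as.integer(seed)),
            class = "ensembleConfig")
}

#' Under-sample negatives into balanced training sets
#'
#' Builds `nModels` training sets, each holding all positives plus
#' `negativesPerSet` negatives sampled without replacement within the
#' set. By default the sets are drawn independently (negatives may
#' recur across sets); with `disjointSets = TRUE` they partition a
#' single global draw.
#'
#' @param positives,negatives integer row indices of the two classes.
#' @param config an [ensembleConfig()].
#' @return List of `nModels` lists with elements `positives` and
#'   `negatives` (index vectors).
#' @export
undersampleSets <- function(positives, negatives, config = ensembleConfig()) {
  nps <- config$negativesPerSet %||% length(positives)
  if (config$disjointSets && length(negatives) < nps * config$nModels)
    stop("not enough negatives for ", config$nModels,
         " disjoint sets of ", nps)
  if (length(negatives) < nps)
    stop("not enough negatives: need ", nps, ", have ", length(negatives))
  set.seed(config$seed)
  if (config$disjointSets) {
    pool <- sample(negatives, nps * config$nModels)
    negSets <- split(pool, rep(seq_len(config$nModels), each = nps))
  } else {
    negSets <- lapply(seq_len(config$nModels), function(psi)
      sample(negatives, nps))
  }
  lapply(negSets, function(neg)
    list(positives = positives, negatives = unname(neg)))
}

## median-heuristic RBF width on (a subsample of) the scaled features
medianHeuristicGamma <- function(x, maxRows = 300L) {
  if (nrow(x) > maxRows) x <- x[seq_len(maxRows), , drop = FALSE]
  d2 <- stats::dist(x)^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) 1 / ncol(x) else 1 / (2 * med)
}

#' Train the under-sampled SVM ensemble
#'
#' Features are standardised with statistics fitted on the union of the
#' positives and all sampled negatives; each balanced set trains one
#' C-classification RBF SVM with probability outputs (Platt-style
#' calibration as fitted by e1071, seeded for reproducibility).
#'
#' @param x numeric feature matrix (rows = residue pairs, typically 920
#'   columns from [chainPairVectors()]).
#' @param y 0/1 (or logical) interface labels per row.
#' @param config an [ensembleConfig()].
#' @return A fitted [SvmEnsemble-class].
#' @export
trainEnsemble <- function(x, y, config = ensembleConfig()) {
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% 0:1))
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (!length(pos) || !length(neg))
    stop("training data must contain both classes")
  sets <- undersampleSets(pos, neg, config)
  union <- sort(unique(c(pos, unlist(lapply(sets, `[[`, "negatives")))))
  center <- colMeans(x[union, , drop = FALSE])
  scale <- apply(x[union, , drop = FALSE], 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  gamma <- config$gamma
  if (is.null(gamma)) {
    set.seed(config$seed)
    gamma <- medianHeuristicGamma(
      xs[sample(union, min(length(union), 300L)), , drop = FALSE])
  }
  models <- lapply(seq_along(sets), function(psi) {
    rows <- c(sets[[psi]]$positives, sets[[psi]]$negatives)
    set.seed(config$seed + psi)
    e1071::svm(xs[rows, , drop = FALSE],
               factor(y[rows], levels = c(0L, 1L)),
               type = "C-classification", kernel = "radial",
               cost = config$cost, gamma = gamma, probability = TRUE)
  })
  cfg <- unclass(config)
  cfg$gamma <- gamma
  new("SvmEnsemble", models = models, center = center, scale = scale,
      config = cfg)
}

#' Ensemble interface score of residue pairs
#'
#' Each member SVM emits the probability that a pair is an interface
#' pair; the fused score is their sum. By default the sum is divided by
#' the number of members so the reported score lies in [0, 1]; the
#' ranking is identical either way.
#'
#' @param ensemble a fitted [SvmEnsemble-class].
#' @param x feature matrix of pairs to score (unscaled; the stored
#'   scaler is applied).
#' @param raw return the raw sum instead of the normalised mean.
#' @return Numeric score vector.
#' @export
scoreEnsemble <- function(ensemble, x, raw = FALSE) {
  stopifnot(is(ensemble, "SvmEnsemble"))
  xs <- sweep(sweep(x, 2L, ensemble@center), 2L, ensemble@scale, "/")
  total <- rowSums(vapply(ensemble@models, function(m) {
    p <- attr(stats::predict(m, xs, probability = TRUE), "probabilities")
    p[, "1"]
  }, numeric(nrow(xs))))
  if (raw) total else total / length(ensemble@models)
}

#' Top-t interface residue-pair ranking for one chain pair
#'
#' Sorts candidate pairs by descending score; ties are broken by
#' ascending chain-1 then chain-2 residue index, making the ranking
#' deterministic.
#'
#' @param pairs two-column integer matrix of candidate (chain-1,
#'   chain-2) residue indices.
#' @param scores ensemble scores aligned with `pairs`.
#' @param t number of top predictions to return; when `t` exceeds the
#'   number of candidates all are returned with a warning.
#' @return Data.frame with columns `res1`, `res2`, `score`, `rank`.
#' @export
rankInterface <- function(pairs, scores, t) {
  stopifnot(nrow(pairs) == length(scores), t >= 1L)
  if (t > nrow(pairs)) {
    warning("t = ", t, " exceeds the ", nrow(pairs),
            " candidate pairs; returning all")
    t <- nrow(pairs)
  }
  o <- order(-scores, pairs[, 1L], pairs[, 2L])[seq_len(t)]
  data.frame(res1 = pairs[o, 1L], res2 = pairs[o, 2L],
             score = scores[o], rank = seq_len(t))
}
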