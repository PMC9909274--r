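#' @include chain-features.R
NULL

## Small chain-interaction CNN, implemented natively: the network is
## tiny (two conv layers with a handful of kernels on a 20 x 24 input)
## and the whole forward/backward pass is a few dozen small matrix
## operations per sample.

#' CNN configuration
#'
#' @param kernelsConv1,kernelsConv2 number of kernels in the first
#'   (3 x 3) and second (2 x 2) convolution layer; default 2 each.
#' @param learningRate Adam learning rate; default 0.000801. The
#'   hyperparameter search samples in `[1e-5, 1e-3]`.
#' @param batchSize minibatch size; default 128.
#' @param epochs training epochs; default 20.
#' @param seed integer RNG seed controlling initialisation and
#'   minibatch shuffling.
#' @param restarts number of seeded training restarts; networks this
#'   small occasionally collapse into a dead basin, so [trainCnn()]
#'   trains `restarts` independently initialised copies and keeps the
#'   one with the lowest validation loss (training loss when no
#'   validation set is given). Default 1 (single run).
#' @return A list of class `cnnConfig`.
#' @export
cnnConfig <- function(kernelsConv1 = 2L, kernelsConv2 = 2L,
                      learningRate = 0.000801, batchSize = 128L,
                      epochs = 20L, seed = 1L, restarts = 1L) {
  stopifnot(kernelsConv1 >= 1L, kernelsConv2 >= 1L, learningRate > 0,
            batchSize >= 1L, epochs >= 1L, restarts >= 1L)
  structure(list(kernelsConv1 = as.integer(kernelsConv1),
                 kernelsConv2 = as.integer(kernelsConv2),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 restarts = as.integer(restarts)),
            class = "cnnConfig")
}

#' Layer output shapes of the CNN
#'
#' Computed from the convolution arithmetic (valid convolutions of
#' kernel sizes 3 and 2, then 2 x 2 max-pooling with stride 2 and floor
#' division).
#'
#' @param input input spatial dimensions; default `c(20, 24)`.
#' @param config a [cnnConfig()] (for the flattened length).
#' @return List with `input`, `conv1`, `conv2`, `pool` spatial
#'   dimensions and `flat`, the flattened per-sample vector length.
#' @export
cnnShapes <- function(input = c(20L, 24L), config = cnnConfig()) {
  conv1 <- input - 3L + 1L
  conv2 <- conv1 - 2L + 1L
  pool <- conv2 %/% 2L
  list(input = input, conv1 = conv1, conv2 = conv2, pool = pool,
       flat = as.integer(config$kernelsConv2 * prod(pool)))
}

#' Initialise an untrained CNN
#'
#' Architecture: 1 x 20 x 24 input, 3 x 3 valid convolution (k1
#' kernels) + ReLU, 2 x 2 valid convolution (k2 kernels) + ReLU, 2 x 2
#' max-pool stride 2, flatten, fully connected layer to 2 logits.
#' Weights use scaled-normal initialisation, seeded from the config.
#'
#' @param config a [cnnConfig()].
#' @return An untrained [CnnModel-class].
#' @export
buildCnn <- function(config = cnnConfig()) {
  stopifnot(inherits(config, "cnnConfig"))
  set.seed(config$seed)
  k1 <- config$kernelsConv1; k2 <- config$kernelsConv2
  flat <- cnnShapes(config = config)$flat
  he <- function(n, fanIn) stats::rnorm(n, sd = sqrt(2 / fanIn))
  weights <- list(
    W1 = array(he(9 * k1, 9), dim = c(3L, 3L, k1)),
    b1 = rep(0, k1),
    W2 = array(he(4 * k1 * k2, 4 * k1), dim = c(2L, 2L, k1, k2)),
    b2 = rep(0, k2),
    W3 = matrix(he(2 * flat, flat), nrow = 2L),
    b3 = rep(0, 2))
  new("CnnModel", weights = weights, config = unclass(config),
      history = data.frame(epoch = integer(), loss = numeric()))
}

## valid 2-D cross-correlation of X with kernel K
convValid <- function(X, K) {
  nr <- nrow(X) - nrow(K) + 1L
  nc <- ncol(X) - ncol(K) + 1L
  out <- matrix(0, nr, nc)
  for (a in seq_len(nrow(K)))
    for (b in seq_len(ncol(K)))
      out <- out + K[a, b] * X[a:(a + nr - 1L), b:(b + nc - 1L)]
  out
}

## 2x2 max pool, stride 2, floor; returns pooled values and the offset
## (1..4, fixed tie order) of the argmax inside each window
maxPool2 <- function(M) {
  nr <- nrow(M) %/% 2L
  nc <- ncol(M) %/% 2L
  r <- seq(1L, 2L * nr, 2L); cc <- seq(1L, 2L * nc, 2L)
  s <- list(M[r, cc, drop = FALSE], M[r + 1L, cc, drop = FALSE],
            M[r, cc + 1L, drop = FALSE], M[r + 1L, cc + 1L, drop = FALSE])
  pooled <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  which <- matrix(1L, nr, nc)
  for (o in 4:1) which[s[[o]] == pooled] <- o
  list(pooled = pooled, argmax = which, nr = nr, nc = nc)
}

## scatter pooled-gradient G back through the recorded argmax offsets
maxPoolBackward <- function(G, pool, dimIn) {
  out <- matrix(0, dimIn[1L], dimIn[2L])
  r <- seq(1L, 2L * pool$nr, 2L); cc <- seq(1L, 2L * pool$nc, 2L)
  dr <- c(0L, 1L, 0L, 1L); dc <- c(0L, 0L, 1L, 1L)
  for (o in 1:4) {
    sel <- pool$argmax == o
    if (!any(sel)) next
    sub <- out[r + dr[o], cc + dc[o], drop = FALSE]
    sub[sel] <- sub[sel] + G[sel]
    out[r + dr[o], cc + dc[o]] <- sub
  }
  out
}

## forward pass for one 20 x 24 sample; returns intermediates for
## backprop when keep = TRUE
cnnForward <- function(weights, X, keep = FALSE) {
  k1 <- length(weights$b1); k2 <- length(weights$b2)
  O1 <- lapply(seq_len(k1), function(k)
    convValid(X, weights$W1[, , k]) + weights$b1[k])
  A1 <- lapply(O1, pmax, 0)
  O2 <- lapply(seq_len(k2), function(k) {
    acc <- 0
    for (c in seq_len(k1))
      acc <- acc + convValid(A1[[c]], weights$W2[, , c, k])
    acc + weights$b2[k]
  })
  A2 <- lapply(O2, pmax, 0)
  pools <- lapply(A2, maxPool2)
  v <- unlist(lapply(pools, function(p) as.vector(p$pooled)))
  z <- as.vector(weights$W3 %*% v + weights$b3)
  zs <- z - max(z)
  p <- exp(zs) / sum(exp(zs))
  if (!keep) return(list(prob = p, logits = z))
  list(prob = p, logits = z, X = X, O1 = O1, A1 = A1, O2 = O2, A2 = A2,
       pools = pools, v = v)
}

## backward pass; y in {0, 1}; returns per-sample weight gradients
cnnBackward <- function(weights, fw, y) {
  k1 <- length(weights$b1); k2 <- length(weights$b2)
  dz <- fw$prob
  dz[y + 1L] <- dz[y + 1L] - 1
  dW3 <- dz %o% fw$v
  db3 <- dz
  dv <- as.vector(crossprod(weights$W3, dz))
  nPool <- length(fw$pools[[1L]]$pooled)
  dW2 <- array(0, dim = dim(weights$W2)); db2 <- numeric(k2)
  dA1 <- lapply(seq_len(k1), function(c) matrix(0, nrow(fw$A1[[1L]]),
                                                ncol(fw$A1[[1L]])))
  for (k in seq_len(k2)) {
    dP <- matrix(dv[((k - 1L) * nPool + 1L):(k * nPool)],
                 fw$pools[[k]]$nr, fw$pools[[k]]$nc)
    dA2 <- maxPoolBackward(dP, fw$pools[[k]], dim(fw$A2[[k]]))
    dO2 <- dA2 * (fw$O2[[k]] > 0)
    db2[k] <- sum(dO2)
    nr <- nrow(dO2); nc <- ncol(dO2)
    for (c in seq_len(k1)) {
      for (a in 1:2) for (b in 1:2) {
        dW2[a, b, c, k] <- dW2[a, b, c, k] +
          sum(dO2 * fw$A1[[c]][a:(a + nr - 1L), b:(b + nc - 1L)])
        dA1[[c]][a:(a + nr - 1L), b:(b + nc - 1L)] <-
          dA1[[c]][a:(a + nr - 1L), b:(b + nc - 1L)] +
          weights$W2[a, b, c, k] * dO2
      }
    }
  }
  dW1 <- array(0, dim = dim(weights$W1)); db1 <- numeric(k1)
  for (k in seq_len(k1)) {
    dO1 <- dA1[[k]] * (fw$O1[[k]] > 0)
    db1[k] <- sum(dO1)
    nr <- nrow(dO1); nc <- ncol(dO1)
    for (a in 1:3) for (b in 1:3)
      dW1[a, b, k] <- dW1[a, b, k] +
        sum(dO1 * fw$X[a:(a + nr - 1L), b:(b + nc - 1L)])
  }
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

adamInit <- function(weights)
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)

adamStep <- function(weights, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mHat <- state$m[[nm]] / (1 - beta1^state$t)
    vHat <- state$v[[nm]] / (1 - beta2^state$t)
    weights[[nm]] <- weights[[nm]] - lr * mHat / (sqrt(vHat) + eps)
  }
  list(weights = weights, state = state)
}

asMapMatrix <- function(m) {
  if (is(m, "FeatureMap")) featureMatrix(m) else as.matrix(m)
}

mapLabels <- function(maps, labels) {
  if (!is.null(labels)) return(as.integer(labels))
  vapply(maps, function(m)
    if (is(m, "FeatureMap")) sampleLabel(m) else NA_integer_, integer(1))
}

#' Train the chain-interaction CNN
#'
#' Cross-entropy loss over the two softmax outputs, optimised with Adam
#' (conventional moment parameters 0.9/0.999, epsilon 1e-8) in shuffled
#' minibatches. Training is deterministic given the config seed. When a
#' validation set is supplied, the weights with the lowest validation
#' loss across epochs are retained.
#'
#' @param maps list of [FeatureMap-class] objects (or bare 20 x 24
#'   matrices).
#' @param labels integer 0/1 labels; taken from the maps when `NULL`.
#' @param config a [cnnConfig()].
#' @param validation,validationLabels optional validation set in the
#'   same format.
#' @return A fitted [CnnModel-class] with per-epoch loss history.
#' @export
trainCnn <- function(maps, labels = NULL, config = cnnConfig(),
                     validation = NULL, validationLabels = NULL) {
  X <- lapply(maps, asMapMatrix)
  y <- mapLabels(maps, labels)
  if (!length(X)) stop("empty training set")
  if (length(y) != length(X) || anyNA(y))
    stop("labels missing for some training samples")
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  valX <- if (!is.null(validation)) lapply(validation, asMapMatrix)
  valY <- if (!is.null(validation)) mapLabels(validation, validationLabels)
  runs <- lapply(seq_len(config$restarts %||% 1L), function(r) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * (r - 1L)
    trainCnnOnce(X, y, cfg, valX, valY)
  })
  crit <- vapply(runs, `[[`, numeric(1), "criterion")
  winner <- runs[[which.min(crit)]]
  new("CnnModel", weights = winner$weights, config = unclass(config),
      history = winner$history)
}

## one seeded optimisation run
trainCnnOnce <- function(X, y, config, valX, valY) {
  model <- buildCnn(structure(config, class = "cnnConfig"))
  weights <- model@weights
  state <- adamInit(weights)
  n <- length(X)
  hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_)
  if (!is.null(valX)) hist$valLoss <- NA_real_
  bestVal <- Inf; bestWeights <- weights
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = config$batchSize)) {
      batch <- ord[start:min(start + config$batchSize - 1L, n)]
      grads <- NULL
      bl <- 0
      for (i in batch) {
        fw <- cnnForward(weights, X[[i]], keep = TRUE)
        bl <- bl - log(max(fw$prob[y[i] + 1L], 1e-12))
        g <- cnnBackward(weights, fw, y[i])
        grads <- if (is.null(grads)) g else
          Map(function(a, b) a + b, grads, g)
      }
      grads <- lapply(grads, function(g) g / length(batch))
      upd <- adamStep(weights, grads, state, config$learningRate)
      weights <- upd$weights; state <- upd$state
      losses <- c(losses, bl / length(batch))
    }
    hist$loss[epoch] <- mean(losses)
    if (!is.null(valX)) {
      vl <- mean(vapply(seq_along(valX), function(i)
        -log(max(cnnForward(weights, valX[[i]])$prob[valY[i] + 1L],
                 1e-12)), numeric(1)))
      hist$valLoss[epoch] <- vl
      if (vl < bestVal) { bestVal <- vl; bestWeights <- weights }
    }
  }
  list(weights = if (is.null(valX)) weights else bestWeights,
       history = hist,
       criterion = if (is.null(valX)) hist$loss[config$epochs] else bestVal)
}

#' Interaction probabilities for feature maps
#'
#' @param model a fitted [CnnModel-class].
#' @param maps list of [FeatureMap-class] objects or 20 x 24 matrices.
#' @return Numeric vector of P(interacting) from the softmax outputs.
#' @export
predictCnn <- function(model, maps) {
  stopifnot(is(model, "CnnModel"))
  vapply(lapply(maps, asMapMatrix), function(x)
    cnnForward(model@weights, x)$prob[2L], numeric(1))
}

#' Predict the six chain-pair interactions of one complex
#'
#' @param model a fitted [CnnModel-class].
#' @param maps the six [FeatureMap-class] samples of one complex.
#' @param trueLabels optional 0/1 vector of the six true interactions;
#'   taken from the maps when available.
#' @param threshold probability threshold for the hard label.
#' @return Data.frame with columns `chainPair`, `probability`,
#'   `predicted` (and `label` when known). When labels are known the
#'   attribute `PT` holds `c(a, b, norm)`: correctly predicted
#'   interactions, correctly predicted non-interactions, and their sum.
#' @export
predictComplex <- function(model, maps, trueLabels = NULL,
                           threshold = 0.5) {
  if (length(maps) != 6L)
    stop("a tetramer complex yields exactly 6 chain-pair samples, got ",
         length(maps))
  prob <- predictCnn(model, maps)
  pn <- vapply(seq_along(maps), function(i)
    if (is(maps[[i]], "FeatureMap")) maps[[i]]@chainPair else
      paste0("pair", i), character(1))
  out <- data.frame(chainPair = pn, probability = prob,
                    predicted = as.integer(prob >= threshold))
  y <- mapLabels(maps, trueLabels)
  if (!anyNA(y)) {
    out$label <- y
    attr(out, "PT") <- ptNorm(out$predicted, y)
  }
  out
}

#' Seeded random hyperparameter search
#'
#' Samples `budget` configurations (learning rate log-uniform in
#' `[1e-5, 1e-3]`, kernel counts 1..4 per layer), trains each on the
#' training maps and returns the configuration with the highest
#' validation AUC. Ties are broken by lower learning rate, then fewer
#' kernels. Candidate b of a budget-b search is always identical to
#' candidate b of a larger search with the same seed (nested sampling).
#'
#' @param maps,labels training feature maps and 0/1 labels.
#' @param validation,validationLabels validation set used for AUC.
#' @param budget number of sampled configurations (>= 1).
#' @param seed integer seed for the candidate draw.
#' @param epochs epochs per candidate (default 20).
#' @return The winning [cnnConfig()]; attribute `trace` holds a
#'   data.frame of all candidates with their validation AUC.
#' @export
searchHyperparams <- function(maps, labels = NULL, validation,
                              validationLabels = NULL, budget = 10L,
                              seed = 1L, epochs = 20L) {
  stopifnot(budget >= 1L)
  valY <- mapLabels(validation, validationLabels)
  trace <- data.frame(candidate = seq_len(budget), learningRate = NA_real_,
                      kernelsConv1 = NA_integer_,
                      kernelsConv2 = NA_integer_, auc = NA_real_)
  best <- NULL; bestKey <- NULL
  for (b in seq_len(budget)) {
    set.seed(seed + b)
    lr <- 10^stats::runif(1, -5, -3)
    k1 <- sample(1:4, 1); k2 <- sample(1:4, 1)
    cfg <- cnnConfig(kernelsConv1 = k1, kernelsConv2 = k2,
                     learningRate = lr, epochs = epochs,
                     seed = seed + b)
    fit <- trainCnn(maps, labels, cfg)
    auc <- aucScore(predictCnn(fit, validation), valY)
    trace[b, 2:5] <- c(lr, k1, k2, auc)
    key <- c(-auc, lr, k1 + k2)   # lexicographic preference
    if (is.null(best) ||
        (key[1] < bestKey[1] ||
         (key[1] == bestKey[1] &&
          (key[2] < bestKey[2] ||
           (key[2] == bestKey[2] && key[3] < bestKey[3]))))) {
      best <- cfg; bestKey <- key
    }
  }
  attr(best, "trace") <- trace
  best
}
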