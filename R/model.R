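# Feature vectors are canonical shell-major with the combination fastest;
# the network consumes column-major (shell fastest) image vectors.  This
# permutation converts one sample row to the layer layout.
.imagePerm <- function(H, W) {
  h <- rep(seq_len(H), W)
  w <- rep(seq_len(W), each = H)
  (h - 1L) * W + w
}

#' Build an untrained CNN regressor
#'
#' Layer sequence: input image (N x width x 1) -> three convolution + ReLU
#' blocks -> flatten -> two dense blocks (dense -> batch-norm -> ReLU, L2 on
#' the dense weights) -> linear dense(1) output.  Weights are He-initialised
#' from the given seed, so two builds with the same seed are bitwise
#' identical.
#'
#' @param inputDim integer(2): image rows (number of shells) and columns
#'   (combinations; 168, or 167 after one ablation).
#' @param config a \linkS4class{TrainConfig}.
#' @param seed RNG seed for the weight initialisation (default
#'   \code{config@seedBase}).
#' @return An untrained \linkS4class{ShellCNN}.
#' @export
#' @examples
#' m <- buildModel(c(10L, 168L), trainConfig(convFilters = c(4, 8, 16),
#'                                           fcWidths = c(32, 16)))
#' countParameters(m)
buildModel <- function(inputDim, config = trainConfig(),
                       seed = config@seedBase) {
  stopifnot(length(inputDim) == 2L)
  inputDim <- as.integer(inputDim)
  validObject(config)
  H <- inputDim[1L]; W <- inputDim[2L]; C <- 1L
  plans <- list()
  for (f in config@convFilters) {
    plan <- .convPlan(H, W, C, config@kernelSize, config@stride,
                      config@padding)
    plans[[length(plans) + 1L]] <- plan
    H <- plan$Hout; W <- plan$Wout; C <- f
  }
  flat <- H * W * C
  params <- withr::with_seed(as.integer(seed), {
    p <- list(conv = list(), dense = list(), out = NULL)
    Cin <- 1L
    for (f in config@convFilters) {
      kkc <- config@kernelSize^2 * Cin
      p$conv[[length(p$conv) + 1L]] <- list(
        W = matrix(stats::rnorm(f * kkc, sd = sqrt(2 / kkc)), f, kkc),
        b = numeric(f))
      Cin <- f
    }
    nin <- flat
    for (wdt in config@fcWidths) {
      p$dense[[length(p$dense) + 1L]] <- list(
        W = matrix(stats::rnorm(wdt * nin, sd = sqrt(2 / nin)), wdt, nin),
        b = numeric(wdt), gamma = rep(1, wdt), beta = numeric(wdt),
        runMean = numeric(wdt), runVar = rep(1, wdt))
      nin <- wdt
    }
    p$out <- list(W = matrix(stats::rnorm(nin, sd = sqrt(1 / nin)), 1L, nin),
                  b = 0)
    p
  })
  new("ShellCNN", inputDim = inputDim, config = config, params = params,
      plans = plans, seed = as.integer(seed), trained = FALSE,
      history = data.frame())
}

#' Number of trainable parameters
#'
#' Convolution and dense weights and biases plus the batch-norm gain/offset
#' pairs (running statistics are not trainable and are not counted).
#'
#' @param x a \linkS4class{ShellCNN}.
#' @return integer count.
#' @export
setGeneric("countParameters", function(x) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "ShellCNN", function(x) {
  p <- x@params
  n <- sum(vapply(p$conv, function(l) length(l$W) + length(l$b), 0))
  n <- n + sum(vapply(p$dense, function(l)
    length(l$W) + length(l$b) + length(l$gamma) + length(l$beta), 0))
  as.integer(n + length(p$out$W) + length(p$out$b))
})

# Full forward pass.  X: B x (H*W) feature rows (already standardized).
# Returns predictions; with cache = TRUE also every intermediate needed by
# the backward pass.
.forwardCNN <- function(model, X, training = FALSE, cache = FALSE) {
  cfg <- model@config
  perm <- .imagePerm(model@inputDim[1L], model@inputDim[2L])
  A <- t(X[, perm, drop = FALSE])                 # D x B
  caches <- list(convIn = list(), convPre = list(), dense = list())
  for (i in seq_along(model@plans)) {
    if (cache) caches$convIn[[i]] <- A
    Z <- .convForward(A, model@params$conv[[i]]$W, model@params$conv[[i]]$b,
                      model@plans[[i]])
    if (cache) caches$convPre[[i]] <- Z
    A <- pmax(Z, 0)
  }
  if (cache) caches$flat <- A
  for (i in seq_along(model@params$dense)) {
    fw <- .denseBnForward(A, model@params$dense[[i]], training,
                          cfg@bnMomentum)
    model@params$dense[[i]] <- fw$layer          # running stats update
    if (cache) caches$dense[[i]] <- fw$cache
    A <- fw$out
  }
  pred <- as.numeric(model@params$out$W %*% A + model@params$out$b)
  if (cache) list(pred = pred, caches = caches, lastAct = A, model = model)
  else list(pred = pred, model = model)
}

# Validation loss with the same degenerate-batch guard as training.
.safeCompositeLoss <- function(pred, obs, alpha) {
  rm <- sqrt(mean((obs - pred)^2))
  if (stats::sd(pred) <= 1e-12 || stats::sd(obs) <= 1e-12)
    return(alpha + (1 - alpha) * rm)
  alpha * (1 - stats::cor(pred, obs)) + (1 - alpha) * rm
}

#' Early-stopping rule over a validation-loss history
#'
#' Training stops once the validation loss has failed to improve on the
#' best value so far by at least \code{minDelta} for \code{patience}
#' consecutive epochs.  Pure function of the loss sequence, used by
#' [trainModel()] and directly testable.
#'
#' @param valLosses numeric vector, one value per epoch in order.
#' @param patience consecutive non-improving epochs tolerated.
#' @param minDelta minimum improvement that resets the counter.
#' @return the 1-based epoch at which training stops, or \code{NA} if the
#'   sequence never triggers the rule.
#' @export
#' @examples
#' earlyStopEpoch(c(1, 0.5, rep(0.4999, 25)), patience = 20, minDelta = 0.001)
earlyStopEpoch <- function(valLosses, patience = 20L, minDelta = 0.001) {
  best <- Inf
  wait <- 0L
  for (ep in seq_along(valLosses)) {
    if (best - valLosses[ep] >= minDelta) {
      best <- valLosses[ep]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(ep)
    }
    if (valLosses[ep] < best) best <- valLosses[ep]
  }
  NA_integer_
}

#' Train one CNN regressor
#'
#' Minibatch SGD on the configured objective (composite loss per batch by
#' default), L2 weight decay on the dense weights, per-epoch validation on
#' the full validation set with the composite loss, early stopping
#' ([earlyStopEpoch()] semantics) and best-checkpoint selection: the
#' returned weights are those of the epoch with minimum validation loss.
#'
#' @param model an untrained \linkS4class{ShellCNN} from [buildModel()].
#' @param Xtr,ytr standardized training features (rows = complexes, canonical
#'   columns) and pKd labels.
#' @param Xval,yval validation partition, standardized with the training
#'   statistics.
#' @param seed run seed governing shuffling (default: the model's seed).
#' @param verbose print per-epoch losses.
#' @return the trained \linkS4class{ShellCNN} with its \code{history} filled.
#' @export
trainModel <- function(model, Xtr, ytr, Xval, yval, seed = model@seed,
                       verbose = FALSE) {
  stopifnot(is(model, "ShellCNN"), nrow(Xtr) == length(ytr),
            nrow(Xval) == length(yval),
            ncol(Xtr) == prod(model@inputDim),
            ncol(Xval) == prod(model@inputDim))
  cfg <- model@config
  nTr <- nrow(Xtr)
  bestLoss <- Inf
  bestParams <- model@params
  wait <- 0L
  waitDecay <- 0L
  lr <- cfg@learningRate
  hist <- vector("list", cfg@maxEpochs)
  # start the linear output at the training-label mean so the first epochs
  # fit structure rather than the offset
  if (!model@trained && identical(model@params$out$b, 0))
    model@params$out$b <- mean(ytr)
  withr::local_seed(as.integer(seed))
  for (epoch in seq_len(cfg@maxEpochs)) {
    ord <- sample.int(nTr)
    batchLosses <- c()
    for (s in seq(1L, nTr, by = cfg@batchSize)) {
      rows <- ord[s:min(nTr, s + cfg@batchSize - 1L)]
      if (length(rows) < 2L) next        # a 1-sample tail has no R term
      fw <- .forwardCNN(model, Xtr[rows, , drop = FALSE], training = TRUE,
                        cache = TRUE)
      model <- fw$model
      if (any(!is.finite(fw$pred)))
        stop("NaN/Inf predictions at epoch ", epoch,
             "; learning rate ", cfg@learningRate,
             ", feature scale max |x| = ", max(abs(Xtr)),
             ". Lower the learning rate or check standardization.")
      lg <- .lossGradient(fw$pred, ytr[rows], cfg@alpha, cfg@lossMode)
      if (!is.finite(lg$loss))
        stop("NaN/Inf training loss at epoch ", epoch,
             "; learning rate ", cfg@learningRate,
             ", feature scale max |x| = ", max(abs(Xtr)),
             ". Lower the learning rate or check standardization.")
      batchLosses <- c(batchLosses, lg$loss)
      model <- .sgdStep(model, fw, lg$grad, lr)
    }
    valPred <- .forwardCNN(model, Xval)$pred
    valLoss <- .safeCompositeLoss(valPred, yval, cfg@alpha)
    hist[[epoch]] <- c(epoch = epoch, trainLoss = mean(batchLosses),
                       valLoss = valLoss)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      mean(batchLosses), valLoss))
    improved <- bestLoss - valLoss >= cfg@minDelta
    if (improved) {
      wait <- 0L
      waitDecay <- 0L
    } else {
      wait <- wait + 1L
      waitDecay <- waitDecay + 1L
    }
    if (valLoss < bestLoss) {
      bestLoss <- valLoss
      bestParams <- model@params
    }
    if (wait >= cfg@patience) break
    if (cfg@lrDecay < 1 && waitDecay >= cfg@decayEvery) {
      lr <- lr * cfg@lrDecay
      waitDecay <- 0L
    }
  }
  model@params <- bestParams
  model@trained <- TRUE
  model@history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null,
                                                             TRUE)]))
  model
}

# One SGD update from a cached forward pass.  L2 decay applies to the two
# dense hidden layers only (not convolutions, not the output layer).
.sgdStep <- function(model, fw, dPred, lr = model@config@learningRate) {
  cfg <- model@config
  p <- model@params
  dA <- p$out$W[1L, ] %o% dPred                 # grad into last activation
  dOutW <- dPred %*% t(fw$lastAct)
  p$out$W <- p$out$W - lr * dOutW
  p$out$b <- p$out$b - lr * sum(dPred)
  for (i in rev(seq_along(p$dense))) {
    bw <- .denseBnBackward(p$dense[[i]], fw$caches$dense[[i]], dA)
    p$dense[[i]]$W <- p$dense[[i]]$W -
      lr * (bw$dW + cfg@l2Weight * p$dense[[i]]$W)
    p$dense[[i]]$b <- p$dense[[i]]$b - lr * bw$db
    p$dense[[i]]$gamma <- p$dense[[i]]$gamma - lr * bw$dgamma
    p$dense[[i]]$beta <- p$dense[[i]]$beta - lr * bw$dbeta
    dA <- bw$dX
  }
  for (i in rev(seq_along(p$conv))) {
    dA <- dA * (fw$caches$convPre[[i]] > 0)     # ReLU gate
    bw <- .convBackward(fw$caches$convIn[[i]], p$conv[[i]]$W,
                        model@plans[[i]], dA, needDx = i > 1L)
    p$conv[[i]]$W <- p$conv[[i]]$W - lr * bw$dW
    p$conv[[i]]$b <- p$conv[[i]]$b - lr * bw$db
    dA <- bw$dX
  }
  model@params <- p
  model
}

#' Predict pKd with a trained model
#'
#' @param object a trained \linkS4class{ShellCNN}.
#' @param X standardized feature rows.
#' @param ... ignored.
#' @return numeric predictions, one per row.
#' @export
setMethod("predict", "ShellCNN", function(object, X, ...) {
  stopifnot(ncol(X) == prod(object@inputDim))
  .forwardCNN(object, X)$pred
})

# --- standardizer -----------------------------------------------------------

#' Fit / apply the feature standardizer
#'
#' \code{fitStandardizer} learns per-column means and population standard
#' deviations (divisor n) from the training rows only.
#' \code{applyStandardizer} centres and scales any rows with those frozen
#' statistics; columns that were constant in training map to exactly 0.
#'
#' @param X training feature matrix (rows = complexes).
#' @return \code{fitStandardizer}: a \linkS4class{Standardizer};
#'   \code{applyStandardizer}: the transformed matrix.
#' @export
#' @examples
#' s <- fitStandardizer(matrix(c(0, 2, 5, 5), 2))
#' applyStandardizer(s, matrix(c(0, 2, 5, 5), 2))
fitStandardizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training rows")
  ctr <- colMeans(X)
  sc <- sqrt(pmax(0, colMeans(X^2) - ctr^2))    # population SD
  new("Standardizer", center = as.numeric(ctr), scale = as.numeric(sc))
}

#' @rdname fitStandardizer
#' @param std a fitted \linkS4class{Standardizer}.
#' @export
applyStandardizer <- function(std, X) {
  stopifnot(is(std, "Standardizer"))
  X <- as.matrix(X)
  if (ncol(X) != length(std@center))
    stop("column count ", ncol(X), " does not match the fitted ",
         length(std@center))
  sc <- ifelse(std@scale == 0, 1, std@scale)
  out <- sweep(sweep(X, 2L, std@center), 2L, sc, "/")
  out[, std@scale == 0] <- 0
  out
}

# --- ensemble ---------------------------------------------------------------

#' Train a seed ensemble
#'
#' Fits the standardizer on the training rows, then trains
#' \code{config@nRuns} independent models from seeds
#' \code{seedBase, seedBase+1, ...}; each member keeps its own
#' validation-best checkpoint.  Ensemble predictions average the members.
#'
#' @param Xtr,ytr raw (unstandardized) training features and labels.
#' @param Xval,yval validation partition (must hold distinct complexes).
#' @param config a \linkS4class{TrainConfig}.
#' @param imageWidth columns of the feature image (168, or 167 after
#'   ablation).
#' @param verbose print progress.
#' @return A \linkS4class{ShellCNNEnsemble}.
#' @export
trainEnsemble <- function(Xtr, ytr, Xval, yval, config = trainConfig(),
                          imageWidth = 168L, verbose = FALSE) {
  if (ncol(Xtr) %% imageWidth != 0L)
    stop("feature count ", ncol(Xtr), " is not a multiple of the image width ",
         imageWidth)
  inputDim <- c(ncol(Xtr) %/% imageWidth, as.integer(imageWidth))
  std <- fitStandardizer(Xtr)
  Ztr <- applyStandardizer(std, Xtr)
  Zval <- applyStandardizer(std, Xval)
  members <- lapply(seq_len(config@nRuns), function(k) {
    seed <- config@seedBase + k - 1L
    if (verbose) message("training ensemble member ", k, " (seed ", seed, ")")
    m <- buildModel(inputDim, config, seed = seed)
    trainModel(m, Ztr, ytr, Zval, yval, seed = seed, verbose = FALSE)
  })
  new("ShellCNNEnsemble", members = members, standardizer = std,
      config = config, inputDim = inputDim)
}

#' Ensemble prediction: per-complex mean over members
#'
#' @param ensemble a \linkS4class{ShellCNNEnsemble}.
#' @param X raw feature rows; the ensemble's own standardizer is applied.
#' @return list with \code{mean} (the ensemble prediction), \code{members}
#'   (matrix, one column per member) and \code{sd} (per-complex spread
#'   across members).
#' @export
ensemblePredict <- function(ensemble, X) {
  stopifnot(is(ensemble, "ShellCNNEnsemble"))
  Z <- applyStandardizer(ensemble@standardizer, X)
  per <- vapply(ensemble@members, function(m) predict(m, Z),
                numeric(nrow(Z)))
  per <- matrix(per, nrow = nrow(Z))
  list(mean = rowMeans(per), members = per, sd = apply(per, 1L, stats::sd))
}

#' @rdname ensemblePredict
#' @param object a \linkS4class{ShellCNNEnsemble}.
#' @param ... ignored.
#' @export
setMethod("predict", "ShellCNNEnsemble", function(object, X, ...) {
  ensemblePredict(object, X)$mean
})

# --- ablation ---------------------------------------------------------------

#' Remove one residue-atom combination from a feature table
#'
#' Drops the combination's column in every shell (N columns), producing the
#' 167-combinations-wide table used to retrain the model for the
#' feature-importance (delta-loss) procedure.
#'
#' @param X feature matrix with canonical \code{<shell>_<res>_<atom>}
#'   column names (or unnamed with \code{spec} supplied).
#' @param spec the \linkS4class{ShellSpec} the table was built with.
#' @param combo the combination, either \code{"CYS_H"} or
#'   \code{c("CYS", "H")}.
#' @return the reduced matrix; attribute \code{imageWidth} is 167 and
#'   attribute \code{removed} names the dropped columns.
#' @export
ablateCombination <- function(X, spec, combo) {
  stopifnot(is(spec, "ShellSpec"))
  if (length(combo) == 2L) combo <- paste(combo, collapse = "_")
  parts <- strsplit(combo, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !parts[1L] %in% residueClasses() ||
      !parts[2L] %in% ligandAtomClasses())
    stop("unknown combination '", combo, "'")
  cn <- colnames(X)
  if (is.null(cn)) {
    if (ncol(X) != 168L * spec@nShells)
      stop("unnamed table with unexpected column count")
    cn <- featureNames(spec)
  }
  drop <- grepl(paste0("^[0-9]+_", combo, "$"), cn)
  if (sum(drop) != spec@nShells)
    stop("expected ", spec@nShells, " columns for '", combo, "', found ",
         sum(drop))
  out <- X[, !drop, drop = FALSE]
  attr(out, "imageWidth") <- 167L
  attr(out, "removed") <- cn[drop]
  out
}
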