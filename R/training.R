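## Two-phase optimization: contrastive prior learning over labeled pairs,
## then transfer learning of the classifier head with the trunk frozen.

#' Training configuration
#'
#' @param batch_size mini-batch size, counted in PAIRS during prior learning
#'   (the studied full-scale settings are 500, 3,000 and 5,000; scaled-down
#'   runs use smaller values).  During transfer learning batches are single
#'   subjects and the effective size is capped at the training-set size.
#' @param learning_rate Adam step size (default 1e-4; may be 0 for testing
#'   the stopping rule).
#' @param patience epochs without validation improvement before stopping
#'   (default 10).
#' @param max_epochs hard epoch cap (default 200, >= 1).
#' @param transfer_max_epochs epoch cap for the transfer phase (default:
#'   same as `max_epochs`).  Transfer epochs are far cheaper than prior
#'   epochs (head-only updates), so a larger cap is often appropriate in
#'   scaled-down runs.
#' @param lambda_weight entropy coefficient lambda of the IIC loss
#'   (default 5.0).
#' @param c_oc overclustering-head class count used when a network is built
#'   from this configuration (default 10); when training an existing model
#'   its own head width takes precedence.
#' @param seed integer driving pair shuffling and validation-pair selection.
#' @param val_pair_cap maximum number of fixed validation pairs used for the
#'   early-stopping criterion (default 1000).
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(batch_size = 500L, learning_rate = 1e-4,
                        patience = 10L, max_epochs = 200L,
                        transfer_max_epochs = max_epochs,
                        lambda_weight = 5.0, c_oc = 10L, seed = 1L,
                        val_pair_cap = 1000L) {
  .assertScalarNumber(batch_size, "batch_size", lower = 1)
  .assertScalarNumber(learning_rate, "learning_rate", lower = 0)
  .assertScalarNumber(patience, "patience", lower = 1)
  .assertScalarNumber(max_epochs, "max_epochs", lower = 1)
  .assertScalarNumber(transfer_max_epochs, "transfer_max_epochs", lower = 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 transfer_max_epochs = as.integer(transfer_max_epochs),
                 lambda_weight = lambda_weight, c_oc = as.integer(c_oc),
                 seed = as.integer(seed),
                 val_pair_cap = as.integer(val_pair_cap)),
            class = "TrainConfig")
}

#' Pool of all unordered subject pairs, shuffled
#'
#' The pair pool for one epoch: every unordered pair \{i < j\} of the m
#' training subjects in a seeded random order (m(m-1)/2 pairs).  The pool is
#' regenerated (reshuffled) each epoch.
#'
#' @param n_records number of training subjects (>= 2), or a vector of
#'   indices.
#' @return two-column integer matrix of index pairs, one row per pair.
#' @export
makePairPool <- function(n_records) {
  idx <- if (length(n_records) == 1L) seq_len(n_records) else n_records
  m <- length(idx)
  if (m < 2L) stop("need at least 2 records to form pairs", call. = FALSE)
  pairs <- t(utils::combn(m, 2L))
  ord <- sample.int(nrow(pairs))
  cbind(i = idx[pairs[ord, 1L]], j = idx[pairs[ord, 2L]])
}

#' Draw the next mini-batch of pairs
#'
#' Removes and returns the next `batch_size` pairs from the pool; when fewer
#' than `batch_size` remain the epoch is over and the partial remainder is
#' discarded (an epoch terminates on failure to extract a full mini-batch).
#'
#' @param pool state list created by `list(pool = makePairPool(m), pos = 1L)`
#'   or returned by a previous call.
#' @param batch_size pairs per batch.
#' @return list with `batch` (matrix of pairs or NULL), `exhausted`
#'   (logical) and the updated pool state.
#' @export
nextMinibatch <- function(pool, batch_size) {
  if (is.matrix(pool)) pool <- list(pairs = pool, pos = 1L)
  remaining <- nrow(pool$pairs) - pool$pos + 1L
  if (remaining < batch_size)
    return(list(batch = NULL, exhausted = TRUE, pool = pool))
  take <- pool$pos:(pool$pos + batch_size - 1L)
  pool$pos <- pool$pos + batch_size
  list(batch = pool$pairs[take, , drop = FALSE], exhausted = FALSE,
       pool = pool)
}

## Fixed, seeded validation pair set for the early-stopping criterion.
.validationPairs <- function(nVal, cap, seed) {
  .withSeed(seed, {
    p <- makePairPool(nVal)
    p[seq_len(min(nrow(p), cap)), , drop = FALSE]
  })
}

## Prior (or validation) loss of a set of pairs, evaluation mode.
.priorLossEval <- function(params, buffers, X, y, pairs, cfg) {
  X1 <- X[pairs[, 1L], , drop = FALSE]
  X2 <- X[pairs[, 2L], , drop = FALSE]
  same <- y[pairs[, 1L]] == y[pairs[, 2L]]
  fw <- .trunkForward(params, buffers, rbind(X1, X2), training = FALSE)
  n <- nrow(X1)
  m <- .headForward(params, fw$A, "iic")
  o <- .headForward(params, fw$A, "oc")
  priorPairLoss(m[seq_len(n), , drop = FALSE],
                m[n + seq_len(n), , drop = FALSE],
                o[seq_len(n), , drop = FALSE],
                o[n + seq_len(n), , drop = FALSE], same, cfg)
}

.newHistory <- function() {
  data.frame(epoch = integer(0), iterations = integer(0),
             train_loss = numeric(0), val_loss = numeric(0))
}

#' Contrastive prior learning
#'
#' Trains the trunk and the two IIC heads with Adam on the pair loss
#' ([priorPairLoss()]): per epoch the pool of all unordered training pairs is
#' reshuffled and consumed in mini-batches of `batch_size` pairs (partial
#' remainder discarded).  After each epoch the loss on a fixed, seeded
#' validation pair set is computed in evaluation mode; training stops when it
#' fails to improve for `patience` epochs, and the parameters (and
#' batch-normalization buffers) of the best epoch are returned.  The
#' classifier head receives no gradient in this phase.
#'
#' @param model an [EiicModel-class] (unfrozen).
#' @param Xtrain,ytrain standardized training features (subjects x features)
#'   and binary labels; both classes must be present.
#' @param Xval,yval validation features and labels.
#' @param config a [trainConfig()].
#' @return list with `model` (best-epoch parameters) and `history`, a
#'   data.frame of per-epoch train/validation losses with attributes
#'   `best_epoch` and `stopped_early`.
#' @export
trainPrior <- function(model, Xtrain, ytrain, Xval, yval, config) {
  if (length(unique(ytrain)) < 2L)
    stop("prior learning requires both classes in the training set",
         call. = FALSE)
  ## the network's own overclustering width defines the loss config
  cfg <- iicConfig(lambda_weight = config$lambda_weight,
                   c_oc = model@spec$c_oc)
  .trainLoop(model, Xtrain, ytrain, Xval, yval, config, phase = "prior",
             iicCfg = cfg)
}

#' Transfer learning of the classifier head
#'
#' With the trunk frozen ([freezeTrunk()]), trains only the classifier
#' head's linear map with Adam on the mean cross entropy over subject
#' mini-batches; the trunk runs in evaluation mode so its running statistics
#' stay fixed.  Early stopping on validation cross entropy with the same
#' patience; best-epoch parameters returned.
#'
#' @inheritParams trainPrior
#' @export
trainTransfer <- function(model, Xtrain, ytrain, Xval, yval, config) {
  if (!model@frozen)
    stop("transfer learning requires a frozen trunk (see freezeTrunk)",
         call. = FALSE)
  if (!is.null(config$transfer_max_epochs))
    config$max_epochs <- config$transfer_max_epochs
  .trainLoop(model, Xtrain, ytrain, Xval, yval, config, phase = "transfer")
}

#' Supervised end-to-end training (no-prior ablation)
#'
#' Trains the whole network (trunk + classifier head) with cross entropy
#' only, skipping the contrastive prior phase.  Serves as the
#' supervised-only ablation against which the two-phase procedure is
#' compared.
#'
#' @inheritParams trainPrior
#' @export
trainSupervised <- function(model, Xtrain, ytrain, Xval, yval, config) {
  if (length(unique(ytrain)) < 2L)
    stop("supervised training requires both classes", call. = FALSE)
  .trainLoop(model, Xtrain, ytrain, Xval, yval, config, phase = "all")
}

## Shared epoch loop.  phase: "prior" (pair batches, IIC losses),
## "transfer" (subject batches, CE, frozen trunk, eval-mode BN),
## "all" (subject batches, CE, everything trainable, training-mode BN).
.trainLoop <- function(model, Xtrain, ytrain, Xval, yval, config, phase,
                       iicCfg = NULL) {
  params <- model@params
  buffers <- model@buffers
  mask <- .trainableMask(params, if (phase == "all") "all" else phase)
  state <- .adamInit(params)
  nTr <- nrow(Xtrain)
  pairPhase <- phase == "prior"

  if (pairPhase) {
    valPairs <- .validationPairs(nrow(Xval), config$val_pair_cap,
                                 .deriveSeed(config$seed, 1L))
    batchSize <- config$batch_size
    poolSize <- nTr * (nTr - 1) / 2
  } else {
    batchSize <- min(config$batch_size, nTr)
    poolSize <- nTr
  }
  if (poolSize < batchSize)
    warning("batch_size exceeds the pool; zero iterations per epoch",
            call. = FALSE)

  history <- .newHistory()
  best <- list(val = Inf, epoch = 0L, params = params, buffers = buffers)
  sinceBest <- 0L
  stoppedEarly <- FALSE

  for (epoch in seq_len(config$max_epochs)) {
    epochLosses <- numeric(0)
    .withSeed(.deriveSeed(config$seed, 100L + epoch), {
      pool <- if (pairPhase) list(pairs = makePairPool(nTr), pos = 1L)
              else list(pairs = cbind(sample.int(nTr), 0L), pos = 1L)
      repeat {
        nb <- nextMinibatch(pool, batchSize)
        pool <- nb$pool
        if (nb$exhausted) break
        if (pairPhase) {
          step <- .priorStep(params, buffers, Xtrain, ytrain, nb$batch,
                             iicCfg)
        } else {
          step <- .ceStep(params, buffers, Xtrain, ytrain,
                          nb$batch[, 1L], training = (phase == "all"))
        }
        epochLosses <- c(epochLosses, step$loss)
        buffers <- step$buffers
        ad <- .adamStep(params, step$grads, state, mask,
                        config$learning_rate)
        params <- ad$params
        state <- ad$state
      }
    })
    valLoss <- if (pairPhase)
      .priorLossEval(params, buffers, Xval, yval, valPairs, iicCfg)
    else {
      fw <- .trunkForward(params, buffers, Xval, training = FALSE)
      crossEntropy(.headForward(params, fw$A, "cls"), yval)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, iterations = length(epochLosses),
      train_loss = if (length(epochLosses)) mean(epochLosses) else NA_real_,
      val_loss = valLoss))
    if (valLoss < best$val) {
      best <- list(val = valLoss, epoch = epoch, params = params,
                   buffers = buffers)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= config$patience) {
        stoppedEarly <- TRUE
        break
      }
    }
  }

  attr(history, "best_epoch") <- best$epoch
  attr(history, "stopped_early") <- stoppedEarly
  model@params <- best$params
  model@buffers <- best$buffers
  list(model = model, history = history)
}

## One prior-phase mini-batch: loss, parameter grads, updated buffers.
.priorStep <- function(params, buffers, X, y, batch, iicCfg) {
  n <- nrow(batch)
  X1 <- X[batch[, 1L], , drop = FALSE]
  X2 <- X[batch[, 2L], , drop = FALSE]
  same <- y[batch[, 1L]] == y[batch[, 2L]]
  fw <- .trunkForward(params, buffers, rbind(X1, X2), training = TRUE)
  phiM <- .headForward(params, fw$A, "iic")
  phiO <- .headForward(params, fw$A, "oc")
  g <- .priorPairLossGrad(phiM[seq_len(n), , drop = FALSE],
                          phiM[n + seq_len(n), , drop = FALSE],
                          phiO[seq_len(n), , drop = FALSE],
                          phiO[n + seq_len(n), , drop = FALSE],
                          same, iicCfg)
  dPhiM <- rbind(g$dMain1, g$dMain2)
  dPhiO <- rbind(g$dOc1, g$dOc2)
  hM <- .headBackward(params, fw$A, phiM, dPhiM, "iic")
  hO <- .headBackward(params, fw$A, phiO, dPhiO, "oc")
  trunkGrads <- .trunkBackward(params, fw$caches, hM$dA + hO$dA,
                               training = TRUE)
  grads <- .zeroGrads(params)
  grads$trunk <- trunkGrads
  grads$heads$iic <- list(W = hM$dW, b = hM$db)
  grads$heads$oc <- list(W = hO$dW, b = hO$db)
  list(loss = g$loss, grads = grads, buffers = fw$buffers)
}

## One cross-entropy mini-batch (transfer or end-to-end).
.ceStep <- function(params, buffers, X, y, idx, training) {
  Xb <- X[idx, , drop = FALSE]
  yb <- y[idx]
  fw <- .trunkForward(params, buffers, Xb, training = training)
  phi <- .headForward(params, fw$A, "cls")
  nb <- length(yb)
  eps <- 1e-12
  loss <- crossEntropy(phi, yb)
  dPhi <- matrix(0, nb, 2L)
  sel <- cbind(seq_len(nb), yb + 1L)
  dPhi[sel] <- -1 / (phi[sel] + eps) / nb
  h <- .headBackward(params, fw$A, phi, dPhi, "cls")
  grads <- .zeroGrads(params)
  grads$heads$cls <- list(W = h$dW, b = h$db)
  if (training) {
    grads$trunk <- .trunkBackward(params, fw$caches, h$dA, training = TRUE)
    buffers <- fw$buffers
  }
  list(loss = loss, grads = grads, buffers = buffers)
}
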