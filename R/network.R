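## Shared-trunk multi-head network: four FC + batch-normalization + ReLU
## blocks, then three linear-softmax heads (iic: 2 classes, oc:
## overclustering, cls: the supervised classifier).  Forward, backward and
## the Adam optimizer are implemented directly in matrix code.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

#' Network architecture specification
#'
#' @param input_dim feature dimension (5,995 for 110 ROIs).
#' @param hidden_dims widths of the four intermediate blocks; the default
#'   `c(1024, 512, 256, 128)` suits full-scale 5,995-dimensional input,
#'   while scaled-down runs typically use `c(32, 32, 16, 16)`.
#' @param c_main main-head class count (2).
#' @param c_oc overclustering-head class count (default 10).
#' @param seed integer controlling parameter initialization.
#' @return list of class `NetworkSpec`.
#' @export
networkSpec <- function(input_dim, hidden_dims = c(1024L, 512L, 256L, 128L),
                        c_main = 2L, c_oc = 10L, seed = 1L) {
  if (length(hidden_dims) != 4L)
    stop("the trunk has exactly four intermediate blocks", call. = FALSE)
  dims <- c(input_dim, hidden_dims, c_main, c_oc)
  if (any(dims < 1L)) stop("all layer widths must be >= 1", call. = FALSE)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 c_main = as.integer(c_main), c_oc = as.integer(c_oc),
                 seed = as.integer(seed)),
            class = "NetworkSpec")
}

#' Build an EIIC network
#'
#' Deterministic He-style initialization given `spec$seed`; the three heads
#' share the trunk.
#'
#' @param spec a [networkSpec()].
#' @return an [EiicModel-class] with `frozen = FALSE`.
#' @export
buildNetwork <- function(spec) {
  if (!inherits(spec, "NetworkSpec")) spec <- do.call(networkSpec, spec)
  dims <- c(spec$input_dim, spec$hidden_dims)
  .withSeed(spec$seed, {
    trunk <- vector("list", 4L)
    for (k in 1:4) {
      fanIn <- dims[k]
      trunk[[k]] <- list(
        W = matrix(stats::rnorm(fanIn * dims[k + 1L], sd = sqrt(2 / fanIn)),
                   fanIn, dims[k + 1L]),
        b = numeric(dims[k + 1L]),
        gamma = rep(1, dims[k + 1L]),
        beta = numeric(dims[k + 1L]))
    }
    names(trunk) <- paste0("l", 1:4)
    d4 <- dims[5L]
    mkHead <- function(cOut)
      list(W = matrix(stats::rnorm(d4 * cOut, sd = sqrt(1 / d4)), d4, cOut),
           b = numeric(cOut))
    heads <- list(iic = mkHead(spec$c_main), oc = mkHead(spec$c_oc),
                  cls = mkHead(2L))
    buffers <- lapply(1:4, function(k)
      list(mean = numeric(dims[k + 1L]), var = rep(1, dims[k + 1L])))
    names(buffers) <- paste0("l", 1:4)
    new("EiicModel", spec = unclass(spec),
        params = list(trunk = trunk, heads = heads),
        buffers = buffers, frozen = FALSE)
  })
}

## Trunk forward pass.  training = TRUE uses batch statistics and returns
## updated running buffers; training = FALSE uses the running statistics.
.trunkForward <- function(params, buffers, X, training) {
  n <- nrow(X)
  caches <- vector("list", 4L)
  A <- X
  for (k in 1:4) {
    L <- params$trunk[[k]]
    Z <- .addRow(A %*% L$W, L$b)
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(Z * Z) - mu * mu
      v[v < 0] <- 0
      buffers[[k]]$mean <- (1 - .BN_MOMENTUM) * buffers[[k]]$mean +
        .BN_MOMENTUM * mu
      buffers[[k]]$var <- (1 - .BN_MOMENTUM) * buffers[[k]]$var +
        .BN_MOMENTUM * v
    } else {
      mu <- buffers[[k]]$mean
      v <- buffers[[k]]$var
    }
    inv <- 1 / sqrt(v + .BN_EPS)
    Zhat <- .mulRow(.addRow(Z, -mu), inv)
    Y <- .addRow(.mulRow(Zhat, L$gamma), L$beta)
    Anew <- Y * (Y > 0)
    caches[[k]] <- list(Xin = A, Zhat = Zhat, inv = inv, mask = (Y > 0))
    A <- Anew
  }
  list(A = A, caches = caches, buffers = buffers, n = n)
}

.headForward <- function(params, A, head) {
  H <- params$heads[[head]]
  .softmaxRows(.addRow(A %*% H$W, H$b))
}

#' Forward pass through one head
#'
#' Evaluation mode (the default) uses the batch-normalization running
#' statistics and is deterministic; training mode normalizes with the batch's
#' own statistics and requires a batch of at least 2 (running buffers are
#' persisted only inside the training routines).
#'
#' @param model an [EiicModel-class].
#' @param X numeric matrix, subjects x features.
#' @param head `"iic"`, `"iic_oc"` or `"classifier"`.
#' @param training logical.
#' @return matrix of class distributions, one row per subject.
#' @export
forwardPass <- function(model, X,
                        head = c("classifier", "iic", "iic_oc"),
                        training = FALSE) {
  head <- match.arg(head)
  X <- rbind(X)
  if (ncol(X) != model@spec$input_dim)
    stop(sprintf("input has %d features but the network expects %d",
                 ncol(X), model@spec$input_dim), call. = FALSE)
  if (training && nrow(X) < 2L)
    stop("batch normalization in training mode requires a batch of >= 2",
         call. = FALSE)
  fw <- .trunkForward(model@params, model@buffers, X, training)
  .headForward(model@params, fw$A,
               switch(head, classifier = "cls", iic = "iic", iic_oc = "oc"))
}

## Backward through a head given dL/dPhi; returns head grads and dL/dA.
.headBackward <- function(params, A, phi, dPhi, head) {
  dLog <- phi * (dPhi - rowSums(dPhi * phi))
  list(dW = crossprod(A, dLog), db = colSums(dLog),
       dA = tcrossprod(dLog, params$heads[[head]]$W))
}

## Backward through the trunk given dL/dA at the trunk output.
## training selects the batch-statistics BN backward.
.trunkBackward <- function(params, caches, dA, training) {
  grads <- vector("list", 4L)
  names(grads) <- paste0("l", 1:4)
  for (k in 4:1) {
    cc <- caches[[k]]
    L <- params$trunk[[k]]
    dY <- dA * cc$mask
    dgamma <- colSums(dY * cc$Zhat)
    dbeta <- colSums(dY)
    dZhat <- .mulRow(dY, L$gamma)
    if (training) {
      n <- nrow(dZhat)
      s1 <- colSums(dZhat)
      s2 <- colSums(dZhat * cc$Zhat)
      dZ <- .mulRow(.addRow(dZhat, -s1 / n) -
                      .mulRow(cc$Zhat, s2 / n), cc$inv)
    } else {
      dZ <- .mulRow(dZhat, cc$inv)
    }
    grads[[k]] <- list(W = crossprod(cc$Xin, dZ), b = colSums(dZ),
                       gamma = dgamma, beta = dbeta)
    dA <- tcrossprod(dZ, L$W)
  }
  grads
}

## Zero-filled gradient structure matching params.
.zeroGrads <- function(params) .mapLeaves(function(p, ...) p * 0, params)

#' Freeze the trunk for transfer learning
#'
#' Marks every parameter except the classifier head's linear map as
#' non-trainable and freezes the batch-normalization running statistics;
#' subsequent [trainTransfer()] updates only the weights directly connected
#' to the output layer.
#'
#' @param model an [EiicModel-class] after prior learning.
#' @return the model with `frozen = TRUE`.
#' @export
freezeTrunk <- function(model) {
  model@frozen <- TRUE
  model
}

## Trainable mask: TRUE leaves get Adam updates.
.trainableMask <- function(params, phase = c("prior", "transfer", "all")) {
  phase <- match.arg(phase)
  .mapLeavesNamed <- function(p, path) {
    if (is.list(p)) {
      out <- lapply(seq_along(p), function(i)
        .mapLeavesNamed(p[[i]], c(path, names(p)[i])))
      names(out) <- names(p)
      out
    } else {
      switch(phase,
             all = TRUE,
             prior = !identical(path[1:2], c("heads", "cls")),
             transfer = identical(path[1:2], c("heads", "cls")))
    }
  }
  .mapLeavesNamed(params, character(0))
}

## Adam optimizer over the nested parameter list.
.adamInit <- function(params) {
  list(m = .zeroGrads(params), v = .zeroGrads(params), t = 0L)
}

.adamStep <- function(params, grads, state, mask, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .mapLeaves(function(m, g, ...) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .mapLeaves(function(v, g, ...) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- function(p, pieces, flag) {
    if (!isTRUE(flag)) return(p)
    p - lr * (pieces$m / c1) / (sqrt(pieces$v / c2) + eps)
  }
  walk <- function(p, m, v, msk) {
    if (is.list(p)) {
      out <- lapply(seq_along(p), function(i) walk(p[[i]], m[[i]], v[[i]],
                                                   msk[[i]]))
      names(out) <- names(p)
      out
    } else upd(p, list(m = m, v = v), msk)
  }
  list(params = walk(params, state$m, state$v, mask), state = state)
}
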