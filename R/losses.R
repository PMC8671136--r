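## The IIC objective: joint class-assignment matrix, lambda-weighted mutual
## information, per-head losses for same/different-label pairs, and cross
## entropy.  All distributions are row vectors (batches: rows of a matrix).

#' IIC loss configuration
#'
#' @param lambda_weight weight on the marginal-entropy terms of the mutual
#'   information (default 5.0); values > 1 discourage collapsing all inputs
#'   into one cluster.
#' @param c_main classes of the main head (fixed at 2).
#' @param c_oc classes of the overclustering head (default 10).
#' @param eps additive stabilizer inside every logarithm (default 1e-12).
#' @param symmetrize symmetrize the joint assignment matrix (default TRUE).
#' @return list of class `IicConfig`.
#' @export
iicConfig <- function(lambda_weight = 5.0, c_main = 2L, c_oc = 10L,
                      eps = 1e-12, symmetrize = TRUE) {
  .assertScalarNumber(lambda_weight, "lambda_weight", lower = 1)
  if (c_main != 2L) stop("the main head is two-class", call. = FALSE)
  if (c_oc <= 2L) stop("the overclustering head needs > 2 classes",
                       call. = FALSE)
  structure(list(lambda_weight = lambda_weight, c_main = 2L,
                 c_oc = as.integer(c_oc), eps = eps,
                 symmetrize = isTRUE(symmetrize)),
            class = "IicConfig")
}

.checkDistributionRows <- function(phi, what = "phi") {
  if (any(phi < -1e-9))
    stop(what, " has negative entries", call. = FALSE)
  if (any(abs(rowSums(phi) - 1) > 1e-6))
    stop(what, " rows must sum to 1", call. = FALSE)
  invisible(phi)
}

#' Joint class-assignment matrix of a paired batch
#'
#' For n paired softmax outputs the empirical joint assignment is
#' `P = (1/n) * sum_i phi1_i %o% phi2_i`.  With `symmetrize = TRUE`
#' (the default) `P` is replaced by `(P + t(P)) / 2` and renormalized to sum
#' exactly 1.
#'
#' @param phi1,phi2 n x C matrices whose rows are class distributions.
#' @param symmetrize logical.
#' @return C x C matrix with nonnegative entries summing to 1.
#' @export
jointAssignment <- function(phi1, phi2, symmetrize = TRUE) {
  phi1 <- rbind(phi1); phi2 <- rbind(phi2)
  if (!all(dim(phi1) == dim(phi2)))
    stop(sprintf("paired batches must match in shape (%d x %d vs %d x %d)",
                 nrow(phi1), ncol(phi1), nrow(phi2), ncol(phi2)),
         call. = FALSE)
  .checkDistributionRows(phi1, "phi1"); .checkDistributionRows(phi2, "phi2")
  P <- crossprod(phi1, phi2) / nrow(phi1)
  if (symmetrize) {
    P <- (P + t(P)) / 2
    P <- P / sum(P)
  }
  P
}

#' Marginal entropy of a class distribution
#'
#' `H(p) = -sum(p * log(p + eps))`, in nats; 0 <= H <= log(C).
#'
#' @param p probability vector.
#' @param eps log stabilizer.
#' @export
marginalEntropy <- function(p, eps = 1e-12) {
  if (any(p < -1e-12)) stop("probabilities must be nonnegative", call. = FALSE)
  -sum(p * log(p + eps))
}

#' Lambda-weighted mutual information of a joint assignment
#'
#' `I_lambda(z, z') = sum_cc' P_cc' log(P_cc' / (Pc^lambda * Pc'^lambda))`
#' where `Pc`, `Pc'` are the row/column marginals of `P`; equivalently
#' `I_1 + (lambda - 1) * (H(z) + H(z'))`.  With `lambda = 1` this is the
#' ordinary mutual information.
#'
#' @param P C x C joint assignment matrix.
#' @param lambda_weight the entropy coefficient lambda.
#' @param eps log stabilizer.
#' @export
mutualInformationLambda <- function(P, lambda_weight = 5.0, eps = 1e-12) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("P must be square", call. = FALSE)
  if (any(P < -1e-9)) stop("P must be nonnegative", call. = FALSE)
  pr <- rowSums(P); pc <- colSums(P)
  sum(P * log(P + eps)) -
    lambda_weight * sum(pr * log(pr + eps)) -
    lambda_weight * sum(pc * log(pc + eps))
}

#' IIC loss of a joint assignment
#'
#' The lambda-weighted mutual information multiplied by -1 and divided by the
#' natural logarithm of the head's class count, turning information
#' maximization into loss minimization on a scale commensurate across heads.
#'
#' @inheritParams mutualInformationLambda
#' @param classes the head's class count C (>= 2); defaults to `nrow(P)`.
#' @export
iicLoss <- function(P, lambda_weight = 5.0, classes = nrow(as.matrix(P)),
                    eps = 1e-12) {
  if (classes < 2L) stop("need at least 2 discriminant classes", call. = FALSE)
  -mutualInformationLambda(P, lambda_weight, eps) / log(classes)
}

## d(iicLoss)/dP for the eps-stabilized expression, marginals included.
.iicLossGrad <- function(P, lambda_weight, classes, eps = 1e-12) {
  pr <- rowSums(P); pc <- colSums(P)
  gJoint <- log(P + eps) + P / (P + eps)
  gRow <- log(pr + eps) + pr / (pr + eps)
  gCol <- log(pc + eps) + pc / (pc + eps)
  dI <- gJoint - lambda_weight * outer(gRow, rep(1, length(pc))) -
    lambda_weight * outer(rep(1, length(pr)), gCol)
  -dI / log(classes)
}

#' Two-class complement distribution
#'
#' For a two-class softmax output, `1 - phi` is the distribution of the
#' opposite class assignment (elementwise complement; for C = 2 this swaps
#' the two probabilities).  Used to push different-label pairs apart.
#'
#' @param phi distribution vector of length 2, or an n x 2 matrix of rows.
#' @export
complementDistribution <- function(phi) {
  m <- rbind(phi)
  if (ncol(m) != 2L)
    stop("the complement trick is defined for two-class outputs only",
         call. = FALSE)
  out <- 1 - m
  if (is.matrix(phi)) out else drop(out)
}

#' Cross-entropy loss for a binary label
#'
#' `-log(pred[label] + eps)` with the label one-hot encoded.
#'
#' @param pred distribution vector of length 2 (or n x 2 matrix).
#' @param label integer vector in {0, 1}.
#' @param eps log stabilizer.
#' @return mean cross entropy over the batch (scalar).
#' @export
crossEntropy <- function(pred, label, eps = 1e-12) {
  m <- rbind(pred)
  if (!all(label %in% c(0L, 1L))) stop("label must be 0 or 1", call. = FALSE)
  if (length(label) != nrow(m))
    stop("one label per prediction required", call. = FALSE)
  .checkDistributionRows(m, "pred")
  p <- m[cbind(seq_len(nrow(m)), label + 1L)]
  mean(-log(p + eps))
}

#' Prior-learning pair loss
#'
#' The contrastive objective of the prior phase.  Same-label pairs contribute
#' the IIC loss at both the main head and the overclustering head; pairs with
#' different labels contribute the IIC loss at the main head only, with the
#' second member's distribution complemented (the complement trick is
#' two-class only).  Empty groups contribute 0; both groups empty is an
#' error.
#'
#' @param main1,main2 n x 2 main-head outputs for the pair members.
#' @param oc1,oc2 n x C_oc overclustering-head outputs.
#' @param same logical vector of length n: does the pair share its label?
#' @param config an [iicConfig()].
#' @return scalar loss.
#' @export
priorPairLoss <- function(main1, main2, oc1, oc2, same,
                          config = iicConfig()) {
  main1 <- rbind(main1); main2 <- rbind(main2)
  oc1 <- rbind(oc1); oc2 <- rbind(oc2)
  n <- nrow(main1)
  if (length(same) != n) stop("'same' must flag every pair", call. = FALSE)
  if (n == 0L || (!any(same) && !any(!same)))
    stop("need at least one labeled pair", call. = FALSE)
  lam <- config$lambda_weight
  total <- 0
  if (any(same)) {
    Ps <- jointAssignment(main1[same, , drop = FALSE],
                          main2[same, , drop = FALSE], config$symmetrize)
    total <- total + iicLoss(Ps, lam, 2L, config$eps)
    Po <- jointAssignment(oc1[same, , drop = FALSE],
                          oc2[same, , drop = FALSE], config$symmetrize)
    total <- total + iicLoss(Po, lam, config$c_oc, config$eps)
  }
  if (any(!same)) {
    Pd <- jointAssignment(main1[!same, , drop = FALSE],
                          complementDistribution(main2[!same, , drop = FALSE]),
                          config$symmetrize)
    total <- total + iicLoss(Pd, lam, 2L, config$eps)
  }
  total
}

## Loss + gradients wrt the four phi matrices; used by the training loop.
## Returns list(loss, dMain1, dMain2, dOc1, dOc2).
.priorPairLossGrad <- function(main1, main2, oc1, oc2, same, config) {
  n <- nrow(main1)
  lam <- config$lambda_weight
  eps <- config$eps
  dM1 <- matrix(0, n, 2L); dM2 <- matrix(0, n, 2L)
  dO1 <- matrix(0, n, config$c_oc); dO2 <- matrix(0, n, config$c_oc)
  total <- 0

  term <- function(a, b, classes) {
    ## joint (with optional symmetrize+renormalize), loss, and dL/d(a,b)
    m <- nrow(a)
    P0 <- crossprod(a, b) / m
    if (config$symmetrize) {
      Ps <- (P0 + t(P0)) / 2
      s <- sum(Ps)
      P <- Ps / s
    } else P <- P0
    loss <- iicLoss(P, lam, classes, eps)
    G <- .iicLossGrad(P, lam, classes, eps)
    if (config$symmetrize) {
      G <- (G - sum(G * P)) / s      # through renormalization
      G <- (G + t(G)) / 2            # through symmetrization
    }
    list(loss = loss,
         da = b %*% t(G) / m,
         db = a %*% G / m)
  }

  if (any(same)) {
    tm <- term(main1[same, , drop = FALSE], main2[same, , drop = FALSE], 2L)
    total <- total + tm$loss
    dM1[same, ] <- dM1[same, ] + tm$da
    dM2[same, ] <- dM2[same, ] + tm$db
    to <- term(oc1[same, , drop = FALSE], oc2[same, , drop = FALSE],
               config$c_oc)
    total <- total + to$loss
    dO1[same, ] <- dO1[same, ] + to$da
    dO2[same, ] <- dO2[same, ] + to$db
  }
  if (any(!same)) {
    td <- term(main1[!same, , drop = FALSE],
               1 - main2[!same, , drop = FALSE], 2L)
    total <- total + td$loss
    dM1[!same, ] <- dM1[!same, ] + td$da
    dM2[!same, ] <- dM2[!same, ] - td$db   # through the complement
  }
  list(loss = total, dMain1 = dM1, dMain2 = dM2, dOc1 = dO1, dOc2 = dO2)
}
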