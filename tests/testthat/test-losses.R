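test_that("joint assignment is the batch-averaged outer product", {
  P <- jointAssignment(c(1, 0), c(1, 0), symmetrize = FALSE)
  expect_equal(P, matrix(c(1, 0, 0, 0), 2, 2))

  phi1 <- rbind(c(1, 0), c(0, 1))
  phi2 <- rbind(c(0, 1), c(1, 0))
  Ps <- jointAssignment(phi1, phi2, symmetrize = TRUE)
  expect_equal(Ps, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_lt(max(abs(Ps - t(Ps))), 1e-12)

  expect_error(jointAssignment(phi1, phi2[1, , drop = FALSE]), "shape")
  expect_error(jointAssignment(rbind(c(2, -1)), rbind(c(1, 0))), "negative")
})

test_that("joint assignment entries are nonnegative and sum to one", {
  set.seed(21)
  for (i in 1:25) {
    C <- sample(2:6, 1)
    n <- sample(1:40, 1)
    P <- jointAssignment(randomSoftmax(n, C), randomSoftmax(n, C))
    expect_true(all(P >= 0))
    expect_lt(abs(sum(P) - 1), 1e-9)
  }
})

test_that("marginal entropy has its closed-form values", {
  expect_equal(marginalEntropy(c(1, 0)), 0, tolerance = 1e-10)
  expect_equal(marginalEntropy(c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_equal(marginalEntropy(rep(0.25, 4)), log(4), tolerance = 1e-9)
  expect_error(marginalEntropy(c(-0.1, 1.1)), "nonnegative")
})

test_that("lambda-weighted mutual information matches closed forms", {
  indep <- outer(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(mutualInformationLambda(indep, 1), 0, tolerance = 1e-9)
  expect_equal(mutualInformationLambda(diag(c(0.5, 0.5)), 1), log(2),
               tolerance = 1e-9)
  expect_equal(mutualInformationLambda(diag(c(0.5, 0.5)), 5), 9 * log(2),
               tolerance = 1e-8)
})

test_that("vectorized I_lambda equals a brute-force double sum on random joints", {
  # independent oracle: literal double sum over cells of
  # P * ln(P / (Pr^lam * Pc^lam)), same eps stabilization per logarithm
  oracle <- function(P, lam, eps = 1e-12) {
    pr <- rowSums(P); pc <- colSums(P)
    acc <- 0
    for (a in seq_len(nrow(P))) for (b in seq_len(ncol(P)))
      acc <- acc + P[a, b] *
        (log(P[a, b] + eps) - lam * log(pr[a] + eps) - lam * log(pc[b] + eps))
    acc
  }
  set.seed(8)
  for (i in 1:100) {
    C <- sample(2:8, 1)
    P <- matrix(rexp(C * C), C, C)
    P <- P / sum(P)
    lam <- sample(c(1, 2, 5), 1)
    expect_equal(mutualInformationLambda(P, lam), oracle(P, lam),
                 tolerance = 1e-10)
  }
})

test_that("IIC loss closed forms and bounds hold", {
  expect_equal(iicLoss(diag(c(0.5, 0.5)), 1), -1, tolerance = 1e-8)
  expect_equal(iicLoss(diag(c(0.5, 0.5)), 5), -9, tolerance = 1e-8)
  expect_equal(iicLoss(matrix(0.25, 2, 2), 1), 0, tolerance = 1e-9)
  expect_equal(iicLoss(matrix(0.25, 2, 2), 5), -8, tolerance = 1e-8)
  expect_error(iicLoss(diag(c(0.5, 0.5)), 5, classes = 1), "2 discriminant")

  # with lambda = 1 the loss lies in [-1, ~0] for any valid joint
  set.seed(13)
  for (i in 1:50) {
    P <- jointAssignment(randomSoftmax(10, 2), randomSoftmax(10, 2))
    l <- iicLoss(P, 1)
    expect_gte(l, -1 - 1e-10)
    expect_lte(l, 1e-10)
  }
})

test_that("the ideal two-class joint minimizes the IIC loss (grid oracle)", {
  # brute force over symmetric 2x2 joints P = [[a, b], [b, 1 - a - 2b]]
  for (lam in c(1, 5)) {
    best <- Inf; argmins <- list()
    for (a in seq(0, 1, by = 0.01)) for (b in seq(0, (1 - a) / 2, by = 0.01)) {
      P <- matrix(c(a, b, b, 1 - a - 2 * b), 2, 2)
      l <- iicLoss(P, lam)
      if (l < best - 1e-9) { best <- l; argmins <- list(P) }
      else if (l < best + 1e-9) argmins <- c(argmins, list(P))
    }
    expect_equal(best, -(2 * lam - 1), tolerance = 1e-6)
    # the ideal diagonal joint attains the minimum; the only other grid
    # minimizer is its class relabeling (the anti-diagonal)
    expect_equal(iicLoss(diag(c(0.5, 0.5)), lam), best, tolerance = 1e-6)
    for (P in argmins)
      expect_true(isTRUE(all.equal(P, diag(c(0.5, 0.5)), tolerance = 1e-9)) ||
                  isTRUE(all.equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2),
                                   tolerance = 1e-9)))
  }
})

test_that("two-class complement swaps probabilities and is an involution", {
  expect_equal(complementDistribution(c(0.3, 0.7)), c(0.7, 0.3))
  expect_equal(complementDistribution(c(1, 0)), c(0, 1))
  set.seed(4)
  phi <- randomSoftmax(20, 2)
  expect_equal(complementDistribution(complementDistribution(phi)), phi,
               tolerance = 1e-12)
  expect_error(complementDistribution(c(0.2, 0.3, 0.5)), "two-class")
})

test_that("cross entropy matches closed forms and is nonnegative", {
  expect_equal(crossEntropy(c(1, 0), 0L), 0, tolerance = 1e-10)
  expect_equal(crossEntropy(c(0.5, 0.5), 1L), log(2), tolerance = 1e-9)
  expect_equal(crossEntropy(c(0.25, 0.75), 1L), log(4 / 3), tolerance = 1e-9)
  set.seed(17)
  phi <- randomSoftmax(30, 2)
  y <- rbinom(30, 1, 0.5)
  expect_gte(crossEntropy(phi, y), 0)
  expect_error(crossEntropy(c(0.5, 0.5), 2L), "0 or 1")
})

test_that("prior pair loss assembles the per-head terms", {
  cfg1 <- iicConfig(lambda_weight = 1, c_oc = 4)
  # diff-only batch: complemented second members give the ideal joint
  main1 <- rbind(c(1, 0), c(0, 1))
  main2 <- rbind(c(0, 1), c(1, 0))
  oc <- matrix(0.25, 2, 4)
  lossDiff <- priorPairLoss(main1, main2, oc, oc, same = c(FALSE, FALSE),
                            config = cfg1)
  expect_equal(lossDiff, -1, tolerance = 1e-8)

  # same-only batch hitting both classes: main-head term is -1; the oc term
  # is computed by the standalone loss functions as an oracle
  oc1 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  lossSame <- priorPairLoss(main1, main1, oc1, oc1, same = c(TRUE, TRUE),
                            config = cfg1)
  ocTerm <- iicLoss(jointAssignment(oc1, oc1), 1, classes = 4)
  expect_equal(lossSame, -1 + ocTerm, tolerance = 1e-8)

  # empty diff group contributes exactly zero
  mixed <- priorPairLoss(main1, main1, oc1, oc1, same = c(TRUE, TRUE),
                         config = cfg1)
  expect_equal(mixed, lossSame)
  expect_error(priorPairLoss(main1[0, ], main1[0, ], oc1[0, ], oc1[0, ],
                             same = logical(0), config = cfg1),
               "at least one")
})

test_that("prior pair loss gradients match finite differences", {
  cfg <- iicConfig(lambda_weight = 5, c_oc = 3)
  set.seed(31)
  n <- 5
  m1 <- randomSoftmax(n, 2); m2 <- randomSoftmax(n, 2)
  o1 <- randomSoftmax(n, 3); o2 <- randomSoftmax(n, 3)
  same <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  g <- eiic:::.priorPairLossGrad(m1, m2, o1, o2, same, cfg)
  expect_equal(g$loss, priorPairLoss(m1, m2, o1, o2, same, cfg))
  h <- 1e-6
  for (trial in 1:10) {
    i <- sample(n, 1); j <- sample(2, 1)
    up <- m1; up[i, j] <- up[i, j] + h
    dn <- m1; dn[i, j] <- dn[i, j] - h
    num <- (eiic:::.priorPairLossGrad(up, m2, o1, o2, same, cfg)$loss -
            eiic:::.priorPairLossGrad(dn, m2, o1, o2, same, cfg)$loss) / (2 * h)
    expect_equal(g$dMain1[i, j], num, tolerance = 1e-4)
  }
})
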