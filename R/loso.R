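## Leave-one-site-out cross-validation: per-site splits, stratified inner
## five-fold CV, five-model ensembling, accuracy and binomial significance.

#' Leave-one-site-out splits
#'
#' One split per eligible test site; the modeling set is every subject from
#' the remaining sites.  Sites with fewer than `min_site_size` subjects are
#' never used as test sites but still contribute their subjects to modeling.
#'
#' @param x a screened [ConnectivitySet-class].
#' @param min_site_size minimum site size to serve as a test site.
#' @return list of splits, each `list(test_site=, test_idx=, modeling_idx=)`.
#' @export
losoSplits <- function(x, min_site_size = 2L) {
  site <- siteIds(x)
  cnt <- table(site)
  if (length(cnt) < 2L)
    stop("leave-one-site-out needs at least 2 sites", call. = FALSE)
  eligible <- names(cnt)[cnt >= min_site_size]
  if (!length(eligible))
    stop("no site is large enough to serve as a test site", call. = FALSE)
  lapply(eligible, function(s)
    list(test_site = s,
         test_idx = which(site == s),
         modeling_idx = which(site != s)))
}

#' Stratified five-fold assignment
#'
#' Assigns modeling subjects to 5 folds so each fold's site and class
#' composition tracks the overall proportions: within every (site x class)
#' cell, members are shuffled (seeded) and dealt round-robin, with the deal
#' pointer carried across cells to balance fold sizes.
#'
#' @param site,label per-subject site IDs and binary labels.
#' @param seed integer.
#' @param k fold count (default 5).
#' @return integer vector of fold indices in `1:k`.
#' @export
stratifiedFiveFolds <- function(site, label, seed = 1L, k = 5L) {
  n <- length(site)
  if (n < 2L * k) stop("too few modeling subjects for ", k, " folds",
                       call. = FALSE)
  if (length(unique(label)) < 2L)
    stop("both classes must be present for stratification", call. = FALSE)
  fold <- integer(n)
  .withSeed(seed, {
    ptr <- 0L
    cells <- split(seq_len(n), list(site, label), drop = TRUE)
    for (cell in cells[order(names(cells))]) {
      cell <- cell[sample.int(length(cell))]
      for (i in cell) {
        fold[i] <- (ptr %% k) + 1L
        ptr <- ptr + 1L
      }
    }
  })
  fold
}

#' Fit the five-model ensemble for one LOSO split
#'
#' For each inner fold: the other four folds are the training set and the
#' fold itself the validation set; a standardizer is fitted on the training
#' folds only; a fresh network is built and trained — contrastive prior
#' learning, trunk freeze, then transfer learning (or end-to-end supervised
#' training when `ablation = "no-prior"`).
#'
#' @param x a [ConnectivitySet-class] restricted to the modeling subjects.
#' @param netspec a [networkSpec()] (its seed is re-derived per fold).
#' @param config a [trainConfig()].
#' @param seed integer; fans out to per-fold streams.
#' @param ablation `"none"` (the full two-phase method); `"no-prior"` (the
#'   controlled ablation: identical pipeline with the prior phase removed,
#'   i.e. the randomly initialized trunk is frozen and only the classifier
#'   head is trained); or `"supervised"` (end-to-end cross-entropy training
#'   of the whole network, no freeze).
#' @return an [EiicEnsemble-class].
#' @export
fitSiteEnsemble <- function(x, netspec, config, seed = 1L,
                            ablation = c("none", "no-prior", "supervised")) {
  ablation <- match.arg(ablation)
  Xall <- .subjectMatrix(x)
  y <- diagnosisLabels(x)
  fold <- stratifiedFiveFolds(siteIds(x), y, seed = .deriveSeed(seed, 1L))
  members <- vector("list", 5L)
  for (kf in 1:5) {
    trIdx <- which(fold != kf)
    vaIdx <- which(fold == kf)
    stats <- fitStandardizer(Xall[trIdx, , drop = FALSE])
    Xtr <- applyStandardizer(stats, Xall[trIdx, , drop = FALSE])
    Xva <- applyStandardizer(stats, Xall[vaIdx, , drop = FALSE])
    spec <- netspec
    spec$seed <- .deriveSeed(seed, 10L + kf)
    model <- buildNetwork(spec)
    cfgK <- config
    cfgK$seed <- .deriveSeed(seed, 20L + kf)
    res <- tryCatch({
      switch(ablation,
        "supervised" = trainSupervised(model, Xtr, y[trIdx], Xva, y[vaIdx],
                                       cfgK),
        "no-prior" = trainTransfer(freezeTrunk(model), Xtr, y[trIdx], Xva,
                                   y[vaIdx], cfgK),
        "none" = {
          pr <- trainPrior(model, Xtr, y[trIdx], Xva, y[vaIdx], cfgK)
          trainTransfer(freezeTrunk(pr$model), Xtr, y[trIdx], Xva, y[vaIdx],
                        cfgK)
        })
    }, error = function(e)
      stop(sprintf("fold %d: %s", kf, conditionMessage(e)), call. = FALSE))
    members[[kf]] <- list(model = res$model, standardizer = stats,
                          history = res$history)
  }
  new("EiicEnsemble", members = members)
}

#' Ensemble prediction by output averaging
#'
#' Each member standardizes the test input with its own training-fold
#' statistics and evaluates its classifier head; the five two-node outputs
#' are averaged and the predicted category is obtained by rounding the mean
#' score of class 1 (a mean of exactly 0.5 predicts class 1).
#'
#' @param ensemble an [EiicEnsemble-class].
#' @param x a [ConnectivitySet-class] or matrix (subjects x features) of
#'   test subjects.
#' @return data.frame with `score_0`, `score_1` (mean class scores) and
#'   `predicted` label.
#' @export
ensemblePredict <- function(ensemble, x) {
  Xraw <- if (is(x, "ConnectivitySet")) .subjectMatrix(x) else as.matrix(x)
  if (!nrow(Xraw)) stop("empty test set", call. = FALSE)
  scores <- 0
  for (m in ensemble@members) {
    Xs <- applyStandardizer(m$standardizer, Xraw)
    scores <- scores + forwardPass(m$model, Xs, head = "classifier")
  }
  scores <- scores / length(ensemble@members)
  data.frame(score_0 = scores[, 1L], score_1 = scores[, 2L],
             predicted = as.integer(scores[, 2L] >= 0.5))
}

#' Exact binomial test of accuracy against chance
#'
#' Two-sided exact binomial test of `k` correct out of `n` against chance
#' level `p0` (default 50%).
#'
#' @param k correct predictions.
#' @param n test-set size.
#' @param p0 chance level.
#' @return the p-value.
#' @export
binomialTest <- function(k, n, p0 = 0.5) {
  if (n < 1L || k < 0L || k > n)
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Full leave-one-site-out evaluation
#'
#' Runs the complete pipeline for every eligible test site: stratified inner
#' five-fold CV, five trained models, ensemble prediction on the held-out
#' site, and an exact binomial test of the accuracy against 50% chance.
#' Deterministic given `seed`.
#'
#' @param x a screened [ConnectivitySet-class].
#' @param netspec a [networkSpec()] template.
#' @param config a [trainConfig()].
#' @param seed integer master seed; fans out per site and fold.
#' @param ablation `"none"`, `"no-prior"` or `"supervised"`; see
#'   [fitSiteEnsemble()].
#' @param min_site_size minimum site size to serve as a test site.
#' @return a [LosoReport-class].
#' @export
losoReport <- function(x, netspec, config, seed = 1L,
                       ablation = c("none", "no-prior", "supervised"),
                       min_site_size = 2L) {
  ablation <- match.arg(ablation)
  splits <- losoSplits(x, min_site_size)
  rows <- vector("list", length(splits))
  preds <- vector("list", length(splits))
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    modeling <- x[, sp$modeling_idx]
    test <- x[, sp$test_idx]
    stopifnot(length(intersect(SummarizedExperiment::colData(modeling)$subject_id,
                               SummarizedExperiment::colData(test)$subject_id)) == 0L)
    ens <- fitSiteEnsemble(modeling, netspec, config,
                           seed = .deriveSeed(seed, 1000L + si),
                           ablation = ablation)
    pr <- ensemblePredict(ens, test)
    yTest <- diagnosisLabels(test)
    nCorrect <- sum(pr$predicted == yTest)
    n <- length(yTest)
    pval <- binomialTest(nCorrect, n)
    rows[[si]] <- data.frame(
      site = sp$test_site, n = n, n_correct = nCorrect,
      accuracy = nCorrect / n, p_value = pval,
      significant = pval < 0.01, stringsAsFactors = FALSE)
    preds[[si]] <- cbind(
      data.frame(site = sp$test_site,
                 subject_id = SummarizedExperiment::colData(test)$subject_id,
                 label = yTest, stringsAsFactors = FALSE), pr)
  }
  new("LosoReport", table = do.call(rbind, rows),
      predictions = do.call(rbind, preds), seed = as.integer(seed))
}

#' @describeIn losoReport extract the per-site table from a report.
#' @param report a [LosoReport-class].
#' @export
losoTable <- function(report) report@table
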