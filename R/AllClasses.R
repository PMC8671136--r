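#' ConnectivitySet: Fisher-z connectivity features with subject metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay `"z"`
#' (features x subjects: the strictly-lower-triangular Fisher-z connectivity
#' values) and per-subject `colData` columns `subject_id`, `site_id` and
#' `label` (1 = ASD, 0 = typical control).
#'
#' @aliases ConnectivitySet-class
#' @export
setClass("ConnectivitySet", contains = "SummarizedExperiment")

setValidity("ConnectivitySet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "site_id", "label")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("colData is missing column(s): %s",
                   paste(miss, collapse = ", ")))
  if (!all(SummarizedExperiment::assayNames(object) == "z"))
    return("assay must be named 'z'")
  lab <- cd$label
  if (!all(lab %in% c(0L, 1L)))
    return("label must be binary (1 = ASD, 0 = TC)")
  if (anyDuplicated(cd$subject_id))
    return("duplicate subject_id in colData")
  TRUE
})

#' EiicModel: shared-trunk multi-head network
#'
#' Holds the parameters of the EIIC network: a trunk of four fully-connected
#' + batch-normalization + ReLU blocks, and three linear-softmax heads
#' (`iic`: 2 classes, `oc`: overclustering, `cls`: the supervised
#' classifier).  `frozen` records whether [freezeTrunk()] has been applied,
#' after which only the classifier head may be trained.
#'
#' @slot spec list, the [networkSpec()] used to build the model.
#' @slot params list of weight/bias/scale/shift matrices per layer and head.
#' @slot buffers list of batch-normalization running means/variances.
#' @slot frozen logical(1).
#' @aliases EiicModel-class
#' @export
setClass("EiicModel", representation(
  spec = "list", params = "list", buffers = "list", frozen = "logical"))

setValidity("EiicModel", function(object) {
  if (length(object@frozen) != 1L) return("frozen must be logical(1)")
  if (!identical(names(object@params), c("trunk", "heads")))
    return("params must have components 'trunk' and 'heads'")
  if (length(object@params$trunk) != 4L)
    return("trunk must have exactly four blocks")
  TRUE
})

#' EiicEnsemble: five fold-wise trained models
#'
#' One trained [EiicModel-class] plus its own training-fold standardizer per
#' inner-CV fold; predictions average the five classifier-head outputs.
#'
#' @slot members list of five `list(model=, standardizer=, history=)`.
#' @aliases EiicEnsemble-class
#' @export
setClass("EiicEnsemble", representation(members = "list"))

setValidity("EiicEnsemble", function(object) {
  if (length(object@members) != 5L) return("an ensemble has exactly 5 members")
  ok <- vapply(object@members, function(m)
    is(m$model, "EiicModel") && inherits(m$standardizer, "StandardizerStats"),
    logical(1))
  if (!all(ok)) return("each member needs a model and a standardizer")
  TRUE
})

#' LosoReport: per-site leave-one-site-out accuracy table
#'
#' @slot table data.frame with columns `site`, `n`, `n_correct`, `accuracy`,
#'   `p_value` (exact two-sided binomial test against chance 0.5) and
#'   `significant` (p < 0.01).
#' @slot predictions data.frame of per-subject ensemble scores.
#' @slot seed integer seed the report was generated under.
#' @aliases LosoReport-class
#' @export
setClass("LosoReport", representation(
  table = "data.frame", predictions = "data.frame", seed = "integer"))

setValidity("LosoReport", function(object) {
  need <- c("site", "n", "n_correct", "accuracy", "p_value", "significant")
  if (!all(need %in% colnames(object@table)))
    return(sprintf("table needs columns: %s", paste(need, collapse = ", ")))
  tb <- object@table
  if (nrow(tb) && any(abs(tb$accuracy - tb$n_correct / tb$n) > 1e-12))
    return("accuracy must equal n_correct / n")
  if (nrow(tb) && any(tb$significant != (tb$p_value < 0.01)))
    return("significance flags inconsistent with p-values")
  TRUE
})

setMethod("show", "EiicModel", function(object) {
  s <- object@spec
  cat("EiicModel:", s$input_dim, "->",
      paste(s$hidden_dims, collapse = " -> "),
      sprintf("-> heads {iic: %d, oc: %d, classifier: 2}%s\n",
              s$c_main, s$c_oc,
              if (object@frozen) " [trunk frozen]" else ""))
})

setMethod("show", "EiicEnsemble", function(object) {
  cat("EiicEnsemble of 5 fold-wise models; input_dim =",
      object@members[[1L]]$model@spec$input_dim, "\n")
})

setMethod("show", "LosoReport", function(object) {
  cat("Leave-one-site-out cross-validation report (seed ",
      object@seed, "):\n", sep = "")
  print(object@table, row.names = FALSE)
})
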