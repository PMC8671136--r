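## Feature extraction: ROI time series -> Fisher-z lower-triangle vectors.

#' Read an ROI-averaged BOLD time-series matrix
#'
#' Parses a whitespace-delimited text matrix (AFNI `.1D` dialect) of
#' time points x ROIs.  Lines starting with `#` are comments; if the last
#' comment line before the data tokenizes to exactly one name per ROI column
#' it is used as ROI names.
#'
#' @param path path to the text file.
#' @return numeric matrix (T x R), with `colnames` set when a header of ROI
#'   names is present.
#' @export
readRoiTimeseries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    stop(sprintf("format error: '%s' contains no data rows", path),
         call. = FALSE)
  isComment <- grepl("^\\s*#", lines)
  dataIdx <- which(!isComment)
  if (!length(dataIdx))
    stop(sprintf("format error: '%s' contains no data rows", path),
         call. = FALSE)
  toks <- strsplit(trimws(lines[dataIdx]), "\\s+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L) {
    bad <- dataIdx[which(ncols != ncols[1L])[1L]]
    stop(sprintf("format error: ragged row at line %d of '%s' (%d tokens, expected %d)",
                 lineno[bad], path, ncols[ncols != ncols[1L]][1L], ncols[1L]),
         call. = FALSE)
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]) & !(toks[[i]] %in% c("NA", "NaN", "nan")))
    if (length(bad))
      stop(sprintf("parse error: non-numeric token '%s' at line %d, column %d of '%s'",
                   toks[[i]][bad[1L]], lineno[dataIdx[i]], bad[1L], path),
           call. = FALSE)
  }
  m <- do.call(rbind, vals)
  ## ROI names: last comment line whose token count matches the column count
  hdr <- which(isComment)
  hdr <- hdr[hdr < dataIdx[1L]]
  if (length(hdr)) {
    for (h in rev(hdr)) {
      nm <- strsplit(trimws(sub("^\\s*#\\s*", "", lines[h])), "\\s+")[[1L]]
      if (length(nm) == ncol(m) && all(nzchar(nm))) {
        colnames(m) <- nm
        break
      }
    }
  }
  m
}

#' Read a phenotype table
#'
#' Reads a CSV with subject-ID, site-ID and diagnosis columns.  The ABIDE
#' dialect codes diagnosis as 1 = ASD, 2 = TC; the native dialect uses
#' 1 = ASD, 0 = TC directly.  The explicit dialect flag avoids silent label
#' flips.
#'
#' @param path CSV path.
#' @param dialect `"abide"` (default) or `"binary"`.
#' @param columns named character vector with entries `subject`, `site`,
#'   `diagnosis` giving the column names.
#' @return data.frame with columns `subject_id`, `site_id`, `label`
#'   (1 = ASD, 0 = TC).
#' @export
readPhenotype <- function(path, dialect = c("abide", "binary"),
                          columns = c(subject = "SUB_ID", site = "SITE_ID",
                                      diagnosis = "DX_GROUP")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(columns), colnames(tab))
  if (length(miss))
    stop(sprintf("phenotype table is missing required column(s): %s (need %s)",
                 paste(miss, collapse = ", "),
                 paste(columns, collapse = ", ")), call. = FALSE)
  sub <- as.character(tab[[columns[["subject"]]]])
  if (anyDuplicated(sub))
    stop(sprintf("duplicate subject IDs in phenotype table: %s",
                 paste(unique(sub[duplicated(sub)]), collapse = ", ")),
         call. = FALSE)
  dx <- tab[[columns[["diagnosis"]]]]
  lab <- if (dialect == "abide") {
    if (!all(dx %in% c(1, 2)))
      stop("unknown diagnosis code(s) under ABIDE dialect (expected 1=ASD, 2=TC): ",
           paste(unique(dx[!dx %in% c(1, 2)]), collapse = ", "), call. = FALSE)
    ifelse(dx == 1, 1L, 0L)
  } else {
    if (!all(dx %in% c(0, 1)))
      stop("unknown diagnosis code(s) under binary dialect (expected 1=ASD, 0=TC): ",
           paste(unique(dx[!dx %in% c(0, 1)]), collapse = ", "), call. = FALSE)
    as.integer(dx)
  }
  data.frame(subject_id = sub,
             site_id = as.character(tab[[columns[["site"]]]]),
             label = lab, stringsAsFactors = FALSE)
}

#' Pearson correlation matrix of an ROI time-series matrix
#'
#' Columns are ROIs.  A constant column yields non-finite entries which are
#' propagated (and later caught by [screenSubjects()]), never silently fixed.
#'
#' @param timeseries numeric matrix, T time points x R ROIs, T >= 2.
#' @return symmetric R x R correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 2L)
    stop("need at least 2 time points", call. = FALSE)
  if (ncol(timeseries) < 2L)
    stop("need at least 2 ROIs", call. = FALSE)
  suppressWarnings(stats::cor(timeseries))
}

#' Fisher z-transformation
#'
#' `atanh` of a correlation, variance-stabilizing it.  Correlations are
#' clipped to `1 - eps` in magnitude first so that degenerate `|r| = 1`
#' inputs stay finite; the (unit) diagonal never enters the feature vector.
#'
#' @param r correlation scalar, vector or matrix with `|r| <= 1`.
#' @param eps clipping margin, default `1e-7`.
#' @return transformed values, same shape as `r`.
#' @export
fisherZ <- function(r, eps = 1e-7) {
  mx <- suppressWarnings(max(abs(r), na.rm = TRUE))
  if (is.finite(mx) && mx > 1 + 1e-12)
    stop(sprintf("correlation out of range: |r| = %g > 1", mx), call. = FALSE)
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Strictly-lower-triangle vectorization
#'
#' Extracts the strictly-lower-triangular entries of a square matrix in
#' row-major order: (2,1), (3,1), (3,2), (4,1), ...  For an R x R matrix the
#' result has length R(R-1)/2 (5,995 for the 110-region Harvard-Oxford
#' atlas).
#'
#' @param m square matrix.
#' @return numeric vector of length `nrow(m) * (nrow(m) - 1) / 2`.
#' @export
lowerTriangleVector <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix must be square, got %d x %d", nrow(m), ncol(m)),
         call. = FALSE)
  t(m)[upper.tri(m)]
}

#' Fisher-z connectivity features for one subject
#'
#' Pipeline `correlationMatrix` -> `fisherZ` -> `lowerTriangleVector`.
#'
#' @param timeseries T x R time-series matrix.
#' @return numeric feature vector of length R(R-1)/2.
#' @export
connectivityFeatures <- function(timeseries) {
  lowerTriangleVector(fisherZ(correlationMatrix(timeseries)))
}

#' Assemble a ConnectivitySet from subject records
#'
#' @param records list of subject records, each a list with `subject_id`,
#'   `site_id`, `label` and `timeseries` (T x R matrix); all subjects must
#'   share R.
#' @return a [ConnectivitySet-class] (features are not screened; see
#'   [screenSubjects()]).
#' @export
buildConnectivitySet <- function(records) {
  if (!length(records)) stop("no subject records", call. = FALSE)
  rois <- vapply(records, function(r) ncol(r$timeseries), integer(1))
  if (length(unique(rois)) != 1L)
    stop("all subjects must share the same ROI count", call. = FALSE)
  feats <- vapply(records, function(r) connectivityFeatures(r$timeseries),
                  numeric(rois[1L] * (rois[1L] - 1L) / 2L))
  ConnectivitySet(
    features = feats,
    subject_id = vapply(records, `[[`, character(1), "subject_id"),
    site_id = vapply(records, `[[`, character(1), "site_id"),
    label = vapply(records, function(r) as.integer(r$label), integer(1)))
}

#' Construct a ConnectivitySet
#'
#' @param features numeric matrix, features x subjects.
#' @param subject_id,site_id character vectors, one entry per subject.
#' @param label integer vector in {0, 1} (1 = ASD, 0 = TC).
#' @return a [ConnectivitySet-class].
#' @export
ConnectivitySet <- function(features, subject_id, site_id, label) {
  features <- as.matrix(features)
  colnames(features) <- subject_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = features),
    colData = S4Vectors::DataFrame(subject_id = as.character(subject_id),
                                   site_id = as.character(site_id),
                                   label = as.integer(label),
                                   row.names = subject_id))
  new("ConnectivitySet", se)
}

#' @describeIn ConnectivitySet feature matrix (features x subjects).
#' @param x a `ConnectivitySet`.
#' @export
featureMatrix <- function(x) SummarizedExperiment::assay(x, "z")

#' @describeIn ConnectivitySet per-subject site IDs.
#' @export
siteIds <- function(x) SummarizedExperiment::colData(x)$site_id

#' @describeIn ConnectivitySet per-subject diagnosis labels (1 = ASD, 0 = TC).
#' @export
diagnosisLabels <- function(x) SummarizedExperiment::colData(x)$label

## subjects-in-rows view used by the learning code
.subjectMatrix <- function(x) t(SummarizedExperiment::assay(x, "z"))

#' Screen subjects with non-finite connectivity features
#'
#' Subjects whose feature vector contains any NaN/Inf (typically a constant
#' ROI time course) are removed, mirroring the NaN screening applied to the
#' Harvard-Oxford ABIDE extracts.  Sites whose remaining count falls below
#' `min_site_size` are logged as ineligible to serve as left-out test sites
#' (their subjects still contribute to modeling).
#'
#' @param x a [ConnectivitySet-class].
#' @param min_site_size minimum kept subjects for a site to be a LOSO test
#'   site (default 2).
#' @return list with `dataset` (screened `ConnectivitySet`) and `log`, a list
#'   with `excluded_subjects` (data.frame subject_id, reason) and
#'   `excluded_sites` (data.frame site_id, remaining_count).
#' @export
screenSubjects <- function(x, min_site_size = 2L) {
  feats <- featureMatrix(x)
  ok <- apply(feats, 2L, function(col) all(is.finite(col)))
  excluded <- data.frame(
    subject_id = SummarizedExperiment::colData(x)$subject_id[!ok],
    reason = rep("non-finite connectivity", sum(!ok)),
    stringsAsFactors = FALSE)
  if (!any(ok))
    stop("screening excluded every subject", call. = FALSE)
  kept <- x[, ok]
  cnt <- table(siteIds(kept))
  small <- names(cnt)[cnt < min_site_size]
  log <- list(
    excluded_subjects = excluded,
    excluded_sites = data.frame(site_id = small,
                                remaining_count = as.integer(cnt[small]),
                                stringsAsFactors = FALSE))
  S4Vectors::metadata(kept)$screening <- log
  list(dataset = kept, log = log)
}

#' Fit / apply per-feature standardization
#'
#' Statistics are fitted on training subjects only; validation and test data
#' are always transformed with training statistics.  Constant features
#' (sd below `tol`) are transformed to 0.
#'
#' @param x numeric matrix (subjects x features) or a
#'   [ConnectivitySet-class].
#' @param tol threshold under which a feature is flagged constant.
#' @return an object of class `StandardizerStats`: list with `mean`, `sd`
#'   (the fitted sd, >= 0) and `constant` (logical).
#' @export
fitStandardizer <- function(x, tol = 1e-12) {
  m <- if (is(x, "ConnectivitySet")) .subjectMatrix(x) else as.matrix(x)
  if (nrow(m) < 2L)
    stop("need at least 2 training subjects to fit a standardizer",
         call. = FALSE)
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  structure(list(mean = mu, sd = sd, constant = sd < tol),
            class = "StandardizerStats")
}

#' @rdname fitStandardizer
#' @param stats a fitted `StandardizerStats`.
#' @export
applyStandardizer <- function(stats, x) {
  m <- if (is(x, "ConnectivitySet")) .subjectMatrix(x) else as.matrix(x)
  if (ncol(m) != length(stats$mean))
    stop("feature dimension does not match the fitted standardizer",
         call. = FALSE)
  div <- ifelse(stats$constant, 1, stats$sd)
  out <- sweep(sweep(m, 2L, stats$mean), 2L, div, "/")
  out[, stats$constant] <- 0
  out
}

#' Write / read the feature cache CSV
#'
#' One row per subject: `subject_id`, `site_id`, `label`, then `f_0 ...
#' f_{D-1}`.
#'
#' @param x a [ConnectivitySet-class].
#' @param path CSV path.
#' @export
writeFeatureCSV <- function(x, path) {
  m <- .subjectMatrix(x)
  colnames(m) <- sprintf("f_%d", seq_len(ncol(m)) - 1L)
  df <- cbind(data.frame(subject_id = SummarizedExperiment::colData(x)$subject_id,
                         site_id = siteIds(x), label = diagnosisLabels(x),
                         stringsAsFactors = FALSE),
              as.data.frame(m))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @return `readFeatureCSV` returns a [ConnectivitySet-class].
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f_", colnames(df))
  if (!length(fcols)) stop("no feature columns (f_*) in ", path, call. = FALSE)
  ConnectivitySet(features = t(as.matrix(df[, fcols, drop = FALSE])),
                  subject_id = as.character(df$subject_id),
                  site_id = df$site_id, label = df$label)
}
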