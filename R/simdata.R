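## Seeded generator of multi-site, two-class ROI time series.  Site effects
## (connectivity mean shift, temporal autocorrelation, measurement noise)
## and a class effect on a subset of edges are applied on the Fisher-z
## scale, then back-transformed and projected to a valid correlation matrix;
## time series are drawn from a stationary vector AR(1) process whose
## instantaneous covariance equals the target.

#' Per-site settings for the simulator
#'
#' @param site_id site name.
#' @param n_subjects subjects at the site (>= 2).
#' @param t_points time points per subject (a repetition-time proxy: fewer
#'   points mean noisier sample correlations).
#' @param noise_scale standard deviation of additive white measurement noise
#'   (attenuates observed correlations; 0 = none).
#' @param mean_shift site-wide additive shift applied to every edge on the
#'   Fisher-z scale (a scanner effect).
#' @param class_ratio fraction of subjects with label 1 (ASD).
#' @param ar_coeff temporal AR(1) coefficient in [0, 1).
#' @return list of class `SimSite`.
#' @export
simSite <- function(site_id, n_subjects = 50L, t_points = 200L,
                    noise_scale = 0, mean_shift = 0, class_ratio = 0.5,
                    ar_coeff = 0.3) {
  if (n_subjects < 2L) stop("each site needs >= 2 subjects", call. = FALSE)
  if (class_ratio <= 0 || class_ratio >= 1)
    stop("class_ratio must be in (0, 1)", call. = FALSE)
  if (ar_coeff < 0 || ar_coeff >= 1)
    stop("ar_coeff must be in [0, 1)", call. = FALSE)
  structure(list(site_id = as.character(site_id),
                 n_subjects = as.integer(n_subjects),
                 t_points = as.integer(t_points),
                 noise_scale = noise_scale, mean_shift = mean_shift,
                 class_ratio = class_ratio, ar_coeff = ar_coeff),
            class = "SimSite")
}

#' Simulation specification
#'
#' @param n_rois atlas size (default 20 for scaled-down runs; 110 mimics the
#'   Harvard-Oxford atlas).
#' @param sites list of [simSite()] entries.
#' @param effect_edges fraction of edges carrying the class effect
#'   (default 0.2).
#' @param effect_size delta added on the Fisher-z scale to the masked edges
#'   of class-1 subjects (default 0.6).
#' @param seed integer.
#' @return list of class `SimSpec`.
#' @export
simSpec <- function(n_rois = 20L,
                    sites = list(simSite("SITE_A"), simSite("SITE_B"),
                                 simSite("SITE_C"), simSite("SITE_D")),
                    effect_edges = 0.2, effect_size = 0.6, seed = 1L) {
  if (n_rois < 2L) stop("need at least 2 ROIs", call. = FALSE)
  if (effect_edges < 0 || effect_edges > 1)
    stop("effect_edges is a fraction in [0, 1]", call. = FALSE)
  structure(list(n_rois = as.integer(n_rois), sites = sites,
                 effect_edges = effect_edges, effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "SimSpec")
}

#' Site-confounded simulation specification
#'
#' A ready-made [simSpec()] in which site scanner shifts are confounded with
#' class prevalence inconsistently across sites: two sites shift all edges
#' by +0.4 and two by -0.4 (z scale), with ASD prevalence 0.75 or 0.25
#' arranged so the shift-prevalence association differs between sites.  A
#' classifier that uses the shift as a shortcut is therefore misled on
#' held-out sites, which is the failure mode site harmonization must
#' overcome.  The class effect is 0.5 on 20% of edges.
#'
#' @param seed integer.
#' @param n_per_site subjects per site (default 24).
#' @return a `SimSpec`.
#' @export
confoundedSimSpec <- function(seed = 1L, n_per_site = 24L) {
  shifts <- c(0.4, -0.4, 0.4, -0.4)
  ratios <- c(0.75, 0.25, 0.25, 0.75)
  simSpec(n_rois = 20L,
          sites = lapply(1:4, function(i)
            simSite(paste0("SITE_", LETTERS[i]), n_per_site, 200L,
                    mean_shift = shifts[i], class_ratio = ratios[i])),
          effect_edges = 0.2, effect_size = 0.5, seed = seed)
}

## Random well-conditioned base correlation matrix (factor structure).
.baseCorrelation <- function(R, q = max(2L, R %/% 4L)) {
  L <- matrix(stats::rnorm(R * q, sd = 0.4), R, q)
  S <- tcrossprod(L) + diag(R)
  stats::cov2cor(S)
}

## Nearest-PD projection by eigenvalue clipping, rescaled to correlation.
.projectCorrelation <- function(C, floorEig = 1e-6) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, floorEig)
  S <- e$vectors %*% (vals * t(e$vectors))
  stats::cov2cor(S)
}

## Fill a symmetric matrix from a strictly-lower-triangle vector
## (row-major order, matching lowerTriangleVector), unit diagonal.
.symFromLower <- function(z, R) {
  m <- matrix(0, R, R)
  tm <- t(m)
  tm[upper.tri(tm)] <- z
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- 1
  m
}

## Stationary vector AR(1) with instantaneous covariance `C`
## (x_t = rho x_{t-1} + e_t, e ~ N(0, (1 - rho^2) C)), plus optional white
## measurement noise.  Uses the caller's RNG stream.
.simulateTimeseries <- function(C, t_points, ar_coeff, noise_scale = 0) {
  R <- nrow(C)
  ch <- chol(C)
  innov <- matrix(stats::rnorm(t_points * R), t_points, R) %*% ch
  ts <- matrix(0, t_points, R)
  ts[1L, ] <- innov[1L, ]
  if (t_points > 1L) {
    sc <- sqrt(1 - ar_coeff^2)
    for (tt in 2:t_points)
      ts[tt, ] <- ar_coeff * ts[tt - 1L, ] + sc * innov[tt, ]
  }
  if (noise_scale > 0)
    ts <- ts + matrix(stats::rnorm(t_points * R, sd = noise_scale),
                      t_points, R)
  ts
}

#' Simulate a multi-site two-class dataset
#'
#' Draws one shared base connectivity structure, adds the class effect
#' (`effect_size` on a seeded random `effect_edges` fraction of edges, on
#' the z scale) for class-1 subjects and each site's `mean_shift` on all
#' edges, back-transforms, projects to the nearest valid correlation matrix,
#' and generates each subject's time series from a stationary AR(1) process
#' with that instantaneous correlation, plus optional white measurement
#' noise.
#'
#' @param spec a [simSpec()].
#' @return list with `records` (subject records consumable by
#'   [buildConnectivitySet()]) and `effect_mask`, the logical ground-truth
#'   edge mask in strictly-lower-triangle order.
#' @export
simulateDataset <- function(spec) {
  R <- spec$n_rois
  D <- R * (R - 1L) / 2L
  .withSeed(spec$seed, {
    base <- .baseCorrelation(R)
    z0 <- fisherZ(lowerTriangleVector(base))
    nMask <- round(spec$effect_edges * D)
    mask <- rep(FALSE, D)
    if (nMask > 0) mask[sample.int(D, nMask)] <- TRUE
    records <- list()
    for (st in spec$sites) {
      nAsd <- round(st$class_ratio * st$n_subjects)
      labels <- c(rep(1L, nAsd), rep(0L, st$n_subjects - nAsd))
      for (si in seq_len(st$n_subjects)) {
        z <- z0 + st$mean_shift
        if (labels[si] == 1L) z <- z + spec$effect_size * mask
        Ct <- .projectCorrelation(.symFromLower(tanh(z), R))
        ts <- tryCatch(
          .simulateTimeseries(Ct, st$t_points, st$ar_coeff, st$noise_scale),
          error = function(e)
            stop(sprintf("subject %s_%03d: target correlation not positive definite",
                         st$site_id, si), call. = FALSE))
        records[[length(records) + 1L]] <- list(
          subject_id = sprintf("%s_%03d", st$site_id, si),
          site_id = st$site_id, label = labels[si], timeseries = ts)
      }
    }
    list(records = records, effect_mask = mask)
  })
}

#' Write a simulated dataset as text fixtures
#'
#' One `.1D`-dialect whitespace-delimited time-series file per subject (with
#' a `#` ROI-name header) plus one phenotype CSV (`SUB_ID`, `SITE_ID`,
#' `DX_GROUP` in the ABIDE coding 1 = ASD, 2 = TC), round-trippable through
#' [readRoiTimeseries()] and [readPhenotype()].
#'
#' @param records list of subject records from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the phenotype CSV path.
#' @export
writeFixture <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (r in records) {
    path <- file.path(dir, paste0(r$subject_id, ".1D"))
    con <- file(path, "w")
    writeLines(paste("#", paste(sprintf("ROI_%d", seq_len(ncol(r$timeseries))),
                                collapse = " ")), con)
    utils::write.table(format(r$timeseries, digits = 10, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  pheno <- data.frame(
    SUB_ID = vapply(records, `[[`, character(1), "subject_id"),
    SITE_ID = vapply(records, `[[`, character(1), "site_id"),
    DX_GROUP = ifelse(vapply(records, `[[`, integer(1), "label") == 1L,
                      1L, 2L))
  out <- file.path(dir, "phenotype.csv")
  utils::write.csv(pheno, out, row.names = FALSE)
  invisible(out)
}

#' Load a fixture directory back into subject records
#'
#' Companion reader to [writeFixture()]: reads the phenotype CSV and one
#' time-series file per subject.
#'
#' @param dir fixture directory.
#' @param dialect phenotype diagnosis coding, see [readPhenotype()].
#' @return list of subject records.
#' @export
readFixture <- function(dir, dialect = "abide") {
  pheno <- readPhenotype(file.path(dir, "phenotype.csv"), dialect = dialect)
  lapply(seq_len(nrow(pheno)), function(i) {
    list(subject_id = pheno$subject_id[i], site_id = pheno$site_id[i],
         label = pheno$label[i],
         timeseries = readRoiTimeseries(
           file.path(dir, paste0(pheno$subject_id[i], ".1D"))))
  })
}
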