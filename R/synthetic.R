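#' Cohort specification for the synthetic generator
#'
#' Describes the study design the generator emulates: two cohorts scanned
#' longitudinally, band-limited region signals sampled at a fixed TR. The
#' defaults reproduce the reference design: 13 transgenic-analog and 11
#' wild-type-analog subjects, 25 DMLN regions, 980 usable time points at
#' TR 0.6 s, signals band-limited to 0.01-0.17 Hz, two timepoints (4 and
#' 6 months).
#'
#' @param n_group_a,n_group_b Subjects per cohort (group labels default to
#'   `"TG"` and `"WT"`).
#' @param n_regions Number of regions.
#' @param n_timepoints Number of time samples per series.
#' @param tr Repetition time in seconds.
#' @param band Pass band in Hz, `c(low, high)`; must satisfy
#'   `0 < low < high < 1/(2 * tr)` (Nyquist). Use `NULL` for unfiltered
#'   white series.
#' @param timepoints Character labels of the longitudinal timepoints.
#' @param groups Character labels of the two cohorts.
#' @param seed Master integer seed; together with the spec it fully
#'   determines every generated series.
#'
#' @return A list of class `cohort_spec`.
#' @examples
#' cohort_spec(n_group_a = 3, n_group_b = 3, n_timepoints = 50)
#' @export
cohort_spec <- function(n_group_a = 13, n_group_b = 11, n_regions = 25,
                        n_timepoints = 980, tr = 0.6,
                        band = c(0.01, 0.17),
                        timepoints = c("4M", "6M"),
                        groups = c("TG", "WT"), seed = 1L) {
  stopifnot(n_group_a >= 2, n_group_b >= 2, n_regions >= 2,
            n_timepoints >= 10, tr > 0, length(groups) == 2,
            length(timepoints) >= 1)
  if (!is.null(band)) {
    nyquist <- 1 / (2 * tr)
    if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] ||
        band[2] >= nyquist) {
      stop("`band` must satisfy 0 < low < high < Nyquist (",
           signif(nyquist, 4), " Hz)", call. = FALSE)
    }
  }
  structure(list(n_group_a = n_group_a, n_group_b = n_group_b,
                 n_regions = n_regions, n_timepoints = n_timepoints,
                 tr = tr, band = band, timepoints = timepoints,
                 groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Factor-model network for synthetic connectivity
#'
#' The generator draws each subject's region signals from a Gaussian
#' factor model: region i loads on k latent factors with loadings
#' \eqn{\lambda_{ik}}, plus independent unique noise. The implied
#' correlation matrix is \eqn{\Lambda \Lambda^T} off the diagonal and 1 on
#' it; it is positive semi-definite by construction. The unique-noise
#' standard deviation is not free: the unit-variance constraint fixes it
#' at \eqn{\sqrt{1 - \sum_k \lambda_{ik}^2}} per region.
#'
#' @param loadings Either a vector of per-region loadings (single factor)
#'   or an R x k matrix (k factors). A scalar is recycled over
#'   `n_regions`. Each region's squared loadings must sum to < 1.
#' @param n_regions Required when `loadings` is a scalar.
#'
#' @return A list of class `network_model` with elements `loadings`
#'   (R x k matrix) and `noise_sd` (length-R vector).
#' @examples
#' m <- network_model(0.6, n_regions = 25)
#' range(m$noise_sd)
#' @export
network_model <- function(loadings, n_regions = NULL) {
  if (is.matrix(loadings)) {
    lambda <- loadings
  } else if (length(loadings) == 1L) {
    if (is.null(n_regions)) {
      stop("`n_regions` is required when `loadings` is a scalar",
           call. = FALSE)
    }
    lambda <- matrix(loadings, nrow = n_regions, ncol = 1L)
  } else {
    lambda <- matrix(loadings, ncol = 1L)
  }
  if (any(lambda < 0)) {
    stop("loadings must be non-negative", call. = FALSE)
  }
  comm <- rowSums(lambda^2)
  if (any(comm >= 1)) {
    stop("each region's squared loadings must sum to < 1", call. = FALSE)
  }
  structure(list(loadings = lambda, noise_sd = sqrt(1 - comm)),
            class = "network_model")
}

#' Plantable connectivity lesion
#'
#' Scales the factor loadings of selected regions in selected cohort
#' cells, producing hypo-connectivity (`loading_multiplier < 1`) or
#' hyper-connectivity (`> 1`) of those nodes relative to baseline: the
#' lesioned node i's off-diagonal correlations scale as
#' `multiplier * lambda_i * lambda_j`.
#'
#' @param target_regions Character labels (or integer indices) of the
#'   lesioned regions.
#' @param loading_multiplier Non-negative scale factor applied to the
#'   target regions' loadings.
#' @param groups,timepoints The cohort cells the lesion applies to: every
#'   (group, timepoint) combination of the two vectors.
#'
#' @return A list of class `effect_spec`.
#' @examples
#' effect_spec("CA2_L", 0.5, groups = "TG", timepoints = "4M")
#' @export
effect_spec <- function(target_regions, loading_multiplier,
                        groups, timepoints) {
  stopifnot(length(loading_multiplier) == 1, loading_multiplier >= 0,
            length(target_regions) >= 1)
  structure(list(target_regions = target_regions,
                 loading_multiplier = loading_multiplier,
                 groups = as.character(groups),
                 timepoints = as.character(timepoints)),
            class = "effect_spec")
}

effect_applies <- function(effect, group, timepoint) {
  group %in% effect$groups && timepoint %in% effect$timepoints
}

resolve_regions <- function(targets, labels) {
  if (is.numeric(targets)) {
    idx <- as.integer(targets)
    if (any(idx < 1 | idx > length(labels))) {
      stop("region index out of range", call. = FALSE)
    }
    return(idx)
  }
  idx <- match(targets, labels)
  if (anyNA(idx)) {
    stop("unknown region label(s): ",
         paste(targets[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Target correlation matrix for one cohort cell
#'
#' Builds the factor-model correlation matrix for a (group, timepoint)
#' cell, applying whichever lesions are in force there.
#'
#' @param model A [network_model()].
#' @param effects A single [effect_spec()], a list of them, or `NULL`.
#' @param group,timepoint Cohort cell selectors (matched against each
#'   effect's `groups`/`timepoints`).
#' @param regions A [region_set()] used to resolve effect target labels;
#'   defaults to anonymous regions of matching size.
#'
#' @return A symmetric positive semi-definite correlation matrix with unit
#'   diagonal and region labels as dimnames.
#' @examples
#' m <- network_model(0.7, n_regions = 3)
#' build_correlation(m)[1, 2]  # 0.49
#' @export
build_correlation <- function(model, effects = NULL, group = NA_character_,
                              timepoint = NA_character_, regions = NULL) {
  stopifnot(inherits(model, "network_model"))
  lambda <- model$loadings
  r <- nrow(lambda)
  if (is.null(regions)) regions <- synthetic_regions(r)
  if (nrow(regions) != r) {
    stop("region set size does not match the model", call. = FALSE)
  }
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  for (eff in effects) {
    if (!effect_applies(eff, group, timepoint)) next
    idx <- resolve_regions(eff$target_regions, regions$label)
    lambda[idx, ] <- lambda[idx, , drop = FALSE] * eff$loading_multiplier
    if (any(rowSums(lambda^2) >= 1)) {
      stop("lesioned loadings must keep squared sums < 1", call. = FALSE)
    }
  }
  corr <- tcrossprod(lambda)
  diag(corr) <- 1
  # factor model with unit diagonal is PSD by construction; guard anyway
  ev <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  stopifnot(ev > -1e-8)
  dimnames(corr) <- list(regions$label, regions$label)
  corr
}

#' One subject's region time series
#'
#' @param subject_id,group,timepoint Metadata labels.
#' @param data T x R numeric matrix, one column per region, in region-set
#'   order (column names = region labels).
#' @return A list of class `subject_ts`.
#' @export
subject_ts <- function(data, subject_id, group, timepoint) {
  data <- as.matrix(data)
  if (nrow(data) < 3) stop("need at least 3 time samples", call. = FALSE)
  if (anyNA(data)) stop("time series contains missing values", call. = FALSE)
  structure(list(data = data, subject_id = as.character(subject_id),
                 group = as.character(group),
                 timepoint = as.character(timepoint)),
            class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("<subject_ts> %s %s %s: %d samples x %d regions\n",
              x$subject_id, x$group, x$timepoint,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

# Zero-phase band-pass: 2nd-order Butterworth applied forward and backward
# (signal::filtfilt), identically to every column, so the cross-correlation
# structure is preserved up to sampling noise.
band_filter <- function(x, band, tr) {
  nyquist <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] >= nyquist || band[1] >= band[2]) {
    stop("`band` must lie strictly inside (0, Nyquist)", call. = FALSE)
  }
  bf <- signal::butter(2, band / nyquist, type = "pass")
  for (j in seq_len(ncol(x))) {
    x[, j] <- signal::filtfilt(bf, x[, j])
  }
  x
}

#' Draw one band-limited correlated time series
#'
#' Samples T correlated Gaussian vectors with the target correlation,
#' then applies the same zero-phase band-pass filter to every column and
#' removes column means. Filtering all channels identically leaves the
#' cross-correlation structure intact up to sampling noise (which the
#' band-limiting inflates by roughly the inverse square root of the band
#' fraction of Nyquist, because neighbouring samples become dependent).
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param corr Target correlation matrix (symmetric PSD, unit diagonal).
#' @param n_timepoints Number of samples T (>= 10).
#' @param band Pass band in Hz or `NULL` to skip filtering.
#' @param tr Repetition time in seconds.
#' @param subject_id,group,timepoint Metadata for the returned object.
#'
#' @return A [subject_ts()] whose `data` is a T x R matrix with zero-mean
#'   columns.
#' @examples
#' set.seed(1)
#' ts <- generate_subject(diag(3), 100, band = NULL)
#' colMeans(ts$data)
#' @export
generate_subject <- function(corr, n_timepoints, band = c(0.01, 0.17),
                             tr = 0.6, subject_id = "S01", group = "A",
                             timepoint = "T1") {
  assert_square_symmetric(corr, "corr")
  stopifnot(n_timepoints >= 10)
  r <- nrow(corr)
  # symmetric square root via eigen: tolerates semi-definite targets
  es <- eigen(corr, symmetric = TRUE)
  if (min(es$values) < -1e-8) stop("`corr` must be PSD", call. = FALSE)
  root <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  x <- matrix(stats::rnorm(n_timepoints * r), n_timepoints, r) %*% root
  if (!is.null(band)) x <- band_filter(x, band, tr)
  x <- sweep(x, 2L, colMeans(x))
  colnames(x) <- colnames(corr)
  subject_ts(x, subject_id, group, timepoint)
}

#' Generate a full synthetic cohort
#'
#' Produces one series per subject x timepoint under the factor model,
#' with any lesions applied in their cohort cells, plus a manifest. Each
#' subject's stream is seeded deterministically from
#' `(spec$seed, subject_id, timepoint)`, so the same spec and seed
#' reproduce every file bit for bit, and a subject's data at one
#' timepoint does not depend on cohort composition.
#'
#' @param spec A [cohort_spec()].
#' @param model A [network_model()]; defaults to a single factor with
#'   loading 0.6 everywhere (pairwise r = 0.36, a typical within-network
#'   coupling).
#' @param effects `NULL`, one [effect_spec()], or a list of them.
#' @param regions A [region_set()]; defaults to [dmln_regions()] when
#'   `spec$n_regions == 25`, otherwise anonymous regions.
#' @param dir If non-`NULL`, write one CSV per series (header = region
#'   labels) and a `manifest.tsv` there, and put file paths in the
#'   manifest.
#'
#' @return A list with `series` (list of [subject_ts()]), `manifest`
#'   (data frame: subject_id, group, timepoint, path) and `regions`.
#' @examples
#' spec <- cohort_spec(n_group_a = 2, n_group_b = 2, n_regions = 4,
#'                     n_timepoints = 40, timepoints = "4M", band = NULL)
#' cohort <- generate_cohort(spec)
#' nrow(cohort$manifest)
#' @export
generate_cohort <- function(spec, model = NULL, effects = NULL,
                            regions = NULL, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(model)) model <- network_model(0.6, spec$n_regions)
  if (nrow(model$loadings) != spec$n_regions) {
    stop("model size does not match spec$n_regions", call. = FALSE)
  }
  if (is.null(regions)) {
    regions <- if (spec$n_regions == 25) dmln_regions()
               else synthetic_regions(spec$n_regions)
  }
  stopifnot(nrow(regions) == spec$n_regions)
  if (inherits(effects, "effect_spec")) effects <- list(effects)

  ids <- c(sprintf("%s%02d", spec$groups[1], seq_len(spec$n_group_a)),
           sprintf("%s%02d", spec$groups[2], seq_len(spec$n_group_b)))
  if (anyDuplicated(ids)) stop("duplicate subject ids", call. = FALSE)
  grp <- rep(spec$groups, c(spec$n_group_a, spec$n_group_b))

  series <- list()
  rows <- list()
  for (i in seq_along(ids)) {
    for (tp in spec$timepoints) {
      corr <- build_correlation(model, effects, grp[i], tp, regions)
      ts <- with_seed(
        derive_seed(spec$seed, ids[i], tp),
        generate_subject(corr, spec$n_timepoints, spec$band, spec$tr,
                         subject_id = ids[i], group = grp[i],
                         timepoint = tp)
      )
      key <- paste(ids[i], tp, sep = "_")
      path <- NA_character_
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        path <- file.path(dir, paste0(key, ".csv"))
        utils::write.csv(ts$data, path, row.names = FALSE)
      }
      series[[key]] <- ts
      rows[[key]] <- data.frame(subject_id = ids[i], group = grp[i],
                                timepoint = tp, path = path,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(dir)) {
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(series = series, manifest = manifest, regions = regions)
}
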