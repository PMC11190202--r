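#' Define a cohort contrast
#'
#' Specifies one group comparison of mean nodal-degree profiles:
#' unpaired (e.g. genotype at one age, subjects relabeled across cohorts)
#' or paired (e.g. one genotype across two ages, timepoint labels swapped
#' within subject only, so no permuted group ever mixes two timepoints of
#' the same subject).
#'
#' @param kind `"unpaired"` or `"paired"`.
#' @param side_a,side_b Cohort cells, each a named vector or list with
#'   `group` and `timepoint`. The reported difference is
#'   `mean(side_a) - mean(side_b)`.
#' @param n_perm Number of permutation resamples (default 10000).
#' @param alpha Significance level for the FDR-corrected decision.
#' @param ci_level Confidence level of the permutation band, in percent.
#' @param seed Integer seed for the permutation stream.
#' @param fdr_family `"joint"` (default) corrects over all
#'   region x density cells of the contrast at once; `"per_density"`
#'   corrects within each density column separately.
#' @param name Optional label used in result tables.
#'
#' @return A list of class `nd_contrast_spec`.
#' @examples
#' contrast("unpaired", c(group = "TG", timepoint = "4M"),
#'          c(group = "WT", timepoint = "4M"))
#' @export
contrast <- function(kind = c("unpaired", "paired"), side_a, side_b,
                     n_perm = 10000, alpha = 0.05, ci_level = 95,
                     seed = 1L, fdr_family = c("joint", "per_density"),
                     name = NULL) {
  kind <- match.arg(kind)
  fdr_family <- match.arg(fdr_family)
  side_a <- as.list(side_a)
  side_b <- as.list(side_b)
  stopifnot(!is.null(side_a$group), !is.null(side_a$timepoint),
            !is.null(side_b$group), !is.null(side_b$timepoint),
            n_perm >= 100, alpha > 0, alpha < 1,
            ci_level > 0, ci_level < 100)
  if (identical(side_a, side_b)) {
    stop("side_a and side_b must differ", call. = FALSE)
  }
  if (is.null(name)) {
    name <- sprintf("%s_%s_vs_%s_%s", side_a$group, side_a$timepoint,
                    side_b$group, side_b$timepoint)
  }
  structure(list(kind = kind, side_a = side_a, side_b = side_b,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 ci_level = ci_level, seed = as.integer(seed),
                 fdr_family = fdr_family, name = name),
            class = "nd_contrast_spec")
}

side_key <- function(side) paste(side$group, side$timepoint, sep = "_")

select_profiles <- function(profiles, side) {
  hit <- vapply(profiles, function(p) {
    p$group == side$group && p$timepoint == side$timepoint
  }, logical(1))
  sel <- profiles[hit]
  sel[order(vapply(sel, function(p) p$subject_id, character(1)))]
}

# Stack profiles into a (R * |densities|) x n matrix; cells vary region
# fastest. All profiles must share region order and density grid.
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]
  for (p in profiles) {
    if (!identical(p$densities, ref$densities) ||
        !identical(p$regions, ref$regions)) {
      stop("profiles disagree on region order or density grid",
           call. = FALSE)
    }
  }
  matrix(vapply(profiles, function(p) as.vector(p$values),
                numeric(length(ref$values))),
         nrow = length(ref$values), ncol = length(profiles))
}

#' Mean nodal-degree profile of a cohort cell
#'
#' @param profiles Non-empty list of `nd_profile` objects on a common
#'   region order and density grid.
#' @return R x |densities| matrix of mean degrees.
#' @export
group_mean_nd <- function(profiles) {
  if (length(profiles) == 0) stop("empty profile selection", call. = FALSE)
  ref <- profiles[[1]]
  m <- rowMeans(profile_matrix(profiles))
  matrix(m, nrow(ref$values), ncol(ref$values),
         dimnames = list(ref$regions, as.character(ref$densities)))
}

#' Observed mean-degree difference between two cohort cells
#'
#' @param profiles_a,profiles_b Lists of `nd_profile` objects.
#' @return R x |densities| matrix `mean(a) - mean(b)`.
#' @export
observed_difference <- function(profiles_a, profiles_b) {
  ma <- group_mean_nd(profiles_a)
  mb <- group_mean_nd(profiles_b)
  if (!identical(dimnames(ma), dimnames(mb))) {
    stop("the two sides disagree on region order or density grid",
         call. = FALSE)
  }
  ma - mb
}

#' Random relabeling for the unpaired permutation null
#'
#' Returns a uniformly random permutation of the cohort labels over the
#' pooled subjects, preserving the group sizes. Uses the current RNG
#' state.
#'
#' @param labels Character vector of group labels, one per subject.
#' @return Permuted label vector of the same length.
#' @export
permute_unpaired <- function(labels) {
  labels[sample.int(length(labels))]
}

#' Random within-subject swaps for the paired permutation null
#'
#' Each subject's two timepoint labels are independently swapped with
#' probability 1/2; subjects are never mixed. Uses the current RNG state.
#'
#' @param n Number of paired subjects.
#' @return Logical vector: `TRUE` where the subject's timepoints swap.
#' @export
permute_paired <- function(n) {
  stats::runif(n) < 0.5
}

#' Permutation test of mean nodal-degree differences
#'
#' For every (region, density) cell: computes the observed difference in
#' mean nodal degree between the two sides, builds the permutation null
#' (`n_perm` random relabelings for unpaired contrasts, within-subject
#' timepoint swaps for paired ones), and reports a two-sided add-one
#' p-value `p = (#\{|null| >= |observed|\} + 1) / (n_perm + 1)` together
#' with equal-tail percentile confidence bounds of the null. P-values
#' are then FDR-adjusted (Benjamini-Hochberg) over the contrast's family
#' of cells and significance flagged at `alpha`.
#'
#' Unpaired nulls are generated in a canonical side order, so swapping
#' `side_a`/`side_b` under the same seed negates every difference exactly
#' and leaves every p-value unchanged.
#'
#' @param profiles List of `nd_profile` objects covering both sides.
#' @param spec An [contrast()] specification.
#' @param regions Optional [region_set()] used to attach hemisphere
#'   labels to the result.
#' @param keep_null If `TRUE`, attach the null-difference matrix
#'   (cells x n_perm, region varying fastest) as attribute `"null"`.
#'
#' @return A data frame of class `nd_contrast` with one row per
#'   (region, density): `contrast`, `region`, (`hemisphere`,) `density`,
#'   `mean_a`, `mean_b`, `diff`, `ci_low`, `ci_high`, `p_raw`, `p_fdr`,
#'   `significant`, `outside_ci`.
#' @examples
#' spec <- cohort_spec(n_group_a = 4, n_group_b = 4, n_regions = 6,
#'                     n_timepoints = 60, timepoints = "4M")
#' cohort <- generate_cohort(spec)
#' profs <- cohort_profiles(cohort$series, densities = c(20, 30))
#' ct <- contrast("unpaired", c(group = "TG", timepoint = "4M"),
#'                c(group = "WT", timepoint = "4M"), n_perm = 200)
#' res <- permutation_test(profs, ct)
#' head(res)
#' @export
permutation_test <- function(profiles, spec, regions = NULL,
                             keep_null = FALSE) {
  stopifnot(inherits(spec, "nd_contrast_spec"))
  prof_a <- select_profiles(profiles, spec$side_a)
  prof_b <- select_profiles(profiles, spec$side_b)
  if (length(prof_a) == 0 || length(prof_b) == 0) {
    stop("empty selection for contrast side (", side_key(spec$side_a),
         " vs ", side_key(spec$side_b), ")", call. = FALSE)
  }
  invisible(profile_matrix(c(prof_a, prof_b)))  # common grid/ordering check
  ref <- prof_a[[1]]
  b_perm <- spec$n_perm

  if (spec$kind == "unpaired") {
    # canonical orientation: side with the smaller key goes first, so the
    # null stream is independent of the side_a/side_b ordering
    flip <- side_key(spec$side_a) > side_key(spec$side_b)
    first <- if (flip) prof_b else prof_a
    second <- if (flip) prof_a else prof_b
    p1 <- profile_matrix(first)
    p2 <- profile_matrix(second)
    pooled <- cbind(p1, p2)
    n1 <- ncol(p1); n <- ncol(pooled)
    obs_canon <- rowMeans(p1) - rowMeans(p2)
    w <- with_seed(spec$seed, {
      vapply(seq_len(b_perm), function(b) {
        idx <- sample.int(n)
        wt <- numeric(n)
        wt[idx[seq_len(n1)]] <- 1 / n1
        wt[idx[(n1 + 1L):n]] <- -1 / (n - n1)
        wt
      }, numeric(n))
    })
    null_canon <- pooled %*% w
    s <- if (flip) -1 else 1
    obs <- s * obs_canon
    null_rep <- s * null_canon
  } else {
    ids_a <- vapply(prof_a, function(p) p$subject_id, character(1))
    ids_b <- vapply(prof_b, function(p) p$subject_id, character(1))
    if (anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
      stop("duplicate subject in one side of a paired contrast",
           call. = FALSE)
    }
    lonely <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    if (length(lonely)) {
      stop("unpaired subject(s) in paired contrast: ",
           paste(sort(lonely), collapse = ", "), call. = FALSE)
    }
    # select_profiles sorts by subject id, so columns align
    dm <- profile_matrix(prof_a) - profile_matrix(prof_b)
    n <- ncol(dm)
    obs <- rowMeans(dm)
    signs <- with_seed(spec$seed, {
      matrix(ifelse(permute_paired(n * b_perm), -1, 1), n, b_perm)
    })
    null_rep <- (dm %*% signs) / n
  }

  # two-sided add-one p; tiny tolerance so ties in the discrete degree
  # statistic are not lost to float error
  tol <- 1e-9
  p_raw <- (rowSums(abs(null_rep) >= abs(obs) - tol) + 1) / (b_perm + 1)
  tail <- (1 - spec$ci_level / 100) / 2
  ci <- row_quantiles(null_rep, c(tail, 1 - tail))

  ma <- rowMeans(profile_matrix(prof_a))
  mb <- rowMeans(profile_matrix(prof_b))
  out <- data.frame(
    contrast = spec$name,
    region = rep(ref$regions, times = length(ref$densities)),
    density = rep(ref$densities, each = length(ref$regions)),
    mean_a = ma, mean_b = mb, diff = obs,
    ci_low = ci[, 1L], ci_high = ci[, 2L],
    p_raw = p_raw, stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(regions)) {
    out$hemisphere <- regions$hemisphere[match(out$region, regions$label)]
    out <- out[, c("contrast", "region", "hemisphere", "density",
                   "mean_a", "mean_b", "diff", "ci_low", "ci_high",
                   "p_raw")]
  }
  out$p_fdr <- fdr_adjust(out$p_raw,
                          family = if (spec$fdr_family == "per_density")
                            out$density else NULL)
  out <- flag_significance(out, spec$alpha)
  attr(out, "spec") <- spec
  attr(out, "n_a") <- length(prof_a)
  attr(out, "n_b") <- length(prof_b)
  if (keep_null) attr(out, "null") <- null_rep
  class(out) <- c("nd_contrast", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values over one family of comparisons (by default
#' all region x density cells of a contrast jointly).
#'
#' @param p Numeric vector (or matrix) of raw p-values in (0, 1].
#' @param family Optional grouping vector of the same length; when given,
#'   the adjustment is applied within each family level separately.
#' @return Adjusted p-values, same shape as `p`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.9))
#' @export
fdr_adjust <- function(p, family = NULL) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  adj <- if (is.null(family)) {
    stats::p.adjust(as.vector(p), method = "BH")
  } else {
    out <- numeric(length(p))
    for (lev in unique(family)) {
      sel <- family == lev
      out[sel] <- stats::p.adjust(as.vector(p)[sel], method = "BH")
    }
    out
  }
  if (is.matrix(p)) adj <- matrix(adj, nrow(p), ncol(p), dimnames = dimnames(p))
  adj
}

#' Flag significant cells
#'
#' The decision criterion is the FDR-adjusted p-value (`p_fdr < alpha`).
#' The auxiliary flag `outside_ci` records whether the observed
#' difference falls outside the permutation confidence band, the
#' figure-style display criterion.
#'
#' @param result A contrast result data frame with `p_fdr`, `diff`,
#'   `ci_low`, `ci_high` columns.
#' @param alpha Significance level.
#' @return The result with `significant` and `outside_ci` columns set.
#' @export
flag_significance <- function(result, alpha = 0.05) {
  stopifnot(all(c("p_fdr", "diff", "ci_low", "ci_high") %in% names(result)))
  result$significant <- result$p_fdr < alpha
  result$outside_ci <- result$diff < result$ci_low |
    result$diff > result$ci_high
  result
}
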