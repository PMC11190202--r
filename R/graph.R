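#' Density grid
#'
#' The proportional-threshold densities (in percent) at which graphs are
#' built. The default sweeps 5-50% in 1% steps: below 5% the network
#' fragments, above 50% it approaches randomness.
#'
#' @param from,to,by Percent bounds and step.
#' @return Numeric vector of strictly increasing densities in (0, 100].
#' @export
density_grid <- function(from = 5, to = 50, by = 1) {
  d <- seq(from, to, by = by)
  if (any(d <= 0 | d > 100) || is.unsorted(d, strictly = TRUE)) {
    stop("densities must be strictly increasing and in (0, 100]",
         call. = FALSE)
  }
  d
}

#' Deterministic edge ranking
#'
#' Orders the R(R-1)/2 upper-triangle edges by weight, strongest first.
#' Ties are broken lexicographically (smaller row index, then smaller
#' column index) so that "the strongest D% of connections" is a
#' deterministic, reproducible set.
#'
#' @param fcm Symmetric weight matrix (zero diagonal).
#' @return Data frame with columns `i`, `j` (1-based, `i < j`) and
#'   `weight`, one row per edge, in rank order.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 0.9; w[2, 3] <- w[3, 2] <- 0.4
#' rank_edges(w)
#' @export
rank_edges <- function(fcm) {
  assert_square_symmetric(fcm, "fcm")
  r <- nrow(fcm)
  idx <- which(upper.tri(fcm), arr.ind = TRUE)
  # upper.tri ordering is column-major; reorder to (i, j) lexicographic so
  # ties resolve by smaller row then smaller column
  lex <- order(idx[, 1L], idx[, 2L])
  idx <- idx[lex, , drop = FALSE]
  w <- fcm[idx]
  ord <- order(-w)  # stable sort: preserves lexicographic order within ties
  data.frame(i = idx[ord, 1L], j = idx[ord, 2L], weight = w[ord])
}

edge_count <- function(density, r) {
  m_total <- r * (r - 1) / 2
  # half-up rounding (round() is banker's): floor(x + 0.5)
  m <- floor(density / 100 * m_total + 0.5)
  if (m < 1) {
    stop(sprintf("density %.3g%% keeps no edges for %d regions", density, r),
         call. = FALSE)
  }
  as.integer(m)
}

#' Proportional density threshold
#'
#' Binarises a weighted connectivity matrix by keeping exactly the
#' strongest D% of all possible edges: `m = round(D/100 * R(R-1)/2)`
#' edges (half-up rounding), taken as the first `m` edges of
#' [rank_edges()].
#'
#' @param fcm Symmetric weight matrix (zero diagonal).
#' @param density Percent density in (0, 100].
#' @return Symmetric 0/1 adjacency matrix with zero diagonal and
#'   attribute `density`.
#' @examples
#' set.seed(1)
#' a <- proportional_threshold(fc_matrix(matrix(rnorm(500), 20, 25)), 5)
#' sum(a) / 2  # 15 edges for R = 25 at D = 5
#' @export
proportional_threshold <- function(fcm, density) {
  stopifnot(length(density) == 1, density > 0, density <= 100)
  edges <- rank_edges(fcm)
  m <- edge_count(density, nrow(fcm))
  adj <- matrix(0L, nrow(fcm), ncol(fcm), dimnames = dimnames(fcm))
  keep <- edges[seq_len(m), , drop = FALSE]
  adj[cbind(keep$i, keep$j)] <- 1L
  adj[cbind(keep$j, keep$i)] <- 1L
  attr(adj, "density") <- density
  adj
}

#' Nodal degree
#'
#' The degree centrality of each node in a binary graph: the number of
#' edges incident to it, \eqn{ND_i = \sum_j a_{ij}}.
#'
#' @param adj Symmetric 0/1 adjacency matrix with zero diagonal.
#' @return Integer vector of degrees, named by region when the adjacency
#'   has dimnames.
#' @export
nodal_degree <- function(adj) {
  assert_square_symmetric(adj, "adjacency")
  if (!all(adj %in% c(0, 1)) || any(diag(adj) != 0)) {
    stop("adjacency must be 0/1 with zero diagonal", call. = FALSE)
  }
  stats::setNames(as.integer(rowSums(adj)), rownames(adj))
}

#' Nodal-degree profile across the density sweep
#'
#' Thresholds one subject's weighted connectivity matrix at every density
#' of the grid and records the nodal degrees. The edge ranking is
#' computed once, so the graphs are nested: the adjacency at a lower
#' density is a subset of the adjacency at any higher density, and each
#' region's degree is non-decreasing along the grid.
#'
#' @param fcm An `fc_matrix` (or any symmetric non-negative weight
#'   matrix with zero diagonal).
#' @param densities Density grid in percent (default [density_grid()]).
#' @param subject_id,group,timepoint Metadata carried into the profile.
#' @return An object of class `nd_profile`: list with `values` (R x
#'   |densities| integer matrix, rows = regions, columns = densities),
#'   `densities`, `regions` (labels) and the metadata fields.
#' @examples
#' set.seed(1)
#' p <- density_sweep(fc_matrix(matrix(rnorm(2500), 100, 25)))
#' dim(p$values)  # 25 x 46
#' @export
density_sweep <- function(fcm, densities = density_grid(),
                          subject_id = NA_character_,
                          group = NA_character_,
                          timepoint = NA_character_) {
  if (any(densities <= 0 | densities > 100) ||
      is.unsorted(densities, strictly = TRUE)) {
    stop("densities must be strictly increasing and in (0, 100]",
         call. = FALSE)
  }
  edges <- rank_edges(fcm)
  r <- nrow(fcm)
  labels <- rownames(fcm)
  if (is.null(labels)) labels <- as.character(seq_len(r))
  values <- matrix(0L, r, length(densities),
                   dimnames = list(labels, as.character(densities)))
  # one ranking, incremental degree accumulation => nested graphs
  deg <- integer(r)
  prev_m <- 0L
  for (k in seq_along(densities)) {
    m <- edge_count(densities[k], r)
    if (m > prev_m) {
      new <- edges[(prev_m + 1L):m, , drop = FALSE]
      deg <- deg + tabulate(c(new$i, new$j), nbins = r)
      prev_m <- m
    }
    values[, k] <- deg
  }
  structure(list(values = values, densities = densities, regions = labels,
                 subject_id = as.character(subject_id),
                 group = as.character(group),
                 timepoint = as.character(timepoint)),
            class = "nd_profile")
}

#' @export
print.nd_profile <- function(x, ...) {
  cat(sprintf("<nd_profile> %s %s %s: %d regions x %d densities\n",
              x$subject_id, x$group, x$timepoint,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Nodal-degree profiles for a whole cohort
#'
#' Maps the connectivity + sweep stages over a list of recordings.
#'
#' @param series List of [subject_ts()] objects.
#' @param densities Density grid in percent.
#' @return List of `nd_profile` objects (same names as `series`).
#' @export
cohort_profiles <- function(series, densities = density_grid()) {
  lapply(series, function(ts) {
    density_sweep(fc_matrix(ts), densities,
                  subject_id = ts$subject_id, group = ts$group,
                  timepoint = ts$timepoint)
  })
}

#' Long-format export of nodal-degree profiles
#'
#' @param profiles List of `nd_profile` objects.
#' @return Data frame with columns subject_id, group, timepoint, region,
#'   density, nd.
#' @export
profiles_to_long <- function(profiles) {
  do.call(rbind, lapply(unname(profiles), function(p) {
    data.frame(subject_id = p$subject_id, group = p$group,
               timepoint = p$timepoint,
               region = rep(p$regions, times = length(p$densities)),
               density = rep(p$densities, each = length(p$regions)),
               nd = as.vector(p$values), stringsAsFactors = FALSE)
  }))
}
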