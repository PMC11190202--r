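# Shared fixture builders. Everything is generated in code at test time.

# Random symmetric non-negative weight matrix with zero diagonal
# (an fc_matrix-shaped object without going through time series).
rand_fcm <- function(r, weights = NULL) {
  w <- matrix(0, r, r)
  ut <- upper.tri(w)
  w[ut] <- if (is.null(weights)) stats::runif(sum(ut)) else weights
  w + t(w)
}

# Random 0/1 symmetric adjacency with zero diagonal.
rand_adjacency <- function(r, p = 0.4) {
  a <- matrix(0L, r, r)
  ut <- upper.tri(a)
  a[ut] <- as.integer(stats::runif(sum(ut)) < p)
  a + t(a)
}

# Build an nd_profile directly from a value matrix (for group-stats tests
# that need prescribed degrees rather than generated data).
make_profile <- function(values, densities, subject_id, group, timepoint) {
  values <- as.matrix(values)
  regions <- rownames(values)
  if (is.null(regions)) regions <- as.character(seq_len(nrow(values)))
  structure(list(values = values, densities = densities, regions = regions,
                 subject_id = as.character(subject_id),
                 group = as.character(group),
                 timepoint = as.character(timepoint)),
            class = "nd_profile")
}

# A small two-cell cohort of prescribed single-cell profiles: values_a /
# values_b are numeric vectors, one entry per subject (1 region x 1 density).
scalar_profiles <- function(values_a, values_b, group_a = "TG",
                            group_b = "WT", timepoint = "4M",
                            timepoint_b = timepoint) {
  pa <- lapply(seq_along(values_a), function(i) {
    make_profile(matrix(values_a[i], 1, 1, dimnames = list("R1", "20")),
                 20, sprintf("%s%02d", group_a, i), group_a, timepoint)
  })
  pb <- lapply(seq_along(values_b), function(i) {
    make_profile(matrix(values_b[i], 1, 1, dimnames = list("R1", "20")),
                 20, sprintf("%s%02d", group_b, i), group_b, timepoint_b)
  })
  c(pa, pb)
}
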