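# Internal helpers.

# Deterministic per-subject seed stream: hashes (seed, subject_id, timepoint)
# into [1, 2^31 - 2] so one master seed reproduces every series exactly.
derive_seed <- function(seed, subject_id, timepoint) {
  key <- paste(subject_id, timepoint, sep = "\r")
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h) + 1L
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Row-wise equal-tail quantiles (type 7), used for permutation CI bands.
row_quantiles <- function(x, probs) {
  t(apply(x, 1L, stats::quantile, probs = probs, names = FALSE, type = 7))
}

assert_square_symmetric <- function(m, what = "matrix",
                                    tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  invisible(m)
}
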