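test_that("group means and differences follow the arithmetic oracles", {
  p10 <- make_profile(matrix(10, 3, 2), c(20, 30), "a1", "A", "T1")
  p20 <- make_profile(matrix(20, 3, 2), c(20, 30), "a2", "A", "T1")
  # one subject: mean is that profile
  expect_equal(unname(group_mean_nd(list(p10))), matrix(10, 3, 2))
  # two flat profiles average cellwise
  expect_equal(unname(group_mean_nd(list(p10, p20))), matrix(15, 3, 2))
  expect_error(group_mean_nd(list()), "empty")

  # seeded profiles against an explicit summation oracle
  set.seed(21)
  vals <- replicate(5, matrix(sample(0:10, 6, TRUE), 3, 2),
                    simplify = FALSE)
  profs <- lapply(seq_along(vals), function(i)
    make_profile(vals[[i]], c(20, 30), paste0("s", i), "A", "T1"))
  oracle <- Reduce(`+`, vals) / 5
  expect_equal(unname(group_mean_nd(profs)), oracle)

  # observed difference: zero for identical sides, antisymmetric on swap
  expect_equal(unname(observed_difference(profs, profs)),
               matrix(0, 3, 2))
  d_ab <- observed_difference(profs[1:2], profs[3:5])
  d_ba <- observed_difference(profs[3:5], profs[1:2])
  expect_equal(d_ab, -d_ba)
  expect_equal(unname(d_ab), vals[[1]] / 2 + vals[[2]] / 2 -
                 (vals[[3]] + vals[[4]] + vals[[5]]) / 3)

  # mismatched grids are rejected
  p_bad <- make_profile(matrix(1, 3, 2), c(20, 40), "x", "B", "T1")
  expect_error(observed_difference(profs, list(p_bad)), "grid")
})

test_that("unpaired relabeling preserves sizes and is uniform", {
  labels <- rep(c("TG", "WT"), c(13, 11))
  set.seed(22)
  for (rep in 1:20) {
    perm <- permute_unpaired(labels)
    expect_equal(sum(perm == "TG"), 13)
    expect_equal(sum(perm == "WT"), 11)
  }
  # 2 + 2 subjects: only the C(4,2) = 6 assignments occur, uniformly
  set.seed(23)
  draws <- replicate(6000, paste(permute_unpaired(c("A", "A", "B", "B")),
                                 collapse = ""))
  tab <- table(draws)
  expect_length(tab, 6)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  # seeded stream is reproducible
  set.seed(24); a <- replicate(5, permute_unpaired(labels))
  set.seed(24); b <- replicate(5, permute_unpaired(labels))
  expect_identical(a, b)
})

test_that("paired swaps are independent fair coin flips per subject", {
  set.seed(25)
  draws <- replicate(8000, paste(as.integer(permute_paired(3)),
                                 collapse = ""))
  tab <- table(draws)
  expect_length(tab, 8)  # all 2^3 patterns appear
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("degenerate nulls give p = 1 under the add-one convention", {
  # both sides carry identical flat profiles: zero diff, zero-variance null
  profs <- scalar_profiles(rep(4, 5), rep(4, 5))
  ct <- contrast("unpaired", c(group = "TG", timepoint = "4M"),
                 c(group = "WT", timepoint = "4M"), n_perm = 200)
  res <- permutation_test(profs, ct)
  expect_equal(res$diff, 0)
  expect_equal(res$p_raw, 1)
  expect_false(any(res$significant))
})

test_that("a strong planted lesion is detected at the add-one floor", {
  # synthetic cohort, multiplier 0.3 lesion on node 1 in the TG analogs
  m <- network_model(0.6, 8)
  eff <- effect_spec(1, 0.3, groups = "TG", timepoints = "4M")
  spec <- cohort_spec(n_group_a = 8, n_group_b = 8, n_regions = 8,
                      n_timepoints = 300, timepoints = "4M", seed = 26)
  cohort <- generate_cohort(spec, model = m, effects = eff)
  profs <- cohort_profiles(cohort$series, densities = c(20, 30, 40))
  ct <- contrast("unpaired", c(group = "TG", timepoint = "4M"),
                 c(group = "WT", timepoint = "4M"), n_perm = 1000,
                 seed = 27)
  res <- permutation_test(profs, ct)
  r1 <- res[res$region == "R01", ]
  expect_lte(min(r1$p_raw), 3 / 1001)
  expect_lt(r1$diff[which.min(r1$p_raw)], 0)
})

test_that("swapping contrast sides negates diffs and keeps p-values", {
  set.seed(28)
  profs <- scalar_profiles(rpois(6, 8), rpois(5, 10))
  fwd <- contrast("unpaired", c(group = "TG", timepoint = "4M"),
                  c(group = "WT", timepoint = "4M"), n_perm = 500,
                  seed = 29)
  rev <- contrast("unpaired", c(group = "WT", timepoint = "4M"),
                  c(group = "TG", timepoint = "4M"), n_perm = 500,
                  seed = 29)
  ra <- permutation_test(profs, fwd)
  rb <- permutation_test(profs, rev)
  expect_equal(rb$diff, -ra$diff)
  expect_identical(rb$p_raw, ra$p_raw)
  expect_equal(rb$ci_low, -ra$ci_high)
  expect_equal(rb$ci_high, -ra$ci_low)
})

test_that("paired nulls are within-subject sign flips only", {
  set.seed(30)
  n <- 6
  v1 <- rpois(n, 10); v2 <- rpois(n, 8)
  profs <- c(
    lapply(seq_len(n), function(i)
      make_profile(matrix(v1[i], 1, 1, dimnames = list("R1", "20")), 20,
                   sprintf("S%02d", i), "TG", "6M")),
    lapply(seq_len(n), function(i)
      make_profile(matrix(v2[i], 1, 1, dimnames = list("R1", "20")), 20,
                   sprintf("S%02d", i), "TG", "4M")))
  ct <- contrast("paired", c(group = "TG", timepoint = "6M"),
                 c(group = "TG", timepoint = "4M"), n_perm = 2000,
                 seed = 31)
  res <- permutation_test(profs, ct, keep_null = TRUE)
  expect_equal(res$diff, mean(v1 - v2))
  # every sampled null value lies in the exhaustive 2^n sign-flip support
  d <- v1 - v2
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  support <- sort(unique(as.vector(signs %*% d) / n))
  null <- as.vector(attr(res, "null"))
  expect_true(all(vapply(null, function(x)
    any(abs(support - x) < 1e-9), logical(1))))

  # a subject present at only one timepoint is a named error
  lonely <- make_profile(matrix(5, 1, 1, dimnames = list("R1", "20")), 20,
                         "S99", "TG", "6M")
  expect_error(permutation_test(c(profs, list(lonely)), ct),
               "unpaired subject.*S99")
})

test_that("permutation results are reproducible under a fixed seed", {
  set.seed(32)
  profs <- scalar_profiles(rpois(5, 6), rpois(5, 9))
  ct <- contrast("unpaired", c(group = "TG", timepoint = "4M"),
                 c(group = "WT", timepoint = "4M"), n_perm = 300,
                 seed = 33)
  expect_identical(permutation_test(profs, ct), permutation_test(profs, ct))
})

test_that("BH adjustment matches the hand-worked step-up", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.060, 0.074, 0.205, 0.212,
         0.216)
  # step-up worked by hand: p_(i) * m / i, cumulative minimum from the
  # largest rank down
  hand <- c(0.01, 0.04, 0.084, 0.084, 0.084, 0.1, 0.74 / 7, 0.216, 0.216,
            0.216)
  expect_equal(fdr_adjust(p), hand, tolerance = 1e-12)
  # shuffled input adjusts identically after unshuffling
  ord <- c(5, 1, 9, 3, 7, 2, 10, 4, 6, 8)
  expect_equal(fdr_adjust(p[ord])[order(ord)], hand, tolerance = 1e-12)
  # single comparison is untouched; all-1 input rejects nothing
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  # adjusted values are monotone in the raw values
  set.seed(34)
  pr <- runif(50)
  adj <- fdr_adjust(pr)
  expect_true(all(diff(adj[order(pr)]) >= -1e-12))
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
})

test_that("per-density FDR families adjust each column separately", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  dens <- c(20, 20, 30, 30)
  joint <- fdr_adjust(p)
  per <- fdr_adjust(p, family = dens)
  expect_equal(per[1:2], stats::p.adjust(p[1:2], "BH"))
  expect_equal(per[3:4], stats::p.adjust(p[3:4], "BH"))
  expect_false(identical(joint, per))
})

test_that("significance is driven by FDR with the CI band as display", {
  res <- data.frame(diff = c(-3, 2, 0.1), ci_low = c(-2, -1, -1),
                    ci_high = c(2, 1, 1), p_fdr = c(0.01, 0.20, 0.60))
  out <- flag_significance(res, alpha = 0.05)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(out$outside_ci, c(TRUE, TRUE, FALSE))
})
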