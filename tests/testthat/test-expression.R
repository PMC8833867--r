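# Filtering, normalization, aggregation, monotone selection, fold changes
# and total-expression ranking.

toy_meta <- function(animals = 2, timepoints = c(0, 3, 4.5)) {
  grid <- expand.grid(animal_id = sprintf("d%d", seq_len(animals)),
                      timepoint_minutes = timepoints,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_t%s", grid$animal_id, grid$timepoint_minutes)
  grid[, c("sample_id", "animal_id", "timepoint_minutes")]
}

test_that("low-count filter keeps a gene iff some library reaches the threshold", {
  m <- matrix(c(9, 9, 9,  0, 0, 10,  10, 10, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("below", "edge", "above"), c("s1", "s2", "s3")))
  kept <- filter_low_counts(m, 10)
  expect_identical(rownames(kept), c("edge", "above"))
  expect_identical(colnames(kept), colnames(m))
  # idempotent, and min_reads = 0 is the identity
  expect_identical(filter_low_counts(kept, 10), kept)
  expect_identical(filter_low_counts(m, 0), m)
  # degenerate: everything filtered away is still a valid (empty) matrix
  none <- filter_low_counts(m, 1000)
  expect_identical(nrow(none), 0L)
  expect_identical(colnames(none), colnames(m))
})

test_that("size factors match the closed-form two-library case and recover depth distortions", {
  base <- matrix(c(10, 20, 30, 40), ncol = 1)
  m <- cbind(base, 2 * base)
  dimnames(m) <- list(paste0("g", 1:4), c("s1", "s2"))
  f <- estimate_size_factors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical libraries give unit factors
  same <- cbind(base, base); dimnames(same) <- dimnames(m)
  expect_equal(unname(estimate_size_factors(same)), c(1, 1))
  # proportional libraries: known integer depth distortions are recovered exactly
  set.seed(42)
  depth <- c(1, 2, 4)
  m3 <- outer(rpois(100, 50) + 1, depth)
  dimnames(m3) <- list(sprintf("g%03d", 1:100), c("a", "b", "c"))
  f3 <- estimate_size_factors(m3)
  target <- depth / exp(mean(log(depth)))
  expect_equal(unname(f3), target, tolerance = 1e-12)
  # permutation equivariance
  perm <- m3[, c(3, 1, 2)]
  expect_equal(estimate_size_factors(perm), f3[c(3, 1, 2)])
  # geometric mean is one
  expect_equal(mean(log(f3)), 0, tolerance = 1e-9)
  # all-zero-containing genes only -> estimation error advising filtering
  z <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimate_size_factors(z), "pre-filter")
})

test_that("size factors agree with the reference median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  m <- matrix(rpois(600, lambda = rep(c(20, 200, 1000), each = 200)) + 1,
              nrow = 150)
  dimnames(m) <- list(sprintf("g%03d", 1:150), paste0("s", 1:4))
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))   # same geometric-mean-1 convention
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("normalization divides columns and equalizes proportional libraries", {
  m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  f <- estimate_size_factors(m)
  norm <- normalize_counts(m, f)
  # proportional libraries end up identical after normalization
  expect_equal(norm[, 1], norm[, 2])
  expect_equal(normalize_counts(m, c(s1 = 1, s2 = 1)), m)
  half <- normalize_counts(m, c(s1 = 1, s2 = 2))
  expect_equal(half[, "s2"], m[, "s2"] / 2)
  expect_error(normalize_counts(m, c(s1 = 1)), "no size factor")
})

test_that("timepoint aggregation averages animals and honours per-animal mode", {
  meta <- toy_meta(2)
  norm <- matrix(c(1, 3,  2, 2,  3, 1), nrow = 1,
                 dimnames = list("g1", meta$sample_id))
  prof <- timepoint_profiles(norm, meta)
  expect_equal(unname(prof$profiles["g1", ]), c(2, 2, 2))
  # relabeling animals leaves the mean profile unchanged
  meta2 <- meta; meta2$animal_id <- rev(meta2$animal_id)
  expect_equal(timepoint_profiles(norm, meta2)$profiles, prof$profiles)
  pa <- timepoint_profiles(norm, meta, mode = "per_animal")
  expect_equal(unname(pa$profiles["g1", , "d1"]), c(1, 2, 3))
  expect_equal(unname(pa$profiles["g1", , "d2"]), c(3, 2, 1))
})

test_that("step-wise selection honours strictness and unanimity", {
  meta <- toy_meta(2)
  norm <- rbind(
    up_both   = c(1, 2,  2, 4,  4, 8),    # rises in both animals
    up_mean   = c(1, 5,  4, 3,  6, 9),    # rises on average, not in animal 2
    plateau   = c(2, 2,  3, 3,  3, 3),
    down      = c(5, 5,  4, 4,  3, 3))
  colnames(norm) <- meta$sample_id
  mean_prof <- timepoint_profiles(norm, meta)
  expect_setequal(select_stepwise_increasing(mean_prof), c("up_both", "up_mean"))
  expect_setequal(select_stepwise_increasing(mean_prof, strict = FALSE),
                  c("up_both", "up_mean", "plateau"))
  pa <- timepoint_profiles(norm, meta, mode = "per_animal")
  expect_identical(select_stepwise_increasing(pa, unanimity = TRUE), "up_both")
  expect_error(select_stepwise_increasing(mean_prof, unanimity = TRUE),
               "per_animal")
})

test_that("profile examples from the selection contract behave as stated", {
  meta <- toy_meta(1)
  norm <- rbind(sel = c(5, 10, 20), not = c(5, 10, 10))
  colnames(norm) <- meta$sample_id
  prof <- timepoint_profiles(norm, meta)
  expect_identical(select_stepwise_increasing(prof), "sel")
  expect_setequal(select_stepwise_increasing(prof, strict = FALSE),
                  c("sel", "not"))
})

test_that("fold changes divide last timepoint by baseline with pseudocount control", {
  meta <- toy_meta(1)
  norm <- rbind(a = c(10, 20, 40), b = c(3, 3, 3), c = c(0, 5, 9))
  colnames(norm) <- meta$sample_id
  prof <- timepoint_profiles(norm, meta)
  expect_error(fold_changes(prof, pseudocount = 0), "pseudocount")
  fc <- fold_changes(prof, pseudocount = 1)
  expect_equal(unname(fc["c"]), 10)        # (9 + 1) / (0 + 1)
  prof2 <- timepoint_profiles(norm[c("a", "b"), ], meta)
  fc2 <- fold_changes(prof2)
  expect_equal(unname(fc2), c(4, 1))
})

test_that("total-expression ranking is deterministic with ascending-id tie-break", {
  norm <- matrix(c(50, 50, 5, 5, 100, 0), nrow = 3, byrow = TRUE,
                 dimnames = list(c("zz", "aa", "mm"), c("s1", "s2")))
  ranked <- rank_by_total_expression(norm)
  expect_equal(ranked$gene_id, c("mm", "zz", "aa"))  # 100-tie: mm before zz
  expect_equal(ranked$rank, 1:3)
  # invariant to sample permutation
  expect_equal(rank_by_total_expression(norm[, c(2, 1)]), ranked)
  single <- rank_by_total_expression(norm["mm", , drop = FALSE])
  expect_equal(single$rank, 1L)
})

test_that("null genes pass the strict two-step filter at about one in six", {
  # three exchangeable timepoint means: P(strict increase) = 1/3! = 1/6
  cfg <- synthetic_config(n_genes = 10000, n_monotone = 0, hub_module_size = 0,
                          seed = 77)
  sim <- generate_counts(cfg)
  filt <- filter_low_counts(sim$counts)
  norm <- normalize_counts(filt, estimate_size_factors(filt))
  sel <- select_stepwise_increasing(timepoint_profiles(norm, sim$metadata))
  expect_equal(length(sel) / nrow(filt), 1 / 6, tolerance = 0.012 * 6)
})
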