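test_that("stratified subsampling draws exactly n per group", {
  group <- rep(c("case", "control"), c(723, 865))
  idx <- withr::with_seed(1, stratified_subsample(group, 361))
  expect_length(idx, 722)
  expect_identical(sum(group[idx] == "case"), 361L)
  expect_identical(sum(group[idx] == "control"), 361L)
  expect_identical(anyDuplicated(idx), 0L)

  # exhaustive case returns every sample; oversized request names the group
  small <- rep(c("case", "control"), c(4, 4))
  expect_setequal(withr::with_seed(1, stratified_subsample(small, 4)), 1:8)
  expect_error(withr::with_seed(1, stratified_subsample(small, 5)), "case")
  expect_identical(withr::with_seed(9, stratified_subsample(group, 100)),
                   withr::with_seed(9, stratified_subsample(group, 100)))
})

test_that("top_k ranks by directional p with deterministic tie-breaks", {
  d <- data.frame(gene = c("a", "b", "c"), t = c(0.1, 5, -1),
                  p_up = c(0.9, 0.001, 0.5), p_down = c(0.1, 0.999, 0.5))
  d2 <- directional_pvalues(data.frame(gene = d$gene, t = d$t, df = 10))
  expect_identical(top_k(d, 2), c("b", "a"))  # min(p_up, p_down): b .001, a .1
  expect_identical(top_k(d, 3), c("b", "a", "c"))
  expect_error(top_k(d, 4), "exceeds")
  # permutation of rows does not change the selection
  expect_identical(top_k(d2[c(3, 1, 2), ], 2), top_k(d2, 2))
})

test_that("overlap is the shared fraction of equal-length lists", {
  expect_equal(overlap(letters[1:5], letters[1:5]), 1)
  expect_equal(overlap(letters[1:5], letters[6:10]), 0)
  expect_equal(overlap(c("a", "b", "c", "d"), c("c", "d", "e", "f")), 0.5)
  expect_error(overlap(letters[1:3], letters[1:4]), "equal length")
})

test_that("run_robustness accumulates counts and overlaps consistently", {
  sim <- simulate_expression(n_genes = 300, n_case = 40, n_control = 40,
                             n_up = 15, n_down = 15, seed = 23)
  rr <- run_robustness(sim$matrix, B = 12, n_per_group = 20, k = 25,
                       seed = 23)
  expect_identical(sum(rr$selection_count), 12L * 25L)
  expect_length(rr$overlap_values, 12 * 11 / 2)
  expect_true(all(rr$overlap_values >= 0 & rr$overlap_values <= 1))
  expect_equal(rr$median_overlap, median(rr$overlap_values))
  # reproducible from the master seed
  rr2 <- run_robustness(sim$matrix, B = 12, n_per_group = 20, k = 25,
                        seed = 23)
  expect_identical(rr$selection_count, rr2$selection_count)
  # a single subsample is reproducible in isolation from its sub-seed
  idx <- withr::with_seed(rr$subsample_seeds[5],
                          stratified_subsample(sim$matrix$group, 20))
  deg <- directional_pvalues(t_statistics(subset_samples(sim$matrix, idx)))
  expect_identical(top_k(deg, 25), rr$top_lists[[5]])

  rr_b2 <- run_robustness(sim$matrix, B = 2, n_per_group = 20, k = 25,
                          seed = 5)
  expect_length(rr_b2$overlap_values, 1)
  expect_equal(rr_b2$median_overlap, rr_b2$overlap_values)
})

test_that("null overlap obeys the hypergeometric law for sparse subsamples", {
  # two independent random k-subsets of G genes share k/G on average;
  # subsamples of 10 from 100 per group are nearly independent lists
  sim <- simulate_expression(n_genes = 1000, n_case = 100, n_control = 100,
                             n_up = 0, n_down = 0, batch_sd = 0,
                             n_studies = 1, seed = 29)
  rr <- run_robustness(sim$matrix, B = 50, n_per_group = 10, k = 50,
                       seed = 29)
  G <- 1000; k <- 50
  sigma <- sqrt(k * (k / G) * (1 - k / G) * ((G - k) / (G - 1))) / k
  expect_lt(abs(mean(rr$overlap_values) - k / G), 3 * sigma)
})

test_that("median overlap is monotone in planted effect size", {
  med_at <- function(effect_mean, seed) {
    sim <- simulate_expression(n_genes = 400, n_case = 60, n_control = 60,
                               n_up = 40, n_down = 40,
                               effect_mean = effect_mean, effect_sd = 0.1,
                               seed = seed)
    run_robustness(sim$matrix, B = 10, n_per_group = 30, k = 40,
                   seed = seed)$median_overlap
  }
  grid <- vapply(c(0, 0.8, 2.5), function(em) {
    mean(vapply(1:5, function(s) med_at(em, 100 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("robust_set thresholds selection counts and is monotone", {
  rr <- structure(list(B = 200, k = 3,
                       selection_count = c(a = 200L, b = 180L, c = 100L),
                       overlap_values = 0.5, median_overlap = 0.5,
                       subsample_seeds = 1:200, top_lists = list()),
                  class = "robustness_result")
  expect_identical(robust_set(rr, 0.9), c("a", "b"))
  expect_identical(robust_set(rr, 1), "a")
  expect_identical(robust_set(rr, 1e-9), c("a", "b", "c"))
  expect_error(robust_set(rr, 0), "min_fraction")
  # monotone: larger threshold -> subset
  for (f in c(0.3, 0.6, 0.95))
    expect_true(all(robust_set(rr, f + 0.04) %in% robust_set(rr, f)))
})

test_that("final_signature intersects while preserving order and direction", {
  sig <- structure(list(up = c("u1", "u2", "u3"), down = c("d1", "d2")),
                   class = "gene_signature")
  expect_identical(final_signature(c("u3", "u1", "d2", "x"), sig),
                   structure(list(up = c("u1", "u3"), down = "d2"),
                             class = "gene_signature"))
  all_in <- final_signature(c(sig$up, sig$down), sig)
  expect_identical(all_in$up, sig$up)
  none <- final_signature(character(0), sig)
  expect_length(c(none$up, none$down), 0)
})
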