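test_that("null simulation is exchangeable between groups", {
  sim <- simulate_expression(n_genes = 2000, n_case = 50, n_control = 50,
                             n_up = 0, n_down = 0, batch_sd = 0,
                             n_studies = 1, seed = 11)
  d <- t_statistics(sim$matrix)
  expect_lt(abs(mean(d$t)), 3 / sqrt(2000))
  expect_identical(length(sim$truth$de_genes_up), 0L)
})

test_that("generators are pure functions of their arguments and seed", {
  a <- simulate_expression(n_genes = 50, n_case = 8, n_control = 8,
                           n_up = 5, n_down = 5, seed = 3)
  b <- simulate_expression(n_genes = 50, n_case = 8, n_control = 8,
                           n_up = 5, n_down = 5, seed = 3)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$de_genes_up, b$truth$de_genes_up)
  c <- simulate_expression(n_genes = 50, n_case = 8, n_control = 8,
                           n_up = 5, n_down = 5, seed = 4)
  expect_false(identical(a$matrix$values, c$matrix$values))

  s1 <- simulate_survival(20, seed = 5)
  s2 <- simulate_survival(20, seed = 5)
  expect_identical(s1, s2)

  p1 <- simulate_ppi(30, n_hubs = 2, hub_degree = 5, seed = 6)
  p2 <- simulate_ppi(30, n_hubs = 2, hub_degree = 5, seed = 6)
  expect_identical(p1, p2)

  g1 <- simulate_gene_sets(a$truth, n_decoy_sets = 4, set_size = 10,
                           seed = 7)
  g2 <- simulate_gene_sets(a$truth, n_decoy_sets = 4, set_size = 10,
                           seed = 7)
  expect_identical(g1$sets, g2$sets)
})

test_that("planted genes dominate the top of the p-value ranking", {
  sim <- simulate_expression(n_genes = 2000, n_case = 100, n_control = 100,
                             n_up = 100, n_down = 100, seed = 1)
  d <- directional_pvalues(t_statistics(sim$matrix))
  top <- top_k(d, 200)
  planted <- c(sim$truth$de_genes_up, sim$truth$de_genes_down)
  expect_gte(mean(top %in% planted), 0.9)
  # planted direction matches the sign of the shift
  up_in_top <- intersect(top, sim$truth$de_genes_up)
  expect_true(all(d$t[match(up_in_top, d$gene)] > 0))
})

test_that("simulation structure matches its stated parameters", {
  sim <- simulate_expression(n_genes = 500, n_case = 150, n_control = 150,
                             n_up = 40, n_down = 40, batch_sd = 0,
                             n_studies = 1, noise_sd = 1, seed = 21)
  # per-gene variance concentrates around noise_sd^2 on background genes
  bg <- setdiff(sim$truth$genes,
                c(sim$truth$de_genes_up, sim$truth$de_genes_down))
  vars <- apply(sim$matrix$values[bg, ], 1, var)
  expect_lt(abs(mean(vars) - 1), 0.05)
  # planted mean shift tracks the drawn effects
  diff <- rowMeans(sim$matrix$values[sim$truth$de_genes_up,
                                     sim$matrix$group == "case"]) -
    rowMeans(sim$matrix$values[sim$truth$de_genes_up,
                               sim$matrix$group == "control"])
  eff <- sim$truth$effect_sizes[sim$truth$de_genes_up]
  expect_lt(max(abs(diff - eff)), 0.5)
  expect_lt(abs(mean(diff - eff)), 2 / sqrt(40))
  # disjoint planted sets, all present in the matrix
  expect_length(intersect(sim$truth$de_genes_up,
                          sim$truth$de_genes_down), 0)
  expect_true(all(c(sim$truth$de_genes_up, sim$truth$de_genes_down) %in%
                    rownames(sim$matrix$values)))
  expect_error(simulate_expression(n_genes = 10, n_case = 5, n_control = 5,
                                   n_up = 6, n_down = 6, seed = 1),
               "exceeds")
})

test_that("survival generator obeys its proportional-hazards design", {
  x <- withr::with_seed(31, cbind(grp = rbinom(1000, 1, 0.5)))
  surv <- simulate_survival(1000, covariates = x, coefs = 1,
                            baseline_rate = 0.1, censor_rate = 0.001,
                            seed = 31)
  fit <- cox_fit(surv[, "grp", drop = FALSE], surv$time, surv$event)
  expect_lt(abs(fit$coefficient - 1), 0.2)
  expect_error(simulate_survival(10, baseline_rate = -1, seed = 1),
               "positive")

  # null: log-rank p approximately uniform over replicates
  pvals <- vapply(1:300, function(i) {
    s <- simulate_survival(40, seed = 1000 + i, censor_rate = 0.02)
    grp <- rep(c("a", "b"), 20)  # arbitrary split, independent of times
    logrank_test(s$time, s$event, grp)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("ppi generator plants recoverable hubs", {
  el <- simulate_ppi(40, n_hubs = 1, hub_degree = 10,
                     background_edge_prob = 0, seed = 8)
  hub <- attr(el, "hub_nodes")
  deg <- table(c(el$node_a, el$node_b))
  expect_identical(as.integer(deg[hub]), 10L)
  expect_true(all(deg[setdiff(names(deg), hub)] <= 1))

  el2 <- simulate_ppi(100, n_hubs = 3, hub_degree = 25,
                      background_edge_prob = 0.02, seed = 9)
  deg2 <- sort(table(c(el2$node_a, el2$node_b)), decreasing = TRUE)
  expect_setequal(names(deg2)[1:3], attr(el2, "hub_nodes"))
  expect_true(all(el2$combined_score >= 0.4 & el2$combined_score <= 1))
})

test_that("gene-set generator embeds the planted signature", {
  sim <- simulate_expression(n_genes = 300, n_case = 30, n_control = 30,
                             n_up = 20, n_down = 20, seed = 13)
  gs <- simulate_gene_sets(sim$truth, n_decoy_sets = 10, set_size = 25,
                           seed = 14)
  expect_identical(gs$sets$planted_up, sim$truth$de_genes_up)
  expect_length(gs, 12)
  res <- ora(sim$truth$de_genes_up, gs, universe = sim$truth$genes)
  expect_identical(res$set[1], "planted_up")
})
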