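# Network weighting and the CMA activation score.

make_net <- function(genes, directions, families) {
  df <- data.frame(gene_id = genes, functional_group = "effector",
                   direction = directions, paralog_family = families,
                   stringsAsFactors = FALSE)
  df$n_paralogs <- as.integer(table(families)[families])
  df$weight <- NA_real_
  class(df) <- c("cma_network", "data.frame")
  df
}

expr_matrix <- function(values, samples, genes) {
  matrix(values, nrow = length(samples), ncol = length(genes),
         dimnames = list(samples, genes))
}

test_that("weights follow the 1/n paralog rule with a lamp2a family total of
           exactly 2", {
  net <- make_net(c("g1", "l1", "l2", "t1", "t2", "t3"),
                  c(1L, 1L, 1L, -1L, -1L, -1L),
                  c("solo", "lamp2a", "lamp2a", "trio", "trio", "trio"))
  w <- assign_weights(net)
  expect_equal(w$weight[w$gene_id == "g1"], 1)            # singleton: 1/1
  expect_equal(w$weight[w$paralog_family == "lamp2a"], c(1, 1))
  expect_equal(sum(w$weight[w$is_lamp2a_family]), 2)
  expect_equal(w$weight[w$paralog_family == "trio"], rep(1 / 3, 3))

  # measured lamp2a contributions reapportion the family total of 2
  w2 <- assign_weights(net, lamp2a_contributions = c(l1 = 0.8, l2 = 0.2))
  expect_equal(w2$weight[w2$gene_id == "l1"], 1.6)
  expect_equal(sum(w2$weight[w2$is_lamp2a_family]), 2)
  expect_error(assign_weights(net, lamp2a_contributions = c(0.5, 0.4)),
               "sum to 1")
  expect_error(assign_weights(net, lamp2a_contributions = c(0.5, 0.5, 0.1)),
               "one entry per")

  # explicit weights win over the derived rule
  net$weight[net$gene_id == "g1"] <- 0.123
  expect_equal(assign_weights(net)$weight[net$gene_id == "g1"], 0.123)
})

test_that("the score is the signed weighted sum of transformed expression", {
  # one positive gene, weight 1, sample at log2 fold change 3
  net <- assign_weights(make_net("g1", 1L, "g1"))
  expr <- expr_matrix(c(1, 1, 8), c("r1", "r2", "s"), "g1")
  res <- compute_cma_score(expr, net, reference_sample_ids = c("r1", "r2"))
  expect_equal(res$score[res$sample_id == "s"], 3)

  # adding a negative modulator at log2 fold change 2 subtracts its term
  net2 <- assign_weights(make_net(c("g1", "neg"), c(1L, -1L),
                                  c("g1", "neg")))
  expr2 <- expr_matrix(c(1, 1, 8, 1, 1, 4), c("r1", "r2", "s"),
                       c("g1", "neg"))
  res2 <- compute_cma_score(expr2, net2,
                            reference_sample_ids = c("r1", "r2"))
  expect_equal(res2$score[res2$sample_id == "s"], 3 - 2)

  # reference group is centred at score 0 under the log2 transform
  expect_equal(mean(res2$score[res2$sample_id != "s"]), 0)

  # the weighted-average option divides by the total absolute weight
  res3 <- compute_cma_score(expr2, net2, reference_sample_ids = c("r1", "r2"),
                            average = TRUE)
  expect_equal(res3$score[res3$sample_id == "s"], (3 - 2) / 2)
})

test_that("score linearity: doubling one gene adds weight x direction", {
  net <- assign_weights(example_cma_network())
  samples <- c("r1", "r2", "s1")
  expr <- expr_matrix(1, samples, net$gene_id)
  base <- compute_cma_score(expr, net, reference_sample_ids = c("r1", "r2"))
  for (g in c("hspa8a", "akt1a", "lamp2a_c31")) {
    expr2 <- expr
    expr2["s1", g] <- 2
    res <- compute_cma_score(expr2, net,
                             reference_sample_ids = c("r1", "r2"))
    w <- net$weight[net$gene_id == g]
    d <- net$direction[net$gene_id == g]
    expect_equal(res$score[3] - base$score[3], w * d)
  }
})

test_that("scores are invariant to gene column order", {
  net <- assign_weights(example_cma_network())
  sim <- generate_network_expression(net, "stressor", n_per_group = 3,
                                     seed = 21)
  ref <- names(sim$groups)[sim$groups == "control"]
  a <- compute_cma_score(sim$expr, net, reference_sample_ids = ref)
  b <- compute_cma_score(sim$expr[, sample(ncol(sim$expr))], net,
                         reference_sample_ids = ref)
  expect_equal(a$score, b$score)
})

test_that("missing and undetected genes are excluded with the renormalize
           policy keeping weights comparable", {
  net <- assign_weights(make_net(c("g1", "g2"), c(1L, 1L), c("g1", "g2")))
  expr <- expr_matrix(c(1, 1, 4, 1, 1, NA), c("r1", "r2", "s"),
                      c("g1", "g2"))
  res <- compute_cma_score(expr, net, reference_sample_ids = c("r1", "r2"))
  # sample s uses only g1 (weight 1 of total 2): renormalized by 2
  expect_equal(res$score[res$sample_id == "s"], 2 * 2)
  expect_equal(res$n_genes_used, c(2L, 2L, 1L))
  expect_equal(attr(res, "genes_excluded")[["s"]], "g2")

  res_ex <- compute_cma_score(expr, net, reference_sample_ids = c("r1", "r2"),
                              missing_policy = "exclude")
  expect_equal(res_ex$score[res_ex$sample_id == "s"], 2)

  # undetected (zero) expression under a log transform: excluded, warned
  expr0 <- expr_matrix(c(1, 1, 4, 1, 1, 0), c("r1", "r2", "s"),
                       c("g1", "g2"))
  expect_warning(res0 <- compute_cma_score(
    expr0, net, reference_sample_ids = c("r1", "r2")), "undetected")
  expect_equal(res0$score[res0$sample_id == "s"], 4)

  # a network entirely absent from the table is an error
  expr_none <- expr_matrix(1, c("r1", "r2"), c("x1", "x2"))
  expect_error(compute_cma_score(expr_none, net,
                                 reference_sample_ids = "r1"),
               "all network genes missing")
})

test_that("synthetic knockout sits below matched controls and the stressor
           shift equals the sum of positive weights", {
  net <- assign_weights(example_cma_network())

  ko <- generate_network_expression(net, "knockout", gene = "lamp2a_c31",
                                    noise_sd_log2 = 0, seed = 4)
  ref <- names(ko$groups)[ko$groups == "control"]
  sc <- compute_cma_score(ko$expr, net, transform = "fold_change",
                          reference_sample_ids = ref)
  diff <- mean(sc$score[ko$groups == "treated"]) -
    mean(sc$score[ko$groups == "control"])
  expect_equal(diff, ko$truth$expected_difference)
  expect_equal(diff, -1)  # lamp2a_c31 has weight 1, direction +1
  expect_true(all(sc$score[ko$groups == "treated"] <
                    sc$score[ko$groups == "control"]))

  st <- generate_network_expression(net, "stressor", fold = 2,
                                    noise_sd_log2 = 0, seed = 4)
  sc2 <- compute_cma_score(st$expr, net,
                           reference_sample_ids = ref)
  diff2 <- mean(sc2$score[st$groups == "treated"]) -
    mean(sc2$score[st$groups == "control"])
  expect_equal(diff2, st$truth$expected_difference)
  expect_equal(diff2, sum(net$weight[net$direction == 1L]))
})

test_that("group comparisons delegate to the right tests and reject
           degenerate designs", {
  net <- assign_weights(example_cma_network())
  sim <- generate_network_expression(net, "stressor", n_per_group = 6,
                                     seed = 8)
  ref <- names(sim$groups)[sim$groups == "control"]
  sc <- compute_cma_score(sim$expr, net, reference_sample_ids = ref)

  cmp <- compare_scores(sc, sim$groups, design = "two_group")
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$mean_difference, 0)
  expect_equal(cmp$p_value,
               t.test(sc$score ~ factor(sim$groups),
                      var.equal = TRUE)$p.value)

  # identical groups: near-zero difference, p ~ 1 on average
  same <- compare_scores(
    data.frame(sample_id = paste0("s", 1:8),
               score = rep(c(1.0, 1.1, 0.9, 1.0), 2)),
    rep(c("a", "b"), each = 4))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_scores(
    data.frame(sample_id = c("s1", "s2", "s3"), score = 1:3),
    c("a", "a", "b")), "at least 2 samples")

  # tissue-by-condition two-way ANOVA
  set.seed(10)
  tissues <- rep(c("liver", "gills"), each = 8)
  cond <- rep(rep(c("normoxia", "hypoxia"), each = 4), 2)
  scores <- data.frame(
    sample_id = paste0("s", 1:16),
    score = rnorm(16, sd = 0.2) + ifelse(cond == "hypoxia", 1.5, 0))
  cmp2 <- compare_scores(scores, data.frame(tissue = tissues,
                                            condition = cond),
                         design = "tissue_by_condition")
  expect_lt(cmp2$p_value, 0.001)
  expect_true("tissue" %in% names(cmp2$p_values))
})
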