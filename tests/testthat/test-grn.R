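test_that("adjusted Rand index matches closed forms and the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(9, 9, 4, 4)), 1)  # label invariance
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    p1 <- sample(1:4, n, replace = TRUE)
    p2 <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(p1, p2), oracle_ari(p1, p2))
  }
})

test_that("hierarchical clustering merges duplicates at 0 and follows hand agglomeration", {
  # duplicated profiles merge at height 0
  act <- structure(list(auc = NULL, scaled = rbind(c(0, 0), c(0, 0), c(3, 4)),
                        threshold_frac = 0.05), class = "ActivityMatrix")
  rownames(act$scaled) <- c("a", "b", "c")
  hc <- hcluster_cells(act, "average")
  expect_equal(min(hc$height), 0)
  expect_equal(length(hc$height), 2)   # n - 1 merges

  # 3 cells on a line at 0, 1, 2.2: distances 1, 1.2, 2.2
  # average linkage: merge (x1,x2) at 1, then height (1.2 + 2.2)/2 = 1.7
  act2 <- structure(list(auc = NULL,
                         scaled = matrix(c(0, 1, 2.2), ncol = 1,
                                         dimnames = list(c("a", "b", "c"), "r")),
                         threshold_frac = 0.05), class = "ActivityMatrix")
  hc2 <- hcluster_cells(act2, "average")
  expect_equal(sort(hc2$height), c(1, 1.7))

  act_bad <- act
  act_bad$scaled[1, 1] <- NaN
  expect_error(hcluster_cells(act_bad), "non-finite")
})

test_that("regulon specificity score hits exact extremes and the JSD hand oracle", {
  # activity uniform on the state's cells, zero elsewhere -> RSS 1
  auc <- cbind(conc = c(1, 1, 0, 0), disj = c(0, 0, 1, 1),
               hand = c(0.4, 0.4, 0.1, 0.1))
  act <- structure(list(auc = auc, scaled = NULL, threshold_frac = 0.05),
                   class = "ActivityMatrix")
  assign <- c("g1", "g1", "g2", "g2")
  tab <- regulon_specificity(act, assign)
  rssm <- attr(tab, "rss_matrix")
  expect_equal(rssm["conc", "g1"], 1)
  expect_equal(rssm["disj", "g1"], 0)
  expect_equal(rssm["hand", "g1"],
               1 - sqrt(oracle_jsd2(c(0.4, 0.4, 0.1, 0.1), c(0.5, 0.5, 0, 0))))
  # assignment and ranking
  expect_identical(tab$grn[tab$regulon == "conc"], "g1")
  expect_identical(tab$grn[tab$regulon == "disj"], "g2")
  r1 <- tab[tab$grn == "g1", ]
  expect_identical(sort(r1$rank), seq_len(nrow(r1)) * 1.0)
  expect_identical(r1$regulon[r1$rank == 1], "conc")
})

test_that("RSS lies in [0,1], is scale-invariant, and flags all-zero regulons", {
  set.seed(7)
  auc <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  act <- structure(list(auc = auc, scaled = NULL, threshold_frac = 0.05),
                   class = "ActivityMatrix")
  assign <- rep(c("x", "y"), each = 10)
  rss <- attr(regulon_specificity(act, assign), "rss_matrix")
  expect_true(all(rss >= 0 & rss <= 1))
  act10 <- act; act10$auc <- act$auc * 10
  expect_equal(attr(regulon_specificity(act10, assign), "rss_matrix"), rss)

  act0 <- act; act0$auc[, "b"] <- 0
  expect_warning(tab <- regulon_specificity(act0, assign), "all-zero")
  expect_false("b" %in% tab$regulon)
})

test_that("stability-guided cut recovers planted states and degenerates gracefully", {
  spec <- synthetic_spec(n_cells = 400, n_genes = 300, n_grn_states = 5,
                         regulon_size = 15, activity_effect = 2.0,
                         dropout_rate = 0.3, seed = 7)
  sim <- simulate_expression(spec)
  cfg <- pipeline_config(rng_seed = 7, n_boot = 10, max_k = 10)
  act <- scale_activity(score_regulons(normalize_expression(sim$expr),
                                       sim$regulons, cfg))
  part <- discover_grns(act, cfg)
  expect_identical(part$n_grn, 5L)
  expect_gte(adjusted_rand_index(part$assignment, sim$truth), 0.9)
  expect_true(all(part$cut$stability >= -1 & part$cut$stability <= 1))

  # identical duplicated halves: perfectly reproducible at the true height
  half <- act$scaled[1:100, ]
  dup <- structure(list(auc = act$auc[c(1:100, 1:100), ],
                        scaled = rbind(half, half), threshold_frac = 0.05),
                   class = "ActivityMatrix")
  rownames(dup$scaled) <- rownames(dup$auc) <- sprintf("c%03d", 1:200)
  dend <- hcluster_cells(dup, "ward")
  cut <- select_cut(dend, dup, n_boot = 5, seed = 1, max_k = 8)
  expect_gte(max(cut$stability), 0.99)

  # no signal (at the generator's default gene count, where AUC values are
  # continuous enough to avoid degenerate duplicate profiles): stability low
  # for k > 1, falls back to a single state
  spec0 <- synthetic_spec(n_cells = 500, n_genes = 1000, n_grn_states = 5,
                          regulon_size = 25, activity_effect = 0,
                          dropout_rate = 0.3, seed = 8)
  sim0 <- simulate_expression(spec0)
  act0 <- scale_activity(score_regulons(normalize_expression(sim0$expr),
                                        sim0$regulons,
                                        pipeline_config(rng_seed = 8)))
  dend0 <- hcluster_cells(act0, "ward")
  expect_warning(cut0 <- select_cut(dend0, act0, n_boot = 8, seed = 8, max_k = 8),
                 "single state")
  expect_identical(cut0$chosen_k, 1L)
  expect_lt(max(cut0$stability), 0.5)

  # and a forced multi-way cut recovers the truth map no better than chance
  forced <- stats::cutree(dend0, k = 5)
  expect_lt(abs(adjusted_rand_index(forced, sim0$truth)), 0.05)
})

test_that("fixed seed makes cut selection and robustness deterministic", {
  spec <- synthetic_spec(n_cells = 200, n_genes = 200, n_grn_states = 3,
                         regulon_size = 10, activity_effect = 2, seed = 2)
  sim <- simulate_expression(spec)
  cfg <- pipeline_config(rng_seed = 2, n_boot = 5, max_k = 6)
  act <- scale_activity(score_regulons(normalize_expression(sim$expr),
                                       sim$regulons, cfg))
  dend <- hcluster_cells(act, "ward")
  c1 <- select_cut(dend, act, n_boot = 5, seed = 99, max_k = 6)
  c2 <- select_cut(dend, act, n_boot = 5, seed = 99, max_k = 6)
  expect_identical(c1, c2)
})

test_that("robustness reports bootstrap and LOPO ARI and finds patient-private states", {
  # 3 planted states; one patient exclusively owns state 3
  set.seed(33)
  n_per <- 40
  sc <- rbind(matrix(rnorm(n_per * 2, 0), ncol = 2),
              matrix(rnorm(n_per * 2, 6), ncol = 2),
              cbind(rnorm(n_per, 12), rnorm(n_per, -6)))
  rownames(sc) <- sprintf("c%03d", 1:(3 * n_per))
  act <- structure(list(auc = pmax(sc, 0) / 20, scaled = sc, threshold_frac = 0.05),
                   class = "ActivityMatrix")
  rownames(act$auc) <- rownames(sc)
  patients <- c(sample(c("P1", "P2"), 2 * n_per, replace = TRUE), rep("P3", n_per))
  cfg <- pipeline_config(rng_seed = 4, n_boot = 5, max_k = 6)
  # reference partition fixed at the planted k = 3 cut
  dend <- hcluster_cells(act, "ward")
  k3_height <- mean(sort(dend$height, decreasing = TRUE)[2:3])
  part <- structure(list(
    assignment = stats::setNames(sprintf("GRN%02d", stats::cutree(dend, k = 3)),
                                 rownames(sc)),
    n_grn = 3L, dendrogram = dend, cut_height = k3_height,
    cut = NULL, regulon_table = NULL), class = "GRNPartition")
  rep <- robustness(act, part, patients, cfg)
  expect_length(rep$cell_bootstrap_ari, 5)
  expect_true(all(rep$cell_bootstrap_ari >= -1 & rep$cell_bootstrap_ari <= 1))
  expect_gte(median(rep$lopo_ari, na.rm = TRUE), 0.8)

  # the P3-private state cannot be recurrent at a 100% matching requirement:
  # it vanishes (Jaccard 0) in P3's leave-out replicate
  rep_all <- robustness(act, part, patients, cfg, recurrent_frac = 1)
  grn3 <- names(which.max(table(part$assignment[patients == "P3"])))
  expect_false(grn3 %in% rep_all$recurrent_grns)
  expect_true(rep_all$match_frac[[grn3]] < 1)

  # n_boot = 0: empty bootstrap field, no error
  cfg0 <- pipeline_config(rng_seed = 4, n_boot = 0, max_k = 6)
  rep0 <- robustness(act, part, patients, cfg0)
  expect_length(rep0$cell_bootstrap_ari, 0)

  expect_warning(robustness(act, part, rep("P1", nrow(sc)), cfg0), "single patient")
})
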