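test_that("module score is ~0 for random signatures and ranks planted states first", {
  spec <- synthetic_spec(n_cells = 500, n_genes = 400, n_grn_states = 2,
                         regulon_size = 20, activity_effect = 2, seed = 14)
  sim <- simulate_expression(spec)
  expr <- normalize_expression(sim$expr)

  set.seed(30)
  null_means <- vapply(1:10, function(s) {
    sig <- sample(setdiff(expr$gene_ids, unlist(sim$regulons$regulons)), 25)
    mean(module_score(expr, sig, seed = s)$score)
  }, numeric(1))
  expect_lt(max(abs(null_means)), 0.05)

  # signature = planted up-shifted genes: cells of that state score highest
  ms <- module_score(expr, sim$regulons$regulons[[1]], seed = 1)
  in_state <- sim$truth == 1
  expect_gt(median(ms$score[in_state]), max(0.2, median(ms$score[!in_state])))
  pairs_correct <- mean(outer(ms$score[in_state], ms$score[!in_state], ">"))
  expect_gte(pairs_correct, 0.95)                             # AUROC >= 0.95

  expect_error(module_score(expr, c("absent1", "absent2")), "no signature gene")
  # controls never overlap the signature
  expect_length(intersect(ms$controls, ms$signature), 0)
})

test_that("module score control draw tolerates bins smaller than n_controls", {
  toy <- make_toy_expr(n_cells = 30, n_genes = 20, seed = 2)
  expr <- normalize_expression(toy$expr)
  ms <- module_score(expr, c("g01", "g02"), n_bins = 5, n_controls = 50, seed = 3)
  expect_true(all(is.finite(ms$score)))
  expect_identical(length(ms$controls), 100L)   # with replacement, 2 x 50
})

test_that("per-GRN marker summary min-max scales exactly and flags flat markers", {
  set.seed(16)
  n <- 90
  counts <- matrix(rpois(n * 30, 2), n, 30)
  grn <- rep(c("GRN01", "GRN02", "GRN03"), each = 30)
  counts[grn == "GRN02", 1] <- counts[grn == "GRN02", 1] + 12L   # marker g01 peak
  counts[, 2] <- 3L                                              # flat marker g02
  meta <- data.frame(patient_id = "p", category = "x")[rep(1, n), ]
  # values passed as already log-normalized so the flat marker stays exactly flat
  nexpr <- expression_matrix(log1p(counts), sprintf("g%02d", 1:30),
                             sprintf("c%02d", 1:n), meta, normalized = TRUE)
  ms <- module_score(nexpr, c("g01", "g03"), seed = 2)
  assign <- stats::setNames(grn, nexpr$cell_ids)
  expect_warning(summ <- grn_marker_summary(nexpr, assign, c("g01", "g02"), ms),
                 "undefined")
  s1 <- summ$per_grn$g01_scaled
  expect_equal(max(s1), 1)
  expect_equal(min(s1), 0)
  expect_equal(summ$per_grn$grn[which.max(s1)], "GRN02")
  expect_true(all(is.na(summ$per_grn$g02_scaled)))
  expect_true(is.na(summ$associations$ccc[summ$associations$marker == "g02"]))
})

test_that("marker tracking a module across states yields high Pearson r", {
  spec <- synthetic_spec(n_cells = 600, n_genes = 300, n_grn_states = 4,
                         regulon_size = 15, activity_effect = 2, seed = 17)
  sim <- simulate_expression(spec)
  expr <- normalize_expression(sim$expr)
  assign <- stats::setNames(paste0("GRN0", sim$truth), expr$cell_ids)
  # marker = a gene of regulon 1; module = regulon-1 signature:
  # both peak in state 1, giving a tight state-level relationship
  ms <- module_score(expr, sim$regulons$regulons[[1]], seed = 4)
  marker <- sim$regulons$regulons[[1]][1]
  summ <- grn_marker_summary(expr, assign, marker, ms)
  expect_gte(summ$associations$pearson_r, 0.9)
})

test_that("diffusion imputation: identity at t = 0, convexity, 3-cell hand oracle", {
  toy <- make_toy_expr(n_cells = 40, n_genes = 25, seed = 18)
  expr <- normalize_expression(toy$expr)
  x <- as.matrix(expr$values)
  expect_equal(magic_impute(expr, k = 5, t = 0), x)

  imp <- magic_impute(expr, k = 5, t = 2)
  for (j in seq_len(ncol(x))) {
    expect_gte(min(imp[, j]), min(x[, j]) - 1e-12)
    expect_lte(max(imp[, j]), max(x[, j]) + 1e-12)
  }
  # increasing t contracts per-gene variance monotonically
  v1 <- apply(magic_impute(expr, k = 5, t = 1), 2, var)
  v2 <- apply(magic_impute(expr, k = 5, t = 2), 2, var)
  v3 <- apply(magic_impute(expr, k = 5, t = 3), 2, var)
  expect_true(all(v2 <= v1 + 1e-12))
  expect_true(all(v3 <= v2 + 1e-12))

  expect_error(magic_impute(expr, k = 40, t = 1), "smaller")

  # 3 cells, k = 1: the Markov matrix is computable by hand from the
  # pairwise distances; imputed values are its convex combinations
  vals <- matrix(c(0, 1, 10,
                   0, 1, 10), 3, 2)
  meta <- data.frame(patient_id = "p", category = "x")[rep(1, 3), ]
  e3 <- expression_matrix(vals, c("gA", "gB"), c("c1", "c2", "c3"), meta,
                          normalized = TRUE)
  imp3 <- magic_impute(e3, k = 1, t = 1, n_pcs = 2)
  # hand computation: per-cell bandwidth = distance to 1st neighbor, so each
  # neighbor affinity is exp(-1); symmetrized and row-normalized below
  d <- as.matrix(dist(cbind(c(0, 1, 10), c(0, 1, 10))))
  A <- matrix(0, 3, 3)
  for (i in 1:3) {
    nb <- order(d[i, ])[2]
    A[i, nb] <- exp(-1)
  }
  diag(A) <- 1
  A <- (A + t(A)) / 2
  M <- A / rowSums(A)
  expect_equal(unname(imp3), unname(M %*% vals), tolerance = 1e-8)
})

test_that("surfaceome candidates rank state-private genes first and flat genes last", {
  set.seed(19)
  n <- 120
  counts <- matrix(rpois(n * 40, 2), n, 40)
  grn <- rep(c("GRN01", "GRN02"), each = 60)
  counts[grn == "GRN01", 1] <- counts[grn == "GRN01", 1] + 25L  # private to GRN01
  counts[grn == "GRN02", 2] <- counts[grn == "GRN02", 2] + 25L  # private to GRN02
  meta <- data.frame(patient_id = "p", category = "x")[rep(1, n), ]
  expr <- expression_matrix(counts, sprintf("g%02d", 1:40), sprintf("c%03d", 1:n), meta)
  assign <- stats::setNames(grn, expr$cell_ids)
  surf <- sprintf("g%02d", 1:10)
  ranked <- candidate_surface_markers(expr, assign, surf)
  expect_lte(ranked$rank[ranked$grn == "GRN01" & ranked$gene == "g01"], 5)
  expect_lte(ranked$rank[ranked$grn == "GRN02" & ranked$gene == "g02"], 5)
  # the two planted markers claim rank 1 in their own state
  expect_identical(ranked$gene[ranked$grn == "GRN01" & ranked$rank == 1], "g01")
  expect_identical(ranked$gene[ranked$grn == "GRN02" & ranked$rank == 1], "g02")
  expect_error(candidate_surface_markers(expr, assign, character(0)), "empty")
  expect_error(candidate_surface_markers(expr, assign, c("zz1", "zz2")), "no surfaceome")
})
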