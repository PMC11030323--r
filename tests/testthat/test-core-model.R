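test_that("expression matrix round-trips losslessly through MTX and CSV", {
  toy <- make_toy_expr(n_cells = 6, n_genes = 5)
  dir <- withr::local_tempdir()
  write_expression(toy$expr, dir)
  back <- read_expression(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                          file.path(dir, "cells.tsv"), file.path(dir, "meta.csv"))
  expect_equal(as.matrix(back$values), as.matrix(toy$expr$values))
  expect_identical(back$gene_ids, toy$expr$gene_ids)
  expect_identical(back$cell_ids, toy$expr$cell_ids)
  expect_identical(back$cell_meta$patient_id, toy$expr$cell_meta$patient_id)

  csv <- file.path(dir, "dense.csv")
  write_expression_csv(toy$expr, csv)
  dense <- read_expression_csv(csv, file.path(dir, "meta.csv"))
  expect_equal(as.matrix(dense$values), as.matrix(toy$expr$values))
  expect_identical(dense$gene_ids, toy$expr$gene_ids)
})

test_that("reader auto-detects orientation and errors name the offending sidecar", {
  toy <- make_toy_expr(n_cells = 3, n_genes = 4)
  dir <- withr::local_tempdir()
  write_expression(toy$expr, dir)   # stored genes x cells
  got <- read_expression(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                         file.path(dir, "cells.tsv"), file.path(dir, "meta.csv"))
  expect_identical(dim(got), c(3L, 4L))

  # transposed storage with swapped sidecars yields the identical object
  Matrix::writeMM(Matrix::Matrix(as.matrix(toy$expr$values), sparse = TRUE),
                  file.path(dir, "matrix_t.mtx"))
  got_t <- read_expression(file.path(dir, "matrix_t.mtx"), file.path(dir, "genes.tsv"),
                           file.path(dir, "cells.tsv"), file.path(dir, "meta.csv"))
  expect_equal(as.matrix(got_t$values), as.matrix(got$values))

  # wrong-length gene sidecar is reported by file name
  writeLines(sprintf("g%02d", 1:5), file.path(dir, "genes5.tsv"))
  expect_error(
    read_expression(file.path(dir, "matrix.mtx"), file.path(dir, "genes5.tsv"),
                    file.path(dir, "cells.tsv"), file.path(dir, "meta.csv")),
    "genes5"
  )
})

test_that("expression matrix validation enforces IDs, alignment and count positivity", {
  vals <- matrix(1:6, 2, 3)
  meta <- data.frame(patient_id = c("P1", "P2"), category = "x")
  expect_error(expression_matrix(vals, c("a", "a", "b"), c("c1", "c2"), meta),
               "duplicate gene")
  expect_error(expression_matrix(vals, c("a", "b", "c"), c("c1", "c1"), meta),
               "duplicate cell")
  expect_error(expression_matrix(vals, c("a", "b", "c"), c("c1", "c2"), meta[1, ]),
               "align")
  expect_error(expression_matrix(-vals, c("a", "b", "c"), c("c1", "c2"), meta),
               "negative")
  expect_error(expression_matrix(vals, c("a", "b", "c"), c("c1", "c2"),
                                 data.frame(patient_id = c("P1", "P2"))),
               "category")
})

test_that("normalization equalizes library size and flags log space", {
  toy <- make_toy_expr(n_cells = 10, n_genes = 8)
  norm <- normalize_expression(toy$expr)
  expect_true(norm$normalized)
  totals <- rowSums(expm1(as.matrix(norm$values)))
  expect_equal(max(totals) / min(totals), 1, tolerance = 1e-8)
  expect_warning(normalize_expression(norm), "already normalized")
})

test_that("GMT regulons parse, validate and round-trip", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "regs.gmt")
  writeLines(c("AR(3g)\tsrc\tKLK3\tNKX3-1\tTMPRSS2",
               "ASCL1(2g)\tsrc\tDLL3\tINSM1"), gmt)
  regs <- read_regulons(gmt)
  expect_identical(names(regs$regulons), c("AR(3g)", "ASCL1(2g)"))
  expect_identical(regs$regulons[["AR(3g)"]], c("KLK3", "NKX3-1", "TMPRSS2"))

  out <- file.path(dir, "out.gmt")
  write_regulons(regs, out)
  expect_identical(read_regulons(out)$regulons, regs$regulons)

  writeLines("AR\tonly_two_fields", gmt)
  expect_error(read_regulons(gmt), "field")
  expect_error(regulon_set(list(A = character(0))), "empty gene list")
  expect_warning(regulon_set(list(A = c("x", "x", "y"))), "duplicate")
})

test_that("H-score tables validate scale, histology and missingness", {
  df <- data.frame(sample_id = c("s1", "s2", "s3"), patient_id = "p1",
                   site = "bone", histology = c("PRAD", "HGC", "NEPC"),
                   ASCL1 = c(0, 100, 200), KI67 = c(10, NA, 90))
  tbl <- hscore_table(df, scales = c(KI67 = 100))
  expect_setequal(hscore_markers(tbl), c("ASCL1", "KI67"))
  expect_true(is.na(tbl$KI67[2]))

  df$ASCL1[2] <- 250
  expect_error(hscore_table(df), "row\\(s\\) 2")
  df$ASCL1[2] <- 100; df$histology[1] <- "unknown"
  expect_error(hscore_table(df), "PRAD, HGC, NEPC")

  dir <- withr::local_tempdir()
  csv <- file.path(dir, "h.csv")
  write_hscores(tbl, csv)
  back <- read_hscores(csv, scales = c(KI67 = 100))
  expect_equal(back$ASCL1, tbl$ASCL1)
  expect_equal(back$KI67, tbl$KI67)
})

test_that("composite H-score averages available markers pairwise", {
  df <- data.frame(sample_id = c("s1", "s2"), patient_id = "p", site = "bone",
                   histology = "NEPC", A = c(100, NA), B = c(200, NA))
  tbl <- hscore_table(df)
  comp <- composite_hscore(tbl, c("A", "B"))
  expect_equal(comp[[1]], 150)
  expect_true(is.na(comp[2]))
})

test_that("config validates ranges and reads JSON/YAML", {
  expect_error(pipeline_config(auc_threshold_frac = 1.2), "\\(0, 1\\)")
  expect_error(pipeline_config(magic_t = -1), "magic_t")
  dir <- withr::local_tempdir()
  jsonlite::write_json(list(cluster_k = 10, rng_seed = 42),
                       file.path(dir, "cfg.json"), auto_unbox = TRUE)
  cfg <- read_config(file.path(dir, "cfg.json"))
  expect_identical(cfg$cluster_k, 10L)
  expect_identical(cfg$rng_seed, 42L)
  writeLines("not_a_field: 3", file.path(dir, "cfg.yaml"))
  expect_error(read_config(file.path(dir, "cfg.yaml")), "not_a_field")
})
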