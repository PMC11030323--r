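#' Two-part hurdle differential expression between two cell groups
#'
#' A dependency-free hurdle test for zero-inflated single-cell expression:
#' per gene, (1) the detection part compares the expressed (> 0) vs
#' not-expressed counts between groups by Fisher's exact test, and (2) the
#' continuous part compares the positive values by the Wilcoxon rank-sum
#' test, skipped when either group has fewer than 3 positive cells. The
#' parts are combined by Fisher's method over whichever parts are available;
#' a gene with no part available (e.g. all-zero in both groups) gets p = 1.
#' P-values are BH-adjusted across genes. This two-part construction mirrors
#' the logistic+continuous hurdle used by single-cell DE frameworks; its
#' acceptance surface is calibration under the null, not identity with any
#' particular implementation.
#'
#' Fold changes are computed on the natural scale of the log-normalized
#' values: log2FC = log2((mean(expm1 x_a) + 1) / (mean(expm1 x_b) + 1)),
#' with the pseudocount keeping the value finite.
#'
#' @param expr an `ExpressionMatrix` (normalized; counts are normalized on
#'   the fly).
#' @param groups binary labels per cell (factor/character/logical with
#'   exactly 2 levels); the first sorted level is the reference "b" group
#'   and positive log2FC means higher in the second level.
#' @return an object of class `"DEResult"`: data.frame with `gene`,
#'   `log2fc`, `p`, `p_adj`, `n_pos_a`, `n_pos_b`.
#' @export
hurdle_de <- function(expr, groups) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (length(groups) != length(expr$cell_ids)) .fail("hurdle_de: groups length mismatch")
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2L) .fail("hurdle_de: exactly two groups required (got %d)", length(lv))
  ia <- which(groups == lv[2]); ib <- which(groups == lv[1])
  if (length(ia) < 3L || length(ib) < 3L) .fail("hurdle_de: both groups need >= 3 cells")
  if (!expr$normalized) expr <- normalize_expression(expr)
  x <- .dense(expr)
  na <- length(ia); nb <- length(ib)

  res <- lapply(seq_len(ncol(x)), function(gi) {
    va <- x[ia, gi]; vb <- x[ib, gi]
    pa <- va[va > 0]; pb <- vb[vb > 0]
    parts <- numeric(0)
    if (length(pa) + length(pb) > 0 && (length(pa) < na || length(pb) < nb)) {
      tab <- matrix(c(length(pa), na - length(pa), length(pb), nb - length(pb)), 2)
      parts <- c(parts, stats::fisher.test(tab)$p.value)
    }
    if (length(pa) >= 3L && length(pb) >= 3L) {
      parts <- c(parts, stats::wilcox.test(pa, pb, exact = FALSE)$p.value)
    }
    p <- if (!length(parts)) 1 else {
      stats::pchisq(-2 * sum(log(pmax(parts, .Machine$double.xmin))),
                    df = 2 * length(parts), lower.tail = FALSE)
    }
    lfc <- log2((mean(expm1(va)) + 1) / (mean(expm1(vb)) + 1))
    c(lfc = lfc, p = max(p, .Machine$double.xmin),
      n_pos_a = length(pa), n_pos_b = length(pb))
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = expr$gene_ids, log2fc = res[, "lfc"], p = res[, "p"],
                    p_adj = stats::p.adjust(res[, "p"], method = "BH"),
                    n_pos_a = res[, "n_pos_a"], n_pos_b = res[, "n_pos_b"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Threshold a DE result into a subtype-defining gene set
#'
#' Strictly greater-than on the fold change (a gene at exactly the cutoff is
#' excluded) and strictly below on the adjusted p.
#'
#' @param de a `DEResult`.
#' @param cfg a [pipeline_config()] (`de_log2fc_min`, `de_padj_max`).
#' @return character vector of gene names.
#' @export
threshold_genes <- function(de, cfg = pipeline_config()) {
  stopifnot(inherits(de, "DEResult"))
  de$gene[de$log2fc > cfg$de_log2fc_min & de$p_adj < cfg$de_padj_max]
}

#' Significance of gene-set overlap by Fisher's exact test
#'
#' One-sided (enrichment) Fisher's exact test of the overlap between two
#' gene sets within a shared universe — the hypergeometric upper tail of the
#' observed intersection.
#'
#' @param set_a,set_b character gene sets, both subsets of `universe`.
#' @param universe character vector of all genes eligible for both sets
#'   (typically the intersection of genes tested in both datasets; recorded
#'   in the result).
#' @return an object of class `"OverlapResult"`: `n_a`, `n_b`,
#'   `n_intersection`, `n_universe`, `odds_ratio`, `p` (one-sided),
#'   `intersection` (the shared genes).
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (!length(universe)) .fail("overlap_test: empty universe")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    .fail("overlap_test: sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  a <- length(set_a); b <- length(set_b); u <- length(universe)
  tab <- matrix(c(k, a - k, b - k, u - a - b + k), 2)
  ft <- stats::fisher.test(tab, alternative = "greater")
  structure(list(n_a = a, n_b = b, n_intersection = k, n_universe = u,
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 intersection = intersect(set_a, set_b)),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("Overlap: %d of %d vs %d genes (universe %d); OR = %.2f, one-sided p = %.3g\n",
              x$n_intersection, x$n_a, x$n_b, x$n_universe, x$odds_ratio, x$p))
  invisible(x)
}

#' Cross-dataset comparison of subtype-defining genes
#'
#' Runs [hurdle_de()] in each dataset, thresholds both with
#' [threshold_genes()], and tests the overlap within the shared tested
#' universe — the analysis used to ask whether neuroendocrine prostate and
#' small-cell lung subtypes share defining genes.
#'
#' @param expr_a,expr_b `ExpressionMatrix` objects for the two datasets.
#' @param groups_a,groups_b binary group labels per dataset.
#' @param cfg a [pipeline_config()].
#' @return list with `de_a`, `de_b` (`DEResult`s), `set_a`, `set_b`,
#'   `overlap` (`OverlapResult`).
#' @export
cross_dataset_overlap <- function(expr_a, groups_a, expr_b, groups_b,
                                  cfg = pipeline_config()) {
  de_a <- hurdle_de(expr_a, groups_a)
  de_b <- hurdle_de(expr_b, groups_b)
  universe <- intersect(de_a$gene, de_b$gene)
  set_a <- intersect(threshold_genes(de_a, cfg), universe)
  set_b <- intersect(threshold_genes(de_b, cfg), universe)
  list(de_a = de_a, de_b = de_b, set_a = set_a, set_b = set_b,
       overlap = overlap_test(set_a, set_b, universe))
}
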