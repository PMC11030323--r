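#' Per-cell regulon activity by rank-recovery AUC
#'
#' For each cell, genes are ranked by decreasing expression (ties broken by a
#' seeded random shuffle so results are reproducible); the recovery curve of
#' a regulon is the cumulative count of its member genes among the top k
#' ranks for k = 1 .. ceiling(threshold_frac * n_genes), and the activity
#' score is the area under that curve normalized by the maximum achievable
#' area (all members at the very top). Scores therefore lie in `[0, 1]` and
#' depend on expression only through ranks, so any monotone transform of the
#' expression values leaves them unchanged.
#'
#' Regulon genes absent from the matrix are ignored, and the normalizing
#' maximum uses only the present genes (otherwise a perfectly recovered
#' regulon could never score 1). Regulons with no gene present are dropped
#' with a warning; if all are dropped this is an error.
#'
#' @param expr an `ExpressionMatrix` (counts or log-normalized; rank-based,
#'   so either works).
#' @param regs a `RegulonSet`.
#' @param cfg a [pipeline_config()]; uses `auc_threshold_frac` and
#'   `rng_seed`.
#' @return an object of class `"ActivityMatrix"`: list with `auc`
#'   (cells x regulons matrix in `[0,1]`), `scaled` (`NULL` until
#'   [scale_activity()] is applied) and `threshold_frac`.
#' @export
score_regulons <- function(expr, regs, cfg = pipeline_config()) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(regs, "RegulonSet"))
  n_genes <- length(expr$gene_ids)
  n_cells <- length(expr$cell_ids)
  w <- ceiling(cfg$auc_threshold_frac * n_genes)
  gene_index <- stats::setNames(seq_len(n_genes), expr$gene_ids)

  present <- lapply(regs$regulons, function(g) unname(gene_index[g[g %in% names(gene_index)]]))
  empty <- lengths(present) == 0L
  if (any(empty)) {
    warning(sprintf("score_regulons: dropping %d regulon(s) with no gene in the matrix: %s",
                    sum(empty), paste(names(present)[empty], collapse = ", ")))
    present <- present[!empty]
  }
  if (!length(present)) .fail("score_regulons: no regulon has any gene in the matrix")

  # maximum achievable area per regulon: members occupy ranks 1..m, m = min(|R|, w)
  max_area <- vapply(present, function(idx) {
    m <- min(length(idx), w)
    sum(w - seq_len(m) + 1)
  }, numeric(1))

  set.seed(stage_seed(cfg$rng_seed, "score_regulons"))
  vals <- .dense(expr)
  auc <- matrix(0, n_cells, length(present),
                dimnames = list(expr$cell_ids, names(present)))
  for (ci in seq_len(n_cells)) {
    tie_break <- sample.int(n_genes)            # one seeded shuffle per cell
    ord <- order(-vals[ci, ], tie_break)
    rk <- integer(n_genes)
    rk[ord] <- seq_len(n_genes)
    for (ri in seq_along(present)) {
      pr <- rk[present[[ri]]]
      pr <- pr[pr <= w]
      auc[ci, ri] <- sum(w - pr + 1) / max_area[ri]
    }
  }
  structure(list(auc = auc, scaled = NULL, threshold_frac = cfg$auc_threshold_frac),
            class = "ActivityMatrix")
}

#' @export
print.ActivityMatrix <- function(x, ...) {
  cat(sprintf("ActivityMatrix: %d cells x %d regulons (recovery window %.1f%% of genes)%s\n",
              nrow(x$auc), ncol(x$auc), 100 * x$threshold_frac,
              if (is.null(x$scaled)) "" else "; z-scaled"))
  invisible(x)
}

#' @export
dim.ActivityMatrix <- function(x) dim(x$auc)

#' Z-scale regulon activity per regulon
#'
#' Per-regulon z-scores across cells using the population standard deviation
#' (divisor n, the heatmap-scaling convention), clipped symmetrically — the
#' familiar "-2 to 2" scaled-activity heatmap range. Constant regulons get
#' all-zero scaled scores with a warning.
#'
#' @param act an `ActivityMatrix`.
#' @param clip symmetric clipping bound (default 2).
#' @return the `ActivityMatrix` with its `scaled` slot filled.
#' @export
scale_activity <- function(act, clip = 2) {
  stopifnot(inherits(act, "ActivityMatrix"), clip > 0)
  mu <- colMeans(act$auc)
  n <- nrow(act$auc)
  sd_pop <- sqrt(colMeans(sweep(act$auc, 2, mu)^2))
  const <- sd_pop == 0
  if (any(const)) {
    warning(sprintf("scale_activity: %d constant regulon(s) scaled to 0: %s",
                    sum(const), paste(colnames(act$auc)[const], collapse = ", ")))
    sd_pop[const] <- 1
  }
  z <- sweep(sweep(act$auc, 2, mu), 2, sd_pop, "/")
  z[, const] <- 0
  z[] <- pmin(clip, pmax(-clip, z))   # [] keeps the matrix shape
  act$scaled <- z
  act
}
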