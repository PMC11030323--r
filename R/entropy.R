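#' Phenograph-style graph clustering of cells
#'
#' K-nearest-neighbor graph on the top principal components of the
#' log-normalized expression, followed by modularity-based community
#' detection (Louvain). Deterministic given the seed.
#'
#' @param expr an `ExpressionMatrix`; raw counts are normalized on the fly.
#' @param k number of nearest neighbors (must be < number of cells).
#' @param seed integer RNG seed.
#' @param n_pcs number of principal components (capped by the data rank).
#' @return integer cluster labels named by cell ID.
#' @export
cluster_cells <- function(expr, k = 30L, seed = 1L, n_pcs = 30L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  n <- length(expr$cell_ids)
  if (k >= n) .fail("cluster_cells: k (%d) must be smaller than the number of cells (%d)", k, n)
  if (!expr$normalized) expr <- normalize_expression(expr)
  x <- .dense(expr)
  n_pcs <- min(n_pcs, n - 1L, ncol(x))
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x

  d <- as.matrix(stats::dist(pcs))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]          # skip self
    edges[[i]] <- cbind(i, nb)
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(stage_seed(seed, "cluster_cells"))
  comm <- igraph::cluster_louvain(g)
  stats::setNames(as.integer(igraph::membership(comm)), expr$cell_ids)
}

#' Subsampled Shannon entropy of patient composition per cluster
#'
#' Quantifies inter-patient heterogeneity: for each cluster,
#' `entropy_subsample_n` cells are drawn with replacement and the Shannon
#' entropy (nats) of the drawn patient frequencies recorded, repeated
#' `entropy_reps` times — controlling for cluster size. Clusters dominated
#' by a single patient (patient-specific states, as seen in
#' castration-resistant and neuroendocrine disease) score low entropy;
#' clusters mixing many patients (castration-sensitive-like) score high.
#' Clusters smaller than the subsample size are still sampled with
#' replacement, so none is dropped.
#'
#' Each cluster is assigned to the disease category of the majority of its
#' cells (ties broken toward the rarer category overall, with a message);
#' replicate entropies are pooled per category, and categories are compared
#' pairwise with the unpaired Wilcoxon rank-sum test. The source figure's
#' legend names a signed-rank test, but replicates are unpaired across
#' categories, so the rank-sum statistic is the primary result; a paired
#' signed-rank statistic (pairing replicates by index) is reported alongside
#' when the pooled sizes happen to match.
#'
#' @param labels cluster label per cell.
#' @param patients patient ID per cell.
#' @param categories disease-category label per cell (optional; without it
#'   only per-cluster entropies are returned).
#' @param cfg a [pipeline_config()] (`entropy_subsample_n`, `entropy_reps`,
#'   `rng_seed`).
#' @return an object of class `"EntropyResult"`: `per_cluster` (data.frame
#'   cluster/replicate/entropy), `cluster_category` (named vector), `pooled`
#'   (data.frame category/entropy), `tests` (pairwise data.frame with
#'   rank-sum and, where defined, signed-rank p-values).
#' @export
subsampled_entropy <- function(labels, patients, categories = NULL,
                               cfg = pipeline_config()) {
  if (length(labels) != length(patients)) .fail("subsampled_entropy: length mismatch")
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (!length(clusters)) .fail("subsampled_entropy: no clusters")
  set.seed(stage_seed(cfg$rng_seed, "subsampled_entropy"))
  reps <- cfg$entropy_reps
  nsub <- cfg$entropy_subsample_n
  per <- do.call(rbind, lapply(clusters, function(cl) {
    pts <- patients[labels == cl]
    ent <- vapply(seq_len(reps), function(r) {
      shannon_entropy(table(sample(pts, nsub, replace = TRUE)))
    }, numeric(1))
    data.frame(cluster = cl, replicate = seq_len(reps), entropy = ent,
               stringsAsFactors = FALSE)
  }))

  cluster_category <- NULL; pooled <- NULL; tests <- NULL
  if (!is.null(categories)) {
    cat_sizes <- table(categories)
    cluster_category <- vapply(clusters, function(cl) {
      tab <- table(categories[labels == cl])
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1L) {
        top <- top[which.min(cat_sizes[top])]   # tie toward the rarer category
        message(sprintf("cluster %s: category tie broken toward '%s'", cl, top))
      }
      top
    }, character(1))
    per$category <- cluster_category[per$cluster]
    pooled <- per[, c("category", "entropy")]
    cats <- sort(unique(pooled$category))
    if (length(cats) >= 2L && reps > 1L) {
      pairs <- utils::combn(cats, 2, simplify = FALSE)
      tests <- do.call(rbind, lapply(pairs, function(pr) {
        a <- pooled$entropy[pooled$category == pr[1]]
        b <- pooled$entropy[pooled$category == pr[2]]
        rs <- stats::wilcox.test(a, b, exact = FALSE)
        sr_p <- if (length(a) == length(b) && any(a != b)) {
          stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
        } else NA_real_
        data.frame(category_a = pr[1], category_b = pr[2],
                   median_a = stats::median(a), median_b = stats::median(b),
                   ranksum_W = unname(rs$statistic), ranksum_p = rs$p.value,
                   signedrank_p = sr_p, stringsAsFactors = FALSE)
      }))
    }
  }
  structure(list(per_cluster = per, cluster_category = cluster_category,
                 pooled = pooled, tests = tests),
            class = "EntropyResult")
}

#' @export
print.EntropyResult <- function(x, ...) {
  cat(sprintf("EntropyResult: %d clusters x %d replicates\n",
              length(unique(x$per_cluster$cluster)),
              max(x$per_cluster$replicate)))
  if (!is.null(x$pooled)) {
    med <- tapply(x$pooled$entropy, x$pooled$category, stats::median)
    cat("  median entropy (nats) per category:\n")
    for (nm in names(med)) cat(sprintf("    %-12s %.3f\n", nm, med[[nm]]))
  }
  if (!is.null(x$tests)) {
    cat("  pairwise rank-sum tests:\n")
    for (i in seq_len(nrow(x$tests))) {
      cat(sprintf("    %s vs %s: p = %.3g\n", x$tests$category_a[i],
                  x$tests$category_b[i], x$tests$ranksum_p[i]))
    }
  }
  invisible(x)
}
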