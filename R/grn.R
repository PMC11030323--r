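#' Hierarchical clustering of cells on scaled regulon activity
#'
#' Agglomerative clustering with Euclidean distance on the z-scaled activity
#' matrix. `"ward"` (Ward's minimum-variance on squared distances, R's
#' `ward.D2`) is the default because GRN states are expected to be compact;
#' `"average"` and `"complete"` are available for sensitivity checks.
#'
#' @param act a scaled `ActivityMatrix` (see [scale_activity()]; raw AUC is
#'   scaled on the fly if needed).
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @return an `hclust` dendrogram over cells.
#' @export
hcluster_cells <- function(act, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  x <- .activity_features(act)
  if (nrow(x) < 2L) .fail("hcluster_cells: need at least 2 cells")
  if (anyNA(x) || any(!is.finite(x))) .fail("hcluster_cells: non-finite activity values")
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  hc <- stats::hclust(stats::dist(x), method = method)
  hc$labels <- rownames(x)
  hc
}

# internal: the feature matrix clustering operates on (scaled activity)
.activity_features <- function(act) {
  stopifnot(inherits(act, "ActivityMatrix"))
  if (is.null(act$scaled)) act <- scale_activity(act)
  act$scaled
}

#' Stability-guided dendrogram cut selection
#'
#' Chooses the number of GRN states by bootstrap stability of the adjusted
#' Rand index. Candidate cuts are the heights yielding k = 2 .. `max_k`
#' clusters on the reference dendrogram. Cells are resampled with
#' replacement `n_boot` times and re-clustered; each bootstrap dendrogram is
#' cut at the same height relative to its maximum merge height, and the ARI
#' between the bootstrap partition and the reference partition is computed
#' over the shared cells. The stability of a candidate is the mean ARI over
#' bootstraps, and the chosen cut is the most parsimonious candidate (fewest
#' clusters) whose stability is within `tol` of the maximum. If no candidate
#' reaches `min_stability` the data carry no reproducible multi-state
#' structure and the selection falls back to a single state with a warning.
#'
#' @param dend reference `hclust` from [hcluster_cells()].
#' @param act the `ActivityMatrix` the dendrogram was built from.
#' @param n_boot number of bootstrap re-clusterings (>= 2).
#' @param seed integer RNG seed.
#' @param max_k largest candidate cluster count.
#' @param tol stability tolerance for the parsimony rule (default 0.01).
#' @param min_stability floor below which the single-state fallback applies.
#' @param linkage linkage used for the bootstrap re-clusterings (should match
#'   the reference dendrogram).
#' @return an object of class `"CutSelection"`: `candidate_heights`,
#'   `candidate_k`, `stability` (mean bootstrap ARI per candidate),
#'   `chosen_height`, `chosen_k`.
#' @export
select_cut <- function(dend, act, n_boot = 20L, seed = 1L, max_k = 15L,
                       tol = 0.01, min_stability = 0.5,
                       linkage = c("ward", "average", "complete")) {
  stopifnot(inherits(dend, "hclust"))
  linkage <- match.arg(linkage)
  if (n_boot < 2L) .fail("select_cut: n_boot must be >= 2")
  x <- .activity_features(act)
  n <- nrow(x)
  heights <- sort(dend$height)
  if (max(heights) == 0) {
    warning("select_cut: all cells identical; returning a single state")
    return(.cut_selection(numeric(0), integer(0), numeric(0), 0, 1L))
  }
  ks <- 2:min(max_k, n - 1L)
  # midpoint height between the merges that separate k and k-1 clusters
  cand_h <- vapply(ks, function(k) {
    upper <- heights[n - k + 1L]
    lower <- if (n - k >= 1L) heights[n - k] else 0
    (upper + lower) / 2
  }, numeric(1))
  ref_parts <- lapply(ks, function(k) stats::cutree(dend, k = k))
  h_max <- max(dend$height)

  set.seed(stage_seed(seed, "select_cut"))
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  boot_stats <- matrix(NA_real_, n_boot, length(ks))
  for (b in seq_len(n_boot)) {
    idx <- sort(unique(sample.int(n, n, replace = TRUE)))
    hb <- stats::hclust(stats::dist(x[idx, , drop = FALSE]), method = method)
    hb_max <- max(hb$height)
    for (j in seq_along(ks)) {
      rel_h <- cand_h[j] / h_max
      pb <- stats::cutree(hb, h = rel_h * hb_max)
      boot_stats[b, j] <- adjusted_rand_index(ref_parts[[j]][idx], pb)
    }
  }
  stability <- colMeans(boot_stats)
  if (max(stability) < min_stability) {
    warning("select_cut: no cut is bootstrap-stable; falling back to a single state")
    return(.cut_selection(cand_h, ks, stability, max(dend$height) * 1.01, 1L))
  }
  ok <- which(stability >= max(stability) - tol)
  pick <- ok[which.min(ks[ok])]            # most parsimonious within tolerance
  .cut_selection(cand_h, ks, stability, cand_h[pick], ks[pick])
}

.cut_selection <- function(h, k, s, chosen_h, chosen_k) {
  structure(list(candidate_heights = h, candidate_k = k, stability = s,
                 chosen_height = chosen_h, chosen_k = chosen_k),
            class = "CutSelection")
}

#' @export
print.CutSelection <- function(x, ...) {
  cat(sprintf("CutSelection: chose k = %d (height %.3f)\n", x$chosen_k, x$chosen_height))
  if (length(x$candidate_k)) {
    df <- data.frame(k = x$candidate_k, height = round(x$candidate_heights, 3),
                     stability = round(x$stability, 3))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Regulon specificity score (RSS) and per-state regulon ranking
#'
#' RSS(regulon r, state g) = 1 - sqrt(JSD(P_r, Q_g)) with base-2
#' Jensen-Shannon divergence (so JSD, and hence RSS, lies in `[0, 1]`).
#' P_r is the regulon's cellwise activity min-shifted to be non-negative and
#' normalized to sum 1; Q_g is the uniform distribution over the cells of
#' state g and zero elsewhere. A regulon concentrated uniformly on exactly
#' the cells of g scores 1; a regulon whose support is disjoint from g
#' scores 0. Each regulon is assigned to its argmax-RSS state and regulons
#' are ranked within each state by descending RSS.
#'
#' @param act an `ActivityMatrix`; raw AUC activity is used by default since
#'   it is already non-negative.
#' @param assignment vector of state labels, one per cell (same order as the
#'   activity rows).
#' @return data.frame with columns `regulon`, `grn`, `rss` (the score in the
#'   assigned state) and `rank` (1 = most specific within the state), plus
#'   an attribute `"rss_matrix"` (regulons x states). All-zero activity
#'   vectors are flagged and excluded with a warning.
#' @export
regulon_specificity <- function(act, assignment) {
  stopifnot(inherits(act, "ActivityMatrix"))
  a <- act$auc
  if (length(assignment) != nrow(a)) .fail("regulon_specificity: assignment length mismatch")
  states <- sort(unique(as.character(assignment)))
  if (any(table(assignment) == 0)) .fail("regulon_specificity: empty state")
  rss <- matrix(NA_real_, ncol(a), length(states),
                dimnames = list(colnames(a), states))
  dropped <- character(0)
  for (ri in seq_len(ncol(a))) {
    p <- a[, ri]
    p <- p - min(p, 0)
    if (sum(p) == 0) { dropped <- c(dropped, colnames(a)[ri]); next }
    p <- p / sum(p)
    for (si in seq_along(states)) {
      in_g <- assignment == states[si]
      q <- ifelse(in_g, 1 / sum(in_g), 0)
      rss[ri, si] <- 1 - sqrt(.jsd2(p, q))
    }
  }
  if (length(dropped)) {
    warning(sprintf("regulon_specificity: excluded %d all-zero regulon(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  keep <- rownames(rss)[!rownames(rss) %in% dropped]
  best <- states[apply(rss[keep, , drop = FALSE], 1, which.max)]
  tab <- data.frame(regulon = keep, grn = best,
                    rss = rss[cbind(keep, best)], stringsAsFactors = FALSE)
  tab <- tab[order(tab$grn, -tab$rss), ]
  tab$rank <- stats::ave(-tab$rss, tab$grn, FUN = function(v) rank(v, ties.method = "first"))
  rownames(tab) <- NULL
  attr(tab, "rss_matrix") <- rss
  tab
}

# internal: base-2 Jensen-Shannon divergence between probability vectors
.jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) { i <- a > 0; sum(a[i] * log2(a[i] / m[i])) }
  d <- 0.5 * kl(p) + 0.5 * kl(q)
  min(1, max(0, d))   # guard tiny float excursions
}

#' Discover GRN states from regulon activity
#'
#' The package's central fit: hierarchical clustering of z-scaled regulon
#' activity, bootstrap-ARI selection of the number of states, and RSS-based
#' assignment and ranking of regulons per state. When the metadata carry a
#' `category` column distinguishing adenocarcinoma-like from
#' neuroendocrine-like cells, the two compartments should be fitted
#' separately (as done for the 10 + 3 state decomposition); this function
#' fits the cells it is given.
#'
#' @param act an `ActivityMatrix`.
#' @param cfg a [pipeline_config()] (linkage, bootstrap count, seed, max_k).
#' @return an object of class `"GRNPartition"`: `assignment` (named state
#'   label per cell), `n_grn`, `dendrogram` (`hclust`), `cut_height`,
#'   `cut` (`CutSelection`), `regulon_table`.
#' @export
discover_grns <- function(act, cfg = pipeline_config()) {
  act <- if (is.null(act$scaled)) scale_activity(act, clip = cfg$zscore_clip) else act
  dend <- hcluster_cells(act, linkage = cfg$linkage)
  cut <- select_cut(dend, act, n_boot = cfg$n_boot,
                    seed = cfg$rng_seed, max_k = cfg$max_k, linkage = cfg$linkage)
  labels <- if (cut$chosen_k == 1L) {
    stats::setNames(rep(1L, nrow(act$auc)), rownames(act$auc))
  } else {
    stats::cutree(dend, k = cut$chosen_k)
  }
  assignment <- stats::setNames(sprintf("GRN%02d", labels), rownames(act$auc))
  tab <- regulon_specificity(act, assignment)
  structure(list(assignment = assignment, n_grn = cut$chosen_k,
                 dendrogram = dend, cut_height = cut$chosen_height,
                 cut = cut, regulon_table = tab),
            class = "GRNPartition")
}

#' @export
print.GRNPartition <- function(x, ...) {
  cat(sprintf("GRNPartition: %d states over %d cells\n",
              x$n_grn, length(x$assignment)))
  print(table(x$assignment))
  invisible(x)
}

#' @export
summary.GRNPartition <- function(object, top_n = 3L, ...) {
  cat(sprintf("GRN states: %d (cut height %.3f)\n", object$n_grn, object$cut_height))
  tab <- object$regulon_table
  for (g in sort(unique(tab$grn))) {
    top <- utils::head(tab[tab$grn == g, ], top_n)
    cat(sprintf("  %s (%d cells): %s\n", g, sum(object$assignment == g),
                paste(sprintf("%s (RSS %.2f)", top$regulon, top$rss), collapse = ", ")))
  }
  invisible(object)
}

#' @export
plot.GRNPartition <- function(x, ...) {
  plot(x$dendrogram, labels = FALSE, main = sprintf("%d GRN states", x$n_grn),
       xlab = "", sub = "", ...)
  stats::rect.hclust(x$dendrogram, k = max(2L, x$n_grn))
  invisible(x)
}

#' Cell- and patient-level robustness of a GRN partition
#'
#' Two perturbation analyses of a reference partition: (a) cell bootstrap —
#' cells are resampled with replacement, re-clustered and cut at the same
#' relative dendrogram height, and the ARI against the reference partition is
#' recorded over shared cells; (b) leave-one-patient-out (LOPO) — each
#' patient's cells are dropped, the rest re-clustered, and the ARI computed
#' on retained cells. A reference state is "recurrent" if a replicate
#' cluster matches it with cell-membership Jaccard >= `jaccard_min` in at
#' least `recurrent_frac` of the replicates.
#'
#' @param act the `ActivityMatrix` of the reference fit.
#' @param part the reference `GRNPartition`.
#' @param patients patient label per cell (needed for the LOPO analysis;
#'   with a single patient that analysis is skipped with a warning).
#' @param cfg a [pipeline_config()] (`n_boot`, `linkage`, `rng_seed`).
#' @param jaccard_min minimum Jaccard for a state to count as matched.
#' @param recurrent_frac fraction of replicates in which a state must be
#'   matched to be called recurrent (default 0.7).
#' @return an object of class `"RobustnessReport"`: `cell_bootstrap_ari`
#'   (numeric vector, empty when `n_boot = 0`), `lopo_ari` (named per
#'   patient), `recurrent_grns` (character labels), `match_frac` (per-state
#'   fraction of replicates matched).
#' @export
robustness <- function(act, part, patients, cfg = pipeline_config(),
                       jaccard_min = 0.5, recurrent_frac = 0.7) {
  stopifnot(inherits(part, "GRNPartition"))
  x <- .activity_features(act)
  n <- nrow(x)
  if (length(patients) != n) .fail("robustness: patients length mismatch")
  ref <- part$assignment
  rel_h <- part$cut_height / max(part$dendrogram$height)
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[cfg$linkage]]

  recluster <- function(idx) {
    hb <- stats::hclust(stats::dist(x[idx, , drop = FALSE]), method = method)
    stats::cutree(hb, h = rel_h * max(hb$height))
  }
  jaccard_match <- function(idx, pb) {
    vapply(sort(unique(ref)), function(g) {
      ref_cells <- names(ref)[ref == g]
      best <- 0
      for (cl in unique(pb)) {
        cl_cells <- rownames(x)[idx][pb == cl]
        j <- length(intersect(ref_cells, cl_cells)) /
          length(union(intersect(ref_cells, rownames(x)[idx]), cl_cells))
        best <- max(best, j)
      }
      best
    }, numeric(1))
  }

  set.seed(stage_seed(cfg$rng_seed, "robustness"))
  states <- sort(unique(ref))
  boot_ari <- numeric(0)
  match_count <- stats::setNames(numeric(length(states)), states)
  n_rep <- 0L
  if (cfg$n_boot > 0L) {
    for (b in seq_len(cfg$n_boot)) {
      idx <- sort(unique(sample.int(n, n, replace = TRUE)))
      pb <- recluster(idx)
      boot_ari <- c(boot_ari, adjusted_rand_index(ref[idx], pb))
      match_count <- match_count + (jaccard_match(idx, pb) >= jaccard_min)
      n_rep <- n_rep + 1L
    }
  }

  pts <- unique(patients)
  lopo <- stats::setNames(rep(NA_real_, length(pts)), pts)
  if (length(pts) < 2L) {
    warning("robustness: single patient; leave-one-patient-out analysis skipped")
  } else {
    for (p in pts) {
      idx <- which(patients != p)
      if (length(idx) < 2L) next
      pb <- recluster(idx)
      lopo[p] <- adjusted_rand_index(ref[idx], pb)
      match_count <- match_count + (jaccard_match(idx, pb) >= jaccard_min)
      n_rep <- n_rep + 1L
    }
  }
  match_frac <- if (n_rep > 0L) match_count / n_rep else match_count * NA_real_
  recurrent <- names(match_frac)[!is.na(match_frac) & match_frac >= recurrent_frac]
  structure(list(cell_bootstrap_ari = boot_ari, lopo_ari = lopo,
                 recurrent_grns = recurrent, match_frac = match_frac),
            class = "RobustnessReport")
}

#' @export
print.RobustnessReport <- function(x, ...) {
  cat("Robustness report\n")
  if (length(x$cell_bootstrap_ari)) {
    cat(sprintf("  cell bootstrap ARI: median %.3f (n = %d)\n",
                stats::median(x$cell_bootstrap_ari), length(x$cell_bootstrap_ari)))
  } else cat("  cell bootstrap: not run\n")
  if (any(!is.na(x$lopo_ari))) {
    cat(sprintf("  leave-one-patient-out ARI: median %.3f over %d patients\n",
                stats::median(x$lopo_ari, na.rm = TRUE), sum(!is.na(x$lopo_ari))))
  }
  cat(sprintf("  recurrent states: %s\n",
              if (length(x$recurrent_grns)) paste(x$recurrent_grns, collapse = ", ") else "none"))
  invisible(x)
}
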