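#' Control-bin module score for a gene signature
#'
#' Per-cell mean expression of the signature genes minus the mean of
#' bin-matched control genes: all genes are binned by average expression
#' into `n_bins` bins, and for each signature gene `n_controls` control
#' genes are drawn (with replacement when the bin is small) from its bin.
#' Matching controls on expression level removes the depth/abundance
#' component, so a random signature scores ~0 and a program up-regulated in
#' some cells scores positive there. The familiar defaults are 25 bins and
#' 100 controls per signature gene.
#'
#' @param expr an `ExpressionMatrix` (normalized; counts normalized on the
#'   fly).
#' @param signature character vector of signature genes; genes absent from
#'   the matrix are ignored, and an entirely absent signature is an error.
#' @param n_bins number of average-expression bins.
#' @param n_controls control genes drawn per signature gene.
#' @param seed integer RNG seed for the control draw.
#' @return an object of class `"ModuleScore"`: `score` (named per cell),
#'   `signature` (genes used), `n_bins`, `n_controls`, `controls` (the drawn
#'   control pool, with multiplicity).
#' @export
module_score <- function(expr, signature, n_bins = 25L, n_controls = 100L,
                         seed = 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!expr$normalized) expr <- normalize_expression(expr)
  sig <- intersect(signature, expr$gene_ids)
  if (!length(sig)) .fail("module_score: no signature gene present in the matrix")
  x <- .dense(expr)
  avg <- colMeans(x)
  n_bins <- min(n_bins, length(unique(avg)))
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- expr$gene_ids

  set.seed(stage_seed(seed, "module_score"))
  controls <- unlist(lapply(sig, function(g) {
    pool <- setdiff(names(bins)[bins == bins[[g]]], sig)
    if (!length(pool)) pool <- setdiff(names(bins), sig)
    sample(pool, n_controls, replace = TRUE)
  }))
  score <- rowMeans(x[, sig, drop = FALSE]) - rowMeans(x[, controls, drop = FALSE])
  structure(list(score = stats::setNames(score, expr$cell_ids),
                 signature = sig, n_bins = n_bins, n_controls = n_controls,
                 controls = controls),
            class = "ModuleScore")
}

#' @export
print.ModuleScore <- function(x, ...) {
  cat(sprintf("ModuleScore: %d signature genes, %d bins x %d controls; mean %.3f\n",
              length(x$signature), x$n_bins, x$n_controls, mean(x$score)))
  invisible(x)
}

#' Per-GRN surface-marker summary with concordance
#'
#' For each GRN state, the mean log expression of each marker, min-max
#' scaled to `[0, 1]` across states (the scaling of the one-point-per-state
#' scatter and heatmap displays: the highest state maps to exactly 1 and
#' the lowest to exactly 0), together with the mean module score (e.g. an
#' AR program score). Lin's CCC and Pearson's r between each marker's
#' scaled means and the module score are computed across the state points,
#' optionally restricted to a subset of states (e.g. adenocarcinoma-only).
#'
#' @param expr an `ExpressionMatrix` (normalized; counts normalized on the
#'   fly).
#' @param part a `GRNPartition` (or a named assignment vector).
#' @param markers character vector of marker genes (must be present).
#' @param module a `ModuleScore`.
#' @param cor_states optional subset of state labels over which the
#'   correlations are computed (default: all).
#' @return an object of class `"GRNMarkerSummary"`: `per_grn` (data.frame
#'   with state, n_cells, mean module score, and per-marker scaled/raw
#'   means), `associations` (per-marker CCC and Pearson r across states;
#'   `NA` with a warning where undefined, e.g. a marker flat across states
#'   or fewer than 3 states).
#' @export
grn_marker_summary <- function(expr, part, markers, module,
                               cor_states = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(module, "ModuleScore"))
  assignment <- if (inherits(part, "GRNPartition")) part$assignment else part
  if (!expr$normalized) expr <- normalize_expression(expr)
  miss <- setdiff(markers, expr$gene_ids)
  if (length(miss)) .fail("grn_marker_summary: marker(s) absent: %s",
                          paste(miss, collapse = ", "))
  x <- .dense(expr)[, markers, drop = FALSE]
  states <- sort(unique(assignment))
  raw <- matrix(NA_real_, length(states), length(markers),
                dimnames = list(states, markers))
  for (g in states) raw[g, ] <- colMeans(x[assignment == g, , drop = FALSE])
  rng <- apply(raw, 2, function(v) diff(range(v)))
  scaled <- raw
  for (j in seq_along(markers)) {
    scaled[, j] <- if (rng[j] == 0) NA_real_ else (raw[, j] - min(raw[, j])) / rng[j]
  }
  mod_mean <- vapply(states, function(g) mean(module$score[assignment == g]), numeric(1))

  sel <- if (is.null(cor_states)) states else intersect(states, cor_states)
  assoc <- do.call(rbind, lapply(markers, function(m) {
    v <- scaled[sel, m]
    if (length(sel) < 3L || anyNA(v) || stats::sd(v) == 0 || stats::sd(mod_mean[sel]) == 0) {
      warning(sprintf("grn_marker_summary: association undefined for '%s' (flat or < 3 states)", m))
      return(data.frame(marker = m, ccc = NA_real_, pearson_r = NA_real_,
                        n_states = length(sel), stringsAsFactors = FALSE))
    }
    cc <- lin_ccc(mod_mean[sel], v)
    data.frame(marker = m, ccc = cc$ccc, pearson_r = cc$pearson_r,
               n_states = length(sel), stringsAsFactors = FALSE)
  }))
  per <- data.frame(grn = states, n_cells = as.integer(table(assignment)[states]),
                    module_score = mod_mean, stringsAsFactors = FALSE)
  for (m in markers) {
    per[[paste0(m, "_mean")]] <- raw[, m]
    per[[paste0(m, "_scaled")]] <- scaled[, m]
  }
  rownames(per) <- NULL
  structure(list(per_grn = per, associations = assoc),
            class = "GRNMarkerSummary")
}

#' @export
print.GRNMarkerSummary <- function(x, ...) {
  cat(sprintf("GRNMarkerSummary: %d states\n", nrow(x$per_grn)))
  print(x$associations, row.names = FALSE)
  invisible(x)
}

#' Graph-diffusion (MAGIC-style) expression imputation
#'
#' Denoises expression by diffusing it over a cell-cell Markov matrix: a
#' k-nearest-neighbor graph is built on the top principal components, an
#' adaptive Gaussian kernel with per-cell bandwidth equal to the distance to
#' the ceiling(k/3)-th neighbor converts distances to affinities, the
#' affinity matrix is symmetrized as (A + t(A))/2 and row-normalized to a
#' Markov matrix M, and the imputed expression is M^t x. t = 0 returns the
#' input unchanged, and every imputed value is a convex combination of
#' observed values, hence within each gene's observed range.
#'
#' @param expr an `ExpressionMatrix` (normalized; counts normalized on the
#'   fly).
#' @param k number of nearest neighbors (default 20; must be < n cells).
#' @param t diffusion time (default 1).
#' @param n_pcs principal components used for the neighbor graph.
#' @param seed integer seed (PCA and kernel are deterministic; kept for
#'   interface symmetry with the other stages).
#' @return cells x genes matrix of imputed values (dimnames preserved).
#' @export
magic_impute <- function(expr, k = 20L, t = 1L, n_pcs = 20L, seed = 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  n <- length(expr$cell_ids)
  if (k >= n) .fail("magic_impute: k (%d) must be smaller than the number of cells (%d)", k, n)
  if (t < 0) .fail("magic_impute: t must be >= 0")
  if (!expr$normalized) expr <- normalize_expression(expr)
  x <- .dense(expr)
  if (t == 0) return(x)
  n_pcs <- min(n_pcs, n - 1L, ncol(x))
  pcs <- stats::prcomp(x, center = TRUE, rank. = n_pcs)$x
  d <- as.matrix(stats::dist(pcs))
  bw_idx <- ceiling(k / 3)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    nb <- ord[2:(k + 1L)]
    sigma <- d[i, ord[bw_idx + 1L]]          # distance to the ceil(k/3)-th neighbor
    if (sigma == 0) sigma <- .Machine$double.eps
    A[i, nb] <- exp(-(d[i, nb] / sigma)^2)
  }
  diag(A) <- 1
  A <- (A + t(A)) / 2
  M <- A / rowSums(A)
  imputed <- x
  for (s in seq_len(t)) imputed <- M %*% imputed
  dimnames(imputed) <- dimnames(x)
  imputed
}

#' RSS-style ranking of candidate surface markers per GRN
#'
#' Ranks a surfaceome gene list within each GRN state by the specificity of
#' its expression to that state, using the same Jensen-Shannon specificity
#' score applied to regulon activity: a gene expressed only in one state
#' ranks first there, a uniformly expressed gene ranks near the bottom
#' everywhere. Intended to surface combination targets beyond the canonical
#' antigens (PSMA, STEAP1/2, TROP2, CEACAM5, DLL3).
#'
#' @param expr an `ExpressionMatrix` (normalized; counts normalized on the
#'   fly).
#' @param part a `GRNPartition` (or named assignment vector).
#' @param surfaceome character vector of cell-surface gene symbols; genes
#'   absent from the matrix are ignored. Empty (after intersection) is an
#'   error.
#' @return data.frame: `grn`, `gene`, `specificity`, `rank` (1 = most
#'   specific within the state).
#' @export
candidate_surface_markers <- function(expr, part, surfaceome) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  assignment <- if (inherits(part, "GRNPartition")) part$assignment else part
  if (!length(surfaceome)) .fail("candidate_surface_markers: empty surfaceome")
  genes <- intersect(surfaceome, expr$gene_ids)
  if (!length(genes)) .fail("candidate_surface_markers: no surfaceome gene present")
  if (!expr$normalized) expr <- normalize_expression(expr)
  x <- .dense(expr)[, genes, drop = FALSE]
  fake_act <- structure(list(auc = x, scaled = NULL, threshold_frac = NA_real_),
                        class = "ActivityMatrix")
  rss <- attr(regulon_specificity(fake_act, assignment), "rss_matrix")
  out <- do.call(rbind, lapply(colnames(rss), function(g) {
    data.frame(grn = g, gene = rownames(rss),
               specificity = rss[, g], stringsAsFactors = FALSE)
  }))
  out <- out[!is.na(out$specificity), ]
  out <- out[order(out$grn, -out$specificity), ]
  out$rank <- stats::ave(-out$specificity, out$grn,
                         FUN = function(v) rank(v, ties.method = "first"))
  rownames(out) <- NULL
  out
}
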