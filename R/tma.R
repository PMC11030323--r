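#' Lin's concordance correlation coefficient with 95% CI
#'
#' Agreement along the identity line between two paired measurements:
#' CCC = 2*s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2), computed with
#' population (divisor-n) moments per the original definition. Unlike
#' Pearson's r, the CCC penalizes location and scale shifts, so always
#' |CCC| <= |r|. The 95% confidence interval uses the Fisher z-transform of
#' the CCC with the standard asymptotic variance. Missing values are removed
#' pairwise.
#'
#' @param x,y paired numeric vectors (e.g. H-scores of two markers over the
#'   same tumor samples); at least 3 complete pairs required.
#' @param conf confidence level for the interval (default 0.95).
#' @return an object of class `"ConcordanceResult"`: `ccc`, `ci_low`,
#'   `ci_high`, `pearson_r`, `n_pairs`.
#' @export
lin_ccc <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) .fail("lin_ccc: need >= 3 complete pairs (got %d)", n)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) .fail("lin_ccc: both vectors constant; CCC undefined")
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 == 0 || sy2 == 0) NA_real_ else sxy / sqrt(sx2 * sy2)

  ci <- c(NA_real_, NA_real_)
  if (!is.na(r) && abs(ccc) < 1 && r != 0) {
    u <- (mx - my) / (sx2 * sy2)^0.25
    z <- atanh(ccc)
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(sz2) && sz2 > 0) {
      q <- stats::qnorm(1 - (1 - conf) / 2)
      ci <- tanh(z + c(-1, 1) * q * sqrt(sz2))
    }
  }
  structure(list(ccc = ccc, ci_low = ci[1], ci_high = ci[2],
                 pearson_r = r, n_pairs = n),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("Lin's CCC = %.3f (95%% CI %.3f-%.3f), Pearson r = %.3f, n = %d\n",
              x$ccc, x$ci_low, x$ci_high, x$pearson_r, x$n_pairs))
  invisible(x)
}

#' Pairwise concordance matrix over markers
#'
#' [lin_ccc()] applied to every marker pair of an H-score table with
#' pairwise deletion of missing stains.
#'
#' @param tbl an `HScoreTable`.
#' @param markers marker subset (default: all marker columns).
#' @return long-format data.frame: `marker_x`, `marker_y`, `ccc`, `ci_low`,
#'   `ci_high`, `pearson_r`, `n_pairs`. Pairs with too few complete
#'   observations or undefined CCC are reported as `NA`.
#' @export
concordance_matrix <- function(tbl, markers = hscore_markers(tbl)) {
  pairs <- utils::combn(markers, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    res <- tryCatch(lin_ccc(tbl[[pr[1]]], tbl[[pr[2]]]), error = function(e) NULL)
    data.frame(marker_x = pr[1], marker_y = pr[2],
               ccc = if (is.null(res)) NA_real_ else res$ccc,
               ci_low = if (is.null(res)) NA_real_ else res$ci_low,
               ci_high = if (is.null(res)) NA_real_ else res$ci_high,
               pearson_r = if (is.null(res)) NA_real_ else res$pearson_r,
               n_pairs = if (is.null(res)) NA_integer_ else res$n_pairs,
               stringsAsFactors = FALSE)
  }))
}

# internal: significance tiers per the star convention
.sig_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Histology-stratified marker comparison
#'
#' Pairwise two-sided rank tests of a marker's H-score distribution among
#' the PRAD / HGC / NEPC histology groups, with the usual significance-star
#' tiers. Groups are unpaired (different tumor samples), so the unpaired
#' Wilcoxon rank-sum test is used; the output records the test label.
#' Groups with fewer than 2 scored samples are dropped with a warning.
#'
#' @param tbl an `HScoreTable`.
#' @param marker marker column name.
#' @return data.frame: `group_a`, `group_b`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `p`, `tier`, `test`.
#' @export
histology_tests <- function(tbl, marker) {
  if (!marker %in% names(tbl)) .fail("histology_tests: unknown marker '%s'", marker)
  v <- tbl[[marker]]; h <- tbl$histology
  ok <- !is.na(v)
  v <- v[ok]; h <- h[ok]
  sizes <- table(h)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("histology_tests: dropping group(s) with < 2 samples: %s",
                    paste(small, collapse = ", ")))
  }
  groups <- names(sizes)[sizes >= 2]
  if (length(groups) < 2L) .fail("histology_tests: need >= 2 histology groups with >= 2 samples")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- v[h == pr[1]]; b <- v[h == pr[2]]
    p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
    data.frame(group_a = pr[1], group_b = pr[2], n_a = length(a), n_b = length(b),
               median_a = stats::median(a), median_b = stats::median(b),
               p = p, tier = as.character(.sig_tier(p)),
               test = "wilcoxon rank-sum (legend label: signed-rank)",
               stringsAsFactors = FALSE)
  }))
}

#' Pearson correlation between two markers
#'
#' Pairwise-complete Pearson r, e.g. EZH2 H-score against the Ki67
#' proliferation index.
#'
#' @param tbl an `HScoreTable`.
#' @param x,y marker column names.
#' @return numeric Pearson r.
#' @export
marker_correlation <- function(tbl, x, y) {
  ok <- stats::complete.cases(tbl[[x]], tbl[[y]])
  if (sum(ok) < 3L) .fail("marker_correlation: need >= 3 complete pairs")
  a <- tbl[[x]][ok]; b <- tbl[[y]][ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    .fail("marker_correlation: constant vector; correlation undefined")
  }
  stats::cor(a, b)
}

#' Ischemic-time confound check
#'
#' Postmortem ischemic time can degrade some epitopes; this screens every
#' marker, within each histology stratum, for a Spearman rank association
#' between H-score and ischemic time, adjusting p-values by
#' Benjamini-Hochberg across all marker x stratum tests and flagging
#' adjusted p < `alpha`.
#'
#' @param tbl an `HScoreTable` with an `ischemic_time` column (hours).
#' @param markers marker subset (default: all marker columns).
#' @param alpha flagging threshold on the BH-adjusted p (default 0.05).
#' @return data.frame: `histology`, `marker`, `n`, `rho`, `p`, `p_adj`,
#'   `flagged`.
#' @export
ischemic_confound <- function(tbl, markers = hscore_markers(tbl), alpha = 0.05) {
  if (!"ischemic_time" %in% names(tbl)) {
    .fail("ischemic_confound: table has no 'ischemic_time' column")
  }
  strata <- unique(tbl$histology)
  rows <- list()
  for (h in strata) {
    sub <- tbl[tbl$histology == h, ]
    for (m in markers) {
      ok <- stats::complete.cases(sub[[m]], sub$ischemic_time)
      if (sum(ok) < 4L) next
      ct <- suppressWarnings(stats::cor.test(sub[[m]][ok], sub$ischemic_time[ok],
                                             method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        histology = h, marker = m, n = sum(ok),
        rho = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) .fail("ischemic_confound: no stratum has enough complete observations")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$p_adj < alpha
  out
}
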