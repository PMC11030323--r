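#' Specification for a synthetic single-cell dataset
#'
#' Describes the planted structure of a simulated cells x genes count matrix:
#' a number of GRN states, one planted TF regulon per state whose member
#' genes are up-shifted in that state's cells, a patient-composition dial
#' (`patient_specificity`) that emulates the contrast between patient-specific
#' castration-resistant / neuroendocrine states and patient-shared
#' castration-sensitive states, and Bernoulli dropout on top of a
#' negative-binomial baseline.
#'
#' @param n_cells,n_genes,n_patients,n_grn_states dataset dimensions.
#' @param regulon_size genes per planted regulon.
#' @param activity_effect mean natural-log expression shift applied to a
#'   regulon's genes in cells of its own state (2.0 is a strong, clearly
#'   recoverable program; 0 plants no signal).
#' @param dropout_rate probability in `[0,1]` that an observed count is
#'   zeroed (technical dropout).
#' @param patient_specificity probability in `[0,1]` that all of a state's
#'   cells come from a single patient; 0 mixes patients uniformly.
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); 0.5 by default — overdispersion is the minimal realism needed
#'   for rank-based scoring.
#' @param category single category label stamped on the cells (e.g.
#'   `"CSPC-like"`, `"CRPC-like"`).
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @return an object of class `"SyntheticSpec"`.
#' @export
synthetic_spec <- function(n_cells = 2000L, n_genes = 1000L, n_patients = 8L,
                           n_grn_states = 5L, regulon_size = 25L,
                           activity_effect = 2.0, dropout_rate = 0.3,
                           patient_specificity = 0, dispersion = 0.5,
                           category = "synthetic", seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
               n_patients = as.integer(n_patients),
               n_grn_states = as.integer(n_grn_states),
               regulon_size = as.integer(regulon_size),
               activity_effect = activity_effect, dropout_rate = dropout_rate,
               patient_specificity = patient_specificity,
               dispersion = dispersion, category = category,
               seed = as.integer(seed))
  with(spec, {
    if (n_grn_states > n_cells) .fail("synthetic_spec: more states than cells")
    if (dropout_rate < 0 || dropout_rate > 1) .fail("synthetic_spec: dropout_rate outside [0,1]")
    if (patient_specificity < 0 || patient_specificity > 1) {
      .fail("synthetic_spec: patient_specificity outside [0,1]")
    }
    if (dispersion <= 0) .fail("synthetic_spec: dispersion must be positive")
  })
  class(spec) <- "SyntheticSpec"
  spec
}

#' Simulate an expression matrix with planted GRN states
#'
#' Counts are drawn from a per-gene negative-binomial baseline (lognormal
#' mean profile). Each GRN state owns one disjoint regulon of
#' `regulon_size` genes whose means are multiplied by
#' `exp(activity_effect)` in that state's cells; Bernoulli dropout is then
#' applied. Patient labels are drawn per state according to
#' `patient_specificity`. The true cell-to-state map is returned for
#' parameter-recovery experiments.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `expr` (`ExpressionMatrix`, raw counts),
#'   `regulons` (`RegulonSet`, named `"TF01(25g)"` etc.) and `truth`
#'   (integer state per cell, named by cell ID).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (spec$regulon_size * spec$n_grn_states > spec$n_genes) {
    .fail("simulate_expression: regulon_size x n_grn_states exceeds n_genes (infeasible)")
  }
  set.seed(stage_seed(spec$seed, "simulate_expression"))
  n <- spec$n_cells; g <- spec$n_genes; S <- spec$n_grn_states
  m <- spec$regulon_size
  gene_ids <- sprintf("G%04d", seq_len(g))
  cell_ids <- sprintf("C%05d", seq_len(n))

  mu <- stats::rlnorm(g, meanlog = -0.3, sdlog = 1)   # skewed baseline means
  state <- sample(rep_len(seq_len(S), n))
  patient_pool <- sprintf("P%02d", seq_len(spec$n_patients))
  patient <- character(n)
  for (s in seq_len(S)) {
    idx <- which(state == s)
    if (stats::runif(1) < spec$patient_specificity) {
      patient[idx] <- sample(patient_pool, 1)
    } else {
      patient[idx] <- sample(patient_pool, length(idx), replace = TRUE)
    }
  }

  size <- 1 / spec$dispersion
  fold <- exp(spec$activity_effect)
  counts <- matrix(0L, n, g)
  for (s in seq_len(S)) {
    idx <- which(state == s)
    mu_s <- mu
    own <- ((s - 1) * m + 1):(s * m)
    mu_s[own] <- mu_s[own] * fold
    counts[idx, ] <- matrix(
      stats::rnbinom(length(idx) * g, mu = rep(mu_s, each = length(idx)), size = size),
      nrow = length(idx))
  }
  if (spec$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(n * g, 1L, 1 - spec$dropout_rate), n, g)
    counts <- counts * keep
  }

  regs <- stats::setNames(
    lapply(seq_len(S), function(s) gene_ids[((s - 1) * m + 1):(s * m)]),
    sprintf("TF%02d(%dg)", seq_len(S), m))
  meta <- data.frame(patient_id = patient, category = spec$category,
                     stringsAsFactors = FALSE)
  expr <- expression_matrix(Matrix::Matrix(counts, sparse = TRUE),
                            gene_ids, cell_ids, meta, normalized = FALSE)
  list(expr = expr,
       regulons = regulon_set(regs, provenance = "simulated planted regulons",
                              tf_in_regulon = FALSE),
       truth = stats::setNames(state, cell_ids))
}

#' Simulate a TMA H-score table with planted concordance
#'
#' Each marker pair is drawn from a bivariate normal whose population
#' concordance correlation equals the requested target: with equal means and
#' standard deviations, CCC = 2*rho*sx*sy / (sx^2 + sy^2 + (mx-my)^2)
#' reduces to rho, so rho is set to the target exactly. Values are then
#' rounded and clipped to the 0-200 H-score scale (a slight bias the
#' generator's contractual tolerance of +/-0.05 absorbs). Histology labels
#' are drawn independently and block structure is planted on dedicated
#' neuroendocrine / luminal marker columns (high NE means in NEPC samples,
#' high luminal means in PRAD/HGC).
#'
#' @param n_samples number of tumor samples (rows).
#' @param marker_pairs list of length-2 character vectors naming the paired
#'   marker columns.
#' @param ccc_targets numeric vector in `(-1, 1]`, one target per pair.
#' @param seed integer RNG seed.
#' @param ne_markers,lum_markers extra marker columns given
#'   histology-dependent means (NE high in NEPC; luminal high in PRAD/HGC).
#' @param hist_probs sampling probabilities for PRAD/HGC/NEPC labels.
#' @param pair_mean,pair_sd common location/scale of the paired bivariate
#'   normals (mid-scale defaults keep clipping negligible).
#' @param scales per-marker scale bounds passed to [hscore_table()].
#' @return an `HScoreTable` with `sample_id`, `patient_id`, `site`,
#'   `histology`, `ischemic_time` (hours) and the marker columns.
#' @export
simulate_hscores <- function(n_samples, marker_pairs, ccc_targets, seed = 1L,
                             ne_markers = character(0),
                             lum_markers = character(0),
                             hist_probs = c(PRAD = 0.4, HGC = 0.25, NEPC = 0.35),
                             pair_mean = 100, pair_sd = 35, scales = NULL) {
  if (length(marker_pairs) != length(ccc_targets)) {
    .fail("simulate_hscores: one ccc target per marker pair required")
  }
  if (any(ccc_targets <= -1 | ccc_targets > 1)) {
    .fail("simulate_hscores: ccc targets must lie in (-1, 1]")
  }
  set.seed(stage_seed(seed, "simulate_hscores"))
  hist <- sample(names(hist_probs), n_samples, replace = TRUE, prob = hist_probs)
  df <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    patient_id = sprintf("P%02d", sample.int(max(2L, ceiling(n_samples / 8)),
                                             n_samples, replace = TRUE)),
    site = sample(c("bone", "liver", "lymph_node", "prostate"), n_samples,
                  replace = TRUE),
    histology = hist,
    ischemic_time = round(stats::runif(n_samples, 1, 12), 1),
    stringsAsFactors = FALSE
  )
  clip200 <- function(x, hi = 200) pmin(hi, pmax(0, round(x)))
  for (i in seq_along(marker_pairs)) {
    pair <- marker_pairs[[i]]
    rho <- ccc_targets[i]
    z1 <- stats::rnorm(n_samples)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_samples)
    hi1 <- if (!is.null(scales) && pair[1] %in% names(scales)) scales[[pair[1]]] else 200
    hi2 <- if (!is.null(scales) && pair[2] %in% names(scales)) scales[[pair[2]]] else 200
    df[[pair[1]]] <- clip200(pair_mean * hi1 / 200 + pair_sd * hi1 / 200 * z1, hi1)
    df[[pair[2]]] <- clip200(pair_mean * hi2 / 200 + pair_sd * hi2 / 200 * z2, hi2)
  }
  for (mk in ne_markers) {
    mu <- ifelse(hist == "NEPC", 160, 15)
    df[[mk]] <- clip200(stats::rnorm(n_samples, mu, 20))
  }
  for (mk in lum_markers) {
    mu <- ifelse(hist == "NEPC", 15, 150)
    df[[mk]] <- clip200(stats::rnorm(n_samples, mu, 25))
  }
  hscore_table(df, scales = scales)
}
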