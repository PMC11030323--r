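#' Pipeline configuration
#'
#' Bundles the tunable parameters shared across stages. Defaults follow the
#' conventions of the underlying methods: a 5% recovery window for the
#' rank-AUC activity score, 100 cells x 100 replicates for subsampled
#' entropy with a k = 30 nearest-neighbor graph for phenograph-style
#' clustering, MAGIC diffusion at k = 20 / t = 1, and differential-expression
#' thresholds log2FC > 0.4 with BH-adjusted p < 0.05.
#'
#' @param auc_threshold_frac fraction of the ranked genome defining the AUC
#'   recovery window (in (0,1)).
#' @param entropy_subsample_n cells drawn (with replacement) per cluster and
#'   replicate for Shannon-entropy subsampling.
#' @param entropy_reps number of subsampling replicates per cluster.
#' @param cluster_k nearest-neighbor count for graph-based cell clustering.
#' @param magic_k nearest-neighbor count for the diffusion kernel.
#' @param magic_t diffusion time (number of Markov-matrix powers); t = 0
#'   leaves expression untouched.
#' @param de_log2fc_min strict lower bound on log2 fold change when
#'   thresholding differentially expressed genes.
#' @param de_padj_max upper bound on BH-adjusted p when thresholding.
#' @param rng_seed global seed expanded into per-stage substreams via
#'   [stage_seed()].
#' @param zscore_clip symmetric clip applied to scaled regulon activity.
#' @param linkage agglomeration rule for hierarchical clustering of cells:
#'   `"ward"`, `"average"` or `"complete"`.
#' @param n_boot bootstrap replicates for dendrogram-cut stability and
#'   robustness analyses.
#' @param max_k largest candidate number of GRN states examined by
#'   [select_cut()].
#' @return an object of class `"PipelineConfig"` (a validated named list).
#' @export
pipeline_config <- function(auc_threshold_frac = 0.05,
                            entropy_subsample_n = 100L,
                            entropy_reps = 100L,
                            cluster_k = 30L,
                            magic_k = 20L,
                            magic_t = 1L,
                            de_log2fc_min = 0.4,
                            de_padj_max = 0.05,
                            rng_seed = 1L,
                            zscore_clip = 2,
                            linkage = c("ward", "average", "complete"),
                            n_boot = 20L,
                            max_k = 15L) {
  linkage <- match.arg(linkage)
  cfg <- list(
    auc_threshold_frac = auc_threshold_frac,
    entropy_subsample_n = as.integer(entropy_subsample_n),
    entropy_reps = as.integer(entropy_reps),
    cluster_k = as.integer(cluster_k),
    magic_k = as.integer(magic_k),
    magic_t = as.integer(magic_t),
    de_log2fc_min = de_log2fc_min,
    de_padj_max = de_padj_max,
    rng_seed = as.integer(rng_seed),
    zscore_clip = zscore_clip,
    linkage = linkage,
    n_boot = as.integer(n_boot),
    max_k = as.integer(max_k)
  )
  class(cfg) <- "PipelineConfig"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  frac <- c("auc_threshold_frac", "de_padj_max")
  for (f in frac) {
    if (!.num1(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      .fail("pipeline_config: '%s' must be in (0, 1)", f)
    }
  }
  pos <- c("entropy_subsample_n", "entropy_reps", "cluster_k", "magic_k",
           "de_log2fc_min", "zscore_clip", "max_k")
  for (f in pos) {
    if (!.num1(cfg[[f]]) || cfg[[f]] <= 0) .fail("pipeline_config: '%s' must be positive", f)
  }
  if (!.num1(cfg$magic_t) || cfg$magic_t < 0) .fail("pipeline_config: 'magic_t' must be >= 0")
  if (!.num1(cfg$n_boot) || cfg$n_boot < 0) .fail("pipeline_config: 'n_boot' must be >= 0")
  invisible(cfg)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown fields raise an error (to catch typos); missing fields fall back
#' to the [pipeline_config()] defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a `PipelineConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .fail("read_config: file not found: %s", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) {
    .fail("read_config: unknown field(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}
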