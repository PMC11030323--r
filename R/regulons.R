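#' Construct a regulon set
#'
#' A regulon is a transcription factor plus its target-gene set; activity is
#' scored per cell by [score_regulons()]. Names follow the `"TF(Ng)"`
#' convention in which the parenthesized count records the regulon size,
#' e.g. `"AR(12g)"`.
#'
#' @param regulons named list of character gene vectors; duplicate genes
#'   within a regulon are dropped with a warning.
#' @param provenance free-text description of where the regulons came from
#'   (e.g. a SCENIC run identifier). Regulon inference itself is out of scope
#'   here; regulons are inputs.
#' @param tf_in_regulon logical; whether the TF itself is recorded as a
#'   member of its own gene set.
#' @return an object of class `"RegulonSet"`.
#' @export
regulon_set <- function(regulons, provenance = "unspecified",
                        tf_in_regulon = NA) {
  if (!is.list(regulons) || is.null(names(regulons)) ||
      any(!nzchar(names(regulons)))) {
    .fail("regulon_set: regulons must be a fully named list")
  }
  if (anyDuplicated(names(regulons))) .fail("regulon_set: duplicate regulon names")
  nm <- names(regulons)
  regulons <- lapply(seq_along(regulons), function(i) {
    g <- trimws(as.character(regulons[[i]]))
    g <- g[nzchar(g)]
    if (!length(g)) .fail("regulon_set: regulon '%s' has an empty gene list", nm[i])
    if (anyDuplicated(g)) {
      warning(sprintf("regulon '%s': dropping %d duplicate gene(s)",
                      nm[i], sum(duplicated(g))))
      g <- unique(g)
    }
    g
  })
  names(regulons) <- nm
  structure(list(regulons = regulons, provenance = provenance,
                 tf_in_regulon = tf_in_regulon),
            class = "RegulonSet")
}

#' @export
print.RegulonSet <- function(x, ...) {
  sizes <- lengths(x$regulons)
  cat(sprintf("RegulonSet: %d regulons (gene-set sizes %d-%d)\n",
              length(sizes), min(sizes), max(sizes)))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' @export
length.RegulonSet <- function(x) length(x$regulons)

#' Read regulons from a GMT file
#'
#' One regulon per line: name, description, then the gene members,
#' tab-separated. Lines with fewer than three fields are an error.
#'
#' @param gmt_path path to a GMT file.
#' @param provenance free text recorded on the returned set (default: the
#'   file name).
#' @return a `RegulonSet`.
#' @export
read_regulons <- function(gmt_path, provenance = basename(gmt_path)) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .fail("read_regulons: %s is empty", gmt_path)
  regs <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      .fail("read_regulons: line %d of %s has %d field(s); need name, description, >=1 gene",
            i, gmt_path, length(fields))
    }
    regs[[fields[1]]] <- fields[-(1:2)]
  }
  regulon_set(regs, provenance = provenance)
}

#' Write regulons to a GMT file
#'
#' @param regs a `RegulonSet`.
#' @param gmt_path output path.
#' @return invisibly, `gmt_path`.
#' @export
write_regulons <- function(regs, gmt_path) {
  stopifnot(inherits(regs, "RegulonSet"))
  lines <- vapply(names(regs$regulons), function(nm) {
    paste(c(nm, regs$provenance, regs$regulons[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, gmt_path)
  invisible(gmt_path)
}
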