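#' Construct a validated H-score table
#'
#' Tissue-microarray immunohistochemistry scores: one row per tumor sample,
#' one column per marker on the 0-200 H-score scale (intensity x extent),
#' except proliferation indices such as Ki67 which run 0-100. Missing stains
#' are encoded `NA` and excluded pairwise downstream.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `site`,
#'   `histology` (one of PRAD, HGC, NEPC), optional `ischemic_time` (hours),
#'   and one numeric column per marker.
#' @param scales optional named numeric vector giving the upper bound of each
#'   marker's scale; markers not named default to 200. Ki67-style indices
#'   should be declared 100.
#' @return an object of class `"HScoreTable"` (the validated data.frame with
#'   a `marker_scales` attribute).
#' @export
hscore_table <- function(df, scales = NULL) {
  req <- c("sample_id", "patient_id", "site", "histology")
  miss <- setdiff(req, names(df))
  if (length(miss)) .fail("hscore_table: missing required column(s): %s",
                          paste(miss, collapse = ", "))
  allowed_hist <- c("PRAD", "HGC", "NEPC")
  bad <- setdiff(unique(df$histology), allowed_hist)
  if (length(bad)) {
    .fail("hscore_table: unknown histology label(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(allowed_hist, collapse = ", "))
  }
  markers <- setdiff(names(df), c(req, "ischemic_time"))
  markers <- markers[vapply(df[markers], is.numeric, logical(1))]
  sc <- stats::setNames(rep(200, length(markers)), markers)
  if (!is.null(scales)) sc[names(scales)[names(scales) %in% markers]] <-
      scales[names(scales) %in% markers]
  for (m in markers) {
    v <- df[[m]]
    out <- which(!is.na(v) & (v < 0 | v > sc[[m]]))
    if (length(out)) {
      .fail("hscore_table: marker '%s' out of [0, %g] in row(s) %s",
            m, sc[[m]], paste(out, collapse = ", "))
    }
  }
  structure(df, class = c("HScoreTable", "data.frame"),
            marker_scales = sc, markers = markers)
}

#' Marker names of an H-score table
#' @param tbl an `HScoreTable`.
#' @return character vector of marker column names.
#' @export
hscore_markers <- function(tbl) attr(tbl, "markers")

#' Read an H-score table from CSV
#'
#' @param csv_path CSV with the columns described in [hscore_table()];
#'   missing stains encoded as `NA` or empty fields.
#' @param scales passed through to [hscore_table()].
#' @return an `HScoreTable`.
#' @export
read_hscores <- function(csv_path, scales = NULL) {
  df <- utils::read.csv(csv_path, check.names = FALSE, stringsAsFactors = FALSE)
  hscore_table(df, scales = scales)
}

#' Write an H-score table to CSV
#' @param tbl an `HScoreTable`.
#' @param csv_path output path.
#' @return invisibly, `csv_path`.
#' @export
write_hscores <- function(tbl, csv_path) {
  utils::write.csv(as.data.frame(tbl), csv_path, row.names = FALSE)
  invisible(csv_path)
}

#' Composite H-score over a marker panel
#'
#' Row-wise mean of the available (non-missing) scores over `markers`;
#' used e.g. for a neuroendocrine-TF composite compared against DLL3.
#'
#' @param tbl an `HScoreTable`.
#' @param markers character vector of marker columns to average.
#' @return numeric vector, `NA` where no member marker was scored.
#' @export
composite_hscore <- function(tbl, markers) {
  miss <- setdiff(markers, names(tbl))
  if (length(miss)) .fail("composite_hscore: marker(s) not in table: %s",
                          paste(miss, collapse = ", "))
  res <- rowMeans(as.data.frame(tbl)[markers], na.rm = TRUE)
  res[is.nan(res)] <- NA_real_
  res
}
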