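#' Binary label from an MMSE score
#'
#' The Mini-Mental State Examination (MMSE, 0--30) drives labeling: scores
#' of 23 or lower mark cognitive decline (label 1, CD); 24 or higher mark
#' cognitively normal (label 0, CN).
#'
#' @param mmse Integer MMSE score(s) in 0--30.
#' @return Integer vector of 0/1 labels.
#' @examples
#' label_from_mmse(c(23, 24))  # 1 0
#' @export
label_from_mmse <- function(mmse) {
  if (!is.numeric(mmse) || anyNA(mmse) || any(mmse != round(mmse)))
    stopf("label_from_mmse: MMSE scores must be integers")
  if (any(mmse < 0 | mmse > 30))
    stopf("label_from_mmse: MMSE scores must lie in 0..30")
  as.integer(mmse <= 23)
}

#' Load a subject manifest
#'
#' Reads a CSV manifest mapping clips to MMSE scores. Required columns:
#' `subject_id`, `wav_path`, `mmse`; optional: `diagnosis`, `age`, `sex`,
#' `education_years`, `cdr`, `label`. Labels are always recomputed from the
#' MMSE column via [label_from_mmse]; a stored `label` column is only
#' cross-checked and any inconsistency is an error.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return A data frame of subject records with a derived `label` column.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stopf("load_manifest: file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("load_manifest: empty manifest: %s", path)
  need <- c("subject_id", "wav_path", "mmse")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("load_manifest: missing column(s): %s", paste(miss, collapse = ", "))
  bad <- which(is.na(df$mmse))
  if (length(bad))
    stopf("load_manifest: missing MMSE in row(s) %s", paste(bad, collapse = ", "))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stopf("load_manifest: duplicate subject_id(s): %s", paste(unique(dup), collapse = ", "))
  derived <- label_from_mmse(df$mmse)
  if ("label" %in% names(df)) {
    off <- which(as.integer(df$label) != derived)
    if (length(off))
      stopf("load_manifest: stored label disagrees with the MMSE rule in row(s) %s",
            paste(off, collapse = ", "))
  }
  df$label <- derived
  df
}
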