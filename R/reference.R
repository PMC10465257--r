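#' Published per-rater results of the emulated clinical study
#'
#' Reference table transcribed from the published five-rater, two-round
#' clinical IRF annotation study whose design the synthetic module
#' emulates: per clinician and round, the reported DSC, TNR, TPR,
#' precision and number of annotated fluid areas, measured against the
#' two-expert majority-vote ground truth. Shipped for bookkeeping checks
#' and for qualitative comparison with synthetic studies; the underlying
#' clinical images are not distributed, so these rows cannot be recomputed
#' here.
#'
#' @return Data.frame with columns `rater_id`, `tier`, `round_id`, `dsc`,
#'   `tnr`, `tpr`, `precision`, `n_areas`.
#' @export
published_annotation_tables <- function() {
  path <- system.file("extdata", "published_annotation_tables.csv",
                      package = "annotqc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Total annotated areas across the published tables
#'
#' Sums the "number of annotated areas" column over every clinician and
#' round of the published reference table — the study-level bookkeeping
#' total (every annotated fluid area across all raters and rounds counted
#' once).
#'
#' @return Integer total.
#' @export
annotated_area_total <- function() {
  sum(published_annotation_tables()$n_areas)
}
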