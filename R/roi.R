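#' Canonical analyzed brain measures
#'
#' The nine measures analyzed by the pipeline: eight mean ((left+right)/2)
#' structure volumes — lateral ventricles, thalamus, caudate, putamen,
#' pallidum, hippocampus, amygdala, nucleus accumbens — plus total
#' intracranial volume (ICV). ICV is both a nuisance covariate for the other
#' eight and itself the ninth outcome (analyzed without the ICV covariate).
#' The order is fixed and is used for all result tables.
#'
#' @param include_icv Logical; include `"icv"` as the ninth measure
#'   (default `TRUE`).
#' @return Character vector of measure names in canonical order.
#' @examples
#' roi_names()
#' roi_names(include_icv = FALSE)
#' @export
roi_names <- function(include_icv = TRUE) {
  rois <- c(
    "lateral_ventricles", "thalamus", "caudate", "putamen", "pallidum",
    "hippocampus", "amygdala", "accumbens", "icv"
  )
  if (include_icv) rois else rois[rois != "icv"]
}

# columns every subject table must carry
required_subject_cols <- function() {
  c("subject_id", "site_id", "diagnosis", "age", "sex", "icv")
}

optional_subject_cols <- function() {
  c(
    roi_names(include_icv = FALSE), "scanner_id", "episode_status",
    "age_of_onset", "hdrs17", "bdi_ii", "on_antidepressant",
    "on_antipsychotic", "remitted"
  )
}

canonical_subject_cols <- function() {
  c(
    "subject_id", "site_id", "diagnosis", "age", "sex", "icv",
    roi_names(include_icv = FALSE), "scanner_id", "episode_status",
    "age_of_onset", "hdrs17", "bdi_ii", "on_antidepressant",
    "on_antipsychotic", "remitted"
  )
}

site_moderator_names <- function() {
  c(
    "mean_age", "pct_antidepressant", "pct_antipsychotic", "pct_acute",
    "pct_comorbid_anxiety", "pct_remitted", "pct_recurrent"
  )
}
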