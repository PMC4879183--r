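#' Read and validate a per-site subject table
#'
#' Reads a comma-separated, UTF-8, "."-decimal subject table (header
#' required) and validates it against the subject schema: `subject_id`,
#' `site_id`, `diagnosis` (0 = control, 1 = patient), `age` (years), `sex`,
#' `icv` (mm^3), any subset of the eight structure volume columns (mm^3,
#' mean of left and right), and optional `scanner_id`, `episode_status`
#' (`first`/`recurrent`), `age_of_onset`, `hdrs17` (0-52), `bdi_ii` (0-63),
#' `on_antidepressant`, `on_antipsychotic`, `remitted`.
#'
#' Rows violating a row-level invariant (non-positive age/volume, diagnosis
#' outside \{0, 1\}, `age_of_onset > age`, a control carrying clinical
#' fields, severity score out of range) are rejected with a row-level
#' diagnostic, collected in `attr(x, "rejected")`, and summarized in one
#' warning; validation is total — no silent drops. A missing required
#' column, a non-numeric value in a numeric column, duplicate `subject_id`
#' within the site, or multiple `site_id` values are errors.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(icv = "IntraCranialVol", hippocampus = "Hippo_mean")`. Unmapped
#'   canonical names are looked up verbatim.
#' @param sex_levels Length-2 character vector giving the file's codes for
#'   (reference = 0, other = 1). The default accepts `0/1`, `F/M` and
#'   `female/male`, with female as the reference level 0. The coding is
#'   symmetric for the diagnosis-by-sex interaction; the chosen reference is
#'   recorded in `attr(x, "sex_reference")`.
#' @return A tibble of validated subjects in canonical column order, with
#'   attributes `rejected` (tibble: `row`, `subject_id`, `reason`) and
#'   `sex_reference`.
#' @seealso [write_site_table()], [read_site_metadata()]
#' @export
read_site_table <- function(path, schema = NULL, sex_levels = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "sitemeta_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  validate_subjects(rename_by_schema(raw, schema), sex_levels = sex_levels)
}

rename_by_schema <- function(raw, schema) {
  if (is.null(schema)) return(raw)
  schema <- unlist(schema)
  bad <- setdiff(names(schema), canonical_subject_cols())
  if (length(bad) > 0) {
    abort(paste0("unknown schema field(s): ", paste(bad, collapse = ", ")),
      class = "sitemeta_schema_error"
    )
  }
  missing_src <- setdiff(unname(schema), names(raw))
  if (length(missing_src) > 0) {
    abort(
      paste0(
        "schema maps to column(s) absent from file: ",
        paste(missing_src, collapse = ", ")
      ),
      class = "sitemeta_schema_error"
    )
  }
  dplyr::rename(raw, !!!setNames(unname(schema), names(schema)))
}

# parse a character column as numeric; non-numeric cells are hard errors
# carrying the offending row index
parse_numeric_col <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    abort(
      paste0(
        "non-numeric value ", encodeString(x[bad[1]], quote = "\""),
        " in column '", col, "' at row ", bad[1]
      ),
      class = "sitemeta_parse_error", row = bad[1], column = col
    )
  }
  out[!is.na(x) & x == ""] <- NA_real_
  out
}

decode_sex <- function(x, sex_levels) {
  if (is.null(sex_levels)) {
    vals <- sort(unique(tolower(x[!is.na(x) & x != ""])))
    known <- list(
      c("0", "1"), c("f", "m"), c("female", "male"), c("m"), c("f"),
      c("0"), c("1"), c("female"), c("male")
    )
    if (!any(vapply(known, identical, logical(1), vals)) &&
      !all(vals %in% c("0", "1", "f", "m", "female", "male"))) {
      abort(
        paste0("unrecognized sex coding: ", paste(vals, collapse = ", ")),
        class = "sitemeta_schema_error"
      )
    }
    ref <- "female"
    out <- dplyr::case_match(
      tolower(x),
      c("0", "f", "female") ~ 0, c("1", "m", "male") ~ 1, .default = NA
    )
  } else {
    stopifnot(length(sex_levels) == 2)
    ref <- sex_levels[1]
    out <- dplyr::case_match(x, sex_levels[1] ~ 0, sex_levels[2] ~ 1,
      .default = NA
    )
  }
  list(sex = out, reference = ref)
}

validate_subjects <- function(raw, sex_levels = NULL) {
  missing_req <- setdiff(required_subject_cols(), names(raw))
  if (length(missing_req) > 0) {
    abort(
      paste0(
        "missing required column(s): ", paste(missing_req, collapse = ", ")
      ),
      class = "sitemeta_schema_error"
    )
  }
  keep <- intersect(canonical_subject_cols(), names(raw))
  raw <- raw[keep]

  num_cols <- intersect(
    c(
      "diagnosis", "age", "sex", "icv", roi_names(include_icv = FALSE),
      "age_of_onset", "hdrs17", "bdi_ii", "on_antidepressant",
      "on_antipsychotic", "remitted"
    ),
    names(raw)
  )
  sexdec <- NULL
  x <- raw
  for (col in num_cols) {
    if (col == "sex" && is.character(x[[col]])) {
      sexdec <- decode_sex(x[[col]], sex_levels)
      x[[col]] <- sexdec$sex
    } else if (is.character(x[[col]])) {
      x[[col]] <- parse_numeric_col(x[[col]], col)
    }
  }
  if (is.null(sexdec)) sexdec <- list(reference = "coded 0")

  if (anyDuplicated(x$subject_id) > 0) {
    dup <- x$subject_id[duplicated(x$subject_id)][1]
    abort(paste0("duplicate subject_id within site: ", dup),
      class = "sitemeta_validation_error"
    )
  }
  sites <- unique(x$site_id[!is.na(x$site_id)])
  if (length(sites) > 1) {
    abort(
      paste0(
        "subject table mixes site_id values: ", paste(sites, collapse = ", ")
      ),
      class = "sitemeta_validation_error"
    )
  }

  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- flag(!(x$diagnosis %in% c(0, 1)), "diagnosis not in {0,1}")
  reason <- flag(!(x$sex %in% c(0, 1)), "sex not binary")
  reason <- flag(x$age <= 0 | is.na(x$age), "age not a positive number")
  reason <- flag(x$icv <= 0 | is.na(x$icv), "icv not a positive number")
  for (roi in intersect(roi_names(include_icv = FALSE), names(x))) {
    reason <- flag(x[[roi]] <= 0, paste0("non-positive volume: ", roi))
  }
  if ("age_of_onset" %in% names(x)) {
    reason <- flag(x$age_of_onset > x$age, "age_of_onset exceeds age")
    reason <- flag(
      x$diagnosis == 0 & !is.na(x$age_of_onset),
      "control with age_of_onset"
    )
  }
  if ("episode_status" %in% names(x)) {
    x$episode_status[x$episode_status == ""] <- NA_character_
    reason <- flag(
      !is.na(x$episode_status) & !(x$episode_status %in% c("first", "recurrent")),
      "episode_status not first/recurrent"
    )
    reason <- flag(
      x$diagnosis == 0 & !is.na(x$episode_status),
      "control with episode_status"
    )
  }
  if ("hdrs17" %in% names(x)) {
    reason <- flag(x$hdrs17 < 0 | x$hdrs17 > 52, "hdrs17 outside 0-52")
  }
  if ("bdi_ii" %in% names(x)) {
    reason <- flag(x$bdi_ii < 0 | x$bdi_ii > 63, "bdi_ii outside 0-63")
  }

  bad <- which(!is.na(reason))
  rejected <- tibble::tibble(
    row = bad, subject_id = x$subject_id[bad], reason = reason[bad]
  )
  if (length(bad) > 0) {
    warn(
      paste0(
        length(bad), " row(s) rejected during validation: ",
        paste(
          head(paste0("row ", bad, " (", reason[bad], ")"), 5),
          collapse = "; "
        ),
        if (length(bad) > 5) "; ..." else ""
      ),
      class = "sitemeta_validation_warning"
    )
    x <- x[-bad, ]
  }
  out <- tibble::as_tibble(x)
  attr(out, "rejected") <- rejected
  attr(out, "sex_reference") <- sexdec$reference
  out
}

#' Write a subject table to CSV
#'
#' Writes the canonical comma-separated representation read back by
#' [read_site_table()]; `write_site_table()` then `read_site_table()` is the
#' identity on valid tables up to column order and float formatting.
#'
#' @param subjects Subject tibble (as from [read_site_table()] or
#'   [simulate_consortium()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(subjects, path) {
  stopifnot(is.data.frame(subjects))
  keep <- intersect(canonical_subject_cols(), names(subjects))
  readr::write_csv(subjects[keep], path, progress = FALSE)
  invisible(path)
}

#' Read or write a site metadata table
#'
#' One row per site: `site_id`, `field_strength` (tesla),
#' `software_version` (segmentation software, categorical), and the
#' site-level moderators `mean_age`, `pct_antidepressant`,
#' `pct_antipsychotic`, `pct_acute`, `pct_comorbid_anxiety`, `pct_remitted`,
#' `pct_recurrent` (percentages in `[0, 100]`).
#'
#' @param path CSV path.
#' @return `read_site_metadata()` returns a tibble; `write_site_metadata()`
#'   returns `path` invisibly.
#' @export
read_site_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "sitemeta_io_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"site_id" %in% names(x)) {
    abort("missing required column(s): site_id",
      class = "sitemeta_schema_error"
    )
  }
  pct <- intersect(grep("^pct_", names(x), value = TRUE), names(x))
  for (col in pct) {
    bad <- which(x[[col]] < 0 | x[[col]] > 100)
    if (length(bad) > 0) {
      abort(
        paste0(col, " outside [0,100] at row ", bad[1]),
        class = "sitemeta_validation_error"
      )
    }
  }
  x
}

#' @rdname read_site_metadata
#' @param sites Site metadata tibble.
#' @export
write_site_metadata <- function(sites, path) {
  readr::write_csv(sites, path, progress = FALSE)
  invisible(path)
}

#' Write pooled results in the standard report layout
#'
#' Emits a tab-separated table with columns exactly `roi`, `cohens_d`, `se`,
#' `ci_low`, `ci_high`, `pct_difference`, `p_value`, `i2`, `n_controls`,
#' `n_patients`, `k_sites`, one row per measure in canonical order — the
#' layout of a consortium case-control results table. A JSON variant with
#' identical fields is written by `write_results_json()`.
#'
#' @param results Result tibble from [run_primary()] or [run_stratified()]
#'   (d-metric contrasts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  out <- results_report_columns(results)
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) {
      abort(paste0("failed to write results to ", path, ": ",
        conditionMessage(e)), class = "sitemeta_io_error", parent = e)
    }
  )
  invisible(path)
}

#' @rdname write_results_table
#' @export
write_results_json <- function(results, path) {
  out <- results_report_columns(results)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

results_report_columns <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("results must be a non-empty result table",
      class = "sitemeta_validation_error"
    )
  }
  need <- c(
    "roi", "cohens_d", "se", "ci_low", "ci_high", "pct_difference",
    "p_value", "i2", "n_controls", "n_patients", "k_sites"
  )
  missing <- setdiff(need, names(results))
  if (length(missing) > 0) {
    abort(
      paste0(
        "results table lacks column(s): ", paste(missing, collapse = ", ")
      ),
      class = "sitemeta_validation_error"
    )
  }
  ord <- order(match(results$roi, roi_names()))
  results[ord, need]
}
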