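#' Deterministic edge-case site fixtures
#'
#' Small, fully deterministic single-site subject tables for exercising
#' edge-case code paths: `"tiny_site"` (6 subjects; minimal residual df),
#' `"single_sex_site"` (8 subjects, one sex; trips the interaction
#' contrast's precondition), `"two_scanner_site"` (16 subjects on two
#' scanners; exercises scanner dummy coding) and `"missing_severity_site"`
#' (patients without severity scores; trips the severity precondition).
#' Values are constructed arithmetically, not drawn, so fixtures are
#' byte-stable across calls.
#'
#' @param name Fixture name.
#' @return A single-site subject tibble carrying the `hippocampus`,
#'   `amygdala` and `lateral_ventricles` volume columns.
#' @examples
#' make_fixture("tiny_site")
#' @export
make_fixture <- function(name = c(
                           "tiny_site", "single_sex_site",
                           "two_scanner_site", "missing_severity_site"
                         )) {
  if (!is.character(name) || length(name) != 1 ||
    !name %in% eval(formals(make_fixture)$name)) {
    abort(paste0("unknown fixture: ", paste(name, collapse = ", ")),
      class = "sitemeta_lookup_error"
    )
  }
  base <- function(n, site_id, sex, scanner = "scannerA") {
    i <- seq_len(n)
    dx <- rep_len(c(1L, 0L), n)
    tibble::tibble(
      subject_id = sprintf("%s_%02d", site_id, i),
      site_id = site_id,
      diagnosis = dx,
      age = 30 + 3 * i,
      sex = sex,
      # the irregular wiggle keeps icv outside the span of the other columns
      icv = 1.4e6 + 1.7e4 * i + 5e4 * sex + 7.3e3 *
        rep_len(c(2, -3, 1, 4, -1, -2, 3, 0, -4, 2, 1, -1, 0, 3, -2, 4), n),
      # deterministic wiggle: covariate trends plus a small case deficit
      hippocampus = 4100 - 5 * i + 40 * sex + 0.002 * (1.4e6 + 1.7e4 * i) -
        60 * dx + 23 * ((i * 7) %% 5 - 2),
      amygdala = 1600 - 2 * i + 20 * sex - 10 * dx + 9 * ((i * 3) %% 5 - 2),
      lateral_ventricles = 7000 + 90 * i - 50 * sex + 150 * dx +
        180 * ((i * 11) %% 7 - 3),
      scanner_id = scanner,
      episode_status = ifelse(dx == 1,
        rep_len(c("recurrent", "first"), n), NA_character_
      ),
      age_of_onset = ifelse(dx == 1, 15 + 2 * i, NA_real_),
      hdrs17 = ifelse(dx == 1, 10 + (3 * i) %% 15, NA_real_),
      bdi_ii = ifelse(dx == 1, 12 + (5 * i) %% 20, NA_real_),
      on_antidepressant = ifelse(dx == 1, i %% 2, NA_real_),
      on_antipsychotic = ifelse(dx == 1, 0, NA_real_),
      remitted = ifelse(dx == 1, (i + 1) %% 2, NA_real_)
    )
  }
  # sex patterns run at period 4 and the scanner pattern at period 3 so
  # that neither aliases the alternating diagnosis indicator
  sex_pattern <- function(n) ((seq_len(n) %/% 2) %% 2)
  switch(name,
    tiny_site = base(6, "tiny", sex = sex_pattern(6)),
    single_sex_site = base(8, "onesex", sex = rep(0, 8)),
    two_scanner_site = base(16, "twoscan",
      sex = sex_pattern(16),
      scanner = rep_len(c("scannerA", "scannerA", "scannerB"), 16)
    ),
    missing_severity_site = {
      x <- base(10, "nosev", sex = sex_pattern(10))
      x$hdrs17 <- NA_real_
      x$bdi_ii <- NA_real_
      x
    }
  )
}
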