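# n-weighted pooling of published torsion means. Each study record is one
# reported subgroup mean (side, dominance, stability, ...) with the number
# of shoulders behind it; pooling combines them as if the raw samples had
# been concatenated: an n-weighted mean, and a pooled SD from the
# within-record and between-record sums of squares.

#' Packaged literature study records
#'
#' The bundled transcription of published humeral-retrotorsion summaries
#' by imaging modality: one row per reported subgroup mean with the study
#' label, modality (`ct`, `xray`, `ultrasound`), cohort (`living` or
#' `cadaveric`), shoulder count `n`, `mean_deg` and `sd_deg` (missing where
#' the source reported none). Only subgroups that enter the modality pools
#' are included.
#'
#' @return A tibble of study records.
#' @export
table1_studies <- function() {
  path <- system.file("extdata", "table1_studies.csv", package = "circlehta",
                      mustWork = TRUE)
  read_studies(path)
}

#' Read a study-records CSV
#'
#' @param path CSV with columns `study`, `modality`, `cohort`, `subgroup`,
#'   `n`, `mean_deg`, `sd_deg` (empty `sd_deg` allowed).
#' @return A tibble of study records.
#' @export
read_studies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study", "modality", "n", "mean_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_input(sprintf("studies CSV missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  if (!"sd_deg" %in% names(df)) df$sd_deg <- NA_real_
  if (!"cohort" %in% names(df)) df$cohort <- "living"
  if (any(!is.finite(df$n)) || any(df$n < 1) || any(df$n != round(df$n))) {
    abort_input("study n must be positive integers")
  }
  if (any(!is.finite(df$mean_deg))) abort_input("study means must be numeric")
  tibble::as_tibble(df)
}

#' Pool study records into a combined estimate
#'
#' n-weighted combination of reported subgroup means, equivalent to
#' concatenating raw samples that realise each record exactly:
#' \deqn{\bar m = \sum n_i m_i / N, \quad
#'   s^2 = \frac{\sum (n_i-1)s_i^2 + \sum n_i(m_i-\bar m)^2}{N-1}.}
#' The pooled SD is reported only when every pooled record carries one.
#'
#' @param records Study-record tibble (see [read_studies()]).
#' @param modality Optional filter on the `modality` column.
#' @param cohort Cohort(s) to keep; defaults to living shoulders only, so
#'   mixed living/cadaveric studies contribute their living subgroups.
#' @return One-row tibble: `modality`, `n_records`, `n_total`, `mean_deg`,
#'   `sd_deg` (`NA` when any record lacks an SD).
#' @export
#' @examples
#' pool_studies(table1_studies(), modality = "ultrasound")
pool_studies <- function(records, modality = NULL, cohort = "living") {
  if (!is.null(modality)) {
    records <- dplyr::filter(records, .data$modality %in% !!modality)
  }
  if (!is.null(cohort) && "cohort" %in% names(records)) {
    records <- dplyr::filter(records, .data$cohort %in% !!cohort)
  }
  if (nrow(records) == 0) abort_input("no study records to pool")
  n <- records$n
  m <- records$mean_deg
  s <- records$sd_deg
  N <- sum(n)
  mbar <- sum(n * m) / N
  sd_pooled <- if (anyNA(s) || N < 2) NA_real_ else {
    sqrt((sum((n - 1) * s^2) + sum(n * (m - mbar)^2)) / (N - 1))
  }
  tibble::tibble(
    modality = if (is.null(modality)) "all" else paste(modality, collapse = "+"),
    n_records = nrow(records), n_total = N,
    mean_deg = mbar, sd_deg = sd_pooled
  )
}
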