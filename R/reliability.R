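# Inter-rater reliability and group-comparison statistics: Cronbach's
# alpha as the intraclass correlation of k averaged raters (ICC(3,k)
# consistency) with Feldt's F confidence interval, t-tests, the 2x2
# chi-square, and per-group descriptive summaries.

#' Ratings matrix from long-format records
#'
#' Pivots a long ratings table (one row per case x rater) for one measured
#' quantity into the complete cases x raters matrix that [cronbach_alpha()]
#' requires.
#'
#' @param ratings Data frame with columns `case_id`, `rater_id`,
#'   `quantity`, `value_deg`.
#' @param quantity Which quantity to extract (e.g. `"hta_circle"`); `NULL`
#'   is allowed when the table holds a single quantity.
#' @return Numeric matrix, rows = cases, columns = raters.
#' @export
ratings_matrix <- function(ratings, quantity = NULL) {
  need <- c("case_id", "rater_id", "value_deg")
  if (!all(need %in% names(ratings))) {
    abort_input("ratings must have case_id, rater_id, value_deg columns")
  }
  if (!is.null(quantity)) {
    if (!"quantity" %in% names(ratings)) {
      abort_input("ratings has no quantity column")
    }
    ratings <- dplyr::filter(ratings, .data$quantity == !!quantity)
    if (nrow(ratings) == 0) abort_input("no rows for the requested quantity")
  }
  if (anyDuplicated(ratings[c("case_id", "rater_id")])) {
    abort_input("duplicated (case_id, rater_id) rating")
  }
  wide <- tidyr::pivot_wider(
    ratings[c("case_id", "rater_id", "value_deg")],
    names_from = "rater_id", values_from = "value_deg")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$case_id
  if (anyNA(m)) abort_input("ratings matrix has missing cells")
  m
}

#' Cronbach's alpha ICC with Feldt confidence interval
#'
#' Inter-rater agreement across k raters scoring n cases:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_{total}^2}\right)}
#' with \eqn{s_j^2} the sample variance of rater column j and
#' \eqn{s_{total}^2} the sample variance of the per-case sums. This equals
#' the consistency intraclass correlation of the k-rater average,
#' ICC(3,k). The 95% interval is Feldt's: \eqn{1-(1-\alpha)F} and
#' \eqn{1-(1-\alpha)/F} with F quantiles on (n-1, (n-1)(k-1)) degrees of
#' freedom.
#'
#' @param m Complete n x k numeric matrix (cases x raters), n, k >= 2, or a
#'   long ratings data frame (see [ratings_matrix()]).
#' @param conf_level Confidence level for the Feldt interval.
#' @param quantity Passed to [ratings_matrix()] when `m` is long-format.
#' @return One-row tibble: `alpha`, `ci_low`, `ci_high`, `n_cases`,
#'   `k_raters`, `conf_level`.
#' @export
#' @examples
#' m <- cbind(r1 = 1:4, r2 = 2:5, r3 = 3:6)
#' cronbach_alpha(m) # perfectly congeneric columns: alpha = 1
cronbach_alpha <- function(m, conf_level = 0.95, quantity = NULL) {
  if (is.data.frame(m) && "rater_id" %in% names(m)) {
    m <- ratings_matrix(m, quantity)
  }
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (anyNA(m)) abort_input("ratings matrix has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort_input("need at least 2 cases and 2 raters")
  s_tot <- stats::var(rowSums(m))
  if (s_tot <= 0) {
    abort_degenerate("total variance of case sums is zero: alpha undefined")
  }
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / s_tot)
  a2 <- (1 - conf_level) / 2
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  f_hi <- stats::qf(1 - a2, df1, df2)
  f_lo <- stats::qf(a2, df1, df2)
  tibble::tibble(
    alpha = alpha,
    ci_low = 1 - (1 - alpha) * f_hi,
    ci_high = 1 - (1 - alpha) * f_lo,
    n_cases = n, k_raters = k, conf_level = conf_level
  )
}

#' Two-sample or paired t-test, tidy output
#'
#' Continuous comparisons: the paired test is the one-sample t on the
#' within-case differences; the unpaired test defaults to Welch's unequal
#' variance form (`var_equal = TRUE` gives the pooled Student version).
#' Degenerate inputs with no variance anywhere raise a classed error rather
#' than a spurious statistic.
#'
#' @param x,y Numeric samples (equal length when `paired`).
#' @param paired Paired comparison?
#' @param var_equal Pooled-variance Student test instead of Welch.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `estimate`,
#'   `method`.
#' @export
hta_t_test <- function(x, y, paired = FALSE, var_equal = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (paired && length(x) != length(y)) {
    abort_input("paired test needs equal-length samples")
  }
  if (length(x) < 2 || length(y) < 2) abort_input("need n >= 2 per sample")
  if (paired) {
    if (stats::sd(x - y) == 0) {
      abort_degenerate("paired differences are constant: t undefined")
    }
  } else if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    abort_degenerate("both samples are constant: t undefined")
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = var_equal)
  tibble::tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    estimate = unname(if (paired) tt$estimate else diff(rev(tt$estimate))),
    method = if (paired) "paired t" else if (var_equal) "student t" else "welch t"
  )
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, 1 degree of freedom, two-sided p -- the form
#' used for categorical group comparisons such as gender by cohort.
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(10, 10, 22, 25), 2)) # gender x stability
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) abort_input("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_input("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort_input("chi-square undefined: a table margin is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Descriptive summary of one group of torsion values
#'
#' n, mean, min, max and the (n-1)-denominator SD, the columns of a
#' per-group results table. A single observation reports `sd = 0` with
#' `sd_defined = FALSE`. Values are kept at full precision; round only for
#' presentation.
#'
#' @param values Numeric sample, n >= 1.
#' @param label Group label.
#' @return One-row tibble.
#' @export
group_summary <- function(values, label = "all") {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    abort_input("values must be a non-empty numeric sample without NA")
  }
  n <- length(values)
  tibble::tibble(
    group = as.character(label), n = n,
    mean_deg = mean(values), min_deg = min(values), max_deg = max(values),
    sd_deg = if (n == 1) 0 else stats::sd(values),
    sd_defined = n > 1
  )
}

#' Table of group summaries from measurement results
#'
#' Splits a results table (e.g. from [measure_case()] rows bound together)
#' by method and a grouping column and summarises `hta_deg` per cell.
#'
#' @param results Data frame with `method`, `hta_deg` and the grouping
#'   column; rows with `NA` torsion are dropped.
#' @param by Name of the grouping column (e.g. `"group"` or `"hill_sachs"`).
#' @return Tibble of [group_summary()] rows with `method` and `by` columns.
#' @export
summarise_results <- function(results, by = "group") {
  if (!all(c("method", "hta_deg", by) %in% names(results))) {
    abort_input(sprintf("results must have method, hta_deg and '%s' columns", by))
  }
  results |>
    dplyr::filter(is.finite(.data$hta_deg)) |>
    dplyr::group_by(.data$method, dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      group_summary(d$hta_deg, label = paste(unlist(key), collapse = "/"))[-1]
    }) |>
    dplyr::ungroup()
}
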