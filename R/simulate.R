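# Monte Carlo method-comparison study: how do the Circle-method and the
# B&G method degrade as a Hill-Sachs defect grows? Each condition pairs a
# phantom geometry with an optional lesion; replicates draw fresh contour
# and rater noise, and per-method bias/SD/RMSE of (measured - true torsion)
# are tabulated.

#' Build a comparison condition
#'
#' @param spec A [phantom_spec()].
#' @param lesion A [lesion_spec()] or `NULL` for a lesion-free condition.
#' @param label Condition label for the results table.
#' @return A `comparison_condition` list.
#' @export
comparison_condition <- function(spec, lesion = NULL, label = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(label)) {
    label <- if (is.null(lesion)) "no lesion" else
      sprintf("lesion hw=%g depth=%g", lesion$halfwidth_deg, lesion$depth_mm)
  }
  structure(list(spec = spec, lesion = lesion, label = label),
            class = "comparison_condition")
}

#' Standard lesion half-width sweep
#'
#' The default comparison grid: one lesion-free condition plus lesions of
#' growing angular half-width centred on the posterior cartilage limit,
#' all at the same depth. Half-width 0 means no lesion.
#'
#' @param halfwidths_deg Numeric vector of lesion half-widths, degrees; 0
#'   entries become lesion-free conditions.
#' @param depth_mm Lesion depth, mm.
#' @param spec Phantom geometry shared by all conditions.
#' @return List of [comparison_condition()]s.
#' @export
lesion_sweep <- function(halfwidths_deg = c(0, 10, 20, 30), depth_mm = 3,
                         spec = phantom_spec()) {
  lapply(halfwidths_deg, function(hw) {
    comparison_condition(
      spec,
      lesion = if (hw > 0) lesion_spec(halfwidth_deg = hw, depth_mm = depth_mm),
      label = sprintf("hw=%g", hw)
    )
  })
}

#' Run the method-comparison simulation
#'
#' For each condition, generates `n_reps` phantom cases (fresh contour
#' noise), observes each through the rater model (landmark jitter and, when
#' a lesion covers the posterior cartilage limit, landmark relocation), and
#' measures both methods. Errors are `wrap_axis_angle(hta - theta_true)`;
#' replicates whose fit is degenerate are counted and excluded from the
#' moments. Everything is reproducible from `base_seed`.
#'
#' @param conditions List of [comparison_condition()]s (e.g. from
#'   [lesion_sweep()]).
#' @param rater A [rater_model()].
#' @param n_reps Replicates per condition (>= 1).
#' @param base_seed Integer master seed.
#' @param methods Methods to compare.
#' @param robust,inlier_threshold Circle-method fitting options.
#' @return Tibble with one row per condition x method: `condition`,
#'   `method`, `n_valid`, `n_degenerate`, `bias_deg`, `sd_deg`, `rmse_deg`,
#'   `sd_single_rep` (flags the degenerate SD = 0 report when `n_reps` is 1).
#' @export
run_comparison <- function(conditions, rater = rater_model(), n_reps = 100L,
                           base_seed = 1L, methods = c("circle", "bg"),
                           robust = TRUE, inlier_threshold = 1) {
  if (inherits(conditions, "comparison_condition")) conditions <- list(conditions)
  if (n_reps < 1) abort_input("n_reps must be >= 1")
  rows <- purrr::imap(conditions, function(cond, i) {
    errs <- purrr::map(seq_len(n_reps), function(j) {
      off <- ((i - 1L) * n_reps + (j - 1L)) * 2L
      ph <- generate_case(cond$spec, cond$lesion,
                          seed = derive_seed(base_seed, off + 1L))
      obs <- observe_case(ph, rater, seed = derive_seed(base_seed, off + 2L))
      res <- measure_case(obs, methods = methods, robust = robust,
                          inlier_threshold = inlier_threshold)
      dplyr::transmute(
        res, method = .data$method,
        err = wrap_axis_angle(.data$hta_deg - ph$truth$theta_true),
        failed = !is.na(.data$error))
    })
    errs <- dplyr::bind_rows(errs)
    errs |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(
        n_valid = sum(!.data$failed & is.finite(.data$err)),
        n_degenerate = sum(.data$failed | !is.finite(.data$err)),
        bias_deg = mean(.data$err[!.data$failed]),
        sd_deg = if (n_reps == 1L) 0 else stats::sd(.data$err[!.data$failed]),
        rmse_deg = sqrt(mean(.data$err[!.data$failed]^2)),
        .groups = "drop"
      ) |>
      dplyr::mutate(condition = cond$label, sd_single_rep = n_reps == 1L,
                    .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Plot a method-comparison table
#'
#' RMSE against condition, one line per method.
#'
#' @param sim Result of [run_comparison()].
#' @return A ggplot.
#' @export
plot_comparison <- function(sim) {
  sim <- dplyr::mutate(sim, condition = factor(.data$condition,
                                               levels = unique(.data$condition)))
  ggplot2::ggplot(sim, ggplot2::aes(x = .data$condition, y = .data$rmse_deg,
                                    colour = .data$method,
                                    group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "condition", y = "RMSE (deg)",
                  title = "Torsion error by method and lesion condition")
}
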