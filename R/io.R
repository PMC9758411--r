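# File formats. Everything is plain text: contour CSV (one row per
# digitised point) + companion case JSON (side/group/lesion flags), ratings
# CSV, results CSV. Coordinates are mm with pixel spacing already applied;
# angles are degrees throughout.

contour_structures <- c("head_margin", "tubercle_margin", "lesion")
landmark_structures <- c("cartilage_ant", "cartilage_post",
                         "epicondyle_medial", "epicondyle_lateral")

#' Read digitised cases from contour CSV + case JSON
#'
#' The CSV holds one row per digitised point with columns `case_id`,
#' `slice_role`, `structure`, `point_index`, `x_mm`, `y_mm`; structures are
#' the contours (`head_margin`, `tubercle_margin`) and single landmarks
#' (`cartilage_ant`, `cartilage_post`, `epicondyle_medial`,
#' `epicondyle_lateral`; epicondyles may repeat across serial sections).
#' The companion JSON carries per-case `side`, `group` and `hill_sachs`.
#' Missing landmarks leave the corresponding slot `NULL`, so a case can
#' still be measured by whichever method has its inputs.
#'
#' @param csv_path Contour CSV path.
#' @param json_path Case JSON path; defaults to `csv_path` with a `.json`
#'   extension. If the file does not exist, right/stable defaults are used.
#' @return Named list of [hta_case()] objects.
#' @export
read_contours <- function(csv_path, json_path = NULL) {
  if (!file.exists(csv_path)) rlang::abort(sprintf("no such file: %s", csv_path), class = "circlehta_error_runtime")
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("case_id", "slice_role", "structure", "point_index", "x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_input(sprintf("contour CSV missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_struct <- !(df$structure %in% c(contour_structures, landmark_structures))
  if (any(bad_struct)) {
    abort_input(sprintf("unknown structure '%s' at line %d",
                        df$structure[bad_struct][1], lines[bad_struct][1]))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      abort_input(sprintf("non-numeric %s at line %d", col,
                          lines[is.na(v)][1]))
    }
    v
  }
  df$point_index <- num("point_index")
  df$x_mm <- num("x_mm")
  df$y_mm <- num("y_mm")
  dup <- duplicated(df[c("case_id", "structure", "point_index")])
  if (any(dup)) {
    abort_input(sprintf("duplicated (case_id, structure, point_index) at line %d",
                        lines[dup][1]))
  }

  meta <- list()
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  if (file.exists(json_path)) {
    raw <- jsonlite::read_json(json_path)
    for (rec in raw) meta[[rec$case_id]] <- rec
  }

  build <- function(sub, id) {
    pick <- function(structure) {
      s <- sub[sub$structure == structure, , drop = FALSE]
      if (nrow(s) == 0) return(NULL)
      s <- s[order(s$point_index), , drop = FALSE]
      cbind(x = s$x_mm, y = s$y_mm)
    }
    single <- function(structure) {
      p <- pick(structure)
      if (is.null(p)) NULL else p[1, ]
    }
    info <- meta[[id]] %||% list()
    hta_case(
      case_id = id,
      side = info$side %||% "right",
      head_contour = pick("head_margin"),
      tubercle_contour = pick("tubercle_margin"),
      cartilage_ant = single("cartilage_ant"),
      cartilage_post = single("cartilage_post"),
      epicondyle_medial = pick("epicondyle_medial"),
      epicondyle_lateral = pick("epicondyle_lateral"),
      group = info$group %||% "stable",
      hill_sachs = isTRUE(info$hill_sachs)
    )
  }
  ids <- unique(df$case_id)
  stats::setNames(lapply(ids, function(id) {
    build(df[df$case_id == id, , drop = FALSE], id)
  }), ids)
}

#' Write cases to contour CSV + case JSON
#'
#' Inverse of [read_contours()]: every contour point and landmark becomes a
#' CSV row (0-based `point_index`, coordinates to 9 decimal places), and
#' side/group/lesion flags go to the JSON companion.
#'
#' @param cases List of [hta_case()] (or a single case).
#' @param csv_path,json_path Output paths; `json_path` defaults to
#'   `csv_path` with `.json`.
#' @return Invisibly, the CSV path.
#' @export
write_cases <- function(cases, csv_path, json_path = NULL) {
  if (inherits(cases, "hta_case")) cases <- list(cases)
  if (length(cases) == 0) abort_input("no cases to write")
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", csv_path)
  row_block <- function(case) {
    blocks <- list()
    add <- function(structure, m, role) {
      if (is.null(m)) return()
      m <- if (is.null(dim(m))) matrix(m, 1, 2) else as.matrix(m)
      blocks[[length(blocks) + 1L]] <<- data.frame(
        case_id = case$case_id, slice_role = role, structure = structure,
        point_index = seq_len(nrow(m)) - 1L,
        x_mm = m[, 1], y_mm = m[, 2])
    }
    add("head_margin", case$head_contour, "head")
    add("tubercle_margin", case$tubercle_contour, "head")
    add("cartilage_ant", case$cartilage_ant, "head")
    add("cartilage_post", case$cartilage_post, "head")
    add("epicondyle_medial", case$epicondyle_medial, "epicondyle")
    add("epicondyle_lateral", case$epicondyle_lateral, "epicondyle")
    do.call(rbind, blocks)
  }
  out <- do.call(rbind, lapply(cases, row_block))
  out$x_mm <- formatC(out$x_mm, digits = 9, format = "f")
  out$y_mm <- formatC(out$y_mm, digits = 9, format = "f")
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  meta <- lapply(cases, function(case) {
    list(case_id = case$case_id, side = case$side, group = case$group,
         hill_sachs = case$hill_sachs,
         orientation = "x_anterior_y_medial_right")
  })
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(csv_path)
}

#' Write a measurement-results table
#'
#' Stable column order, angles rendered at 6 decimal places, rows sorted by
#' (`case_id`, `method`, and `rater_id` when present) so identical runs
#' produce byte-identical files.
#'
#' @param results Non-empty data frame of results rows.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort_input("results must be a non-empty data frame")
  }
  keys <- intersect(c("case_id", "method", "rater_id"), names(results))
  results <- dplyr::arrange(results,
                            dplyr::across(dplyr::all_of(keys)))
  out <- as.data.frame(results)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && grepl("deg|_mm$", col)) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           formatC(out[[col]], digits = 6, format = "f"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path), class = "circlehta_error_runtime")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a long-format ratings CSV
#'
#' @param path CSV with columns `case_id`, `rater_id`, `quantity`,
#'   `value_deg`.
#' @return A tibble, ready for [ratings_matrix()] / [cronbach_alpha()].
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path), class = "circlehta_error_runtime")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "rater_id", "quantity", "value_deg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_input(sprintf("ratings CSV missing column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  if (!is.numeric(df$value_deg)) abort_input("value_deg must be numeric")
  tibble::as_tibble(df)
}

#' Session manifest for a measurement campaign
#'
#' Book-keeping for a multi-rater session: which cases, which raters, which
#' measured quantities, and the seeds behind any stochastic step.
#'
#' @param cases Character vector of case ids (or list of [hta_case()]).
#' @param raters Character vector of rater ids.
#' @param quantities Character vector of measured quantities, e.g.
#'   `c("bg_head_axis", "circle_head_axis", "epicondylar")`.
#' @param seeds Optional named list recording seeds.
#' @return A `session_manifest` object.
#' @export
session_manifest <- function(cases, raters,
                             quantities = c("bg_head_axis",
                                            "circle_head_axis",
                                            "epicondylar"),
                             seeds = list()) {
  if (is.list(cases)) {
    cases <- vapply(cases, function(x) x$case_id, character(1))
  }
  structure(list(cases = as.character(cases), raters = as.character(raters),
                 quantities = as.character(quantities), seeds = seeds,
                 tool_version = as.character(utils::packageVersion("circlehta"))),
            class = "session_manifest")
}

#' Count the records a session produces
#'
#' Every rater measures every quantity on every case, so the total is
#' `n_cases * n_raters * n_quantities`.
#'
#' @param manifest A [session_manifest()].
#' @return List with `n_cases`, `n_raters`, `n_quantities`, `total`, and a
#'   `per_quantity` tibble.
#' @export
#' @examples
#' m <- session_manifest(sprintf("c%02d", 1:67), c("r1", "r2", "r3"))
#' session_count(m)$total # 603
session_count <- function(manifest) {
  stopifnot(inherits(manifest, "session_manifest"))
  nc <- length(manifest$cases)
  nr <- length(manifest$raters)
  nq <- length(manifest$quantities)
  list(
    n_cases = nc, n_raters = nr, n_quantities = nq,
    total = nc * nr * nq,
    per_quantity = tibble::tibble(quantity = manifest$quantities,
                                  n_records = nc * nr)
  )
}
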