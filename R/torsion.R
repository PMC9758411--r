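# The two humeral-head-axis constructions and the humeral torsion angle
# (HTA). The Circle-method takes the line through the centres of circles
# fitted to the head margin and the greater-tubercle margin; the
# Bernageau-Godefroy (B&G) method takes the perpendicular to the chord
# joining the anterior and posterior cartilage limits. The HTA is the signed
# angle between the head axis and the transepicondylar axis, positive =
# retrotorsion; left shoulders are sign-normalised onto the right-side
# convention.

#' Assemble the per-case measurement inputs
#'
#' Bundles the digitised structures of one axial humeral-head section plus
#' the distal transepicondylar landmarks. Coordinates are in mm with pixel
#' spacing already applied; any landmark or contour a method needs may be
#' `NULL`, in which case [measure_case()] records a per-method error instead
#' of failing.
#'
#' @param case_id Case identifier (character).
#' @param side `"right"` or `"left"`.
#' @param head_contour,tubercle_contour Data frames of contour points
#'   (`x`, `y` in mm) along the humeral-head margin and the greater-tubercle
#'   margin.
#' @param cartilage_ant,cartilage_post Anterior / posterior limit of the
#'   articular cartilage (length-2 numerics), the B&G landmarks.
#' @param epicondyle_medial,epicondyle_lateral Transepicondylar landmarks.
#'   Either single points or matrices/data frames with one row per serial
#'   section; repeated pairs are averaged by circular mean of the doubled
#'   axis angles.
#' @param group `"stable"` or `"unstable"` cohort label.
#' @param hill_sachs Logical flag: Hill-Sachs lesion present.
#' @return An `hta_case` object.
#' @export
hta_case <- function(case_id, side = c("right", "left"),
                     head_contour = NULL, tubercle_contour = NULL,
                     cartilage_ant = NULL, cartilage_post = NULL,
                     epicondyle_medial = NULL, epicondyle_lateral = NULL,
                     group = c("stable", "unstable"), hill_sachs = FALSE) {
  side <- match.arg(side)
  group <- match.arg(group)
  tidy_contour <- function(ct, what) {
    if (is.null(ct)) return(NULL)
    tibble::as_tibble(as.data.frame(as_xy_matrix(ct, 1L, what)))
  }
  tidy_pt <- function(p, what) if (is.null(p)) NULL else landmark_matrix(p, what)
  x <- structure(
    list(
      case_id = as.character(case_id), side = side, group = group,
      hill_sachs = isTRUE(hill_sachs),
      head_contour = tidy_contour(head_contour, "head_contour"),
      tubercle_contour = tidy_contour(tubercle_contour, "tubercle_contour"),
      cartilage_ant = if (is.null(cartilage_ant)) NULL else as_point(cartilage_ant, "cartilage_ant"),
      cartilage_post = if (is.null(cartilage_post)) NULL else as_point(cartilage_post, "cartilage_post"),
      epicondyle_medial = tidy_pt(epicondyle_medial, "epicondyle_medial"),
      epicondyle_lateral = tidy_pt(epicondyle_lateral, "epicondyle_lateral")
    ),
    class = "hta_case"
  )
  if (!is.null(x$cartilage_ant) && !is.null(x$cartilage_post) &&
      sqrt(sum((x$cartilage_ant - x$cartilage_post)^2)) <= 1e-9) {
    abort_input("cartilage landmarks coincide")
  }
  x
}

# Landmarks that may repeat across serial sections: coerce to an n x 2 matrix.
landmark_matrix <- function(p, what) {
  if (is.numeric(p) && length(p) == 2) p <- matrix(p, 1, 2)
  as_xy_matrix(p, 1L, what)
}

#' @export
print.hta_case <- function(x, ...) {
  n_h <- if (is.null(x$head_contour)) 0L else nrow(x$head_contour)
  n_t <- if (is.null(x$tubercle_contour)) 0L else nrow(x$tubercle_contour)
  cat(sprintf("<hta_case> %s (%s, %s%s): head %d pts, tubercle %d pts\n",
              x$case_id, x$side, x$group,
              if (x$hill_sachs) ", Hill-Sachs" else "", n_h, n_t))
  invisible(x)
}

new_head_axis <- function(method, axis, head_fit = NULL, tubercle_fit = NULL) {
  structure(list(method = method, axis = axis,
                 head_fit = head_fit, tubercle_fit = tubercle_fit),
            class = "head_axis")
}

#' @export
print.head_axis <- function(x, ...) {
  cat(sprintf("<head_axis:%s> %.4f deg\n", x$method, x$axis$angle_deg))
  invisible(x)
}

#' Humeral head axis by the Circle-method
#'
#' Fits one circle to the humeral-head margin and one to the
#' greater-tubercle margin; the head axis is the line through the two
#' centres. With `robust = TRUE` both circles use the Tukey-biweight robust
#' fit, which rejects contour points indented by a Hill-Sachs defect.
#'
#' @param head_contour,tubercle_contour Contour point data frames (mm), each
#'   with at least 3 non-collinear points.
#' @param robust Use [fit_circle_robust()] instead of the plain geometric fit.
#' @param inlier_threshold Robust inlier threshold, mm.
#' @return A `head_axis` object with both `circle_fit`s attached.
#' @export
circle_method_axis <- function(head_contour, tubercle_contour,
                               robust = FALSE, inlier_threshold = 1) {
  fit1 <- function(ct) {
    if (robust) fit_circle_robust(ct, inlier_threshold)
    else fit_circle_geometric(ct)
  }
  hf <- fit1(head_contour)
  tf <- fit1(tubercle_contour)
  c1 <- c(hf$cx, hf$cy); c2 <- c(tf$cx, tf$cy)
  if (sqrt(sum((c1 - c2)^2)) < 1e-6) {
    abort_degenerate("circle centres coincide: head axis undefined")
  }
  new_head_axis("circle", axis_through(c1, c2), hf, tf)
}

#' Humeral head axis by the Bernageau-Godefroy construction
#'
#' The head axis is the perpendicular to the chord through the anterior and
#' posterior limits of the articular cartilage (the anatomical neck),
#' anchored at the chord midpoint. `head_reference` (e.g. a head-circle
#' centre) is carried only as anchor metadata and never changes the angle.
#'
#' @param cartilage_ant,cartilage_post The two cartilage-limit landmarks (mm).
#' @param head_reference Optional reference point used as the axis anchor.
#' @return A `head_axis` object (no circle fits attached).
#' @export
bg_axis <- function(cartilage_ant, cartilage_post, head_reference = NULL) {
  a <- as_point(cartilage_ant, "cartilage_ant")
  p <- as_point(cartilage_post, "cartilage_post")
  if (sqrt(sum((a - p)^2)) <= 1e-9) {
    abort_degenerate("cartilage landmarks coincide: chord undefined")
  }
  chord <- axis_through(a, p)
  anchor <- if (is.null(head_reference)) (a + p) / 2 else as_point(head_reference)
  new_head_axis("bg", axis_at_angle(anchor, chord$angle_deg + 90, "bg"))
}

#' Transepicondylar axis from the epicondyle landmarks
#'
#' With a single landmark pair, the line through the medial and lateral
#' epicondyle. With repeated pairs from serial sections (one row each in
#' `medial` and `lateral`), the per-pair axis angles are averaged by the
#' circular mean of doubled angles, which is the correct mean for undirected
#' lines.
#'
#' @param medial,lateral Single points or n x 2 matrices/data frames of
#'   repeated landmark picks (mm), with matching row counts.
#' @return An `axis_line`.
#' @export
epicondylar_axis <- function(medial, lateral) {
  m <- landmark_matrix(medial, "epicondyle_medial")
  l <- landmark_matrix(lateral, "epicondyle_lateral")
  if (nrow(m) != nrow(l)) abort_input("medial/lateral pair counts differ")
  d <- l - m
  len <- sqrt(rowSums(d^2))
  if (any(len <= 1e-9)) abort_degenerate("coincident epicondyle landmarks")
  ang <- wrap_axis_angle(rad2deg(atan2(d[, 2], d[, 1])))
  anchor <- colMeans(rbind(m, l))
  if (nrow(m) == 1L) return(axis_through(m[1, ], l[1, ]))
  axis_at_angle(anchor, axis_circular_mean(ang), source = "epicondylar-mean")
}

#' Humeral torsion angle from a head axis and the epicondylar axis
#'
#' The HTA is the signed axis angle from the head axis to the
#' transepicondylar axis, wrapped to (-90, 90]; positive values are
#' retrotorsion, negative antetorsion. Left shoulders are mirror images of
#' right ones, so their sign is flipped to put both sides on the same scale.
#'
#' @param head A `head_axis` (from [circle_method_axis()] or [bg_axis()]).
#' @param epi The transepicondylar `axis_line`.
#' @param side `"right"` (reference convention) or `"left"` (sign flipped).
#' @param case_id Optional identifier carried into the result.
#' @return A one-row tibble: `case_id`, `side`, `method`,
#'   `head_axis_deg`, `epi_axis_deg`, `hta_deg`, and circle-fit diagnostics
#'   (`NA` for the B&G method).
#' @export
compute_hta <- function(head, epi, side = c("right", "left"),
                        case_id = NA_character_) {
  side <- match.arg(side)
  if (!inherits(head, "head_axis")) abort_input("head must be a head_axis")
  raw <- signed_axis_angle(head$axis, epi)
  hta <- if (side == "left") wrap_axis_angle(-raw) else raw
  diag_of <- function(f) {
    if (is.null(f)) {
      tibble::tibble(r = NA_real_, rms = NA_real_, n_inliers = NA_integer_,
                     n_points = NA_integer_)
    } else {
      tibble::tibble(r = f$r, rms = f$rms_residual,
                     n_inliers = f$n_inliers, n_points = f$n_points)
    }
  }
  hd <- diag_of(head$head_fit)
  td <- diag_of(head$tubercle_fit)
  tibble::tibble(
    case_id = as.character(case_id), side = side, method = head$method,
    head_axis_deg = head$axis$angle_deg,
    epi_axis_deg = as_axis_angle(epi),
    hta_deg = hta,
    head_r_mm = hd$r, head_rms_mm = hd$rms,
    head_n_inliers = hd$n_inliers, head_n_points = hd$n_points,
    tubercle_r_mm = td$r, tubercle_rms_mm = td$rms,
    tubercle_n_inliers = td$n_inliers, tubercle_n_points = td$n_points,
    error = NA_character_
  )
}

# Empty result row used when a method fails on a case.
hta_error_row <- function(case_id, side, method, msg) {
  tibble::tibble(
    case_id = as.character(case_id), side = side, method = method,
    head_axis_deg = NA_real_, epi_axis_deg = NA_real_, hta_deg = NA_real_,
    head_r_mm = NA_real_, head_rms_mm = NA_real_,
    head_n_inliers = NA_integer_, head_n_points = NA_integer_,
    tubercle_r_mm = NA_real_, tubercle_rms_mm = NA_real_,
    tubercle_n_inliers = NA_integer_, tubercle_n_points = NA_integer_,
    error = msg
  )
}

#' Measure one case with one or both methods
#'
#' Runs the requested head-axis constructions against a case's digitised
#' inputs, sharing a single transepicondylar axis, and returns one result
#' row per method. A method whose inputs are missing or degenerate yields a
#' row with `hta_deg = NA` and the error message in `error`; the other
#' method is still measured.
#'
#' @param case An [hta_case()].
#' @param methods Character subset of `c("circle", "bg")`.
#' @param robust Use the robust circle fit for the Circle-method.
#' @param inlier_threshold Robust inlier threshold, mm.
#' @return A tibble with one row per requested method (see [compute_hta()]).
#' @export
measure_case <- function(case, methods = c("circle", "bg"),
                         robust = FALSE, inlier_threshold = 1) {
  if (!inherits(case, "hta_case")) abort_input("case must be an hta_case")
  methods <- match.arg(methods, c("circle", "bg"), several.ok = TRUE)
  epi <- tryCatch({
    if (is.null(case$epicondyle_medial) || is.null(case$epicondyle_lateral)) {
      abort_input("epicondyle landmarks missing")
    }
    epicondylar_axis(case$epicondyle_medial, case$epicondyle_lateral)
  }, error = function(e) e)
  one <- function(method) {
    if (inherits(epi, "error")) {
      return(hta_error_row(case$case_id, case$side, method,
                           conditionMessage(epi)))
    }
    tryCatch({
      head <- switch(method,
        circle = {
          if (is.null(case$head_contour) || is.null(case$tubercle_contour)) {
            abort_input("head/tubercle contour missing")
          }
          circle_method_axis(case$head_contour, case$tubercle_contour,
                             robust = robust,
                             inlier_threshold = inlier_threshold)
        },
        bg = {
          if (is.null(case$cartilage_ant) || is.null(case$cartilage_post)) {
            abort_input("cartilage landmarks missing")
          }
          bg_axis(case$cartilage_ant, case$cartilage_post)
        }
      )
      compute_hta(head, epi, side = case$side, case_id = case$case_id)
    }, error = function(e) {
      hta_error_row(case$case_id, case$side, method, conditionMessage(e))
    })
  }
  dplyr::bind_rows(lapply(methods, one)) |>
    dplyr::mutate(group = case$group, hill_sachs = case$hill_sachs)
}

#' Plot a case with its fitted axes
#'
#' Overlays the digitised contours, the cartilage and epicondyle landmarks
#' (translated next to the head for display), and the head axes produced by
#' the requested methods -- the same audit view a reader would use to check
#' a measurement.
#'
#' @param object An [hta_case()].
#' @param methods Methods to overlay.
#' @param robust,inlier_threshold Passed to [circle_method_axis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hta_case <- function(object, methods = c("circle", "bg"),
                              robust = FALSE, inlier_threshold = 1, ...) {
  pts <- dplyr::bind_rows(
    if (!is.null(object$head_contour))
      dplyr::mutate(object$head_contour, structure = "head margin"),
    if (!is.null(object$tubercle_contour))
      dplyr::mutate(object$tubercle_contour, structure = "tubercle margin")
  )
  res <- measure_case(object, methods, robust, inlier_threshold)
  ok <- dplyr::filter(res, is.na(.data$error))
  ctr <- c(mean(pts$x), mean(pts$y))
  span <- max(pts$x) - min(pts$x) + max(pts$y) - min(pts$y)
  seg <- dplyr::mutate(
    ok,
    x = ctr[1] - span / 2 * cos(deg2rad(.data$head_axis_deg)),
    xend = ctr[1] + span / 2 * cos(deg2rad(.data$head_axis_deg)),
    y = ctr[2] - span / 2 * sin(deg2rad(.data$head_axis_deg)),
    yend = ctr[2] + span / 2 * sin(deg2rad(.data$head_axis_deg))
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$structure), size = 0.8) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$method)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("case %s (%s)", object$case_id, object$side),
                  x = "x (mm)", y = "y (mm)")
}
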