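# Least-squares circle fitting: Pratt-normalised algebraic fit, Gauss-Newton
# geometric refinement, and a deterministic Tukey-biweight IRLS robust
# variant. These automate the manual circle alignment at the core of the
# Circle-method for humeral torsion; the robust fit is what lets the head
# circle ignore points indented by a Hill-Sachs defect.

new_circle_fit <- function(cx, cy, r, m, inlier_mask, method,
                           converged = TRUE, iterations = 0L) {
  cx <- unname(cx); cy <- unname(cy); r <- unname(r)
  d <- sqrt((m[, 1] - cx)^2 + (m[, 2] - cy)^2)
  res <- d - r
  rms <- sqrt(mean(res[inlier_mask]^2))
  structure(
    list(
      cx = cx, cy = cy, r = r,
      rms_residual = rms,
      n_points = nrow(m),
      n_inliers = sum(inlier_mask),
      inlier_mask = inlier_mask,
      residuals = res,
      method = method,
      converged = converged,
      iterations = iterations
    ),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf(
    "<circle_fit:%s> centre (%.4f, %.4f) mm, r = %.4f mm, rms = %.4g mm, %d/%d inliers%s\n",
    x$method, x$cx, x$cy, x$r, x$rms_residual, x$n_inliers, x$n_points,
    if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

check_fittable <- function(points, what) {
  m <- as_xy_matrix(points, 3L, what)
  if (points_collinear(m)) {
    abort_degenerate(sprintf("%s are collinear: circle fit is degenerate", what))
  }
  m
}

#' Algebraic (Pratt-normalised) least-squares circle fit
#'
#' Fits a circle to 2-D points by minimising the algebraic distance
#' \eqn{A(x^2+y^2) + Bx + Cy + D} under Pratt's normalisation
#' \eqn{B^2 + C^2 - 4AD = 1}, which makes the solution approximate the
#' geometric least-squares circle and behave well on arcs. All points are
#' treated as inliers.
#'
#' @param points Data frame with `x`, `y` columns (or `x_mm`, `y_mm`), or a
#'   two-column matrix; coordinates in mm. At least 3 non-collinear points.
#' @return A `circle_fit` object: centre `cx`, `cy` and radius `r` in mm,
#'   `rms_residual` (RMS of radial residuals over inliers), point counts,
#'   and a per-point `inlier_mask`.
#' @seealso [fit_circle_geometric()], [fit_circle_robust()]
#' @export
#' @examples
#' pts <- tibble::tibble(x = c(1, 0, -1), y = c(0, 1, 0))
#' fit_circle_algebraic(pts)
fit_circle_algebraic <- function(points) {
  m <- check_fittable(points, "points")
  ctr <- colMeans(m)
  xs <- m[, 1] - ctr[1]
  ys <- m[, 2] - ctr[2]
  z <- xs^2 + ys^2
  A <- cbind(z, xs, ys, 1)
  M <- crossprod(A) / nrow(m)
  # Pratt constraint matrix for (A, B, C, D)
  B <- matrix(c(0, 0, 0, -2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                -2, 0, 0, 0), 4, 4, byrow = TRUE)
  ev <- eigen(solve(B, M))
  vals <- ev$values
  vecs <- ev$vectors
  if (is.complex(vals)) {
    keep <- abs(Im(vals)) < 1e-8 * (abs(Re(vals)) + 1)
    vals <- Re(vals)[keep]
    vecs <- Re(vecs)[, keep, drop = FALSE]
  }
  # Pratt solution: eigenvector with the smallest non-negative eigenvalue
  # (zero for exactly circular data; tolerate numerical noise below zero).
  tol <- 1e-9 * max(abs(vals), 1)
  ok <- which(vals > -tol)
  if (length(ok) == 0) abort_degenerate("algebraic circle fit is degenerate")
  i <- ok[which.min(vals[ok])]
  v <- vecs[, i]
  if (abs(v[1]) < 1e-14) abort_degenerate("algebraic fit degenerated to a line")
  cx <- -v[2] / (2 * v[1])
  cy <- -v[3] / (2 * v[1])
  r2 <- cx^2 + cy^2 - v[4] / v[1]
  if (!is.finite(r2) || r2 <= 0) abort_degenerate("algebraic fit has no real radius")
  new_circle_fit(cx + ctr[1], cy + ctr[2], sqrt(r2), m,
                 rep(TRUE, nrow(m)), method = "algebraic")
}

# One weighted Gauss-Newton pass over the geometric objective
# sum w_i (d_i - r)^2; returns the refined (cx, cy, r) and convergence info.
gauss_newton_circle <- function(m, cx, cy, r, w = NULL,
                                tol = 1e-10, max_iter = 100L) {
  if (is.null(w)) w <- rep(1, nrow(m))
  sw <- sqrt(w)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    dx <- m[, 1] - cx
    dy <- m[, 2] - cy
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-12] <- 1e-12
    f <- d - r
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(
      qr.solve(J * sw, -f * sw),
      error = function(e) abort_degenerate("geometric circle fit: singular Jacobian")
    )
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (sqrt(sum(step^2)) < tol) { converged <- TRUE; break }
  }
  list(cx = cx, cy = cy, r = r, converged = converged, iterations = it)
}

#' Geometric (orthogonal-distance) circle fit by Gauss-Newton
#'
#' Refines a circle to minimise the geometric objective
#' \eqn{\sum_i (d_i - r)^2}, where \eqn{d_i} is the distance from point i to
#' the centre. Iterates until the parameter step is below `tol` (1e-10 mm)
#' or `max_iter` iterations; non-convergence is flagged on the result, and
#' the best iterate is returned.
#'
#' @inheritParams fit_circle_algebraic
#' @param init Optional `circle_fit` (or list with `cx`, `cy`, `r`) used as
#'   the starting point; defaults to the algebraic fit of the same points.
#' @param tol Convergence threshold on the Gauss-Newton step, mm.
#' @param max_iter Maximum Gauss-Newton iterations.
#' @return A `circle_fit` object (all points inliers).
#' @export
fit_circle_geometric <- function(points, init = NULL,
                                 tol = 1e-10, max_iter = 100L) {
  m <- check_fittable(points, "points")
  if (is.null(init)) init <- fit_circle_algebraic(m)
  if (!all(is.finite(c(init$cx, init$cy, init$r))) || init$r <= 0) {
    abort_input("init must carry finite cx, cy and positive r")
  }
  gn <- gauss_newton_circle(m, init$cx, init$cy, init$r,
                            tol = tol, max_iter = max_iter)
  new_circle_fit(gn$cx, gn$cy, gn$r, m, rep(TRUE, nrow(m)),
                 method = "geometric", converged = gn$converged,
                 iterations = gn$iterations)
}

#' Robust circle fit with Tukey-biweight IRLS
#'
#' Deterministic robust fit: starting from the algebraic fit, alternates
#' Tukey-biweight reweighting (tuning constant = `inlier_threshold`) with
#' weighted Gauss-Newton refinement; no random sampling is involved, so the
#' result depends only on the input. Points whose final absolute radial
#' residual is at most `inlier_threshold` are marked inliers and the circle
#' is refit geometrically on them alone. This is the variant that discards
#' contour points displaced inward by a Hill-Sachs indentation.
#'
#' @inheritParams fit_circle_algebraic
#' @param inlier_threshold Radial residual (mm) separating inliers from
#'   rejected points; also the biweight tuning constant.
#' @param max_iter Maximum IRLS iterations.
#' @return A `circle_fit`; `inlier_mask` marks the retained points and
#'   `rms_residual` is computed over inliers only.
#' @export
fit_circle_robust <- function(points, inlier_threshold = 1, max_iter = 50L) {
  if (!is.numeric(inlier_threshold) || inlier_threshold <= 0) {
    abort_input("inlier_threshold must be a positive length in mm")
  }
  m <- check_fittable(points, "points")
  fit <- fit_circle_algebraic(m)
  cx <- fit$cx; cy <- fit$cy; r <- fit$r
  cc <- inlier_threshold
  for (i in seq_len(max_iter)) {
    d <- sqrt((m[, 1] - cx)^2 + (m[, 2] - cy)^2)
    res <- d - r
    u <- res / cc
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 3) abort_degenerate(
      "robust circle fit: fewer than 3 points carry weight at this threshold")
    gn <- gauss_newton_circle(m, cx, cy, r, w = w, max_iter = 25L)
    step <- sqrt((gn$cx - cx)^2 + (gn$cy - cy)^2 + (gn$r - r)^2)
    cx <- gn$cx; cy <- gn$cy; r <- gn$r
    if (step < 1e-10) break
  }
  d <- sqrt((m[, 1] - cx)^2 + (m[, 2] - cy)^2)
  inl <- abs(d - r) <= inlier_threshold
  if (sum(inl) < 3 || points_collinear(m[inl, , drop = FALSE])) {
    abort_degenerate(sprintf(
      "robust circle fit: only %d inlier(s) within %.3g mm", sum(inl),
      inlier_threshold))
  }
  gn <- gauss_newton_circle(m[inl, , drop = FALSE], cx, cy, r)
  new_circle_fit(gn$cx, gn$cy, gn$r, m, inl, method = "robust",
                 converged = gn$converged, iterations = gn$iterations)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a circle fit into a one-row tibble
#'
#' @param x A `circle_fit`.
#' @param ... Unused.
#' @return One row with `cx`, `cy`, `r` (mm).
#' @export
tidy.circle_fit <- function(x, ...) {
  tibble::tibble(cx = x$cx, cy = x$cy, r = x$r)
}

#' One-row fit diagnostics for a circle fit
#'
#' @inheritParams tidy.circle_fit
#' @return Tibble with residual and inlier diagnostics.
#' @export
glance.circle_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, cx = x$cx, cy = x$cy, r = x$r,
    rms_residual = x$rms_residual,
    n_points = x$n_points, n_inliers = x$n_inliers,
    converged = x$converged
  )
}

#' Attach per-point residuals and inlier flags to the fitted points
#'
#' @param x A `circle_fit`.
#' @param data The point set the circle was fitted to.
#' @param ... Unused.
#' @return `data` as a tibble with `.resid` (signed radial residual, mm) and
#'   `.inlier` columns appended.
#' @export
augment.circle_fit <- function(x, data, ...) {
  m <- as_xy_matrix(data, 1L, "data")
  if (nrow(m) != x$n_points) abort_input("data does not match the fitted points")
  out <- tibble::as_tibble(as.data.frame(m))
  out$.resid <- x$residuals
  out$.inlier <- x$inlier_mask
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a circle fit over its points
#'
#' @param object A `circle_fit`.
#' @param data The fitted point set (needed because the fit stores only
#'   residuals, not coordinates).
#' @param ... Unused.
#' @return A ggplot: points coloured by inlier status, fitted circle overlaid.
#' @export
autoplot.circle_fit <- function(object, data, ...) {
  aug <- augment(object, data)
  th <- seq(0, 2 * pi, length.out = 361)
  circ <- tibble::tibble(x = object$cx + object$r * cos(th),
                         y = object$cy + object$r * sin(th))
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circ, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$.inlier)) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "inlier", x = "x (mm)", y = "y (mm)",
                  title = sprintf("%s fit: r = %.2f mm, rms = %.3g mm",
                                  object$method, object$r,
                                  object$rms_residual))
}
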