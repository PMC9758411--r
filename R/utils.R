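# Shared helpers: angle arithmetic on undirected axes, coordinate validation,
# classed error conditions.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap an angle onto the undirected-axis range (-90, 90]
#'
#' Undirected lines are identified modulo 180 degrees; all axis angles in
#' this package live on (-90, 90], with the vertical line mapped to +90.
#'
#' @param a Numeric vector of angles in degrees.
#' @return Numeric vector in (-90, 90].
#' @export
#' @examples
#' wrap_axis_angle(c(0, 90, 91, 180, -90, 160))
wrap_axis_angle <- function(a) {
  w <- a %% 180
  ifelse(w > 90, w - 180, w)
}

# Circular mean of undirected-axis angles via the doubled-angle trick.
axis_circular_mean <- function(angles_deg) {
  t2 <- deg2rad(2 * angles_deg)
  wrap_axis_angle(rad2deg(atan2(mean(sin(t2)), mean(cos(t2))) / 2))
}

abort_input <- function(msg, ...) {
  rlang::abort(msg, class = "circlehta_error_input", ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "circlehta_error_degenerate", ...)
}

# Coerce a point set (data frame with x/y or x_mm/y_mm columns, or a
# two-column matrix) to an n x 2 numeric matrix in mm, with validation.
as_xy_matrix <- function(points, min_points = 1L, what = "points") {
  if (is.matrix(points) && ncol(points) == 2) {
    m <- points
  } else if (is.data.frame(points)) {
    nms <- names(points)
    xcol <- intersect(c("x", "x_mm"), nms)[1]
    ycol <- intersect(c("y", "y_mm"), nms)[1]
    if (is.na(xcol) || is.na(ycol)) {
      abort_input(sprintf("%s must have x/y (or x_mm/y_mm) columns", what))
    }
    m <- cbind(points[[xcol]], points[[ycol]])
  } else {
    abort_input(sprintf("%s must be a data frame or two-column matrix", what))
  }
  storage.mode(m) <- "double"
  if (nrow(m) < min_points) {
    abort_input(sprintf("%s: need at least %d point(s), got %d",
                        what, min_points, nrow(m)))
  }
  if (!all(is.finite(m))) {
    abort_input(sprintf("%s: coordinates must be finite", what))
  }
  colnames(m) <- c("x", "y")
  m
}

# A single 2-D point in mm from a length-2 numeric or 1-row data frame.
as_point <- function(p, what = "point") {
  if (is.data.frame(p)) p <- as_xy_matrix(p, 1L, what)[1, ]
  p <- as.numeric(p)
  if (length(p) != 2 || !all(is.finite(p))) {
    abort_input(sprintf("%s must be a finite length-2 numeric (x, y) in mm", what))
  }
  names(p) <- c("x", "y")
  p
}

# Collinearity check used by all circle fits: smallest singular value of the
# centred point matrix below tol means the points do not constrain a circle.
points_collinear <- function(m, tol = 1e-9) {
  mc <- sweep(m, 2, colMeans(m))
  sv <- svd(mc, nu = 0, nv = 0)$d
  length(sv) < 2 || sv[2] < tol
}

# Deterministic child seeds below 2^31 derived from a base seed.
derive_seed <- function(base_seed, offset) {
  as.integer((as.double(base_seed) * 48271 + offset) %% 2147483647)
}
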