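# Undirected axis lines in the measurement plane. An axis is a line without
# orientation: its angle lives on (-90, 90] with respect to the +x axis, and
# the signed angle between two axes is wrapped back onto that range. This is
# the representation both torsion methods reduce to before the HTA is taken.

new_axis_line <- function(anchor, direction, source = "axis") {
  nrm <- sqrt(sum(direction^2))
  direction <- direction / nrm
  structure(
    list(
      anchor = as_point(anchor, "anchor"),
      direction = c(x = direction[1], y = direction[2]),
      angle_deg = unname(wrap_axis_angle(rad2deg(atan2(direction[2], direction[1])))),
      source = source
    ),
    class = "axis_line"
  )
}

#' @export
print.axis_line <- function(x, ...) {
  cat(sprintf("<axis_line> %.4f deg through (%.3f, %.3f) mm [%s]\n",
              x$angle_deg, x$anchor[1], x$anchor[2], x$source))
  invisible(x)
}

#' Undirected line through two points
#'
#' @param p,q Length-2 numerics (x, y) in mm; must be at least 1e-9 mm apart.
#' @return An `axis_line`: anchor `p`, unit direction, and `angle_deg` in
#'   (-90, 90] measured from the +x axis.
#' @export
#' @examples
#' axis_through(c(0, 0), c(1, 1))$angle_deg # 45
axis_through <- function(p, q) {
  p <- as_point(p, "p"); q <- as_point(q, "q")
  d <- q - p
  if (sqrt(sum(d^2)) <= 1e-9) {
    abort_degenerate("axis_through: points coincide, line undefined")
  }
  new_axis_line(p, d, source = "two-point")
}

# Axis at a given angle (degrees), used internally and by the phantom.
axis_at_angle <- function(anchor, angle_deg, source = "angle") {
  a <- deg2rad(angle_deg)
  new_axis_line(as_point(anchor), c(cos(a), sin(a)), source = source)
}

as_axis_angle <- function(a) {
  if (inherits(a, "axis_line")) return(a$angle_deg)
  if (is.numeric(a) && length(a) == 1 && is.finite(a)) return(wrap_axis_angle(a))
  abort_input("expected an axis_line or a single finite angle in degrees")
}

#' Signed angle between two undirected axes
#'
#' The difference of the two axis angles, wrapped to (-90, 90]. Positive
#' means `a` is rotated counter-clockwise from `b`; because the axes are
#' undirected, a difference of 160 degrees is the same axis relation as -20.
#'
#' @param a,b `axis_line` objects (or plain angles in degrees).
#' @return A single angle in degrees, in (-90, 90].
#' @export
#' @examples
#' signed_axis_angle(80, -80) # -20: axes 160 deg apart are 20 deg apart
signed_axis_angle <- function(a, b) {
  wrap_axis_angle(as_axis_angle(a) - as_axis_angle(b))
}
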