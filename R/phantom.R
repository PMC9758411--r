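# Parametric phantom of the axial humeral-head section with known
# ground-truth torsion. The phantom exists because no patient MRI data are
# available: it emulates the digitised inputs (head margin, tubercle margin,
# cartilage limits, epicondyle landmarks) with a known head-axis angle, an
# optional Hill-Sachs indentation, contour noise, and a rater
# landmark-error model, so both measurement methods can be validated and
# compared against truth.

#' Phantom geometry specification
#'
#' Describes one synthetic axial section. The head is a circle of radius
#' `R_head`; the greater tubercle is a smaller circle of radius `r_tub`
#' whose centre sits `d_offset` mm from the head centre along the true head
#' axis, so its protruding arc is the tubercle margin. The articular
#' cartilage spans `cartilage_halfspan` degrees to either side of the
#' direction opposite the tubercle; its ends are the B&G landmarks.
#'
#' Defaults are scaled to an adult humeral head (head radius 25 mm,
#' tubercle radius 10 mm, centre offset 27 mm, cartilage half-span 70
#' degrees). Contour noise is radial Gaussian; the default 0.3 mm is on the
#' order of the in-plane voxel size of a shoulder MRI, i.e. one digitisation
#' pixel.
#'
#' @param R_head Head circle radius, mm.
#' @param r_tub Tubercle circle radius, mm (`< R_head`).
#' @param d_offset Head-centre to tubercle-centre distance, mm; must exceed
#'   `R_head - r_tub` so the tubercle protrudes.
#' @param theta_true True torsion angle, degrees in (-90, 90]; positive =
#'   retrotorsion.
#' @param epi_angle Angle of the transepicondylar line, degrees.
#' @param cartilage_halfspan Half-extent of the articular arc, degrees.
#' @param n_head_pts,n_tub_pts Contour sampling counts.
#' @param sigma_contour Radial contour noise SD, mm.
#' @param side `"right"` or `"left"`; left sections are mirrored.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(R_head = 25, r_tub = 10, d_offset = 27,
                         theta_true = 25, epi_angle = 0,
                         cartilage_halfspan = 70,
                         n_head_pts = 72, n_tub_pts = 24,
                         sigma_contour = 0.3,
                         side = c("right", "left")) {
  side <- match.arg(side)
  if (!(R_head > r_tub && r_tub > 0)) {
    abort_input("need R_head > r_tub > 0")
  }
  if (d_offset <= R_head - r_tub) {
    abort_input("d_offset must exceed R_head - r_tub (tubercle must protrude)")
  }
  if (theta_true <= -90 || theta_true > 90) {
    abort_input("theta_true must lie in (-90, 90]")
  }
  if (cartilage_halfspan <= 0 || cartilage_halfspan >= 90) {
    abort_input("cartilage_halfspan must lie in (0, 90)")
  }
  if (sigma_contour < 0) abort_input("sigma_contour must be >= 0")
  if (n_head_pts < 3 || n_tub_pts < 3) abort_input("need >= 3 contour points")
  structure(list(R_head = R_head, r_tub = r_tub, d_offset = d_offset,
                 theta_true = theta_true, epi_angle = epi_angle,
                 cartilage_halfspan = cartilage_halfspan,
                 n_head_pts = as.integer(n_head_pts),
                 n_tub_pts = as.integer(n_tub_pts),
                 sigma_contour = sigma_contour, side = side),
            class = "phantom_spec")
}

#' Hill-Sachs lesion specification
#'
#' An angular sector of the head circle indented inward, mimicking the
#' impaction defect left by a dislocation. Position is given relative to
#' the posterior cartilage limit, where these lesions occur.
#'
#' @param halfwidth_deg Angular half-extent of the defect, degrees in (0, 90).
#' @param depth_mm Maximum inward indentation, mm (0 < depth < head radius).
#' @param center_angle_deg Sector centre, degrees along the head circle from
#'   the posterior cartilage limit (0 = centred on the limit).
#' @param profile `"chord"` (flat floor along the sector chord, depth capped
#'   at the chord sagitta) or `"arc"` (smooth cosine-tapered floor).
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(halfwidth_deg, depth_mm, center_angle_deg = 0,
                        profile = c("chord", "arc")) {
  profile <- match.arg(profile)
  if (halfwidth_deg <= 0 || halfwidth_deg >= 90) {
    abort_input("halfwidth_deg must lie in (0, 90)")
  }
  if (depth_mm < 0) abort_input("depth_mm must be >= 0")
  structure(list(center_angle_deg = center_angle_deg,
                 halfwidth_deg = halfwidth_deg,
                 depth_mm = depth_mm, profile = profile),
            class = "lesion_spec")
}

#' Rater observation-error model
#'
#' How a human rater's digitisation differs from the underlying anatomy:
#' isotropic Gaussian jitter on every landmark, optional extra per-point
#' jitter on contour picks, and a rule for where the posterior cartilage
#' limit is placed when a lesion has destroyed it -- `"nearest_intact"`
#' moves it to the closest un-lesioned contour point, `"defect_floor"` to
#' the deepest point of the defect. This relocation is the mechanism by
#' which a Hill-Sachs lesion biases the B&G method while the robust circle
#' fit is unaffected.
#'
#' @param sigma_landmark_mm Landmark jitter SD, mm (default 1 mm, roughly
#'   two in-plane pixels of landmark ambiguity).
#' @param lesion_rule Landmark relocation rule under a lesion.
#' @param sigma_contour_pick_mm Extra per-point contour jitter SD, mm.
#' @return A `rater_model` object.
#' @export
rater_model <- function(sigma_landmark_mm = 1,
                        lesion_rule = c("nearest_intact", "defect_floor"),
                        sigma_contour_pick_mm = 0.3) {
  lesion_rule <- match.arg(lesion_rule)
  if (sigma_landmark_mm < 0 || sigma_contour_pick_mm < 0) {
    abort_input("rater sigmas must be >= 0")
  }
  structure(list(sigma_landmark_mm = sigma_landmark_mm,
                 lesion_rule = lesion_rule,
                 sigma_contour_pick_mm = sigma_contour_pick_mm),
            class = "rater_model")
}

# Circular distance between angles in degrees, in [0, 180].
circ_dist <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Indent a contour with a Hill-Sachs-like defect
#'
#' Points of `contour` whose polar angle about the head-circle centre falls
#' inside the lesion sector are displaced radially inward. The `"chord"`
#' profile pushes points onto the chord spanning the sector, with the
#' indentation capped at `depth_mm` (so the sector midpoint moves inward by
#' exactly `min(sagitta, depth_mm)`); the `"arc"` profile applies a cosine
#' taper that is `depth_mm` deep at the sector centre and zero at its edges.
#'
#' @param contour Contour data frame (`x`, `y` in mm).
#' @param lesion A [lesion_spec()].
#' @param head_circle The underlying head circle: a `circle_fit` or list
#'   with `cx`, `cy`, `r`.
#' @param reference_angle_deg Absolute angle (degrees) of the point the
#'   lesion's `center_angle_deg` is measured from, typically the posterior
#'   cartilage limit.
#' @return The indented contour tibble; unchanged (with a warning) if the
#'   sector contains no contour point.
#' @export
apply_lesion <- function(contour, lesion, head_circle,
                         reference_angle_deg = 0) {
  stopifnot(inherits(lesion, "lesion_spec"))
  m <- as_xy_matrix(contour, 1L, "contour")
  cx <- head_circle$cx; cy <- head_circle$cy; R <- head_circle$r
  if (lesion$depth_mm == 0) return(tibble::as_tibble(as.data.frame(m)))
  ang <- rad2deg(atan2(m[, 2] - cy, m[, 1] - cx))
  centre <- reference_angle_deg + lesion$center_angle_deg
  hw <- lesion$halfwidth_deg
  delta <- circ_dist(ang, centre)
  sel <- delta <= hw
  if (!any(sel)) {
    rlang::warn("lesion sector does not overlap the contour; returning it unchanged")
    return(tibble::as_tibble(as.data.frame(m)))
  }
  rho <- sqrt((m[, 1] - cx)^2 + (m[, 2] - cy)^2)
  indent <- numeric(nrow(m))
  if (lesion$profile == "chord") {
    # distance from centre to the sector chord along the ray at offset delta
    chord_r <- R * cos(deg2rad(hw)) / cos(deg2rad(delta[sel]))
    indent[sel] <- pmin(R - chord_r, lesion$depth_mm)
  } else {
    indent[sel] <- lesion$depth_mm * cos(pi * delta[sel] / (2 * hw))
  }
  rho_new <- rho - indent
  out <- cbind(x = cx + rho_new * cos(deg2rad(ang)),
               y = cy + rho_new * sin(deg2rad(ang)))
  tibble::as_tibble(as.data.frame(out))
}

#' Generate one phantom case
#'
#' Builds the full set of measurement inputs for one synthetic section:
#' head contour on the head circle (optionally indented by `lesion`),
#' tubercle contour on the protruding tubercle arc, cartilage limits at
#' \eqn{\pm}`cartilage_halfspan` about the anti-tubercle direction,
#' epicondyle landmarks on the `epi_angle` line, radial Gaussian contour
#' noise, and -- for left-sided specs -- a mirrored section. The returned
#' object carries the ground truth, so with zero noise and no lesion
#' [measure_case()] recovers `theta_true` exactly by both methods.
#'
#' @param spec A [phantom_spec()].
#' @param lesion Optional [lesion_spec()].
#' @param seed Integer seed; identical (spec, lesion, seed) gives identical
#'   output.
#' @return A `phantom_case`: `$case` ([hta_case()]) plus `$truth` (true
#'   torsion, true axis angle, lesion geometry in output coordinates).
#' @export
generate_case <- function(spec, lesion = NULL, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(lesion)) stopifnot(inherits(lesion, "lesion_spec"))
  set.seed(as.integer(seed))
  phi <- spec$epi_angle + spec$theta_true        # true head-axis direction
  post_limit <- phi + 180 + spec$cartilage_halfspan
  ant_limit <- phi + 180 - spec$cartilage_halfspan

  th <- seq(0, 360, length.out = spec$n_head_pts + 1L)[-(spec$n_head_pts + 1L)]
  head <- tibble::tibble(x = spec$R_head * cos(deg2rad(th)),
                         y = spec$R_head * sin(deg2rad(th)))
  lesion_applied <- FALSE
  if (!is.null(lesion) && lesion$depth_mm > 0) {
    head <- apply_lesion(head, lesion,
                         list(cx = 0, cy = 0, r = spec$R_head),
                         reference_angle_deg = post_limit)
    lesion_applied <- TRUE
  }
  if (spec$sigma_contour > 0) {
    rho <- sqrt(head$x^2 + head$y^2)
    ang <- atan2(head$y, head$x)
    rho <- rho + stats::rnorm(nrow(head), 0, spec$sigma_contour)
    head <- tibble::tibble(x = rho * cos(ang), y = rho * sin(ang))
  }

  ct <- spec$d_offset * c(cos(deg2rad(phi)), sin(deg2rad(phi)))
  cos_dmax <- (spec$R_head^2 - spec$d_offset^2 - spec$r_tub^2) /
    (2 * spec$d_offset * spec$r_tub)
  dmax <- rad2deg(acos(max(-1, min(1, cos_dmax))))
  dd <- seq(-0.95 * dmax, 0.95 * dmax, length.out = spec$n_tub_pts)
  tub_r <- rep(spec$r_tub, spec$n_tub_pts)
  if (spec$sigma_contour > 0) {
    tub_r <- tub_r + stats::rnorm(spec$n_tub_pts, 0, spec$sigma_contour)
  }
  tub <- tibble::tibble(x = ct[1] + tub_r * cos(deg2rad(phi + dd)),
                        y = ct[2] + tub_r * sin(deg2rad(phi + dd)))

  cart_ant <- spec$R_head * c(cos(deg2rad(ant_limit)), sin(deg2rad(ant_limit)))
  cart_post <- spec$R_head * c(cos(deg2rad(post_limit)), sin(deg2rad(post_limit)))
  e0 <- c(0, -150)
  u <- c(cos(deg2rad(spec$epi_angle)), sin(deg2rad(spec$epi_angle)))
  epi_med <- e0 - 30 * u
  epi_lat <- e0 + 30 * u

  mirror <- identical(spec$side, "left")
  flip <- function(p) { p[2] <- -p[2]; p }
  if (mirror) {
    head$y <- -head$y
    tub$y <- -tub$y
    cart_ant <- flip(cart_ant); cart_post <- flip(cart_post)
    epi_med <- flip(epi_med); epi_lat <- flip(epi_lat)
  }
  sgn <- if (mirror) -1 else 1

  case <- hta_case(
    case_id = sprintf("phantom-%d", as.integer(seed)),
    side = spec$side,
    head_contour = head, tubercle_contour = tub,
    cartilage_ant = cart_ant, cartilage_post = cart_post,
    epicondyle_medial = epi_med, epicondyle_lateral = epi_lat,
    group = "stable", hill_sachs = lesion_applied
  )
  structure(
    list(
      case = case,
      truth = list(
        theta_true = spec$theta_true,
        true_axis_angle_deg = wrap_axis_angle(sgn * phi),
        lesion_applied = lesion_applied,
        head_centre = c(0, 0), R_head = spec$R_head,
        post_limit_angle_deg = sgn * post_limit,
        ant_limit_angle_deg = sgn * ant_limit,
        lesion_centre_angle_deg = if (lesion_applied)
          sgn * (post_limit + lesion$center_angle_deg) else NA_real_,
        lesion_halfwidth_deg = if (lesion_applied) lesion$halfwidth_deg else NA_real_,
        side = spec$side
      ),
      spec = spec, lesion = lesion, seed = as.integer(seed)
    ),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> theta_true = %g deg, %s%s, seed %d\n",
              x$truth$theta_true, x$truth$side,
              if (x$truth$lesion_applied) ", lesioned" else "", x$seed))
  invisible(x)
}

#' Simulate one rater's observation of a phantom case
#'
#' Returns a perturbed copy of the case as a rater would digitise it: if a
#' lesion covers the posterior cartilage limit the landmark is first
#' relocated per the rater's `lesion_rule`, then all landmarks receive
#' isotropic Gaussian jitter and contour points receive the extra per-point
#' pick jitter.
#'
#' @param phantom A `phantom_case` from [generate_case()].
#' @param rater A [rater_model()].
#' @param seed Integer seed for the observation noise.
#' @return An [hta_case()] ready for [measure_case()].
#' @export
observe_case <- function(phantom, rater, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_case"), inherits(rater, "rater_model"))
  set.seed(as.integer(seed))
  case <- phantom$case
  tr <- phantom$truth
  cart_post <- case$cartilage_post
  if (tr$lesion_applied &&
      circ_dist(tr$post_limit_angle_deg, tr$lesion_centre_angle_deg) <=
        tr$lesion_halfwidth_deg) {
    hc <- tr$head_centre
    ang <- rad2deg(atan2(case$head_contour$y - hc[2],
                         case$head_contour$x - hc[1]))
    d_les <- circ_dist(ang, tr$lesion_centre_angle_deg)
    if (rater$lesion_rule == "nearest_intact") {
      intact <- which(d_les > tr$lesion_halfwidth_deg)
      dist_lm <- (case$head_contour$x[intact] - cart_post[1])^2 +
        (case$head_contour$y[intact] - cart_post[2])^2
      k <- intact[which.min(dist_lm)]
    } else {
      k <- which.min(d_les)
    }
    cart_post <- c(case$head_contour$x[k], case$head_contour$y[k])
  }
  jit_pt <- function(p) p + stats::rnorm(2, 0, rater$sigma_landmark_mm)
  jit_rows <- function(m) m + matrix(
    stats::rnorm(length(m), 0, rater$sigma_landmark_mm), nrow(m), 2)
  jit_contour <- function(ct) {
    if (rater$sigma_contour_pick_mm == 0) return(ct)
    dplyr::mutate(
      ct,
      x = .data$x + stats::rnorm(dplyr::n(), 0, rater$sigma_contour_pick_mm),
      y = .data$y + stats::rnorm(dplyr::n(), 0, rater$sigma_contour_pick_mm))
  }
  hta_case(
    case_id = case$case_id, side = case$side,
    head_contour = jit_contour(case$head_contour),
    tubercle_contour = jit_contour(case$tubercle_contour),
    cartilage_ant = jit_pt(case$cartilage_ant),
    cartilage_post = jit_pt(cart_post),
    epicondyle_medial = jit_rows(case$epicondyle_medial),
    epicondyle_lateral = jit_rows(case$epicondyle_lateral),
    group = case$group, hill_sachs = case$hill_sachs
  )
}
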