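# The two head-axis constructions, the epicondylar axis, and the HTA sign
# conventions.

rot_pts <- function(pts, ang_deg, about = c(0, 0)) {
  a <- ang_deg * pi / 180
  tibble::tibble(
    x = about[1] + (pts$x - about[1]) * cos(a) - (pts$y - about[2]) * sin(a),
    y = about[2] + (pts$x - about[1]) * sin(a) + (pts$y - about[2]) * cos(a)
  )
}
rot_pt <- function(p, ang_deg) as.numeric(rot_pts(tibble::tibble(x = p[1], y = p[2]), ang_deg))

test_that("circle-method axis runs through the two fitted centres", {
  head <- circle_points(40, cx = 0, cy = 0, r = 25)
  tub <- circle_points(15, cx = 30, cy = 0, r = 10, arc_deg = 120,
                       start_deg = -60)
  ax <- circle_method_axis(head, tub)
  expect_equal(ax$axis$angle_deg, 0, tolerance = 1e-9)
  expect_s3_class(ax$head_fit, "circle_fit")
  expect_equal(ax$tubercle_fit$r, 10, tolerance = 1e-6)

  ax25 <- circle_method_axis(rot_pts(head, 25), rot_pts(tub, 25))
  expect_equal(ax25$axis$angle_deg, 25, tolerance = 1e-9)
})

test_that("robust circle-method axis shrugs off a head indentation", {
  spec <- phantom_spec(theta_true = 20, sigma_contour = 0, n_head_pts = 72)
  les <- lesion_spec(halfwidth_deg = 15, depth_mm = 3)
  ph <- generate_case(spec, les, seed = 4)
  ax <- circle_method_axis(ph$case$head_contour, ph$case$tubercle_contour,
                           robust = TRUE, inlier_threshold = 1)
  # reference: fit on the intact points only
  hc <- ph$case$head_contour
  ang <- atan2(hc$y, hc$x) * 180 / pi
  d <- abs((ang - ph$truth$lesion_centre_angle_deg) %% 360)
  intact <- pmin(d, 360 - d) > les$halfwidth_deg
  ref <- circle_method_axis(hc[intact, ], ph$case$tubercle_contour)
  expect_equal(ax$axis$angle_deg, ref$axis$angle_deg, tolerance = 1)
  expect_equal(ax$axis$angle_deg, 20, tolerance = 1)
})

test_that("bg axis is the perpendicular of the cartilage chord", {
  ax <- bg_axis(c(0, 10), c(0, -10))
  expect_equal(ax$axis$angle_deg, 0, tolerance = 1e-12)
  expect_null(ax$head_fit)

  a25 <- bg_axis(rot_pt(c(0, 10), 25), rot_pt(c(0, -10), 25))
  expect_equal(a25$axis$angle_deg, 25, tolerance = 1e-9)

  # head_reference moves the anchor, never the angle
  with_ref <- bg_axis(c(0, 10), c(0, -10), head_reference = c(4, 4))
  expect_equal(with_ref$axis$angle_deg, ax$axis$angle_deg)
  expect_equal(unname(with_ref$axis$anchor), c(4, 4))

  # symmetric cartilage arc about the true axis: exact recovery
  ph <- generate_case(phantom_spec(theta_true = 37, sigma_contour = 0), seed = 2)
  bx <- bg_axis(ph$case$cartilage_ant, ph$case$cartilage_post)
  expect_equal(bx$axis$angle_deg, ph$truth$true_axis_angle_deg,
               tolerance = 1e-9)

  expect_error(bg_axis(c(1, 1), c(1, 1)), class = "circlehta_error_degenerate")
})

test_that("epicondylar axis handles single and serial landmark pairs", {
  expect_equal(epicondylar_axis(c(0, 0), c(50, 0))$angle_deg, 0)
  expect_equal(epicondylar_axis(c(0, 0), c(50, 10))$angle_deg,
               atan2(10, 50) * 180 / pi, tolerance = 1e-9)
  # serial sections: circular mean of doubled angles
  med <- rbind(c(0, 0), c(0, 1), c(1, 0))
  lat <- rbind(c(50, 5), c(50, -2), c(51, 4))
  ax <- epicondylar_axis(med, lat)
  d <- lat - med
  ang <- atan2(d[, 2], d[, 1])
  direct <- atan2(mean(sin(2 * ang)), mean(cos(2 * ang))) / 2 * 180 / pi
  expect_equal(ax$angle_deg, direct, tolerance = 1e-9)
  expect_error(epicondylar_axis(c(2, 3), c(2, 3)),
               class = "circlehta_error_degenerate")
})

test_that("compute_hta applies the retrotorsion sign and side normalisation", {
  epi <- axis_through(c(0, 0), c(1, 0))
  head0 <- bg_axis(c(0, 10), c(0, -10))
  expect_equal(compute_hta(head0, epi, "right")$hta_deg, 0)

  ph <- generate_case(phantom_spec(theta_true = 25, sigma_contour = 0), seed = 1)
  res <- measure_case(ph$case)
  expect_equal(res$hta_deg, c(25, 25), tolerance = 1e-9)

  # identical geometry flagged left flips the sign ...
  head25 <- bg_axis(rot_pt(c(0, 10), 25), rot_pt(c(0, -10), 25))
  expect_equal(compute_hta(head25, epi, "left")$hta_deg,
               -compute_hta(head25, epi, "right")$hta_deg)
  # ... while mirrored coordinates flagged left restore the original value
  mirr <- bg_axis(rot_pt(c(0, 10), -25), rot_pt(c(0, -10), -25))
  expect_equal(compute_hta(mirr, epi, "left")$hta_deg,
               compute_hta(head25, epi, "right")$hta_deg, tolerance = 1e-9)
})

test_that("left-sided phantoms recover the same retrotorsion", {
  for (th in c(-40, 10, 60)) {
    phr <- generate_case(phantom_spec(theta_true = th, sigma_contour = 0,
                                      side = "right"), seed = 3)
    phl <- generate_case(phantom_spec(theta_true = th, sigma_contour = 0,
                                      side = "left"), seed = 3)
    expect_equal(measure_case(phr$case)$hta_deg, c(th, th), tolerance = 1e-8)
    expect_equal(measure_case(phl$case)$hta_deg, c(th, th), tolerance = 1e-8)
  }
})

test_that("HTA is invariant under global rotation and scaling of a case", {
  ph <- generate_case(phantom_spec(theta_true = 33, sigma_contour = 0.2),
                      seed = 9)
  base <- measure_case(ph$case)
  rot_case <- function(case, ang) {
    hta_case(case$case_id, case$side,
             rot_pts(case$head_contour, ang), rot_pts(case$tubercle_contour, ang),
             rot_pt(case$cartilage_ant, ang), rot_pt(case$cartilage_post, ang),
             as.matrix(rot_pts(tibble::as_tibble(as.data.frame(case$epicondyle_medial)), ang)),
             as.matrix(rot_pts(tibble::as_tibble(as.data.frame(case$epicondyle_lateral)), ang)),
             case$group, case$hill_sachs)
  }
  for (ang in c(18, -47)) {
    r <- measure_case(rot_case(ph$case, ang))
    expect_equal(r$hta_deg, base$hta_deg, tolerance = 1e-7)
  }
  scale_case <- function(case, s) {
    sc <- function(p) p * s
    hta_case(case$case_id, case$side,
             dplyr::mutate(case$head_contour, x = x * s, y = y * s),
             dplyr::mutate(case$tubercle_contour, x = x * s, y = y * s),
             sc(case$cartilage_ant), sc(case$cartilage_post),
             case$epicondyle_medial * s, case$epicondyle_lateral * s,
             case$group, case$hill_sachs)
  }
  r <- measure_case(scale_case(ph$case, 3))
  expect_equal(r$hta_deg, base$hta_deg, tolerance = 1e-7)
})

test_that("measure_case records per-method errors and keeps counting straight", {
  ph <- generate_case(phantom_spec(sigma_contour = 0), seed = 1)
  case <- ph$case
  broken <- hta_case(case$case_id, case$side, case$head_contour,
                     case$tubercle_contour, NULL, NULL,
                     case$epicondyle_medial, case$epicondyle_lateral)
  res <- measure_case(broken, methods = c("circle", "bg"))
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$hta_deg[res$method == "bg"]))
  expect_match(res$error[res$method == "bg"], "cartilage")
  expect_false(is.na(res$hta_deg[res$method == "circle"]))

  many <- dplyr::bind_rows(lapply(1:67, function(i) {
    measure_case(generate_case(phantom_spec(sigma_contour = 0), seed = i)$case)
  }))
  expect_equal(nrow(many), 134)
})
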