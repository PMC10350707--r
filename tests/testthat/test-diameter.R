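test_that("frames on an axial straight line are the canonical basis", {
  cl <- centerline(cbind(0, 0, seq(0, 95)))
  fr <- frames_along_centerline(cl)
  expect_equal(nrow(fr), 10)  # levels at 0..90 mm
  expect_equal(fr$position, seq(0, 90, by = 10), tolerance = 1e-9)
  expect_equal(unlist(fr[, c("tx", "ty", "tz")]),
               rep(c(0, 0, 1), each = 10), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(unlist(fr[, c("e1x", "e1y", "e1z")]),
               rep(c(1, 0, 0), each = 10), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(unlist(fr[, c("e2x", "e2y", "e2z")]),
               rep(c(0, 1, 0), each = 10), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("transported frames stay orthonormal and never flip on a planar arc", {
  cl <- resample_centerline(arc_centerline(40, pi))
  fr <- frames_along_centerline(cl, step = 5)
  for (i in seq_len(nrow(fr))) {
    t <- unlist(fr[i, c("tx", "ty", "tz")])
    e1 <- unlist(fr[i, c("e1x", "e1y", "e1z")])
    e2 <- unlist(fr[i, c("e2x", "e2y", "e2z")])
    expect_equal(c(sum(t^2), sum(e1^2), sum(e2^2)), c(1, 1, 1),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_lt(abs(sum(t * e1)), 1e-9)
    expect_lt(abs(sum(e1 * e2)), 1e-9)
    # right-handed: t x e1 = e2
    cx <- c(t[2] * e1[3] - t[3] * e1[2], t[3] * e1[1] - t[1] * e1[3],
            t[1] * e1[2] - t[2] * e1[1])
    expect_equal(cx, e2, tolerance = 1e-9, ignore_attr = TRUE)
  }
  e1m <- as.matrix(fr[, c("e1x", "e1y", "e1z")])
  dots <- rowSums(e1m[-1, ] * e1m[-nrow(e1m), ])
  expect_true(all(dots > 0.99))
})

cyl15 <- make_phantom(phantom_spec("straight", r = 15, length = 95, spacing = 3),
                      with_fields = FALSE)

test_that("a circular cylinder measures 30 mm in every direction and level", {
  dp <- diameter_pairs(cyl15$mesh, cyl15$centerline,
                       from_mark = "stent_start", to_mark = "stent_end")
  expect_true(all(dp$ok))
  expect_true(all(c("stented", "downstream") %in% dp$segment))
  expect_equal(dp$d1, rep(30, nrow(dp)), tolerance = 0.1 / 30)
  expect_equal(dp$d2, rep(30, nrow(dp)), tolerance = 0.1 / 30)
  expect_equal(dp$mean, (dp$d1 + dp$d2) / 2, tolerance = 1e-12)
  expect_true(all(dp$spread_lo <= pmin(dp$d1, dp$d2) + 1e-12))

  # in-plane rotation invariance of a circular section
  dp_rot <- diameter_pairs(cyl15$mesh, cyl15$centerline,
                           from_mark = "stent_start", to_mark = "stent_end",
                           seed_direction = c(0.6, 0.8, 0))
  expect_equal(dp_rot$mean, dp$mean, tolerance = 0.005)
})

test_that("offset ray origins still measure the full chord through a diameter direction", {
  fr <- frames_along_centerline(cyl15$centerline)
  o <- c(5, 0, unlist(fr[5, "position"]))  # 5 mm off-axis along e1
  r1 <- ray_diameter(cyl15$mesh, o, c(1, 0, 0))
  # analytic: hits at x = -15 and x = +15 -> chord 30, asymmetric about o
  expect_equal(r1$diameter, 30, tolerance = 0.1 / 30)
  expect_equal(sort(r1$boundary[, 1]), c(-15, 15), tolerance = 0.02)
})

test_that("an elliptical cylinder yields the two semi-axis diameters", {
  ell <- make_phantom(phantom_spec("straight", r = 20, r2 = 15, length = 60,
                                   spacing = 3), with_fields = FALSE)
  dp <- diameter_pairs(ell$mesh, ell$centerline,
                       from_mark = "stent_start", to_mark = "stent_end")
  expect_equal(dp$d1, rep(40, nrow(dp)), tolerance = 0.1 / 40)
  expect_equal(dp$d2, rep(30, nrow(dp)), tolerance = 0.1 / 30)
  expect_equal(dp$mean, rep(35, nrow(dp)), tolerance = 0.1 / 35)
  expect_equal(dp$spread_lo, dp$d2, tolerance = 1e-12)
  expect_equal(dp$spread_hi, dp$d1, tolerance = 1e-12)

  # convexity: no measured diameter exceeds the maximal width (dense sweep)
  phis <- seq(0, pi, length.out = 181)
  widths <- 2 * sqrt((20 * cos(phis))^2 + (15 * sin(phis))^2)
  expect_true(all(c(dp$d1, dp$d2) <= max(widths) + 0.01))
})

test_that("a curved (torus-arc) tube still cuts circular cross-sections", {
  arc <- make_phantom(phantom_spec("arc", Rc = 40, r = 15, angle = pi,
                                   spacing = 3), with_fields = FALSE)
  dp <- diameter_pairs(arc$mesh, arc$centerline,
                       from_mark = "stent_start", to_mark = "stent_end")
  expect_true(all(dp$ok))
  expect_equal(dp$d1, rep(30, nrow(dp)), tolerance = 0.01)
  expect_equal(dp$d2, rep(30, nrow(dp)), tolerance = 0.01)
})

test_that("open surfaces are flagged and excluded, not fabricated", {
  tri <- surface_mesh(rbind(c(0, -30, -30), c(0, 30, -30), c(0, 0, 60)),
                      matrix(1:3, 1))
  r <- ray_diameter(tri, c(-5, 0, 0), c(0, 1, 0))
  expect_true(is.na(r$diameter))
  expect_identical(r$reason, "open surface")

  cl <- centerline(cbind(-5, 0, seq(-20, 20)))
  expect_warning(dp <- diameter_pairs(tri, cl, step = 10), "open surface")
  expect_true(all(!dp$ok))
})

test_that("mask-based diameters agree with mesh-based ones within a voxel diagonal", {
  ph <- make_phantom(phantom_spec("straight", r = 15, length = 40, spacing = 3,
                                  mask_spacing = 0.75),
                     with_mask = TRUE, with_fields = FALSE)
  fr <- frames_along_centerline(ph$centerline)
  o <- c(0, 0, 20)
  m1 <- ray_diameter(ph$mask, o, c(1, 0, 0))
  m2 <- ray_diameter(ph$mesh, o, c(1, 0, 0))
  expect_lt(abs(m1$diameter - m2$diameter), 0.75 * sqrt(3))
  expect_equal(m1$diameter, 30, tolerance = 1.3 / 30)
})

test_that("pulsatile diameter change recovers radial pulsation and rigid nulls", {
  # radial pulsation dr = 0.4 mm on a cylinder
  ph <- make_phantom(phantom_spec("straight", r = 15, length = 50, spacing = 2,
                                  radial = 0.4))
  dp <- pulsatile_diameter_change(
    diameter_pairs(ph$mesh, ph$centerline, from_mark = "stent_start",
                   to_mark = "stent_end", n_native = 0), ph$fields)
  expected <- 2 * 0.4 * (max(w_phases) - min(w_phases))  # 1.5217 mm
  expect_equal(expected, 1.522, tolerance = 1e-3)
  expect_equal(dp$diameter_change, rep(expected, nrow(dp)), tolerance = 0.05)
  # per-phase means present and consistent
  expect_true(all(vapply(dp$phase_mean, length, integer(1)) == 10))

  # zero fields: no change at all
  hdr <- ph$fields$fields[[1]]$header
  dp0 <- pulsatile_diameter_change(
    diameter_pairs(ph$mesh, ph$centerline, from_mark = "stent_start",
                   to_mark = "stent_end", n_native = 0),
    translation_set(matrix(0, 10, 3), hdr))
  expect_equal(dp0$diameter_change, rep(0, nrow(dp0)), tolerance = 1e-12)

  # rigid translation preserves every distance
  rig <- translation_set(cbind(w_phases, 2 * w_phases, -w_phases), hdr)
  dpr <- pulsatile_diameter_change(
    diameter_pairs(ph$mesh, ph$centerline, from_mark = "stent_start",
                   to_mark = "stent_end", n_native = 0), rig)
  expect_equal(dpr$diameter_change, rep(0, nrow(dpr)), tolerance = 1e-9)
})
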