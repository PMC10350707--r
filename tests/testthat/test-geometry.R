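test_that("resampling yields 1 mm spacing, keeps endpoints and remaps marks", {
  cl <- resample_centerline(cbind(c(0, 10), 0, 0))
  expect_equal(nrow(cl$points), 11)
  expect_equal(cl$points[, 1], 0:10, tolerance = 1e-12)

  # quarter circle R = 40: length 20*pi = 62.83 mm
  th <- seq(0, pi / 2, length.out = 500)
  q <- resample_centerline(cbind(40 * cos(th), 40 * sin(th), 0))
  expect_equal(nrow(q$points), 64)  # 0..62 at 1 mm plus the kept endpoint
  expect_equal(arc_length(q), 20 * pi, tolerance = 20 * pi * 1e-3)

  # random smooth polyline: all gaps in [0.9, 1.1] mm except possibly the last
  set.seed(21)
  turn <- cumsum(rnorm(40, sd = 0.15))
  pitch <- cumsum(rnorm(40, sd = 0.1))
  steps <- 2 * cbind(cos(turn) * cos(pitch), sin(turn) * cos(pitch), sin(pitch))
  raw <- apply(steps, 2, cumsum)
  rs <- resample_centerline(raw)
  gaps <- sqrt(rowSums(diff(rs$points)^2))
  expect_true(all(gaps[-length(gaps)] >= 0.9 & gaps[-length(gaps)] <= 1.1))
  expect_lte(gaps[length(gaps)], 1 + 1e-9)

  # marks follow their arc position
  marked <- centerline(cbind(seq(0, 20, by = 2), 0, 0),
                       marks = c(stent_start = 3L))
  rs2 <- resample_centerline(marked)
  expect_equal(unname(rs2$marks["stent_start"]), 5L)  # was at x = 4 mm

  # degenerate input: all points coincident
  expect_error(suppressWarnings(
    centerline(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)))), "distinct")
  tiny <- structure(list(points = rbind(c(0, 0, 0), c(0, 0, 0)),
                         marks = integer(0)), class = "centerline")
  expect_error(resample_centerline(tiny), "zero total length")
})

test_that("Savitzky-Golay fit is exact on polynomials up to its order, boundaries included", {
  n <- 80
  s <- seq_len(n) - 1
  coefs <- rbind(c(2, -1, 0.5), c(0.3, 1, -0.2), c(-0.01, 0.02, 0.005),
                 c(2e-4, -1e-4, 5e-5), c(-1e-6, 2e-6, 1e-6))
  pts <- cbind(1, s, s^2, s^3, s^4) %*% coefs
  d <- sg_derivatives(centerline(pts))
  d1_true <- cbind(0, 1, 2 * s, 3 * s^2, 4 * s^3) %*% coefs
  d2_true <- cbind(0, 0, 2, 6 * s, 12 * s^2) %*% coefs
  expect_equal(d$smoothed, pts, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(d$d1, d1_true, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(d$d2, d2_true, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("smoothing suppresses noise-born second derivatives on a straight line", {
  n <- 200
  means <- vapply(1:5, function(seed) {
    cl <- add_noise(line_centerline(n - 1), sd = 0.2, seed = seed)
    mean(sg_derivatives(cl)$d2[, 2])
  }, numeric(1))
  expect_true(all(abs(means) < 3 * 0.2 / sqrt(n)))
})

test_that("circle derivatives match the closed form at interior points", {
  R <- 40
  cl <- arc_centerline(R, pi)
  d <- sg_derivatives(cl)
  interior <- 17:(nrow(cl$points) - 16)
  speed <- sqrt(rowSums(d$d1^2))[interior]
  accel <- sqrt(rowSums(d$d2^2))[interior]
  expect_equal(speed, rep(1, length(interior)), tolerance = 0.01)
  expect_equal(accel, rep(1 / R, length(interior)), tolerance = 0.01)
})

test_that("curvature recovers straight lines, circles and helices", {
  expect_equal(curvature(sg_derivatives(line_centerline(80)))$kappa,
               rep(0, 81), tolerance = 1e-9)

  kap <- curvature(sg_derivatives(arc_centerline(40, pi)))$kappa
  interior <- 17:(length(kap) - 16)
  expect_equal(kap[interior], rep(25, length(interior)), tolerance = 0.01)

  # helix radius 20, pitch parameter 5: kappa = 20/(20^2+5^2) mm^-1
  R <- 20; cp <- 5
  w <- 1 / sqrt(R^2 + cp^2)
  s <- seq(0, 150)
  hel <- centerline(cbind(R * cos(w * s), R * sin(w * s), cp * w * s))
  kh <- curvature(sg_derivatives(hel))$kappa
  interior <- 17:(length(kh) - 16)
  expect_equal(kh[interior], rep(1000 * R / (R^2 + cp^2), length(interior)),
               tolerance = 0.01)
  expect_equal(1000 * R / (R^2 + cp^2), 47.06, tolerance = 1e-4)
})

test_that("degenerate tangents are flagged, not propagated", {
  pts <- cbind(c(seq(0, 5), seq(4, 0)), 0, 0)  # doubles back: cusp at x = 5
  cl <- centerline(pts)
  d <- sg_derivatives(cl, window = 5, order = 2)
  expect_warning(prof <- curvature(d), "degenerate")
  expect_gte(attr(prof, "n_degenerate"), 1)
  expect_true(any(is.na(prof$kappa)))
  expect_true(all(is.finite(prof$kappa[!is.na(prof$kappa)])))
})

test_that("short centerlines shrink the window with a warning; tiny ones error", {
  cl <- centerline(cbind(seq(0, 20), 0.01 * seq(0, 20)^2, 0))
  expect_warning(d <- sg_derivatives(cl), "shrunk to 21")
  expect_equal(d$window, 21)
  expect_error(sg_derivatives(centerline(cbind(0:3, 0, 0))), "at least 5")
  expect_error(sg_derivatives(cl, window = 34), "odd")
  expect_error(sg_derivatives(cl, order = 33, window = 33), "order")
})

test_that("arc length and tortuosity match closed forms and each other", {
  cl <- centerline(cbind(0:10, 0, 0))
  expect_equal(arc_length(cl), 10)
  expect_equal(tortuosity_index(cl), 1, tolerance = 1e-12)

  semi <- arc_centerline(30, pi)
  expect_equal(arc_length(semi), pi * 30, tolerance = pi * 30 * 1e-3)
  expect_equal(tortuosity_index(semi), pi / 2, tolerance = pi / 2 * 1e-3)

  # marked sub-segment: 10%..90% of samples covers 80% of the arc
  n <- nrow(semi$points)
  marked <- centerline(semi$points,
                       marks = c(stent_start = as.integer(round(0.1 * (n - 1)) + 1),
                                 stent_end = as.integer(round(0.9 * (n - 1)) + 1)))
  i <- marked$marks[["stent_start"]]; j <- marked$marks[["stent_end"]]
  frac <- (j - i) / (n - 1)
  expect_equal(arc_length(marked, "stent_start", "stent_end"),
               frac * pi * 30, tolerance = 1e-3)
  expect_equal(frac, 0.8, tolerance = 0.02)
  expect_error(arc_length(marked, "nope", "stent_end"), "known marks")

  # TI * chord = length identity
  ti <- tortuosity_index(marked, "stent_start", "stent_end")
  i <- marked$marks[["stent_start"]]; j <- marked$marks[["stent_end"]]
  chord <- sqrt(sum((marked$points[j, ] - marked$points[i, ])^2))
  expect_equal(ti * chord, arc_length(marked, "stent_start", "stent_end"),
               tolerance = 1e-9)

  loop <- centerline(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0)))
  expect_error(tortuosity_index(loop), "coincide")
})

test_that("curvature is rigid-motion invariant; scaling behaves as 1/s", {
  cl <- arc_centerline(40, pi)
  kap <- curvature(sg_derivatives(cl))$kappa
  # rotate + translate
  ang <- 0.7
  Rm <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  moved <- centerline(sweep(cl$points %*% t(Rm), 2, c(5, -3, 8), `+`))
  kap2 <- curvature(sg_derivatives(moved))$kappa
  expect_equal(kap2, kap, tolerance = 1e-3)

  # scale by s = 2: kappa halves, length doubles, TI unchanged (resampled)
  scaled <- resample_centerline(centerline(2 * cl$points))
  kap_s <- curvature(sg_derivatives(scaled))$kappa
  interior <- 33:(length(kap_s) - 32)
  expect_equal(kap_s[interior], rep(12.5, length(interior)), tolerance = 0.01)
  expect_equal(arc_length(scaled), 2 * arc_length(cl), tolerance = 0.01)
  expect_equal(tortuosity_index(scaled), tortuosity_index(cl), tolerance = 1e-3)
})

test_that("TI equals 1 only for collinear points", {
  expect_equal(tortuosity_index(line_centerline(30)), 1, tolerance = 1e-9)
  bent <- centerline(rbind(c(0, 0, 0), c(5, 0.5, 0), c(10, 0, 0)))
  expect_gt(tortuosity_index(bent), 1 + 1e-6)
})

test_that("phase translation copies geometry under zero and rigid fields", {
  cl <- resample_centerline(arc_centerline(25, pi * 0.8))
  hdr <- volume_header(origin = c(-35, -10, -8), spacing = c(2, 2, 2),
                       size = c(36, 25, 9))
  zero <- translation_set(matrix(0, 10, 3), hdr)
  phases <- translate_centerline_to_phases(cl, zero)
  expect_length(phases, 10)
  for (k in 1:10) expect_equal(phases[[k]]$points, cl$points, tolerance = 1e-12)

  vecs <- cbind(2 * w_phases, -w_phases, 0.5 * w_phases)
  rigid <- translation_set(vecs, hdr)
  phases <- translate_centerline_to_phases(cl, rigid)
  kap0 <- curvature(sg_derivatives(cl))$kappa
  for (k in c(1, 4, 8)) {
    expect_equal(phases[[k]]$points, sweep(cl$points, 2, vecs[k, ], `+`),
                 tolerance = 1e-9)
    expect_equal(curvature(sg_derivatives(phases[[k]]))$kappa, kap0,
                 tolerance = 1e-9)
  }
  dyn <- dynamic_changes(phases)
  expect_equal(dyn$length_change, 0, tolerance = 1e-9)
  expect_equal(dyn$TI_change, 0, tolerance = 1e-9)
  expect_equal(dyn$mean_curvature_change, 0, tolerance = 1e-9)
  expect_equal(dyn$max_curvature_change, 0, tolerance = 1e-9)
})

test_that("bending phantom curvature oscillation is recovered through the fields", {
  dk <- 2  # m^-1 curvature oscillation amplitude
  spec <- phantom_spec("arc", Rc = 40, r = 8, angle = pi, spacing = 2,
                       bending = dk)
  ph <- make_phantom(spec)
  cl <- ph$centerline
  phases <- translate_centerline_to_phases(cl, ph$fields)
  # per-phase curvature at the apex matches the oracle within 5%
  kap_phase <- sapply(phases, function(c) {
    k <- curvature(sg_derivatives(c))$kappa
    k[round(length(k) / 2)]
  })
  expect_equal(kap_phase, ph$oracle$kappa_phase, tolerance = 0.05)
  # max curvature change over the segment ~ dk * (max w - min w) within 10%
  dyn <- dynamic_changes(phases, "stent_start", "stent_end")
  expect_equal(dyn$max_curvature_change,
               dk * (max(w_phases) - min(w_phases)), tolerance = 0.1)
})

test_that("geometry_summary combines static and dynamic columns", {
  spec <- phantom_spec("arc", Rc = 40, r = 8, angle = pi, spacing = 2,
                       translation = c(0, 0, 1))
  ph <- make_phantom(spec)
  g <- geometry_summary(ph$centerline, ph$fields, "stent_start", "stent_end")
  expect_equal(g$length, 0.8 * ph$oracle$length, tolerance = 0.01)
  expect_gte(g$TI, 1)
  expect_gte(g$max_curvature, g$mean_curvature)
  expect_equal(g$mean_curvature, 25, tolerance = 0.01)
  # rigid translation: all dynamic changes vanish
  expect_equal(g$length_change, 0, tolerance = 1e-9)
  expect_equal(g$TI_change, 0, tolerance = 1e-9)
  expect_equal(g$mean_curvature_change, 0, tolerance = 1e-9)

  prof <- curvature_change_profile(ph$centerline, ph$fields)
  expect_equal(nrow(prof), nrow(ph$centerline$points))
  expect_true(all(prof$kappa_change < 1e-9))
})
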