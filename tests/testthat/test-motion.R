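test_that("trilinear interpolation reproduces constant and affine fields", {
  f <- const_field(c(1, 0, 0))
  expect_equal(interpolate_displacement(f, c(0.3, -1.7, 2.2)), c(1, 0, 0),
               tolerance = 1e-12)

  # affine displacement: trilinear must be exact anywhere in bounds
  A <- matrix(c(0.01, 0.002, 0, -0.003, 0.02, 0.001, 0, 0.005, -0.01), 3, 3)
  b <- c(0.1, -0.2, 0.05)
  aff <- function(p) sweep(p %*% t(A), 2, b, `+`)
  f <- vector_field_from_function(aff, small_header())
  set.seed(42)
  p <- matrix(runif(60, -4.9, 4.9), ncol = 3)
  expect_equal(interpolate_displacement(f, p), aff(p), tolerance = 1e-9)
})

test_that("off-grid interpolation equals the 8-corner weighted sum", {
  sine_fun <- function(p) cbind(sin(p[, 1] / 3), cos(p[, 2] / 2), sin(p[, 3]))
  hdr <- small_header()
  f <- vector_field_from_function(sine_fun, hdr)
  p <- c(0.37, -1.21, 2.63)
  # independent brute-force oracle: explicit corner positions and weights
  ci <- (p - hdr$origin) / hdr$spacing
  i0 <- floor(ci); fr <- ci - i0
  expected <- c(0, 0, 0)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    corner_world <- hdr$origin + (i0 + c(dx, dy, dz)) * hdr$spacing
    wgt <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
    expected <- expected + wgt * drop(sine_fun(matrix(corner_world, 1)))
  }
  expect_equal(interpolate_displacement(f, p), expected, tolerance = 1e-12)
})

test_that("out-of-bounds queries error with the point and the box", {
  f <- const_field(c(0, 0, 0))
  expect_error(interpolate_displacement(f, c(99, 0, 0)),
               "outside the interpolable box")
  fs <- zero_set()
  expect_error(track_point(fs, c(0, 0, 7)), "phase 0")
})

test_that("tracking adds each phase's displacement to the point", {
  fs <- zero_set()
  tr <- track_point(fs, c(1, 2, 3))
  expect_equal(tr$positions, matrix(rep(c(1, 2, 3), each = 10), 10),
               ignore_attr = TRUE)

  vecs <- cbind(0, 0, 0.1 * (0:9))
  fs <- translation_set(vecs)
  tr <- track_point(fs, c(0, 0, 0))
  expect_equal(tr$positions[, 3], 0.1 * (0:9), tolerance = 1e-12)
})

test_that("amplitudes and pathlength match the enumerated sine closed forms", {
  pos <- cbind(0, 0, w_phases)  # A = 1 mm along z
  tr <- raw_trajectory(pos)
  amp <- motion_amplitudes(tr)
  expect_equal(amp$amplitude_z, max(w_phases) - min(w_phases),
               tolerance = 1e-12)
  expect_equal(amp$amplitude_z, 1.9021, tolerance = 1e-4)
  expect_equal(amp$amplitude_x, 0)
  expect_equal(pathlength(tr, "open"), sum(abs(diff(w_phases))),
               tolerance = 1e-12)
  expect_equal(pathlength(tr, "open"), 3.2166, tolerance = 1e-4)
  expect_equal(pathlength(tr, "cyclic"),
               sum(abs(diff(w_phases))) + abs(w_phases[1] - w_phases[10]),
               tolerance = 1e-12)
  expect_equal(pathlength(tr, "cyclic"), 3.8044, tolerance = 1e-4)

  static <- raw_trajectory(matrix(5, 10, 3))
  expect_equal(unlist(motion_amplitudes(static)), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(pathlength(static, "open"), 0)
  expect_equal(pathlength(static, "cyclic"), 0)
})

test_that("amplitudes are order-free; pathlength closures behave under phase rotation", {
  set.seed(7)
  pos <- matrix(rnorm(30), 10, 3)
  tr <- raw_trajectory(pos)
  perm <- raw_trajectory(pos[sample(10), ])
  expect_equal(motion_amplitudes(tr), motion_amplitudes(perm))

  rot <- raw_trajectory(pos[c(4:10, 1:3), ])
  expect_equal(pathlength(tr, "cyclic"), pathlength(rot, "cyclic"),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pathlength(tr, "open"),
                                pathlength(rot, "open"))))
})

test_that("motion metrics are invariant under global translation and bound each other", {
  set.seed(13)
  for (i in 1:5) {
    pos <- matrix(rnorm(30), 10, 3)
    tr <- raw_trajectory(pos)
    shifted <- raw_trajectory(sweep(pos, 2, c(10, -4, 2.5), `+`))
    expect_equal(motion_amplitudes(tr), motion_amplitudes(shifted),
                 tolerance = 1e-12)
    expect_equal(pathlength(tr, "open"), pathlength(shifted, "open"),
                 tolerance = 1e-12)
    amp <- unlist(motion_amplitudes(tr))
    expect_gte(pathlength(tr, "open"), max(amp) - 1e-12)
  }
  # monotone single-axis motion: pathlength equals the z amplitude
  mono <- raw_trajectory(cbind(0, 0, seq(0, 2, length.out = 10)))
  expect_equal(pathlength(mono, "open"),
               motion_amplitudes(mono)$amplitude_z, tolerance = 1e-12)
})

test_that("sinusoidal motion amplitude is recovered through gridded fields", {
  A <- 1
  spec <- phantom_spec("straight", r = 6, length = 40, spacing = 2,
                       sine_amplitude = c(0, 0, A), sine_wavelength = 60)
  ph <- make_phantom(spec)
  pts <- sample_interior_points(ph, n = 10, seed = 3)
  for (i in seq_len(nrow(pts))) {
    p <- unlist(pts[i, c("x", "y", "z")])
    tr <- track_point(ph$fields, p)
    # local analytic amplitude of the spatial sine at p
    local_amp <- A * abs(sin(2 * pi * unname(p[1] + p[2]) / (sqrt(2) * 60) + 2))
    expected <- local_amp * (max(w_phases) - min(w_phases))
    if (expected > 0.3) {  # avoid near-node points where 5% is sub-micron
      expect_equal(motion_amplitudes(tr)$amplitude_z, expected,
                   tolerance = 0.05)
    }
  }
})

test_that("track_points returns one summary row per labeled point", {
  vecs <- cbind(w_phases, 0, 0.5 * w_phases)
  fs <- translation_set(vecs)
  pts <- tibble::tibble(label = c("a", "b"), x = c(0, 1), y = 0, z = c(0, -2))
  out <- track_points(pts, fs)
  expect_equal(nrow(out), 2)
  expect_equal(out$amplitude_x, rep(max(w_phases) - min(w_phases), 2),
               tolerance = 1e-12)
  expect_equal(out$amplitude_z, rep(0.5 * (max(w_phases) - min(w_phases)), 2),
               tolerance = 1e-12)
  expect_true(all(out$pathlength >= out$amplitude_x))
  out_cyc <- track_points(pts, fs, closure = "cyclic")
  expect_true(all(out_cyc$pathlength > out$pathlength))
})
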