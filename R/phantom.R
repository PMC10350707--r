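#' Analytic vessel phantom specification
#'
#' Defines a tube phantom — an arc (aortic-arch-like), helix or straight
#' cylinder — together with a cardiac motion model sampled at the 10 phase
#' weights `w_k = sin(2 pi k / 10)`, `k = 0..9`. Every derived quantity
#' (centerline, curvature per phase, tortuosity, diameters, point
#' trajectories) has a closed form, so phantoms serve as ground truth for
#' the whole measurement pipeline.
#'
#' The motion model is a sum of independent modes, each scaled by `w_k`:
#' * `translation` — rigid per-phase offset `(Ax, Ay, Az)` mm; leaves all
#'   geometry and diameters unchanged.
#' * `radial` — cross-sectional pulsation: the tube offset from the
#'   centerline is scaled so the surface radius becomes `r + radial * w_k`
#'   (mm at the surface, linear in the offset, zero on the centerline).
#' * `bending` — arc shape only: the arc radius oscillates so that the
#'   per-phase curvature is `1000/Rc + bending * w_k` m^-1, with arc length
#'   along the centerline preserved.
#' * `sine_amplitude` — smooth spatially sinusoidal displacement of
#'   wavelength `sine_wavelength` mm per axis, the regime in which
#'   deformation-field point tracking is validated.
#'
#' @param shape `"arc"`, `"helix"` or `"straight"`.
#' @param Rc centerline radius (arc/helix), mm.
#' @param r tube radius, mm; `r2` the second semi-axis for an elliptical
#'   cross-section (default `r`, circular).
#' @param angle subtended angle (arc/helix winding), rad.
#' @param pitch helix pitch parameter c, mm (climb per unit angle).
#' @param length straight-tube length, mm.
#' @param spacing isotropic field-grid spacing, mm.
#' @param mask_spacing isotropic mask voxel size, mm (default 0.75, between
#'   typical ECG-gated CT in-plane pixel sizes).
#' @param translation,radial,bending,sine_amplitude,sine_wavelength motion
#'   model, see Details.
#' @param noise_sd Gaussian centerline jitter for [add_noise()], mm.
#' @param seed integer seed making phantom randomness reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("arc", "helix", "straight"),
                         Rc = 40, r = 15, r2 = r, angle = pi, pitch = 5,
                         length = 80, spacing = 1.5, mask_spacing = 0.75,
                         translation = c(0, 0, 0), radial = 0, bending = 0,
                         sine_amplitude = c(0, 0, 0), sine_wavelength = 60,
                         noise_sd = 0, seed = 1L) {
  shape <- match.arg(shape)
  if (shape != "straight" && Rc <= r) {
    stop("centerline radius Rc must exceed tube radius r", call. = FALSE)
  }
  if (r <= 0 || r2 <= 0) stop("tube radii must be positive", call. = FALSE)
  if (any(sine_amplitude != 0) && spacing > sine_wavelength / 4) {
    warning("field grid coarser than a quarter wavelength: sinusoidal motion under-resolved",
            call. = FALSE)
  }
  structure(list(shape = shape, Rc = Rc, r = r, r2 = r2, angle = angle,
                 pitch = pitch, length = length, spacing = spacing,
                 mask_spacing = mask_spacing,
                 translation = as.numeric(translation), radial = radial,
                 bending = bending, sine_amplitude = as.numeric(sine_amplitude),
                 sine_wavelength = sine_wavelength,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Cardiac phase weights of the phantom motion model
#'
#' @return `sin(2 pi k / 10)` for phases `k = 0..9`.
#' @export
phase_weights <- function() sin(2 * pi * (0:9) / 10)

# --- closed-form centerline -------------------------------------------------

# Arc-length parameterized centerline point(s); s in mm.
phantom_centerline_point <- function(spec, s) {
  s <- as.numeric(s)
  switch(spec$shape,
    arc = {
      th <- s / spec$Rc
      cbind(spec$Rc * cos(th), spec$Rc * sin(th), 0)
    },
    helix = {
      w <- 1 / sqrt(spec$Rc^2 + spec$pitch^2)
      cbind(spec$Rc * cos(w * s), spec$Rc * sin(w * s), spec$pitch * w * s)
    },
    straight = cbind(0 * s, 0 * s, s)
  )
}

# Frenet frame columns (tangent, normal-ish e1, binormal-ish e2) at arc s.
phantom_frames <- function(spec, s) {
  switch(spec$shape,
    arc = {
      th <- s / spec$Rc
      list(t = cbind(-sin(th), cos(th), 0),
           n = cbind(cos(th), sin(th), 0),
           b = cbind(0 * th, 0 * th, 1 + 0 * th))
    },
    helix = {
      w <- 1 / sqrt(spec$Rc^2 + spec$pitch^2)
      th <- w * s
      tt <- cbind(-spec$Rc * w * sin(th), spec$Rc * w * cos(th),
                  spec$pitch * w + 0 * th)
      nn <- cbind(-cos(th), -sin(th), 0 * th)
      bb <- cbind(tt[, 2] * nn[, 3] - tt[, 3] * nn[, 2],
                  tt[, 3] * nn[, 1] - tt[, 1] * nn[, 3],
                  tt[, 1] * nn[, 2] - tt[, 2] * nn[, 1])
      list(t = tt, n = nn, b = bb)
    },
    straight = {
      o <- 0 * s
      list(t = cbind(o, o, 1 + o), n = cbind(1 + o, o, o), b = cbind(o, 1 + o, o))
    }
  )
}

phantom_total_length <- function(spec) {
  switch(spec$shape,
    arc = spec$Rc * spec$angle,
    helix = spec$angle * sqrt(spec$Rc^2 + spec$pitch^2),
    straight = spec$length)
}

# Polar angle of points about the arc axis, continuous across the arc:
# the atan2 branch cut is moved opposite the arc midpoint so tube points
# just beyond either arc end never jump by 2*pi.
arc_theta <- function(spec, P) {
  mid <- spec$angle / 2
  d <- atan2(P[, 2], P[, 1]) - mid
  d <- d - 2 * pi * round(d / (2 * pi))
  mid + d
}

# Nearest centerline point and in-plane offset for radial pulsation.
phantom_offset <- function(spec, P) {
  switch(spec$shape,
    arc = {
      th <- arc_theta(spec, P)
      th <- pmin(pmax(th, 0), spec$angle)
      cp <- cbind(spec$Rc * cos(th), spec$Rc * sin(th), 0)
      P - cp
    },
    straight = {
      cbind(P[, 1], P[, 2], 0)
    },
    stop("radial pulsation is implemented for arc and straight phantoms only",
         call. = FALSE)
  )
}

#' Analytic per-phase displacement of the phantom motion model
#'
#' Evaluates the exact (non-gridded) motion model at arbitrary world points
#' — the oracle against which field-based tracking is checked. The gridded
#' phase fields of [make_phantom()] are this function sampled at voxel
#' centers.
#'
#' @param spec a [phantom_spec()].
#' @param P world points, `n x 3` mm.
#' @param k phase index 0-9.
#' @return `n x 3` displacement matrix, mm.
#' @export
phantom_displacement <- function(spec, P, k) {
  P <- as_point_matrix(P)
  w <- phase_weights()[k + 1L]
  u <- matrix(0, nrow(P), 3L)
  if (any(spec$translation != 0)) {
    u <- u + matrix(w * spec$translation, nrow(P), 3L, byrow = TRUE)
  }
  if (spec$radial != 0) {
    u <- u + (spec$radial * w / spec$r) * phantom_offset(spec, P)
  }
  if (spec$bending != 0) {
    if (spec$shape != "arc") stop("bending mode requires the arc shape", call. = FALSE)
    kap_k <- 1 / spec$Rc + w * spec$bending / 1000  # mm^-1
    Rk <- 1 / kap_k
    rho <- sqrt(P[, 1]^2 + P[, 2]^2)
    th <- arc_theta(spec, P)
    rho2 <- Rk + (rho - spec$Rc)
    th2 <- th * spec$Rc / Rk
    u <- u + cbind(rho2 * cos(th2) - P[, 1], rho2 * sin(th2) - P[, 2], 0)
  }
  if (any(spec$sine_amplitude != 0)) {
    lam <- spec$sine_wavelength
    s2 <- sqrt(2)
    u <- u + w * cbind(
      spec$sine_amplitude[1] * sin(2 * pi * (P[, 2] + P[, 3]) / (s2 * lam)),
      spec$sine_amplitude[2] * sin(2 * pi * (P[, 1] + P[, 3]) / (s2 * lam) + 1),
      spec$sine_amplitude[3] * sin(2 * pi * (P[, 1] + P[, 2]) / (s2 * lam) + 2))
  }
  u
}

# World-space bounding box that covers tube + motion + one-cell margin.
phantom_grid_header <- function(spec) {
  s <- seq(0, phantom_total_length(spec), length.out = 200)
  cp <- phantom_centerline_point(spec, s)
  rmax <- max(spec$r, spec$r2)
  amax <- sum(abs(spec$translation)) + abs(spec$radial) +
    sum(abs(spec$sine_amplitude)) +
    if (spec$bending != 0) {
      kap <- 1 / spec$Rc + abs(spec$bending) / 1000
      abs(1 / kap - spec$Rc) + spec$Rc * spec$angle * abs(1 - spec$Rc * kap)
    } else 0
  margin <- rmax + amax + 2 * spec$spacing
  lo <- apply(cp, 2L, min) - margin
  hi <- apply(cp, 2L, max) + margin
  size <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  volume_header(origin = lo, spacing = rep(spec$spacing, 3L), size = size)
}

# --- generator ---------------------------------------------------------------

#' Generate an analytic vessel phantom with ground truth
#'
#' Builds everything the measurement pipeline consumes — a 1 mm centerline
#' with stent marks at 10% and 90% of its length, 11 labeled anatomical
#' points (tube-surface and centerline landmarks mimicking an arch with
#' branch vessels), a triangulated tube surface, an optional binary lumen
#' mask, and the 10 per-phase deformation fields — plus an `oracle` list of
#' closed-form reference values.
#'
#' @param spec a [phantom_spec()].
#' @param with_mask rasterize a binary lumen mask (arc/straight, circular
#'   cross-section only).
#' @param with_fields rasterize the 10 per-phase deformation fields
#'   (default `TRUE`; skip for geometry-only phantoms).
#' @param n_circumference circumferential mesh resolution (default 96).
#' @return An object of class `vessel_phantom`: list with `spec`,
#'   `centerline`, `points`, `mesh`, `mask` (or `NULL`), `fields` (or
#'   `NULL`), `oracle`.
#' @export
make_phantom <- function(spec, with_mask = FALSE, with_fields = TRUE,
                         n_circumference = 96L) {
  stopifnot(inherits(spec, "phantom_spec"))
  total <- phantom_total_length(spec)
  s <- seq(0, total, by = 1)
  if (total - s[length(s)] > 1e-9) s <- c(s, total)
  pts <- phantom_centerline_point(spec, s)
  marks <- c(stent_start = which.min(abs(s - 0.1 * total)),
             stent_end = which.min(abs(s - 0.9 * total)))
  cl <- centerline(pts, marks = marks)

  fr <- phantom_frames(spec, s)
  points <- phantom_landmarks(spec, total)
  mesh <- phantom_tube_mesh(spec, s, n_circumference)
  mask <- if (with_mask) phantom_mask(spec) else NULL

  fields <- NULL
  if (with_fields) {
    header <- phantom_grid_header(spec)
    fields <- phase_field_set(lapply(0:9, function(k) {
      vector_field_from_function(function(P) phantom_displacement(spec, P, k),
                                 header)
    }))
  }

  w <- phase_weights()
  kappa0 <- switch(spec$shape,
    arc = 1000 / spec$Rc,
    helix = 1000 * spec$Rc / (spec$Rc^2 + spec$pitch^2),
    straight = 0)
  kappa_phase <- if (spec$shape == "arc" && spec$bending != 0) {
    kappa0 + w * spec$bending
  } else rep(kappa0, 10)
  ti <- switch(spec$shape,
    arc = if (spec$angle > 0) {
      chord <- 2 * spec$Rc * sin(spec$angle / 2)
      (spec$Rc * spec$angle) / chord
    } else NA_real_,
    helix = {
      th <- spec$angle
      chord <- sqrt((spec$Rc * (cos(th) - 1))^2 + (spec$Rc * sin(th))^2 +
                    (spec$pitch * th)^2)
      total / chord
    },
    straight = 1)
  oracle <- list(
    shape = spec$shape,
    length = total,
    TI = ti,
    kappa = kappa0,
    kappa_phase = kappa_phase,
    diameter_d1 = 2 * spec$r,
    diameter_d2 = 2 * spec$r2,
    diameter_change = 2 * spec$radial * (max(w) - min(w)),
    weight_range = max(w) - min(w),
    amplitude = abs(spec$translation) * (max(w) - min(w)),
    pathlength_open = sum(abs(diff(w))) * sqrt(sum(spec$translation^2)),
    pathlength_cyclic = (sum(abs(diff(w))) + abs(w[1] - w[10])) *
      sqrt(sum(spec$translation^2))
  )
  structure(list(spec = spec, centerline = cl, points = points, mesh = mesh,
                 mask = mask, fields = fields, oracle = oracle),
            class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf("<vessel_phantom> %s: length %.1f mm, kappa %.2f m^-1, TI %.4f\n",
              x$spec$shape, x$oracle$length, x$oracle$kappa, x$oracle$TI))
  invisible(x)
}

# 11 labeled landmarks: paired wall points at the proximal end, the apex,
# paired wall points at the distal end, and branch-like points offset from
# the tube, all inside the field grid.
phantom_landmarks <- function(spec, total) {
  fracs <- c(0.05, 0.05, 0.5, 0.95, 0.95, 0.25, 0.25, 0.35, 0.65, 0.65, 0.75)
  offs <- c(0.6, -0.6, 0, 0.6, -0.6, 0.5, -0.5, 0, 0.5, -0.5, 0)
  labels <- c("proximal_ventral", "proximal_dorsal", "apex",
              "distal_ventral", "distal_dorsal",
              "branch1_end_a", "branch1_end_b", "branch1_bifurcation",
              "branch2_end_a", "branch2_end_b", "branch2_bifurcation")
  s <- fracs * total
  cp <- phantom_centerline_point(spec, s)
  fr <- phantom_frames(spec, s)
  p <- cp + (offs * spec$r) * fr$b
  tibble::tibble(label = labels, x = p[, 1], y = p[, 2], z = p[, 3])
}

# Triangulated tube surface with end caps; rings at the 1 mm samples.
phantom_tube_mesh <- function(spec, s, m = 96L) {
  cp <- phantom_centerline_point(spec, s)
  fr <- phantom_frames(spec, s)
  phi <- 2 * pi * (seq_len(m) - 1L) / m
  nring <- length(s)
  verts <- matrix(NA_real_, nring * m + 2L, 3L)
  for (i in seq_len(nring)) {
    ring <- cp[rep(i, m), ] +
      outer(spec$r * cos(phi), fr$n[i, ]) + outer(spec$r2 * sin(phi), fr$b[i, ])
    verts[((i - 1L) * m + 1L):(i * m), ] <- ring
  }
  cap1 <- nring * m + 1L
  cap2 <- nring * m + 2L
  verts[cap1, ] <- cp[1, ]
  verts[cap2, ] <- cp[nring, ]
  faces <- vector("list", nring - 1L + 2L)
  for (i in seq_len(nring - 1L)) {
    a <- (i - 1L) * m + seq_len(m)
    b <- (i - 1L) * m + c(seq_len(m)[-1L], 1L)
    c2 <- i * m + seq_len(m)
    d <- i * m + c(seq_len(m)[-1L], 1L)
    faces[[i]] <- rbind(cbind(a, b, c2), cbind(b, d, c2))
  }
  first <- seq_len(m)
  faces[[nring]] <- cbind(first, rep(cap1, m), c(first[-1L], first[1L]))
  last <- (nring - 1L) * m + seq_len(m)
  faces[[nring + 1L]] <- cbind(last, c(last[-1L], last[1L]), rep(cap2, m))
  surface_mesh(verts, do.call(rbind, faces))
}

# Binary lumen mask from the analytic distance to the centerline.
phantom_mask <- function(spec) {
  if (!spec$shape %in% c("arc", "straight") || spec$r != spec$r2) {
    stop("analytic mask rasterization supports circular arc/straight tubes",
         call. = FALSE)
  }
  s <- seq(0, phantom_total_length(spec), length.out = 100)
  cp <- phantom_centerline_point(spec, s)
  margin <- spec$r + 2 * spec$mask_spacing
  lo <- apply(cp, 2L, min) - margin
  hi <- apply(cp, 2L, max) + margin
  size <- as.integer(ceiling((hi - lo) / spec$mask_spacing)) + 1L
  header <- volume_header(origin = lo, spacing = rep(spec$mask_spacing, 3L),
                          size = size)
  idx <- as.matrix(expand.grid(i = seq_len(size[1]) - 1L,
                               j = seq_len(size[2]) - 1L,
                               k = seq_len(size[3]) - 1L))
  P <- index_to_world(header, idx)
  d2 <- if (spec$shape == "straight") {
    zc <- pmin(pmax(P[, 3], 0), spec$length)
    P[, 1]^2 + P[, 2]^2 + (P[, 3] - zc)^2
  } else {
    th <- pmin(pmax(atan2(P[, 2], P[, 1]), 0), spec$angle)
    rho <- sqrt(P[, 1]^2 + P[, 2]^2)
    cpx <- spec$Rc * cos(th)
    cpy <- spec$Rc * sin(th)
    (P[, 1] - cpx)^2 + (P[, 2] - cpy)^2 + P[, 3]^2
  }
  lumen_mask(array(as.numeric(d2 <= spec$r^2), dim = size), header)
}

#' Add reproducible Gaussian jitter to a centerline
#'
#' Independent normal noise per coordinate, emulating centerline extraction
#' inaccuracies that the Savitzky-Golay filter is there to suppress.
#'
#' @param cl a [centerline()].
#' @param sd noise standard deviation, mm.
#' @param seed integer seed; the same seed reproduces the same jitter.
#' @return A jittered [centerline()].
#' @export
add_noise <- function(cl, sd, seed = 1L) {
  stopifnot(inherits(cl, "centerline"), sd >= 0)
  if (sd == 0) return(cl)
  pts <- cl$points + withr::with_seed(seed,
    matrix(stats::rnorm(length(cl$points), sd = sd), ncol = 3L))
  centerline(pts, marks = cl$marks)
}

#' Sample interior points of the phantom tube
#'
#' Uniformly samples points strictly inside the tube (and away from the
#' ends), for tracking-accuracy experiments.
#'
#' @param ph a [make_phantom()] result (or a [phantom_spec()]).
#' @param n number of points.
#' @param seed integer seed.
#' @return A tibble `label, x, y, z` (mm).
#' @export
sample_interior_points <- function(ph, n = 50, seed = 7L) {
  spec <- if (inherits(ph, "vessel_phantom")) ph$spec else ph
  total <- phantom_total_length(spec)
  withr::with_seed(seed, {
    s <- stats::runif(n, 0.05 * total, 0.95 * total)
    rho <- 0.8 * min(spec$r, spec$r2) * sqrt(stats::runif(n))
    phi <- stats::runif(n, 0, 2 * pi)
    cp <- phantom_centerline_point(spec, s)
    fr <- phantom_frames(spec, s)
    p <- cp + (rho * cos(phi)) * fr$n + (rho * sin(phi)) * fr$b
    tibble::tibble(label = sprintf("pt%02d", seq_len(n)),
                   x = p[, 1], y = p[, 2], z = p[, 3])
  })
}

#' Write a phantom's fixture files to a directory
#'
#' Emits `centerline.csv`, `points.csv`, `lumen.stl`, `field_00.mha` ...
#' `field_09.mha`, optionally `mask.mha`, and `oracle.json` with the
#' closed-form reference values.
#'
#' @param ph a [make_phantom()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  stopifnot(inherits(ph, "vessel_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_centerline_csv(ph$centerline, file.path(dir, "centerline.csv"))
  readr::write_csv(ph$points, file.path(dir, "points.csv"), progress = FALSE)
  write_stl(ph$mesh, file.path(dir, "lumen.stl"))
  for (k in 0:9) {
    write_vector_field(ph$fields$fields[[k + 1L]],
                       file.path(dir, sprintf("field_%02d.mha", k)))
  }
  if (!is.null(ph$mask)) {
    write_mhd_volume(ph$mask$mask, ph$mask$header, file.path(dir, "mask.mha"))
  }
  jsonlite::write_json(ph$oracle, file.path(dir, "oracle.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
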