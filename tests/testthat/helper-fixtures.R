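# Shared in-code fixtures: tiny grids, constant/analytic fields, and the
# enumerated sine phase weights used throughout.

w_phases <- sin(2 * pi * (0:9) / 10)

small_header <- function(n = 11L, spacing = 1, origin = -(n - 1) * spacing / 2) {
  volume_header(origin = rep(origin, 3), spacing = rep(spacing, 3),
                size = rep(n, 3))
}

const_field <- function(v, header = small_header()) {
  vector_field_from_function(function(p) {
    matrix(v, nrow(p), 3, byrow = TRUE)
  }, header)
}

# 10 constant fields with per-phase displacement vectors (10 x 3 matrix).
translation_set <- function(vecs, header = small_header()) {
  phase_field_set(lapply(1:10, function(k) const_field(vecs[k, ], header)))
}

zero_set <- function(header = small_header()) {
  translation_set(matrix(0, 10, 3), header)
}

# Trajectory object built directly from a positions matrix (for pure
# amplitude/pathlength math, no fields involved).
raw_trajectory <- function(positions, label = "t") {
  structure(list(label = label, p_avg = positions[1, ], positions = positions),
            class = "point_trajectory")
}

# Straight-line centerline along +x.
line_centerline <- function(len = 60, marks = integer(0)) {
  centerline(cbind(seq(0, len), 0, 0), marks = marks)
}

# Planar arc centerline in the x-y plane, arc-length sampled at 1 mm.
arc_centerline <- function(R = 40, angle = pi) {
  th <- seq(0, angle, length.out = max(2, round(R * angle) + 1))
  centerline(cbind(R * cos(th), R * sin(th), 0))
}
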