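#' Displacement vector field on a voxel grid
#'
#' A `vector_field` carries one 3-component displacement volume (mm): the
#' vector stored at voxel `(i,j,k)` is the displacement that moves the
#' phase-averaged position of that voxel to its position in one cardiac
#' phase. Displacements larger than `sanity_cap_mm` are physiologically
#' implausible for cardiac pulsatility and are reported (not silently used).
#'
#' @param u numeric 4-d array `size[1] x size[2] x size[3] x 3`, mm.
#' @param header a [volume_header()] describing the grid.
#' @param sanity_cap_mm warn when any displacement magnitude exceeds this
#'   cap (default 25 mm).
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(u, header, sanity_cap_mm = 25) {
  if (length(dim(u)) != 4L || dim(u)[4] != 3L) {
    stop("expected 3-component displacement field (array with dim[4] == 3)",
         call. = FALSE)
  }
  if (!identical(as.integer(dim(u)[1:3]), header$size)) {
    stop("field array dimensions do not match header size", call. = FALSE)
  }
  if (any(!is.finite(u))) {
    stop("displacement field contains non-finite values", call. = FALSE)
  }
  mag2 <- u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2
  n_large <- sum(mag2 > sanity_cap_mm^2)
  if (n_large > 0L) {
    warning(sprintf(
      "%d voxel displacement(s) exceed the %g mm sanity cap (max %.2f mm)",
      n_large, sanity_cap_mm, sqrt(max(mag2))), call. = FALSE)
  }
  storage.mode(u) <- "double"
  structure(list(header = header, u = u), class = "vector_field")
}

#' Build a vector field by evaluating a displacement function on a grid
#'
#' Convenience constructor used by the phantom generator and in tests:
#' `fun` receives an `n x 3` matrix of world coordinates (mm) and must
#' return an `n x 3` matrix of displacements (mm).
#'
#' @param fun vectorized displacement function, world mm -> displacement mm.
#' @inheritParams vector_field
#' @return A `vector_field`.
#' @export
vector_field_from_function <- function(fun, header, sanity_cap_mm = 25) {
  sz <- header$size
  idx <- as.matrix(expand.grid(i = seq_len(sz[1]) - 1L,
                               j = seq_len(sz[2]) - 1L,
                               k = seq_len(sz[3]) - 1L))
  world <- index_to_world(header, idx)
  disp <- fun(world)
  u <- array(0, dim = c(sz, 3L))
  for (c in 1:3) u[, , , c] <- array(disp[, c], dim = sz)
  vector_field(u, header, sanity_cap_mm = sanity_cap_mm)
}

#' @export
print.vector_field <- function(x, ...) {
  cat("<vector_field> 3-component displacement volume (mm)\n")
  print(x$header)
  cat("  |u| range (mm):",
      paste(format(sqrt(range(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)),
                   digits = 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Ordered set of per-phase displacement fields over one cardiac cycle
#'
#' Exactly 10 fields, one per cardiac phase at 0, 10, ..., 90% of the R-R
#' interval, all on the same grid.
#'
#' @param fields list of 10 [vector_field()] objects in phase order.
#' @return An object of class `phase_field_set`.
#' @export
phase_field_set <- function(fields) {
  if (length(fields) != 10L) {
    stop(sprintf("a cardiac cycle needs exactly 10 phase fields, got %d",
                 length(fields)), call. = FALSE)
  }
  ok <- vapply(fields, inherits, logical(1), what = "vector_field")
  if (!all(ok)) stop("all elements must be vector_field objects", call. = FALSE)
  hdr <- fields[[1]]$header
  same <- vapply(fields, function(f) headers_equal(f$header, hdr), logical(1))
  if (!all(same)) stop("all phase fields must share one grid header", call. = FALSE)
  structure(list(fields = fields, phases = seq(0, 0.9, by = 0.1)),
            class = "phase_field_set")
}

#' @export
print.phase_field_set <- function(x, ...) {
  cat("<phase_field_set> 10 cardiac phases (0-90% R-R)\n")
  print(x$fields[[1]]$header)
  invisible(x)
}

#' Trilinearly interpolate a displacement field at world points
#'
#' Component-wise trilinear interpolation of the 8 voxels surrounding each
#' query point. Points outside the grid's voxel-center bounding box (see
#' [grid_bounds()]) raise an error: displacement fields are never
#' extrapolated.
#'
#' @param field a [vector_field()].
#' @param p world points, mm: a 3-vector or `n x 3` matrix.
#' @return An `n x 3` matrix of interpolated displacements, mm (a plain
#'   3-vector if `p` was one).
#' @examples
#' hdr <- volume_header(size = c(4, 4, 4))
#' f <- vector_field_from_function(function(p) cbind(1, 0 * p[, 2], 0), hdr)
#' interpolate_displacement(f, c(1.2, 0.7, 2.4))
#' @export
interpolate_displacement <- function(field, p) {
  single <- is.null(dim(p))
  p <- as_point_matrix(p)
  c_idx <- world_to_index(field$header, p)
  sz <- field$header$size
  eps <- 1e-9
  bad <- c_idx[, 1] < -eps | c_idx[, 1] > sz[1] - 1 + eps |
         c_idx[, 2] < -eps | c_idx[, 2] > sz[2] - 1 + eps |
         c_idx[, 3] < -eps | c_idx[, 3] > sz[3] - 1 + eps
  if (any(bad)) {
    b <- grid_bounds(field$header)
    i <- which(bad)[1]
    stop(sprintf(
      paste0("point (%.3f, %.3f, %.3f) mm is outside the interpolable box ",
             "[%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f] mm"),
      p[i, 1], p[i, 2], p[i, 3],
      b[1, 1], b[2, 1], b[1, 2], b[2, 2], b[1, 3], b[2, 3]), call. = FALSE)
  }
  out <- trilinear_core(field$u, sz, c_idx)
  if (single) drop(out) else out
}

# Trilinear gather over an (nx, ny, nz, nc) array at continuous 0-based
# indices (n x 3). Callers are responsible for bounds checking.
trilinear_core <- function(arr4, sz, c_idx) {
  nc <- dim(arr4)[4]
  i0 <- pmin(pmax(floor(c_idx), 0), matrix(rep(sz - 2, each = nrow(c_idx)), ncol = 3))
  f <- c_idx - i0
  nx <- sz[1]; nxy <- sz[1] * sz[2]; nvol <- prod(sz)
  base <- i0[, 1] + nx * i0[, 2] + nxy * i0[, 3] + 1
  out <- matrix(0, nrow(c_idx), nc)
  uvec <- arr4
  dim(uvec) <- c(nvol, nc)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- base + dx + nx * dy + nxy * dz
    out <- out + w * uvec[idx, , drop = FALSE]
  }
  out
}
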