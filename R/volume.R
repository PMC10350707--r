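#' Grid geometry of a gridded volume
#'
#' A `volume_header` records where a regular axis-aligned voxel grid sits in
#' world space: `origin` (world mm of voxel index `(0,0,0)`), `spacing`
#' (mm per voxel along each axis) and `size` (voxel counts). The index
#' convention is zero-based: index `(i,j,k)` maps to world position
#' `origin + (i,j,k) * spacing`. Direction-cosine rotations are not
#' supported; grids must be axis-aligned.
#'
#' @param origin numeric 3-vector, world mm of the first voxel.
#' @param spacing numeric 3-vector, strictly positive, mm per voxel.
#' @param size integer 3-vector, voxel counts, at least 2 per axis so that
#'   trilinear interpolation has at least one cell.
#' @return An object of class `volume_header`.
#' @examples
#' hdr <- volume_header(origin = c(-10, -10, 0), spacing = c(1.5, 1.5, 1.5),
#'                      size = c(16, 16, 8))
#' index_to_world(hdr, rbind(c(0, 0, 0), c(15, 15, 7)))
#' @export
volume_header <- function(origin = c(0, 0, 0), spacing = c(1, 1, 1), size) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  size <- as.integer(round(size))
  if (length(origin) != 3L || length(spacing) != 3L || length(size) != 3L) {
    stop("origin, spacing and size must each have length 3", call. = FALSE)
  }
  if (any(!is.finite(origin)) || any(!is.finite(spacing))) {
    stop("origin and spacing must be finite", call. = FALSE)
  }
  if (any(spacing <= 0)) {
    stop("spacing must be strictly positive along every axis", call. = FALSE)
  }
  if (any(size < 2L)) {
    stop("size must be >= 2 along every axis (one interpolation cell)",
         call. = FALSE)
  }
  structure(list(origin = origin, spacing = spacing, size = size),
            class = "volume_header")
}

#' @export
print.volume_header <- function(x, ...) {
  cat("<volume_header>\n")
  cat("  origin  (mm):", paste(format(x$origin), collapse = ", "), "\n")
  cat("  spacing (mm):", paste(format(x$spacing), collapse = ", "), "\n")
  cat("  size (vox)  :", paste(x$size, collapse = " x "), "\n")
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' Zero-based voxel indices `(i,j,k)` map to world mm as
#' `origin + index * spacing`; `world_to_index` is the exact inverse.
#' Fractional (continuous) indices are allowed in both directions.
#'
#' @param header a [volume_header()].
#' @param index,world numeric matrix with 3 columns (or a single 3-vector);
#'   one row per point.
#' @return A numeric matrix with 3 columns.
#' @export
index_to_world <- function(header, index) {
  index <- as_point_matrix(index)
  sweep(sweep(index, 2L, header$spacing, `*`), 2L, header$origin, `+`)
}

#' @rdname index_to_world
#' @export
world_to_index <- function(header, world) {
  world <- as_point_matrix(world)
  sweep(sweep(world, 2L, header$origin, `-`), 2L, header$spacing, `/`)
}

#' World-space bounding box covered by the voxel centers of a grid
#'
#' Points are interpolable only inside this box (the outer half-voxel
#' margin of the volume is excluded because no surrounding cell exists).
#'
#' @param header a [volume_header()].
#' @return A 2 x 3 matrix: first row the lower corner, second the upper, mm.
#' @export
grid_bounds <- function(header) {
  lo <- header$origin
  hi <- header$origin + (header$size - 1) * header$spacing
  rbind(lo = lo, hi = hi)
}

# Coerce a 3-vector or n x 3 matrix/data.frame to an n x 3 numeric matrix.
as_point_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y", "z")])
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop("a point must have 3 coordinates", call. = FALSE)
    p <- matrix(as.numeric(p), nrow = 1L)
  }
  p <- unname(as.matrix(p))
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must be n x 3", call. = FALSE)
  p
}

headers_equal <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(a$size == b$size)
}
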