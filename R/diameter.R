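#' Lumen surface representations
#'
#' Diameters are read off either a triangle mesh of the lumen surface
#' (`surface_mesh`) or a binary lumen mask on a voxel grid (`lumen_mask`,
#' iso-surface at 0.5 implied). The surface must be closed around the
#' measured region: a ray cast from an interior centerline point must hit
#' it in both directions.
#'
#' @param vertices `n x 3` numeric matrix, mm.
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @return `surface_mesh()`: an object of class `lumen_surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as_point_matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be m x 3", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of vertex range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces),
            class = "lumen_surface_mesh")
}

#' @param mask 3-d array of 0/1 (or logical) lumen occupancy.
#' @param header a [volume_header()] for the mask grid.
#' @return `lumen_mask()`: an object of class `lumen_mask`.
#' @rdname surface_mesh
#' @export
lumen_mask <- function(mask, header) {
  mask <- array(as.numeric(mask), dim = dim(mask))
  if (!identical(as.integer(dim(mask)), header$size)) {
    stop("mask dimensions do not match header size", call. = FALSE)
  }
  structure(list(mask = mask, header = header), class = "lumen_mask")
}

# Nearest positive ray-triangle intersection distance (Moller-Trumbore,
# vectorized over triangles). Returns +Inf when nothing is hit.
ray_mesh_nearest <- function(mesh, origin, dir, eps = 1e-9) {
  V <- mesh$vertices
  F <- mesh$faces
  v0 <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - v0
  e2 <- V[F[, 3], , drop = FALSE] - v0
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > eps
  t <- rep(Inf, nrow(F))
  if (any(ok)) {
    f <- 1 / a[ok]
    s <- -sweep(v0[ok, , drop = FALSE], 2L, origin, `-`)  # origin - v0
    u <- f * rowSums(s * h[ok, , drop = FALSE])
    q <- cbind(s[, 2] * e1[ok, 3] - s[, 3] * e1[ok, 2],
               s[, 3] * e1[ok, 1] - s[, 1] * e1[ok, 3],
               s[, 1] * e1[ok, 2] - s[, 2] * e1[ok, 1])
    v <- f * (dir[1] * q[, 1] + dir[2] * q[, 2] + dir[3] * q[, 3])
    tt <- f * rowSums(e2[ok, , drop = FALSE] * q)
    hit <- u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & tt > eps
    t[ok][hit] <- tt[hit]
  }
  min(t)
}

# Distance along +dir to the 0.5 iso-crossing of a binary mask, by linear
# interpolation of trilinearly sampled values at fixed marching steps.
ray_mask_nearest <- function(lm, origin, dir, step = 0.2) {
  b <- grid_bounds(lm$header)
  # longest possible chord through the grid box
  tmax <- sqrt(sum((b[2, ] - b[1, ])^2))
  ts <- seq(0, tmax, by = step)
  P <- cbind(origin[1] + ts * dir[1], origin[2] + ts * dir[2],
             origin[3] + ts * dir[3])
  inb <- P[, 1] >= b[1, 1] & P[, 1] <= b[2, 1] &
         P[, 2] >= b[1, 2] & P[, 2] <= b[2, 2] &
         P[, 3] >= b[1, 3] & P[, 3] <= b[2, 3]
  last <- if (all(inb)) length(ts) else which(!inb)[1] - 1L
  if (last < 2L) return(Inf)
  arr <- lm$mask
  dim(arr) <- c(dim(lm$mask), 1L)
  vals <- trilinear_sample(arr, lm$header, P[seq_len(last), , drop = FALSE])[, 1]
  below <- which(vals < 0.5)
  if (!length(below) || below[1] == 1L) return(Inf)
  i <- below[1]
  frac <- (vals[i - 1L] - 0.5) / (vals[i - 1L] - vals[i])
  ts[i - 1L] + frac * step
}

# Generic trilinear sampler on a (possibly 1-channel) gridded array.
trilinear_sample <- function(arr4, header, P) {
  trilinear_core(arr4, header$size, world_to_index(header, P))
}

#' Lumen diameter along one in-plane direction of a cross-section frame
#'
#' Casts rays from the frame origin in the +/- direction, takes the nearest
#' surface hit each way (so a neighboring lumen can never contaminate the
#' measurement), and returns the distance between the two boundary points.
#'
#' @param surface a [surface_mesh()] or [lumen_mask()].
#' @param origin frame origin, 3-vector mm, strictly inside the lumen.
#' @param direction in-plane unit 3-vector (e1 or e2 of the frame).
#' @return A list: `diameter` (mm) and `boundary` (2 x 3 matrix of the two
#'   hit points); `diameter` is `NA` with `reason = "open surface"` when
#'   either ray escapes without a hit.
#' @export
ray_diameter <- function(surface, origin, direction) {
  direction <- direction / sqrt(sum(direction^2))
  t_pos <- if (inherits(surface, "lumen_surface_mesh")) {
    ray_mesh_nearest(surface, origin, direction)
  } else if (inherits(surface, "lumen_mask")) {
    ray_mask_nearest(surface, origin, direction)
  } else stop("surface must be a surface_mesh or lumen_mask", call. = FALSE)
  t_neg <- if (inherits(surface, "lumen_surface_mesh")) {
    ray_mesh_nearest(surface, origin, -direction)
  } else {
    ray_mask_nearest(surface, origin, -direction)
  }
  if (!is.finite(t_pos) || !is.finite(t_neg)) {
    return(list(diameter = NA_real_, boundary = NULL, reason = "open surface"))
  }
  b <- rbind(origin + t_pos * direction, origin - t_neg * direction)
  list(diameter = t_pos + t_neg, boundary = b, reason = NULL)
}

#' Perpendicular diameter pairs at 1 cm centerline levels
#'
#' At every frame from [frames_along_centerline()] two perpendicular
#' diameters are measured along the in-plane directions e1 and e2; the pair
#' is averaged into a mean diameter and its min/max form the spread band.
#' Levels where a ray escapes the surface are flagged and excluded (with a
#' warning); the four boundary points per level are retained so the pair
#' can be followed through the cardiac phases.
#'
#' When stent marks are given, levels run from the proximal mark to the
#' distal mark in `step` increments and are indexed from the proximal end
#' of the stented segment; `n_native` additional levels of the native
#' vessel upstream and downstream of the segment are included and labeled
#' in the `segment` column.
#'
#' @param surface a [surface_mesh()] or [lumen_mask()].
#' @param cl a [centerline()] resampled at 1 mm.
#' @param step level spacing along the centerline, mm (default 10).
#' @param from_mark,to_mark optional marks bounding the stented segment.
#' @param n_native native-vessel levels to add on each side of the marked
#'   segment (default 1; only used with marks).
#' @param order,window,seed_direction passed to [frames_along_centerline()].
#' @return A tibble of class `diameter_pairs`: `level`, `position` (mm),
#'   `segment` (`"stented"`, `"upstream"`, `"downstream"`), `d1`, `d2`,
#'   `mean`, `spread_lo`, `spread_hi` (mm), `ok` (logical) and a `boundary`
#'   list column (4 x 3 matrix: e1+, e1-, e2+, e2- hits).
#' @export
diameter_pairs <- function(surface, cl, step = 10, from_mark = NULL,
                           to_mark = NULL, n_native = 1L, order = 4,
                           window = 33, seed_direction = c(1, 0, 0)) {
  positions <- NULL
  seg_label <- NULL
  if (!is.null(from_mark) || !is.null(to_mark)) {
    s <- arc_positions(cl)
    s_from <- s[resolve_mark(cl, from_mark, 1L)]
    s_to <- s[resolve_mark(cl, to_mark, length(s))]
    stented <- seq(s_from, s_to, by = step)
    up <- rev(s_from - step * seq_len(n_native))
    up <- up[up >= 0]
    down <- s_to + step * seq_len(n_native)
    down <- down[down <= s[length(s)]]
    positions <- c(up, stented, down)
    seg_label <- c(rep("upstream", length(up)),
                   rep("stented", length(stented)),
                   rep("downstream", length(down)))
  }
  frames <- frames_along_centerline(cl, step = step, order = order,
                                    window = window,
                                    seed_direction = seed_direction,
                                    positions = positions)
  rows <- purrr::pmap(frames, function(level, position, ox, oy, oz,
                                       tx, ty, tz, e1x, e1y, e1z,
                                       e2x, e2y, e2z) {
    o <- c(ox, oy, oz)
    r1 <- ray_diameter(surface, o, c(e1x, e1y, e1z))
    r2 <- ray_diameter(surface, o, c(e2x, e2y, e2z))
    ok <- is.finite(r1$diameter %||% NA_real_) && !is.na(r1$diameter) &&
          !is.na(r2$diameter)
    tibble::tibble(
      level = level, position = position,
      d1 = r1$diameter, d2 = r2$diameter,
      mean = (r1$diameter + r2$diameter) / 2,
      spread_lo = pmin(r1$diameter, r2$diameter),
      spread_hi = pmax(r1$diameter, r2$diameter),
      ok = ok,
      boundary = list(if (ok) rbind(r1$boundary, r2$boundary) else NULL)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$segment <- if (is.null(seg_label)) "stented" else seg_label
  if (any(!out$ok)) {
    warning(sprintf("%d level(s) flagged 'open surface' and excluded",
                    sum(!out$ok)), call. = FALSE)
  }
  class(out) <- c("diameter_pairs", class(out))
  out
}

#' Pulsatile diameter change across the cardiac cycle
#'
#' The four boundary points of each level are translated into every cardiac
#' phase with the deformation fields; the per-phase diameters are the
#' distances between the translated point pairs, averaged into a per-phase
#' mean diameter; the diameter change (pulsatile expansion) is the
#' difference between the maximal and minimal per-phase mean.
#'
#' @param pairs a [diameter_pairs()] table.
#' @param fields a [phase_field_set()].
#' @return `pairs` with added columns `diameter_change` (mm) and
#'   `phase_mean` (list column: 10 per-phase mean diameters, mm). Levels
#'   whose boundary points leave the field grid are flagged `ok = FALSE`.
#' @export
pulsatile_diameter_change <- function(pairs, fields) {
  stopifnot(inherits(pairs, "diameter_pairs"), inherits(fields, "phase_field_set"))
  change <- rep(NA_real_, nrow(pairs))
  phase_means <- vector("list", nrow(pairs))
  ok <- pairs$ok
  for (i in seq_len(nrow(pairs))) {
    if (!ok[i]) next
    b <- pairs$boundary[[i]]
    means <- tryCatch({
      vapply(seq_along(fields$fields), function(k) {
        bt <- b + interpolate_displacement(fields$fields[[k]], b)
        d1 <- sqrt(sum((bt[1, ] - bt[2, ])^2))
        d2 <- sqrt(sum((bt[3, ] - bt[4, ])^2))
        (d1 + d2) / 2
      }, numeric(1))
    }, error = function(e) NULL)
    if (is.null(means)) {
      ok[i] <- FALSE
      next
    }
    change[i] <- max(means) - min(means)
    phase_means[[i]] <- means
  }
  if (any(pairs$ok & !ok)) {
    warning(sprintf("%d level(s) with out-of-bounds boundary points flagged",
                    sum(pairs$ok & !ok)), call. = FALSE)
  }
  pairs$ok <- ok
  pairs$diameter_change <- change
  pairs$phase_mean <- phase_means
  pairs
}
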