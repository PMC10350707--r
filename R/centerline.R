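#' Ordered vessel centerline
#'
#' An ordered list of 3-D points (world mm, proximal to distal) with named
#' segment marks (e.g. `stent_start`, `stent_end`) resolved to point
#' indices. Duplicate consecutive points are collapsed with a warning.
#'
#' @param points `n x 3` numeric matrix, world mm.
#' @param marks named integer vector of point indices (1-based).
#' @return An object of class `centerline`.
#' @export
centerline <- function(points, marks = integer(0)) {
  points <- as_point_matrix(points)
  if (nrow(points) < 2L) stop("a centerline needs at least 2 points", call. = FALSE)
  dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate consecutive centerline point(s)",
                    sum(dup)), call. = FALSE)
    # remap marks onto the kept rows
    keep <- which(!dup)
    if (length(marks)) {
      marks <- vapply(marks, function(i) sum(!dup[seq_len(i)]), integer(1))
    }
    points <- points[keep, , drop = FALSE]
  }
  if (nrow(points) < 2L) stop("a centerline needs at least 2 distinct points",
                              call. = FALSE)
  if (length(marks)) {
    marks <- stats::setNames(as.integer(marks), names(marks))
    if (any(marks < 1L | marks > nrow(points))) {
      stop("centerline marks out of range", call. = FALSE)
    }
  }
  structure(list(points = points, marks = marks), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.2f mm\n",
              nrow(x$points), arc_length(x)))
  if (length(x$marks)) {
    cat("  marks:", paste(sprintf("%s=%d", names(x$marks), x$marks),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

# Arc-length coordinate (mm) of every centerline point, starting at 0.
arc_positions <- function(cl) {
  seg <- sqrt(rowSums(diff(cl$points)^2))
  c(0, cumsum(seg))
}

#' Resample a centerline at 1 mm arc spacing
#'
#' The raw polyline is parameterized by cumulative chord length and linearly
#' interpolated at exact `spacing` steps; the last point is always kept, so
#' the final gap may be shorter than `spacing`. Marks are re-mapped to the
#' nearest resampled index (by arc position).
#'
#' @param cl a [centerline()] or an `n x 3` point matrix.
#' @param spacing target arc step, mm (default 1).
#' @return A resampled [centerline()].
#' @export
resample_centerline <- function(cl, spacing = 1.0) {
  if (!inherits(cl, "centerline")) cl <- centerline(cl)
  s <- arc_positions(cl)
  total <- s[length(s)]
  if (total <= 0) stop("centerline has zero total length", call. = FALSE)
  targets <- seq(0, total, by = spacing)
  if (total - targets[length(targets)] > 1e-9) targets <- c(targets, total)
  new_pts <- cbind(
    stats::approx(s, cl$points[, 1], xout = targets, ties = "ordered")$y,
    stats::approx(s, cl$points[, 2], xout = targets, ties = "ordered")$y,
    stats::approx(s, cl$points[, 3], xout = targets, ties = "ordered")$y
  )
  marks <- cl$marks
  if (length(marks)) {
    marks <- stats::setNames(
      vapply(marks, function(i) which.min(abs(targets - s[i])), integer(1)),
      names(marks))
  }
  centerline(new_pts, marks = marks)
}

resolve_mark <- function(cl, mark, default) {
  if (is.null(mark)) return(default)
  if (is.numeric(mark)) {
    i <- as.integer(mark)
    if (i < 1L || i > nrow(cl$points)) stop("mark index out of range", call. = FALSE)
    return(i)
  }
  if (!mark %in% names(cl$marks)) {
    stop(sprintf("unknown mark '%s'; known marks: %s", mark,
                 if (length(cl$marks)) paste(names(cl$marks), collapse = ", ")
                 else "(none)"), call. = FALSE)
  }
  cl$marks[[mark]]
}

#' Centerline segment length
#'
#' Sum of Euclidean distances between consecutive centerline points, over
#' the whole centerline or between two marks.
#'
#' @param cl a [centerline()].
#' @param from_mark,to_mark mark names (or indices); `NULL` means the first
#'   and last point.
#' @return Length in mm.
#' @export
arc_length <- function(cl, from_mark = NULL, to_mark = NULL) {
  i <- resolve_mark(cl, from_mark, 1L)
  j <- resolve_mark(cl, to_mark, nrow(cl$points))
  if (i >= j) stop("segment start must come before segment end", call. = FALSE)
  seg <- cl$points[i:j, , drop = FALSE]
  sum(sqrt(rowSums(diff(seg)^2)))
}

#' Tortuosity index of a centerline segment
#'
#' Centerline length divided by the straight (chord) distance between the
#' segment endpoints; 1 for a straight segment, larger for a winding one.
#'
#' @inheritParams arc_length
#' @return Unitless TI (>= 1 up to floating-point round-off).
#' @export
tortuosity_index <- function(cl, from_mark = NULL, to_mark = NULL) {
  i <- resolve_mark(cl, from_mark, 1L)
  j <- resolve_mark(cl, to_mark, nrow(cl$points))
  if (i >= j) stop("segment start must come before segment end", call. = FALSE)
  chord <- sqrt(sum((cl$points[j, ] - cl$points[i, ])^2))
  if (chord <= 1e-12) {
    stop("tortuosity index undefined: segment endpoints coincide", call. = FALSE)
  }
  arc_length(cl, i, j) / chord
}
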