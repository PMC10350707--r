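#' Track a point through the cardiac cycle
#'
#' The point's position in each cardiac phase is its phase-averaged
#' position plus the trilinearly interpolated displacement of that phase's
#' deformation field — the deformation fields are added to the point
#' coordinates, one phase at a time.
#'
#' @param fields a [phase_field_set()].
#' @param p phase-averaged position, 3-vector mm (must be interpolable in
#'   all 10 fields).
#' @param label optional point label.
#' @return An object of class `point_trajectory`: `label`, `p_avg` and
#'   `positions` (10 x 3 matrix, mm, phase 0-90% R-R).
#' @export
track_point <- function(fields, p, label = "") {
  stopifnot(inherits(fields, "phase_field_set"))
  p <- drop(as_point_matrix(p))
  pos <- matrix(NA_real_, 10L, 3L, dimnames = list(NULL, c("x", "y", "z")))
  for (k in 1:10) {
    disp <- tryCatch(
      interpolate_displacement(fields$fields[[k]], p),
      error = function(e) {
        stop(sprintf("phase %d: %s", k - 1L, conditionMessage(e)), call. = FALSE)
      })
    pos[k, ] <- p + disp
  }
  structure(list(label = label, p_avg = p, positions = pos),
            class = "point_trajectory")
}

#' @export
print.point_trajectory <- function(x, ...) {
  cat(sprintf("<point_trajectory> '%s' at (%.2f, %.2f, %.2f) mm\n",
              x$label, x$p_avg[1], x$p_avg[2], x$p_avg[3]))
  cat(sprintf("  pathlength (open): %.3f mm\n", pathlength(x)))
  invisible(x)
}

#' Per-axis motion amplitudes (pulsatility) of a tracked point
#'
#' Along each axis (x lateral, y ventral-dorsal, z caudal-cranial in a
#' supine feet-first scan) the amplitude is the range, max minus min, of
#' the point's 10 phase positions.
#'
#' @param traj a [track_point()] trajectory.
#' @return A one-row tibble: `amplitude_x`, `amplitude_y`, `amplitude_z` (mm).
#' @export
motion_amplitudes <- function(traj) {
  stopifnot(inherits(traj, "point_trajectory"))
  rng <- apply(traj$positions, 2L, function(v) max(v) - min(v))
  tibble::tibble(amplitude_x = rng[[1]], amplitude_y = rng[[2]],
                 amplitude_z = rng[[3]])
}

#' Traveled pathlength of a tracked point
#'
#' Sum of the Euclidean distances between the point locations in subsequent
#' phases. With `closure = "open"` the 9 steps between phases 0-90% are
#' summed; `"cyclic"` also adds the wrap-around step from phase 90% back to
#' phase 0%, treating the cycle as periodic.
#'
#' @param traj a [track_point()] trajectory.
#' @param closure `"open"` (default) or `"cyclic"`.
#' @return Pathlength in mm.
#' @export
pathlength <- function(traj, closure = c("open", "cyclic")) {
  closure <- match.arg(closure)
  stopifnot(inherits(traj, "point_trajectory"))
  steps <- sqrt(rowSums(diff(traj$positions)^2))
  total <- sum(steps)
  if (closure == "cyclic") {
    total <- total + sqrt(sum((traj$positions[1, ] - traj$positions[10, ])^2))
  }
  total
}

#' Motion summary table for labeled anatomical points
#'
#' Tracks each point through all 10 phases and reports per-axis amplitudes
#' and traveled pathlength — one row per point, the layout of a per-point
#' pulsatility table.
#'
#' @param points tibble/data.frame with columns `label`, `x`, `y`, `z` (mm).
#' @param fields a [phase_field_set()].
#' @param closure pathlength closure, see [pathlength()].
#' @return A tibble: `label`, `amplitude_x/y/z` (mm), `pathlength` (mm).
#' @export
track_points <- function(points, fields, closure = c("open", "cyclic")) {
  closure <- match.arg(closure)
  points <- tibble::as_tibble(points)
  stopifnot(all(c("label", "x", "y", "z") %in% names(points)))
  purrr::pmap_dfr(points[, c("label", "x", "y", "z")], function(label, x, y, z) {
    traj <- track_point(fields, c(x, y, z), label = label)
    dplyr::bind_cols(tibble::tibble(label = label),
                     motion_amplitudes(traj),
                     tibble::tibble(pathlength = pathlength(traj, closure)))
  })
}
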