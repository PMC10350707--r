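#' Numerical curvature along a centerline
#'
#' Curvature at every point from the Savitzky-Golay first and second
#' derivatives of the coordinates,
#' \deqn{\kappa = \frac{\sqrt{(z''y'-y''z')^2+(x''z'-z''x')^2+(y''x'-x''y')^2}}
#'                    {(x'^2+y'^2+z'^2)^{3/2}},}
#' the general (non-unit-speed) space-curve formula; with derivatives taken
#' per 1 mm sample this yields mm^-1, reported as m^-1 (x 1000) as customary
#' for vascular curvature. Points whose tangent speed falls below
#' `tol` are degenerate: their curvature is `NA`, they are excluded from
#' summaries, and their count is reported with a warning.
#'
#' @param derivs a `centerline_derivatives` from [sg_derivatives()], or a
#'   [centerline()] (smoothed internally with the default filter).
#' @param tol degenerate-tangent tolerance on `(x'^2+y'^2+z'^2)^{3/2}`.
#' @return A tibble of class `curvature_profile` with columns
#'   `position` (arc-length coordinate, mm) and `kappa` (m^-1).
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' arc <- centerline(cbind(40 * cos(th), 40 * sin(th), 0))
#' prof <- curvature(sg_derivatives(resample_centerline(arc)))
#' summary(prof$kappa)  # ~25 m^-1 away from the ends
#' @export
curvature <- function(derivs, tol = 1e-9) {
  if (inherits(derivs, "centerline")) derivs <- sg_derivatives(derivs)
  d1 <- derivs$d1
  d2 <- derivs$d2
  cross2 <- (d2[, 3] * d1[, 2] - d2[, 2] * d1[, 3])^2 +
            (d2[, 1] * d1[, 3] - d2[, 3] * d1[, 1])^2 +
            (d2[, 2] * d1[, 1] - d2[, 1] * d1[, 2])^2
  speed3 <- (d1[, 1]^2 + d1[, 2]^2 + d1[, 3]^2)^1.5
  kappa_mm <- sqrt(cross2) / speed3
  degenerate <- speed3 <= tol
  if (any(degenerate)) {
    warning(sprintf("%d centerline point(s) with degenerate tangent excluded",
                    sum(degenerate)), call. = FALSE)
    kappa_mm[degenerate] <- NA_real_
  }
  seg <- sqrt(rowSums(diff(derivs$smoothed)^2))
  out <- tibble::tibble(position = c(0, cumsum(seg)),
                        kappa = 1000 * kappa_mm)
  class(out) <- c("curvature_profile", class(out))
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Translate a phase-averaged centerline into every cardiac phase
#'
#' Each centerline point is displaced by the interpolated displacement of
#' each of the 10 phase fields; marks are carried over by index. The
#' translated polylines are deliberately not re-resampled or re-smoothed
#' here — per-phase derivatives are recomputed by [sg_derivatives()] on the
#' translated points, so per-point correspondence across phases is exact.
#'
#' @param cl a [centerline()].
#' @param fields a [phase_field_set()].
#' @return A list of 10 [centerline()] objects, one per phase.
#' @export
translate_centerline_to_phases <- function(cl, fields) {
  stopifnot(inherits(cl, "centerline"), inherits(fields, "phase_field_set"))
  lapply(seq_along(fields$fields), function(k) {
    disp <- tryCatch(
      interpolate_displacement(fields$fields[[k]], cl$points),
      error = function(e) {
        stop(sprintf("phase %d: %s", k - 1L, conditionMessage(e)), call. = FALSE)
      })
    centerline(cl$points + disp, marks = cl$marks)
  })
}

segment_indices <- function(cl, from_mark, to_mark) {
  i <- resolve_mark(cl, from_mark, 1L)
  j <- resolve_mark(cl, to_mark, nrow(cl$points))
  if (i >= j) stop("segment start must come before segment end", call. = FALSE)
  i:j
}

# Per-phase curvature matrix (points x phases, m^-1) for a list of
# translated centerlines sharing one point count.
phase_curvature_matrix <- function(phase_cls, order = 4, window = 33) {
  n <- vapply(phase_cls, function(c) nrow(c$points), integer(1))
  if (length(unique(n)) != 1L) {
    stop("per-phase centerlines have mismatched point counts", call. = FALSE)
  }
  vapply(phase_cls, function(c) {
    curvature(sg_derivatives(c, order = order, window = window))$kappa
  }, numeric(n[1]))
}

#' Cardiac-pulsatility-induced changes in centerline geometry
#'
#' For every centerline point the curvature range (max - min over the 10
#' phases) is computed; the mean and maximum of these per-point ranges over
#' the segment are the mean and maximal curvature change during the cycle.
#' Length and tortuosity index are evaluated per phase and their ranges over
#' the cycle are the dynamic length and TI changes.
#'
#' @param phase_cls list of 10 per-phase [centerline()]s (equal point
#'   counts), from [translate_centerline_to_phases()].
#' @param from_mark,to_mark optional segment marks restricting the summary.
#' @param order,window Savitzky-Golay settings, see [sg_derivatives()].
#' @return A one-row tibble: `length_change` (mm), `TI_change`,
#'   `mean_curvature_change`, `max_curvature_change` (m^-1), and
#'   `n_degenerate` (points excluded from the curvature summary).
#' @export
dynamic_changes <- function(phase_cls, from_mark = NULL, to_mark = NULL,
                            order = 4, window = 33) {
  kap <- phase_curvature_matrix(phase_cls, order = order, window = window)
  idx <- segment_indices(phase_cls[[1]], from_mark, to_mark)
  kap <- kap[idx, , drop = FALSE]
  rng <- apply(kap, 1L, function(v) max(v) - min(v))
  bad <- is.na(rng)
  lens <- vapply(phase_cls, arc_length, numeric(1),
                 from_mark = from_mark, to_mark = to_mark)
  tis <- vapply(phase_cls, tortuosity_index, numeric(1),
                from_mark = from_mark, to_mark = to_mark)
  tibble::tibble(
    length_change = max(lens) - min(lens),
    TI_change = max(tis) - min(tis),
    mean_curvature_change = mean(rng[!bad]),
    max_curvature_change = max(rng[!bad]),
    n_degenerate = sum(bad)
  )
}

#' Static and dynamic geometry summary of a centerline segment
#'
#' Mid-cycle (phase-averaged) length, tortuosity index and mean/maximal
#' curvature of the segment, plus — when a [phase_field_set()] is given —
#' their cardiac-pulsatility-induced changes over the cycle from
#' [dynamic_changes()]. The full centerline is smoothed first and the
#' segment cut afterwards, so stent-end marks never sit on a filter
#' boundary.
#'
#' @param cl a [centerline()] resampled at 1 mm.
#' @param fields optional [phase_field_set()] for the dynamic columns.
#' @inheritParams dynamic_changes
#' @return A one-row tibble with columns `length` (mm), `TI`,
#'   `mean_curvature`, `max_curvature` (m^-1), `n_degenerate`, and, with
#'   fields, the four `_change` columns.
#' @export
geometry_summary <- function(cl, fields = NULL, from_mark = NULL,
                             to_mark = NULL, order = 4, window = 33) {
  stopifnot(inherits(cl, "centerline"))
  prof <- curvature(sg_derivatives(cl, order = order, window = window))
  idx <- segment_indices(cl, from_mark, to_mark)
  kap <- prof$kappa[idx]
  out <- tibble::tibble(
    length = arc_length(cl, from_mark, to_mark),
    TI = tortuosity_index(cl, from_mark, to_mark),
    mean_curvature = mean(kap, na.rm = TRUE),
    max_curvature = max(kap, na.rm = TRUE),
    n_degenerate = sum(is.na(kap))
  )
  if (!is.null(fields)) {
    phase_cls <- translate_centerline_to_phases(cl, fields)
    out <- dplyr::bind_cols(out[setdiff(names(out), "n_degenerate")],
                            dynamic_changes(phase_cls, from_mark, to_mark,
                                            order = order, window = window))
  }
  class(out) <- c("geometry_summary", class(out))
  out
}

#' Per-point curvature range profile over the cardiac cycle
#'
#' The per-point curvature of the phase-averaged centerline together with
#' the per-point curvature range (max - min over phases), against the
#' arc-length coordinate — the data behind curvature-vs-position plots.
#'
#' @inheritParams geometry_summary
#' @return A tibble: `position` (mm), `kappa` (m^-1, phase-averaged),
#'   `kappa_change` (m^-1 range over the cycle; `NA` without fields).
#' @export
curvature_change_profile <- function(cl, fields = NULL, order = 4, window = 33) {
  prof <- curvature(sg_derivatives(cl, order = order, window = window))
  out <- tibble::tibble(position = prof$position, kappa = prof$kappa,
                        kappa_change = NA_real_)
  if (!is.null(fields)) {
    phase_cls <- translate_centerline_to_phases(cl, fields)
    kap <- phase_curvature_matrix(phase_cls, order = order, window = window)
    out$kappa_change <- apply(kap, 1L, function(v) max(v) - min(v))
  }
  out
}
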