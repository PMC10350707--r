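#' Cross-section frames at regular arc-length steps along a centerline
#'
#' At arc positions 0, `step`, 2*`step`, ... mm a right-handed orthonormal
#' frame \{tangent, e1, e2\} is placed with the tangent from the
#' Savitzky-Golay first derivative. The in-plane directions are propagated
#' by rotation-minimizing transport: e1 starts as the in-plane projection of
#' a global seed direction (+x, falling back to +y when the tangent is near
#' +x) and at every 1 mm sample is re-projected onto the new normal plane
#' and renormalized, so consecutive frames never flip sign.
#'
#' @param cl a [centerline()] resampled at 1 mm.
#' @param step arc-length spacing of the frames, mm (default 10, i.e. 1 cm
#'   diameter levels).
#' @param order,window Savitzky-Golay settings, see [sg_derivatives()].
#' @param seed_direction global direction whose in-plane projection seeds
#'   e1 (default +x).
#' @param positions optional explicit arc positions (mm) overriding the
#'   regular `step` grid; each is snapped to the nearest 1 mm sample.
#' @return A tibble of class `cross_section_frames`: `level` (1-based),
#'   `position` (mm), and unit-vector columns `ox,oy,oz` (origin),
#'   `tx,ty,tz`, `e1x..e1z`, `e2x..e2z`.
#' @export
frames_along_centerline <- function(cl, step = 10, order = 4, window = 33,
                                    seed_direction = c(1, 0, 0),
                                    positions = NULL) {
  stopifnot(inherits(cl, "centerline"))
  derivs <- sg_derivatives(cl, order = order, window = window)
  n <- nrow(derivs$smoothed)
  speed <- sqrt(rowSums(derivs$d1^2))
  if (any(speed <= 1e-9)) {
    stop(sprintf("zero tangent at centerline sample %d", which(speed <= 1e-9)[1]),
         call. = FALSE)
  }
  tang <- derivs$d1 / speed
  # transport e1 through every 1 mm sample
  e1 <- matrix(NA_real_, n, 3L)
  seed <- seed_direction / sqrt(sum(seed_direction^2))
  v <- seed - sum(seed * tang[1, ]) * tang[1, ]
  if (sqrt(sum(v^2)) < 1e-6) {
    alt <- c(0, 1, 0)
    v <- alt - sum(alt * tang[1, ]) * tang[1, ]
  }
  e1[1, ] <- v / sqrt(sum(v^2))
  for (i in 2:n) {
    v <- e1[i - 1L, ] - sum(e1[i - 1L, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) {
      stop(sprintf("frame transport degenerate at sample %d (tangent turned 90 degrees in one step)", i),
           call. = FALSE)
    }
    e1[i, ] <- v / nv
  }
  e2 <- cbind(tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
              tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
              tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1])
  s <- arc_positions(cl)
  total <- s[length(s)]
  targets <- if (is.null(positions)) seq(0, total, by = step) else positions
  pick <- vapply(targets, function(t) which.min(abs(s - t)), integer(1))
  out <- tibble::tibble(
    level = seq_along(pick),
    position = s[pick],
    ox = derivs$smoothed[pick, 1], oy = derivs$smoothed[pick, 2],
    oz = derivs$smoothed[pick, 3],
    tx = tang[pick, 1], ty = tang[pick, 2], tz = tang[pick, 3],
    e1x = e1[pick, 1], e1y = e1[pick, 2], e1z = e1[pick, 3],
    e2x = e2[pick, 1], e2y = e2[pick, 2], e2z = e2[pick, 3]
  )
  class(out) <- c("cross_section_frames", class(out))
  out
}
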