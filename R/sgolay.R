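#' Savitzky-Golay smoothed coordinates and derivatives of a centerline
#'
#' Each coordinate is fit locally by a least-squares polynomial of the given
#' order over a sliding window; the fitted polynomial supplies the smoothed
#' value and its first and second derivatives at every point. Within the
#' first and last half-window the polynomial fitted to the first/last full
#' window is evaluated at the off-center offsets — no mirroring or padding,
#' so no geometry is fabricated at the segment ends. With 1 mm resampling
#' the sample index equals arc length, so derivatives are per mm.
#'
#' Centerlines shorter than the window get the largest odd window that fits
#' (minimum 5), with a warning; fewer than 5 points is an error.
#'
#' @param cl a [centerline()] resampled at 1 mm (see [resample_centerline()]).
#' @param order polynomial order of the local fit (default 4).
#' @param window window length in samples, odd (default 33).
#' @return An object of class `centerline_derivatives`: list with `smoothed`
#'   (`n x 3`), `d1`, `d2` (same shape, per-sample units), `order`, `window`
#'   and the input `marks`.
#' @export
sg_derivatives <- function(cl, order = 4, window = 33) {
  if (!inherits(cl, "centerline")) cl <- centerline(cl)
  n <- nrow(cl$points)
  if (n < 5L) stop("need at least 5 centerline points for smoothing", call. = FALSE)
  if (window %% 2 == 0) stop("window length must be odd", call. = FALSE)
  if (order >= window) stop("polynomial order must be < window length", call. = FALSE)
  if (n < window) {
    window <- max(5L, if (n %% 2 == 1L) n else n - 1L)
    warning(sprintf("centerline shorter than window: window shrunk to %d",
                    window), call. = FALSE)
    if (order >= window) order <- window - 1L
  }
  F0 <- signal::sgolay(p = order, n = window, m = 0)
  F1 <- signal::sgolay(p = order, n = window, m = 1)
  F2 <- signal::sgolay(p = order, n = window, m = 2)
  sm <- apply(cl$points, 2L, sg_apply_matrix, coefs = F0)
  d1 <- apply(cl$points, 2L, sg_apply_matrix, coefs = F1)
  d2 <- apply(cl$points, 2L, sg_apply_matrix, coefs = F2)
  structure(list(smoothed = sm, d1 = d1, d2 = d2,
                 order = order, window = window, marks = cl$marks),
            class = "centerline_derivatives")
}

# Apply a Savitzky-Golay projection matrix to a series: central row as a
# moving filter in the interior, off-center rows on the first/last full
# window at the boundaries.
sg_apply_matrix <- function(x, coefs) {
  n <- length(x)
  w <- nrow(coefs)
  h <- (w - 1L) %/% 2L
  y <- as.numeric(stats::filter(x, rev(coefs[h + 1L, ]), sides = 2))
  y[seq_len(h)] <- coefs[seq_len(h), , drop = FALSE] %*% x[seq_len(w)]
  y[(n - h + 1L):n] <- coefs[(h + 2L):w, , drop = FALSE] %*% x[(n - w + 1L):n]
  y
}

#' @export
print.centerline_derivatives <- function(x, ...) {
  cat(sprintf("<centerline_derivatives> %d points, SG(order %d, window %d)\n",
              nrow(x$smoothed), x$order, x$window))
  invisible(x)
}
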