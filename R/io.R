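#' Read a displacement vector field from disk
#'
#' Supports the two open volume dialects used by medical-imaging stacks:
#' MetaImage (`.mha`, or `.mhd` with a sidecar `.raw`) and NIfTI-1
#' (`.nii`, `.nii.gz`). The file must hold a 3-component volume;
#' displacements are in mm. Non-axis-aligned orientation headers are
#' rejected rather than silently mishandled.
#'
#' @param path path to the volume file.
#' @return A [vector_field()].
#' @seealso [write_vector_field()], [read_phase_fields()]
#' @export
read_vector_field <- function(path) {
  vol <- read_gridded_volume(path)
  if (vol$channels != 3L) {
    stop(sprintf("expected 3-component displacement field, got %d component(s): %s",
                 vol$channels, path), call. = FALSE)
  }
  vector_field(vol$data, vol$header)
}

read_gridded_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    read_mhd_volume(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_nifti_volume(path)
  } else {
    stop("unrecognised volume format (expected .mha/.mhd or .nii/.nii.gz): ",
         path, call. = FALSE)
  }
}

#' Write a displacement vector field to disk
#'
#' @param field a [vector_field()].
#' @param path destination; format chosen by extension (`.mha`, `.mhd`,
#'   `.nii`, `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_vector_field <- function(field, path) {
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    write_mhd_volume(field$u, field$header, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_nifti_volume(field$u, field$header, path)
  } else {
    stop("unrecognised volume format for writing: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read the 10 per-phase deformation fields of one cardiac cycle
#'
#' Files are ordered by the first integer in each filename (phase index 0-9
#' or 0-90, e.g. `field_00.mha` ... `field_90.mha`).
#'
#' @param dir directory containing exactly 10 vector-field volumes, or a
#'   character vector of 10 file paths already in phase order.
#' @return A [phase_field_set()].
#' @export
read_phase_fields <- function(dir) {
  if (length(dir) == 1L && dir.exists(dir)) {
    paths <- list.files(dir, pattern = "\\.(mha|mhd|nii|nii\\.gz)$",
                        full.names = TRUE, ignore.case = TRUE)
    idx <- suppressWarnings(as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1",
                                           basename(paths))))
    if (anyNA(idx)) {
      paths <- sort(paths)
    } else {
      paths <- paths[order(idx)]
    }
  } else {
    paths <- dir
  }
  if (length(paths) != 10L) {
    stop(sprintf("expected 10 phase field files, found %d", length(paths)),
         call. = FALSE)
  }
  phase_field_set(lapply(paths, read_vector_field))
}

#' Read an ordered centerline from CSV
#'
#' Expects columns `x`, `y`, `z` in world mm, ordered proximal to distal,
#' and an optional `mark` column whose non-empty labels (for example
#' `stent_start`, `stent_end`) are resolved to point indices. Duplicate
#' consecutive points are collapsed with a warning giving the count.
#'
#' @param path CSV file path.
#' @return A [centerline()].
#' @export
read_centerline_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("centerline CSV must have columns x, y, z (world mm)", call. = FALSE)
  }
  pts <- as.matrix(df[, need])
  storage.mode(pts) <- "double"
  marks <- integer(0)
  if ("mark" %in% names(df)) {
    lab <- as.character(df$mark)
    keep <- !is.na(lab) & nzchar(lab)
    marks <- stats::setNames(which(keep), lab[keep])
  }
  centerline(pts, marks = marks)
}

#' Write a centerline to CSV
#'
#' @param cl a [centerline()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- tibble::tibble(x = cl$points[, 1], y = cl$points[, 2],
                       z = cl$points[, 3], mark = NA_character_)
  if (length(cl$marks)) df$mark[cl$marks] <- names(cl$marks)
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read labeled anatomical points from CSV
#'
#' @param path CSV with columns `label`, `x`, `y`, `z` (world mm).
#' @return A tibble with those columns.
#' @export
read_points_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("points CSV must have columns label, x, y, z", call. = FALSE)
  }
  tibble::as_tibble(df[, need])
}

# Registered metric vocabulary of the tidy results table; one name per
# reported output column family, with its unit.
results_metric_units <- c(
  amplitude_x = "mm", amplitude_y = "mm", amplitude_z = "mm",
  pathlength = "mm",
  length = "mm", length_change = "mm",
  TI = "unitless", TI_change = "unitless",
  mean_curvature = "m^-1", max_curvature = "m^-1",
  mean_curvature_change = "m^-1", max_curvature_change = "m^-1",
  curvature = "m^-1", curvature_change = "m^-1",
  d1 = "mm", d2 = "mm", diameter = "mm",
  spread_lo = "mm", spread_hi = "mm", diameter_change = "mm"
)

#' Assemble a tidy results table
#'
#' Long-format records keyed by scan, structure, point or centerline level,
#' phase (or `"summary"`), metric name and value. Metric names are checked
#' against the registered vocabulary so that units are never ambiguous.
#'
#' @param scan_id,structure,point_or_level,phase_or_summary,metric,value
#'   vectors, recycled to a common length.
#' @return A tibble of class `archpulse_results` with a `units` column
#'   filled from the vocabulary.
#' @export
results_table <- function(scan_id = character(), structure = character(),
                          point_or_level = character(),
                          phase_or_summary = character(),
                          metric = character(), value = numeric()) {
  metric <- as.character(metric)
  unknown <- setdiff(unique(metric), names(results_metric_units))
  if (length(unknown)) {
    stop("unknown metric name(s): ", paste(unknown, collapse = ", "),
         "; registered metrics are: ",
         paste(names(results_metric_units), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    scan_id = as.character(scan_id),
    structure = as.character(structure),
    point_or_level = as.character(point_or_level),
    phase_or_summary = as.character(phase_or_summary),
    metric = metric,
    value = as.numeric(value),
    units = unname(results_metric_units[metric]) %||% character(0)
  )
  if (nrow(out) == 0L) out$units <- character(0)
  class(out) <- c("archpulse_results", class(out))
  out
}

#' Write and re-read a results table
#'
#' Rows are sorted deterministically (scan, structure, level, phase, metric)
#' before writing; `read_results()` restores a table equal to the one
#' written.
#'
#' @param table an `archpulse_results` table from [results_table()].
#' @param path destination file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  table <- dplyr::arrange(tibble::as_tibble(table),
                          .data$scan_id, .data$structure,
                          .data$point_or_level, .data$phase_or_summary,
                          .data$metric)
  if (format == "csv") {
    readr::write_csv(table, path, progress = FALSE)
  } else {
    jsonlite::write_json(table, path, digits = NA, auto_unbox = FALSE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(
                      scan_id = "c", structure = "c", point_or_level = "c",
                      phase_or_summary = "c", metric = "c", value = "d",
                      units = "c"))
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
  do.call(results_table, df[setdiff(names(df), "units")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
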