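#' Configuration of a full analysis run
#'
#' Collects every option of the phantom-to-report pipeline in one object
#' that serializes losslessly to JSON and is recorded verbatim next to the
#' outputs for provenance.
#'
#' @param fields_dir directory with the 10 per-phase vector-field volumes.
#' @param centerline_csv centerline CSV (columns x,y,z[,mark], mm).
#' @param points_csv labeled points CSV (label,x,y,z).
#' @param mesh_stl lumen surface STL; `NULL` skips the diameter stage.
#' @param out_dir results directory.
#' @param scan_id,structure identifiers stamped into the results tables.
#' @param closure pathlength closure, `"open"` or `"cyclic"`.
#' @param sg_order,sg_window Savitzky-Golay settings.
#' @param diameter_step level spacing, mm.
#' @param segment_from,segment_to mark names bounding the stented segment
#'   (`NULL` = whole centerline).
#' @param frame_seed_direction seed direction for cross-section frames.
#' @param seed integer seed recorded for provenance.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fields_dir, centerline_csv, points_csv = NULL,
                       mesh_stl = NULL, out_dir = "results",
                       scan_id = "scan", structure = "vessel",
                       closure = "open", sg_order = 4, sg_window = 33,
                       diameter_step = 10, segment_from = NULL,
                       segment_to = NULL, frame_seed_direction = c(1, 0, 0),
                       seed = 1L, log_level = "info") {
  structure(list(fields_dir = fields_dir, centerline_csv = centerline_csv,
                 points_csv = points_csv, mesh_stl = mesh_stl,
                 out_dir = out_dir, scan_id = scan_id, structure = structure,
                 closure = closure, sg_order = sg_order, sg_window = sg_window,
                 diameter_step = diameter_step, segment_from = segment_from,
                 segment_to = segment_to,
                 frame_seed_direction = as.numeric(frame_seed_direction),
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

#' Run the full measurement pipeline
#'
#' Orchestrates the stages end to end: read the 10 deformation fields,
#' track the labeled points (motion table), measure centerline geometry and
#' its cardiac-pulsatility-induced changes (summary + curvature profile),
#' and measure diameter pairs with pulsatile expansion. All outputs land in
#' `config$out_dir`: `motion.csv`, `geometry.csv`, `curvature_profile.csv`,
#' `diameters.csv`, `run_config.json` and `run.log`. Outputs are pure
#' functions of the declared inputs — identical config and inputs give
#' byte-identical files. Any stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the four result tibbles and the per-stage
#'   warning counts.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  warn_counts <- c(motion = 0L, geometry = 0L, diameter = 0L)
  note <- function(...) {
    msg <- sprintf(...)
    if (identical(config$log_level, "info")) message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        warn_counts[name] <<- warn_counts[name] + 1L
        log_lines <<- c(log_lines, sprintf("[%s] warning: %s", name,
                                           conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  note("reading inputs")
  fields <- stage("motion", read_phase_fields(config$fields_dir))
  cl <- stage("geometry", resample_centerline(read_centerline_csv(config$centerline_csv)))

  motion <- NULL
  if (!is.null(config$points_csv)) {
    note("tracking %s", config$points_csv)
    pts <- read_points_csv(config$points_csv)
    motion <- stage("motion", track_points(pts, fields, closure = config$closure))
    readr::write_csv(motion, file.path(config$out_dir, "motion.csv"),
                     progress = FALSE)
  }

  note("measuring centerline geometry")
  geom <- stage("geometry", geometry_summary(
    cl, fields, from_mark = config$segment_from, to_mark = config$segment_to,
    order = config$sg_order, window = config$sg_window))
  geom_out <- dplyr::bind_cols(
    tibble::tibble(scan_id = config$scan_id, structure = config$structure),
    tibble::as_tibble(geom))
  readr::write_csv(geom_out, file.path(config$out_dir, "geometry.csv"),
                   progress = FALSE)
  prof <- stage("geometry", curvature_change_profile(
    cl, fields, order = config$sg_order, window = config$sg_window))
  readr::write_csv(prof, file.path(config$out_dir, "curvature_profile.csv"),
                   progress = FALSE)

  diam <- NULL
  if (!is.null(config$mesh_stl)) {
    note("measuring diameter pairs")
    mesh <- read_stl(config$mesh_stl)
    diam <- stage("diameter", pulsatile_diameter_change(
      diameter_pairs(mesh, cl, step = config$diameter_step,
                     from_mark = config$segment_from,
                     to_mark = config$segment_to,
                     order = config$sg_order, window = config$sg_window,
                     seed_direction = config$frame_seed_direction),
      fields))
    readr::write_csv(
      diam[, c("level", "position", "segment", "d1", "d2", "mean",
               "spread_lo", "spread_hi", "diameter_change", "ok")],
      file.path(config$out_dir, "diameters.csv"), progress = FALSE)
  }

  write_run_config(config, file.path(config$out_dir, "run_config.json"))
  log_lines <- c(log_lines, sprintf("warnings: motion=%d geometry=%d diameter=%d",
                                    warn_counts["motion"], warn_counts["geometry"],
                                    warn_counts["diameter"]))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(motion = motion, geometry = geom_out,
                 curvature_profile = prof, diameters = diam,
                 warnings = warn_counts))
}

#' Plain-text summary of a results directory
#'
#' Prints the geometry summary with conventional row names (length, TI,
#' mean/maximal curvature, each with its cardiac-pulsatility-induced
#' change), plus compact motion and diameter overviews.
#'
#' @param run_dir directory written by [run_all()].
#' @return The report lines, invisibly.
#' @export
report_run <- function(run_dir) {
  lines <- character()
  gpath <- file.path(run_dir, "geometry.csv")
  if (file.exists(gpath)) {
    g <- readr::read_csv(gpath, show_col_types = FALSE, progress = FALSE)
    lines <- c(lines,
      sprintf("Geometry (%s / %s)", g$scan_id[1], g$structure[1]),
      sprintf("  Length - mid cardiac cycle (mm): %.1f", g$length),
      sprintf("  Length - cardiac-pulsatility-induced change (mm): %.2f",
              g$length_change %||% NA),
      sprintf("  TI - mid cardiac cycle: %.3f", g$TI),
      sprintf("  TI - cardiac-pulsatility-induced change: %.4f",
              g$TI_change %||% NA),
      sprintf("  Mean curvature - mid cardiac cycle (m^-1): %.1f",
              g$mean_curvature),
      sprintf("  Maximal curvature - mid cardiac cycle (m^-1): %.1f",
              g$max_curvature),
      sprintf("  Mean curvature - cardiac-pulsatility-induced change (m^-1): %.2f",
              g$mean_curvature_change %||% NA),
      sprintf("  Maximal curvature - cardiac-pulsatility-induced change (m^-1): %.2f",
              g$max_curvature_change %||% NA))
  }
  mpath <- file.path(run_dir, "motion.csv")
  if (file.exists(mpath)) {
    m <- readr::read_csv(mpath, show_col_types = FALSE, progress = FALSE)
    lines <- c(lines, "Motion (per-point pulsatility, mm):",
      sprintf("  %-20s ax=%.3f ay=%.3f az=%.3f path=%.3f",
              m$label, m$amplitude_x, m$amplitude_y, m$amplitude_z,
              m$pathlength))
  }
  dpath <- file.path(run_dir, "diameters.csv")
  if (file.exists(dpath)) {
    d <- readr::read_csv(dpath, show_col_types = FALSE, progress = FALSE)
    lines <- c(lines, sprintf(
      "Diameters: %d levels, mean %.1f mm, max pulsatile change %.2f mm",
      nrow(d), mean(d$mean, na.rm = TRUE),
      max(d$diameter_change, na.rm = TRUE)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
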