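# Minimal MetaImage (.mha / .mhd + .raw) reader and writer for 3-D volumes
# with interleaved vector components. Covers the uncompressed binary dialect:
# ASCII "Key = Value" header, then raw voxel data (x fastest, then y, z;
# channels interleaved per voxel).

mhd_type_map <- c(MET_FLOAT = "float", MET_DOUBLE = "double")
mhd_type_size <- c(MET_FLOAT = 4L, MET_DOUBLE = 8L)

parse_mhd_header <- function(lines) {
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", lines))
  kv <- kv[vapply(kv, length, integer(1)) == 3L]
  stats::setNames(vapply(kv, `[`, character(1), 3L),
                  vapply(kv, `[`, character(1), 2L))
}

num3 <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])

#' @noRd
read_mhd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) stop("truncated MetaImage header: ", path, call. = FALSE)
    lines <- c(lines, ln)
    if (grepl("^\\s*ElementDataFile\\s*=", ln)) break
  }
  h <- parse_mhd_header(lines)
  if (!identical(trimws(h[["NDims"]]), "3")) {
    stop("only 3-dimensional MetaImage volumes are supported", call. = FALSE)
  }
  if (is.na(h["ElementSpacing"]) && is.na(h["ElementSize"])) {
    stop("MetaImage header lacks ElementSpacing: grid geometry is required",
         call. = FALSE)
  }
  if (!is.na(h["TransformMatrix"])) {
    tm <- num3(h[["TransformMatrix"]])
    if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-9) {
      stop("non-identity direction matrix: axis-aligned grids only",
           call. = FALSE)
    }
  }
  if (!is.na(h["CompressedData"]) && toupper(trimws(h[["CompressedData"]])) == "TRUE") {
    stop("compressed MetaImage data is not supported", call. = FALSE)
  }
  sz <- as.integer(num3(h[["DimSize"]]))
  spacing <- num3(if (!is.na(h["ElementSpacing"])) h[["ElementSpacing"]] else h[["ElementSize"]])
  origin <- if (!is.na(h["Offset"])) num3(h[["Offset"]]) else c(0, 0, 0)
  nchan <- if (!is.na(h["ElementNumberOfChannels"])) as.integer(h[["ElementNumberOfChannels"]]) else 1L
  etype <- trimws(h[["ElementType"]])
  if (!etype %in% names(mhd_type_map)) {
    stop("unsupported MetaImage ElementType: ", etype, call. = FALSE)
  }
  datafile <- trimws(h[["ElementDataFile"]])
  n <- prod(sz) * nchan
  if (toupper(datafile) == "LOCAL") {
    vals <- readBin(con, "numeric", n = n, size = mhd_type_size[[etype]],
                    endian = "little")
  } else {
    raw_path <- file.path(dirname(path), datafile)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, "numeric", n = n, size = mhd_type_size[[etype]],
                    endian = "little")
  }
  if (length(vals) != n) stop("MetaImage data shorter than header declares", call. = FALSE)
  header <- volume_header(origin = origin, spacing = spacing, size = sz)
  if (nchan == 1L) {
    list(header = header, data = array(vals, dim = sz), channels = 1L)
  } else {
    # interleaved components -> [i,j,k,c]
    arr <- aperm(array(vals, dim = c(nchan, sz)), c(2, 3, 4, 1))
    list(header = header, data = arr, channels = nchan)
  }
}

#' @noRd
write_mhd_volume <- function(data, header, path, element_type = "MET_DOUBLE") {
  nchan <- if (length(dim(data)) == 4L) dim(data)[4] else 1L
  one_file <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (one_file) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(header$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(header$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(header$size, collapse = " ")),
    if (nchan > 1L) paste("ElementNumberOfChannels =", nchan),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", datafile)
  )
  vals <- if (nchan > 1L) as.numeric(aperm(data, c(4, 1, 2, 3))) else as.numeric(data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  size <- mhd_type_size[[element_type]]
  if (one_file) {
    writeBin(vals, con, size = size, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(vals, rcon, size = size, endian = "little")
  }
  invisible(path)
}
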