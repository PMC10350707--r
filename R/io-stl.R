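# ASCII STL read/write for lumen surface meshes. STL stores loose triangles;
# on reading, vertices are merged exactly (identical coordinate strings) to
# rebuild an indexed mesh.

#' Read or write a lumen surface mesh as ASCII STL
#'
#' @param path STL file path.
#' @return `read_stl()`: a [surface_mesh()].
#' @export
read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L) {
    stop("not a valid ASCII STL file: ", path, call. = FALSE)
  }
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  key <- apply(coords, 1L, paste, collapse = ",")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  verts <- coords[uk, , drop = FALSE]
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' @param mesh a [surface_mesh()].
#' @rdname read_stl
#' @export
write_stl <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid lumen", con)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(nrm^2))
  nn[nn == 0] <- 1
  nrm <- nrm / nn
  blocks <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], cc[, 1], cc[, 2], cc[, 3])
  writeLines(blocks, con)
  writeLines("endsolid lumen", con)
  invisible(path)
}
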