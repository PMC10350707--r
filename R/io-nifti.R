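# NIfTI-1 adapter built on RNifti. Vector fields are stored as 4-d volumes
# (x, y, z, component); the sform affine carries origin and spacing. Only
# axis-aligned affines (diagonal, positive) are accepted.

#' @noRd
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6 || any(diag(rot) <= 0)) {
    stop("non-axis-aligned NIfTI orientation: axis-aligned grids only",
         call. = FALSE)
  }
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop niftiImage metadata
  d <- dim(arr)
  # tolerate the 5-d NIfTI vector layout (x, y, z, 1, component)
  if (length(d) == 5L && d[4] == 1L) {
    arr <- array(arr, dim = d[c(1:3, 5)])
    d <- dim(arr)
  }
  header <- volume_header(origin = aff[1:3, 4], spacing = diag(rot),
                          size = d[1:3])
  if (length(d) == 3L) {
    list(header = header, data = arr, channels = 1L)
  } else {
    list(header = header, data = arr, channels = d[4])
  }
}

#' @noRd
write_nifti_volume <- function(data, header, path) {
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  img <- RNifti::`pixdim<-`(img, c(header$spacing, rep(1, nd - 3L)))
  m <- diag(4)
  m[cbind(1:3, 1:3)] <- header$spacing
  m[1:3, 4] <- header$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
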