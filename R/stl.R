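#' Write a mesh as binary STL
#'
#' Binary STL dialect: an 80-byte header, a little-endian `uint32` triangle
#' count, then 50 bytes per triangle — twelve little-endian 32-bit floats
#' (unit normal, three vertices) and a 2-byte attribute set to zero. File
#' size is always `84 + 50 * n_triangles` bytes.
#'
#' @param mesh A `"triangle_mesh"`.
#' @param path Output file path.
#' @param header Optional header string (truncated/padded to 80 bytes).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, header = "msdseg binary STL") {
  stopifnot(inherits(mesh, "triangle_mesh"))
  nt <- nrow(mesh$triangles)
  hdr <- charToRaw(header)
  hdr <- c(hdr[seq_len(min(80L, length(hdr)))],
           raw(80L - min(80L, length(hdr))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.integer(nt), con, size = 4L, endian = "little")
  if (nt > 0L) {
    floats <- rbind(t(mesh$normals),
                    t(mesh$vertices[mesh$triangles[, 1L], , drop = FALSE]),
                    t(mesh$vertices[mesh$triangles[, 2L], , drop = FALSE]),
                    t(mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]))
    fraw <- writeBin(as.numeric(floats), raw(), size = 4L, endian = "little")
    payload <- rbind(matrix(fraw, nrow = 48L), matrix(as.raw(0L), 2L, nt))
    writeBin(as.vector(payload), con)
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' Parses the dialect written by [write_stl()] (the common binary STL
#' layout). Identical vertex coordinates are welded back into an indexed
#' mesh; the triangle float payload round-trips bit-exactly at 32-bit
#' precision.
#'
#' @param path File path.
#' @return A `"triangle_mesh"`.
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 84) stop("malformed STL: file shorter than 84 bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, raw(), n = 80L))
  nt <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  if (sz != 84 + 50 * nt)
    stop(sprintf("malformed STL: expected %d bytes for %d triangles, found %d",
                 84 + 50 * nt, nt, sz))
  if (nt == 0L)
    return(triangle_mesh(matrix(numeric(0), 0L, 3L),
                         matrix(integer(0), 0L, 3L)))
  body <- readBin(con, raw(), n = 50L * nt)
  bm <- matrix(body, nrow = 50L)
  floats <- readBin(as.vector(bm[1:48, , drop = FALSE]), numeric(),
                    n = 12L * nt, size = 4L, endian = "little")
  fm <- matrix(floats, nrow = 12L) # per column: normal, v1, v2, v3
  coords <- rbind(t(fm[4:6, , drop = FALSE]),
                  t(fm[7:9, , drop = FALSE]),
                  t(fm[10:12, , drop = FALSE]))
  # coords rows: all v1, then all v2, then all v3
  key <- paste(coords[, 1L], coords[, 2L], coords[, 3L])
  idx <- match(key, key[!duplicated(key)])
  verts <- coords[!duplicated(key), , drop = FALSE]
  tris <- cbind(idx[seq_len(nt)], idx[nt + seq_len(nt)],
                idx[2L * nt + seq_len(nt)])
  mesh <- triangle_mesh(verts, tris)
  # keep the stored normals so a rewrite reproduces the file bit-exactly
  mesh$normals <- t(fm[1:3, , drop = FALSE])
  mesh
}
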