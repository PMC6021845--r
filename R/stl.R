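#' Write a mesh to STL
#'
#' Binary STL layout: an 80-byte header, a little-endian uint32 triangle
#' count, then 50 bytes per triangle (facet normal and three vertices as
#' float32 triples, followed by a zero uint16 attribute). A unit cube (12
#' triangles) is therefore exactly 80 + 4 + 12*50 = 684 bytes. The ASCII
#' dialect writes the same triangle set as `facet`/`vertex` records. Normals
#' are recomputed from the counter-clockwise winding at write time; internal
#' computation is double precision, with float32 only at the binary boundary
#' (the format mandates it).
#'
#' @param mesh a `loc_mesh`.
#' @param path output path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @param name solid name for the ASCII dialect / binary header comment.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii"), name = "chipmold") {
  stopifnot(inherits(mesh, "loc_mesh"))
  format <- match.arg(format)
  if (any(!is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  tc <- tri_corners(mesh)
  u <- tc$b - tc$a; v <- tc$c - tc$a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  nt <- nrow(mesh$triangles)

  if (format == "binary") {
    hdr <- raw(80)
    cm <- charToRaw(sprintf("%s binary STL", name))
    hdr[seq_along(cm)] <- cm
    # 12 float32 per triangle: normal, v1, v2, v3 (row-per-triangle interleave)
    f <- t(cbind(nrm, tc$a, tc$b, tc$c))      # 12 x nt
    fr <- writeBin(as.vector(f), raw(), size = 4, endian = "little")
    rec <- matrix(as.raw(0), 50, nt)
    if (nt > 0) rec[1:48, ] <- matrix(fr, 48, nt)
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(hdr, con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    writeBin(as.vector(rec), con)
  } else {
    fmt <- paste0("  facet normal %.9g %.9g %.9g\n    outer loop\n",
                  "      vertex %.9g %.9g %.9g\n      vertex %.9g %.9g %.9g\n",
                  "      vertex %.9g %.9g %.9g\n    endloop\n  endfacet")
    body <- sprintf(fmt, nrm[, 1], nrm[, 2], nrm[, 3],
                    tc$a[, 1], tc$a[, 2], tc$a[, 3],
                    tc$b[, 1], tc$b[, 2], tc$b[, 3],
                    tc$c[, 1], tc$c[, 2], tc$c[, 3])
    writeLines(c(sprintf("solid %s", name), body, sprintf("endsolid %s", name)),
               path)
  }
  invisible(path)
}

#' Read an STL file
#'
#' Auto-detects the binary and ASCII dialects. Stored normals are discarded
#' and implied by winding; identical vertex coordinates are welded back into
#' an indexed mesh. Binary files whose payload length disagrees with the
#' declared triangle count are rejected.
#'
#' @param path STL file path.
#' @return a `loc_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  sz <- file.info(path)$size
  if (sz < 84) {
    if (is_ascii_stl(path)) return(read_stl_ascii(path))
    stop("file too short to be a binary STL: ", path)
  }
  con <- file(path, "rb")
  hdr <- readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  close(con)
  if (!is.na(nt) && nt >= 0 && sz == 84 + 50 * as.numeric(nt))
    return(read_stl_binary(path, nt))
  if (is_ascii_stl(path)) return(read_stl_ascii(path))
  stop(sprintf(
    "corrupt binary STL: %d triangles declared need %d bytes, file has %d",
    nt, 84 + 50 * as.numeric(nt), sz))
}

is_ascii_stl <- function(path) {
  n <- min(512, file.info(path)$size)
  bytes <- readBin(path, "raw", n)
  head <- rawToChar(bytes[bytes != as.raw(0)])
  grepl("^\\s*solid", head, useBytes = TRUE) &&
    grepl("facet|endsolid", head, useBytes = TRUE)
}

read_stl_binary <- function(path, nt) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 84)
  payload <- readBin(con, "raw", 50 * nt)
  rec <- matrix(payload, 50, nt)
  f <- readBin(as.vector(rec[1:48, , drop = FALSE]), "double",
               n = 12 * nt, size = 4, endian = "little")
  f <- matrix(f, 12, nt)                       # normal + 3 vertices per column
  vtx <- matrix(as.vector(f[4:12, , drop = FALSE]), ncol = 3, byrow = TRUE)
  soup_to_mesh(vtx)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\b", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: vertex count ", length(vl), " is not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(!is.finite(nums))) stop("non-finite coordinates in ASCII STL")
  soup_to_mesh(nums)
}

# weld a (3T x 3) triangle soup back into an indexed mesh
soup_to_mesh <- function(vtx) {
  key <- paste(vtx[, 1], vtx[, 2], vtx[, 3])
  uk <- unique(key)
  map <- match(key, uk)
  mesh_spec(vtx[match(uk, key), , drop = FALSE],
            matrix(map, ncol = 3, byrow = TRUE))
}
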