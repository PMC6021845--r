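#' Extrude a blueprint into a voxel grid
#'
#' Each blueprint pixel becomes one voxel column: `base_layers` voxels of base
#' slab everywhere, plus the palette height of the pixel's role on top. The
#' grid therefore satisfies the contiguous-column invariant (no floating
#' voxels), which is what makes the later surface extraction exact. Voxel
#' `(x, y, z)` occupies the half-open box
#' `[x*s,(x+1)*s) x [y*s,(y+1)*s) x [z*s,(z+1)*s)` in mm, with `s` the voxel
#' edge from `scale`, `x` increasing along blueprint columns and `y` along
#' blueprint rows (row 1 = top).
#'
#' @param bp a `loc_blueprint`.
#' @param palette palette supplying role heights; defaults to the blueprint's.
#' @param base_layers thickness of the base slab in voxel layers (default 2).
#' @param scale a `loc_scale` giving the voxel edge in mm.
#' @param max_height vertical voxel limit (default 256).
#' @return an object of class `loc_voxelgrid`: fields `heights` (`H x W`
#'   integer matrix of total column heights in voxels), `nx`, `ny`, `nz`,
#'   `voxel_size_mm`, `base_layers`, `max_height`.
#' @export
blueprint_to_grid <- function(bp, palette = bp$palette, base_layers = 2L,
                              scale = compute_scale(1, 1), max_height = 256L) {
  stopifnot(inherits(bp, "loc_blueprint"), inherits(palette, "loc_palette"),
            inherits(scale, "loc_scale"))
  if (base_layers < 0) stop("base_layers must be non-negative")
  if (bp$width_px < 1 || bp$height_px < 1) stop("empty blueprint")
  hb <- role_height(palette, as.vector(bp$roles))
  nz <- as.integer(base_layers + max(palette$entries$height_blocks))
  if (nz > max_height)
    stop(sprintf("height budget exceeded: base_layers %d + max role height %d > max_height %d",
                 base_layers, max(palette$entries$height_blocks), max_height))
  heights <- matrix(as.integer(base_layers + hb),
                    nrow = bp$height_px, ncol = bp$width_px)
  structure(list(heights = heights,
                 nx = bp$width_px, ny = bp$height_px, nz = nz,
                 voxel_size_mm = scale$mm_per_pixel,
                 base_layers = as.integer(base_layers),
                 max_height = as.integer(max_height)),
            class = "loc_voxelgrid")
}

#' Number of occupied voxels in a grid
#' @param grid a `loc_voxelgrid`.
#' @return integer count.
#' @export
occupied_voxels <- function(grid) {
  stopifnot(inherits(grid, "loc_voxelgrid"))
  sum(as.numeric(grid$heights))
}

#' Materialize the boolean occupancy array
#'
#' Expands the column-height representation into the full `nx x ny x nz`
#' logical array. Intended for small grids (tests, debugging); the height
#' matrix is the canonical representation.
#'
#' @param grid a `loc_voxelgrid`.
#' @return logical array indexed `[x, y, z]`.
#' @export
occupancy <- function(grid) {
  stopifnot(inherits(grid, "loc_voxelgrid"))
  h <- t(grid$heights)  # nx x ny
  arr <- array(FALSE, dim = c(grid$nx, grid$ny, grid$nz))
  if (grid$nz > 0)
    for (z in seq_len(grid$nz)) arr[, , z] <- h >= z
  arr
}

#' Check grid dimensions against the supported capacity
#'
#' The pipeline is sized for grids up to `1000*k` voxels per horizontal axis
#' (capacity multiplier `k >= 1`) and `max_height` voxels vertically
#' (default 256). The reference workload, a 1000 x 1000 blueprint with
#' 120-voxel columns, passes at `k = 1`.
#'
#' @param W,H,Z grid dimensions in voxels.
#' @param max_height vertical limit (default 256).
#' @param k horizontal capacity multiplier (default 1).
#' @return `TRUE` if the grid is within capacity.
#' @export
grid_capacity_check <- function(W, H, Z, max_height = 256L, k = 1L) {
  if (k < 1) stop("capacity multiplier k must be >= 1")
  W <= 1000 * k && H <= 1000 * k && Z <= max_height
}

# Grid container format, version 1 (little endian):
#   bytes 0-3   magic "CMVG"
#   int32       version (1)
#   int32 x 4   nx, ny, base_layers, max_height
#   float64     voxel_size_mm
#   int32       nz
#   int32 x (nx*ny)  column heights, column-major over the H x W matrix
GRID_MAGIC <- charToRaw("CMVG")

#' Persist / load a voxel grid
#'
#' Writes the grid to a small versioned binary container (magic header,
#' dimensions, voxel size, base-slab thickness, then the column-height matrix
#' as int32). `read_grid(write_grid(g))` reproduces `g` bit-exactly, metadata
#' included. Truncated or foreign files are rejected.
#'
#' @param grid a `loc_voxelgrid`.
#' @param path file path.
#' @return `write_grid()` returns `path` invisibly; `read_grid()` returns the
#'   `loc_voxelgrid`.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "loc_voxelgrid"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(GRID_MAGIC, con)
  writeBin(as.integer(c(1L, grid$nx, grid$ny, grid$base_layers, grid$max_height)),
           con, size = 4, endian = "little")
  writeBin(as.double(grid$voxel_size_mm), con, size = 8, endian = "little")
  writeBin(as.integer(grid$nz), con, size = 4, endian = "little")
  writeBin(as.integer(grid$heights), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (length(magic) < 4 || !identical(magic, GRID_MAGIC))
    stop("not a chipmold grid container: ", path)
  hdr <- readBin(con, "integer", 5, size = 4, endian = "little")
  if (length(hdr) < 5) stop("corrupt grid container (truncated header)")
  if (hdr[1] != 1L) stop("unsupported grid container version: ", hdr[1])
  nx <- hdr[2]; ny <- hdr[3]
  vs <- readBin(con, "double", 1, size = 8, endian = "little")
  nz <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 4 + 5 * 4 + 8 + 4 + 4 * as.numeric(nx) * ny
  if (sz != expected)
    stop(sprintf("corrupt grid container: %d bytes on disk, %d expected", sz, expected))
  hvec <- readBin(con, "integer", nx * ny, size = 4, endian = "little")
  structure(list(heights = matrix(hvec, nrow = ny, ncol = nx),
                 nx = nx, ny = ny, nz = nz,
                 voxel_size_mm = vs,
                 base_layers = hdr[4], max_height = hdr[5]),
            class = "loc_voxelgrid")
}

#' Export occupied voxel coordinates as CSV
#'
#' Debug helper: writes one `(x, y, z)` row (0-based voxel indices) per
#' occupied voxel. Only sensible for small grids.
#'
#' @param grid a `loc_voxelgrid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
grid_coords_csv <- function(grid, path) {
  stopifnot(inherits(grid, "loc_voxelgrid"))
  h <- t(grid$heights)
  idx <- which(h > 0, arr.ind = TRUE)
  reps <- h[h > 0]
  df <- data.frame(x = rep(idx[, 1] - 1L, reps),
                   y = rep(idx[, 2] - 1L, reps),
                   z = sequence(reps) - 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.loc_voxelgrid <- function(x, ...) {
  cat(sprintf("Voxel grid %d x %d x %d, voxel %g mm, base slab %d layer(s)\n",
              x$nx, x$ny, x$nz, x$voxel_size_mm, x$base_layers))
  cat(sprintf("  occupied voxels: %.0f\n", occupied_voxels(x)))
  invisible(x)
}
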