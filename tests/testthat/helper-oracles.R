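# Independent brute-force oracles, kept deliberately naive.

# Build a voxel grid directly from a column-height matrix (H x W, rows = y).
grid_from_heights <- function(heights, voxel_size_mm = 1, base_layers = 0L,
                              max_height = 256L) {
  heights <- as.matrix(heights)
  storage.mode(heights) <- "integer"
  structure(list(heights = heights,
                 nx = ncol(heights), ny = nrow(heights),
                 nz = max(heights, 1L),
                 voxel_size_mm = voxel_size_mm,
                 base_layers = as.integer(base_layers),
                 max_height = as.integer(max_height)),
            class = "loc_voxelgrid")
}

rand_heights <- function(nx, ny, zmax) {
  matrix(sample(0:zmax, nx * ny, replace = TRUE), ny, nx)
}

# Exhaustive neighbor enumeration: number of (occupied voxel, empty/out-of-
# bounds neighbor) face pairs in a boolean occupancy array.
brute_exposed_faces <- function(occ) {
  d <- dim(occ)
  at <- function(x, y, z) {
    if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) FALSE
    else occ[x, y, z]
  }
  n <- 0L
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!occ[x, y, z]) next
    n <- n + sum(!c(at(x - 1, y, z), at(x + 1, y, z), at(x, y - 1, z),
                    at(x, y + 1, z), at(x, y, z - 1), at(x, y, z + 1)))
  }
  n
}

# Number of pinch (checkerboard-corner) unit edges of a heightmap solid:
# vertical lattice edges where two diagonal columns are both strictly taller
# than both anti-diagonal columns.
brute_pinch_edges <- function(heights) {
  h <- t(as.matrix(heights))  # h[x, y]
  nx <- nrow(h); ny <- ncol(h)
  n <- 0L
  if (nx < 2 || ny < 2) return(0L)
  for (i in 1:(nx - 1)) for (j in 1:(ny - 1)) {
    a <- h[i, j]; b <- h[i + 1, j]; cc <- h[i, j + 1]; d <- h[i + 1, j + 1]
    n <- n + max(0L, min(a, d) - max(b, cc)) + max(0L, min(b, cc) - max(a, d))
  }
  n
}

# Undirected edge multiplicities of a mesh, counted from scratch.
brute_edge_counts <- function(mesh) {
  t3 <- mesh$triangles
  e <- rbind(t3[, 1:2], t3[, 2:3], t3[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

# 4-connected components of a logical matrix (flood fill).
count_components <- function(mask) {
  mask <- as.matrix(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    n <- n + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- p[1]; c <- p[2]
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask)) next
      if (!mask[r, c] || lab[r, c] > 0) next
      lab[r, c] <- n
      stack <- c(stack, list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1)))
    }
  }
  n
}

# palette with tall roles used for capacity-scale runs
tall_palette <- function() {
  palette_spec(data.frame(
    role = c("base", "channel", "chamber", "inlet_small", "inlet_large"),
    r = c(255, 0, 255, 255, 0), g = c(255, 0, 0, 255, 0),
    b = c(255, 0, 0, 0, 255),
    height_blocks = c(0L, 24L, 48L, 72L, 118L)))
}
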