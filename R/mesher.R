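#' Convert a voxel grid into a watertight triangle mesh
#'
#' Emits exactly the exposed voxel faces — faces between an occupied voxel and
#' an unoccupied or out-of-bounds neighbor — each as two triangles with
#' counter-clockwise outward winding, welded into an indexed mesh. The model's
#' minimum corner sits at the origin with the flat base on `z = 0` ("backdown"
#' print orientation) and coordinates in mm. The enclosed volume equals
#' `occupied_voxels(grid) * voxel_size_mm^3` exactly.
#'
#' Checkerboard height configurations (two diagonal columns both taller than
#' both anti-diagonal neighbors) pinch the voxel surface along a vertical
#' edge, where four wall quads would meet. To keep every undirected edge
#' shared by exactly two oppositely-oriented triangles, the two wall quads of
#' one designated diagonal column are fan-triangulated with the pinch-edge
#' midpoint inserted (a coplanar subdivision: no volume change, no duplicate
#' vertices, geometrically sealed T-vertices on the pinch line only).
#'
#' @param grid a `loc_voxelgrid` with at least one occupied voxel.
#' @return an object of class `loc_mesh`: `vertices` (`V x 3` numeric matrix,
#'   mm) and `triangles` (`T x 3` integer matrix, 1-based, CCW outward).
#' @export
grid_to_mesh <- function(grid) {
  stopifnot(inherits(grid, "loc_voxelgrid"))
  nx <- grid$nx; ny <- grid$ny; s <- grid$voxel_size_mm
  h <- t(grid$heights)                       # nx x ny, h[x, y]
  if (sum(as.numeric(h)) == 0) stop("empty grid: no occupied voxels")

  # --- pinch-edge table -----------------------------------------------------
  # keys encode (corner i, corner j, z-unit); designated column keyed separately
  kx <- ny + 2; kz <- max(h) + 2
  ekey <- function(i, j, z) (i * kx + j) * kz + z
  ckey <- function(cx, cy) cx * kx + cy
  pinch_ekey <- numeric(0); pinch_ckey <- numeric(0)
  if (nx > 1 && ny > 1) {
    A <- h[1:(nx - 1), 1:(ny - 1), drop = FALSE]
    B <- h[2:nx,       1:(ny - 1), drop = FALSE]
    C <- h[1:(nx - 1), 2:ny,       drop = FALSE]
    D <- h[2:nx,       2:ny,       drop = FALSE]
    for (case in 1:2) {
      if (case == 1) { hi <- pmin(A, D); lo <- pmax(B, C) }  # designate (i+1, j+1)
      else           { hi <- pmin(B, C); lo <- pmax(A, D) }  # designate (i+1, j)
      w <- which(hi > lo)
      if (length(w)) {
        ai <- arrayInd(w, dim(hi))
        cnt <- (hi - lo)[w]
        ii <- rep(ai[, 1], cnt); jj <- rep(ai[, 2], cnt)
        zz <- rep(lo[w], cnt) + sequence(cnt) - 1L
        pinch_ekey <- c(pinch_ekey, ekey(ii, jj, zz))
        pinch_ckey <- c(pinch_ckey,
                        if (case == 1) ckey(ii + 1L, jj + 1L) else ckey(ii + 1L, jj))
      }
    }
  }
  has_pinch <- length(pinch_ekey) > 0

  # --- quad emission --------------------------------------------------------
  # corners stored in doubled lattice coordinates so pinch midpoints stay
  # integral; each block: corners = n x 12 (c1..c4), subA/subB flags with the
  # cyclic edge position (1:(c1,c2) .. 4:(c4,c1)) carrying the pinch midpoint.
  blocks <- list()
  add_block <- function(corners, subA = NULL, posA = 0L, subB = NULL, posB = 0L) {
    if (nrow(corners) == 0) return(invisible())
    n <- nrow(corners)
    if (is.null(subA)) subA <- rep(FALSE, n)
    if (is.null(subB)) subB <- rep(FALSE, n)
    blocks[[length(blocks) + 1L]] <<- list(c = corners, subA = subA, posA = posA,
                                           subB = subB, posB = posB)
    invisible()
  }
  quad12 <- function(x1, y1, z1, x2, y2, z2, x3, y3, z3, x4, y4, z4)
    cbind(x1, y1, z1, x2, y2, z2, x3, y3, z3, x4, y4, z4) * 2

  # top and bottom faces
  occ <- which(h > 0)
  oc <- arrayInd(occ, dim(h)); cx <- oc[, 1]; cy <- oc[, 2]; ht <- h[occ]
  add_block(quad12(cx - 1L, cy - 1L, ht,  cx, cy - 1L, ht,
                   cx,      cy,      ht,  cx - 1L, cy, ht))
  add_block(quad12(cx - 1L, cy - 1L, 0L,  cx - 1L, cy, 0L,
                   cx,      cy,      0L,  cx, cy - 1L, 0L))

  hp <- matrix(0L, nx + 2, ny + 2); hp[2:(nx + 1), 2:(ny + 1)] <- h

  wall_sub <- function(e1i, e1j, e2i, e2j, z, gcx, gcy) {
    # returns list(subA, subB) for vertical edges at corners (e1i,e1j), (e2i,e2j)
    if (!has_pinch) return(list(a = rep(FALSE, length(z)), b = rep(FALSE, length(z))))
    gk <- ckey(gcx, gcy)
    m1 <- match(ekey(e1i, e1j, z), pinch_ekey)
    m2 <- match(ekey(e2i, e2j, z), pinch_ekey)
    list(a = !is.na(m1) & pinch_ckey[m1] == gk,
         b = !is.na(m2) & pinch_ckey[m2] == gk)
  }

  expand_wall <- function(DL, DR) {
    # DL: heights left/below of plane, DR: right/above; both (nplanes x ncells)
    Dm <- DL - DR
    out <- list()
    for (sgn in c(1, -1)) {
      w <- which(sgn * Dm > 0)
      if (!length(w)) { out[[if (sgn > 0) "pos" else "neg"]] <- NULL; next }
      ai <- arrayInd(w, dim(Dm))
      cnt <- abs(Dm[w])
      p <- rep(ai[, 1] - 1L, cnt)     # plane index 0..nplanes-1
      j <- rep(ai[, 2], cnt)          # cell index 1..ncells
      z0 <- rep((if (sgn > 0) DR else DL)[w], cnt) + sequence(cnt) - 1L
      out[[if (sgn > 0) "pos" else "neg"]] <- list(p = p, j = j, z = z0)
    }
    out
  }

  # walls on x-planes (normal +/- x)
  wx <- expand_wall(hp[1:(nx + 1), 2:(ny + 1), drop = FALSE],
                    hp[2:(nx + 2), 2:(ny + 1), drop = FALSE])
  if (!is.null(wx$pos)) with(wx$pos, {
    sub <- wall_sub(p, j, p, j - 1L, z, p, j)          # gen column (p, j)
    add_block(quad12(p, j - 1L, z,  p, j, z,  p, j, z + 1L,  p, j - 1L, z + 1L),
              subA = sub$a, posA = 2L, subB = sub$b, posB = 4L)
  })
  if (!is.null(wx$neg)) with(wx$neg, {
    sub <- wall_sub(p, j - 1L, p, j, z, p + 1L, j)     # gen column (p+1, j)
    add_block(quad12(p, j - 1L, z,  p, j - 1L, z + 1L,  p, j, z + 1L,  p, j, z),
              subA = sub$a, posA = 1L, subB = sub$b, posB = 3L)
  })

  # walls on y-planes (normal +/- y)
  wy <- expand_wall(t(hp[2:(nx + 1), 1:(ny + 1), drop = FALSE]),
                    t(hp[2:(nx + 1), 2:(ny + 2), drop = FALSE]))
  if (!is.null(wy$pos)) with(wy$pos, {
    # plane q = p, cell x = j, gen column (j, p)
    sub <- wall_sub(j - 1L, p, j, p, z, j, p)
    add_block(quad12(j - 1L, p, z,  j - 1L, p, z + 1L,  j, p, z + 1L,  j, p, z),
              subA = sub$a, posA = 1L, subB = sub$b, posB = 3L)
  })
  if (!is.null(wy$neg)) with(wy$neg, {
    sub <- wall_sub(j, p, j - 1L, p, z, j, p + 1L)
    add_block(quad12(j - 1L, p, z,  j, p, z,  j, p, z + 1L,  j - 1L, p, z + 1L),
              subA = sub$a, posA = 2L, subB = sub$b, posB = 4L)
  })

  # --- triangulation --------------------------------------------------------
  M <- do.call(rbind, lapply(blocks, `[[`, "c"))
  subA <- unlist(lapply(blocks, `[[`, "subA")); posA <- rep(vapply(blocks, `[[`, 0L, "posA"), vapply(blocks, function(b) nrow(b$c), 0L))
  subB <- unlist(lapply(blocks, `[[`, "subB")); posB <- rep(vapply(blocks, `[[`, 0L, "posB"), vapply(blocks, function(b) nrow(b$c), 0L))
  n <- nrow(M)
  corner_ids <- function(q) c(q, n + q, 2L * n + q, 3L * n + q)
  Cmat <- rbind(M[, 1:3, drop = FALSE], M[, 4:6, drop = FALSE],
                M[, 7:9, drop = FALSE], M[, 10:12, drop = FALSE])

  subq <- which(subA | subB)
  reg <- if (length(subq)) seq_len(n)[-subq] else seq_len(n)
  tri_ids <- rbind(cbind(reg, n + reg, 2L * n + reg),
                   cbind(reg, 2L * n + reg, 3L * n + reg))

  extraV <- NULL
  if (length(subq)) {
    ev <- list(); et <- list(); next_id <- 4L * n
    for (q in subq) {
      b <- corner_ids(q)
      mids <- integer(0)                      # cyclic edge position of each midpoint
      if (subA[q]) mids <- c(mids, posA[q])
      if (subB[q]) mids <- c(mids, posB[q])
      mids <- sort(mids)
      poly <- integer(0); midflag <- logical(0)
      for (i in 1:4) {
        poly <- c(poly, b[i]); midflag <- c(midflag, FALSE)
        if (i %in% mids) {
          nxt <- b[i %% 4L + 1L]
          ev[[length(ev) + 1L]] <- (Cmat[b[i], ] + Cmat[nxt, ]) / 2
          next_id <- next_id + 1L
          poly <- c(poly, next_id); midflag <- c(midflag, TRUE)
        }
      }
      m <- length(poly); k <- which(midflag)[1]
      ord <- c(k:m, seq_len(k - 1L))          # rotate so fan apex first
      poly <- poly[ord]
      et[[length(et) + 1L]] <- cbind(poly[1], poly[2:(m - 1L)], poly[3:m])
    }
    extraV <- do.call(rbind, ev)
    tri_ids <- rbind(tri_ids, do.call(rbind, et))
  }

  allV <- if (is.null(extraV)) Cmat else rbind(Cmat, extraV)
  kxv <- 2 * nx + 2; kyv <- 2 * ny + 2
  keys <- allV[, 1] + kxv * (allV[, 2] + kyv * allV[, 3])
  uk <- unique(keys)
  map <- match(keys, uk)
  verts <- allV[match(uk, keys), , drop = FALSE] / 2 * s
  tris <- matrix(map[tri_ids], ncol = 3)
  structure(list(vertices = verts, triangles = tris), class = "loc_mesh")
}

#' Construct a triangle mesh from raw arrays
#'
#' @param vertices `V x 3` numeric matrix (mm).
#' @param triangles `T x 3` integer matrix of 1-based vertex indices with
#'   counter-clockwise outward winding.
#' @return a `loc_mesh`.
#' @export
mesh_spec <- function(vertices, triangles) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            all(triangles >= 1), all(triangles <= nrow(vertices)))
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  structure(list(vertices = vertices, triangles = triangles), class = "loc_mesh")
}

# per-triangle corner coordinate matrices
tri_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$triangles[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$triangles[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$triangles[, 3], , drop = FALSE])
}

#' Signed enclosed volume of a closed mesh
#'
#' Sums the signed volumes of tetrahedra spanned by each triangle and the
#' origin (divergence theorem). Positive for outward-oriented meshes; flipping
#' every winding negates the result. Open meshes are rejected.
#'
#' @param mesh a `loc_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "loc_mesh"))
  nb <- n_boundary_edges(mesh)
  if (nb > 0)
    stop("mesh is not closed: ", nb, " boundary edge(s); volume is undefined")
  signed_volume(mesh)
}

signed_volume <- function(mesh) {
  tc <- tri_corners(mesh)
  a <- tc$a; b <- tc$b; cc <- tc$c
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

edge_tables <- function(mesh) {
  t3 <- mesh$triangles
  ed <- rbind(t3[, 1:2, drop = FALSE], t3[, 2:3, drop = FALSE], t3[, c(3, 1), drop = FALSE])
  nv <- nrow(mesh$vertices) + 1
  lo <- pmin(ed[, 1], ed[, 2]); hi <- pmax(ed[, 1], ed[, 2])
  list(dir = as.numeric(ed[, 1]) * nv + ed[, 2],
       und = as.numeric(lo) * nv + hi)
}

n_boundary_edges <- function(mesh) {
  et <- edge_tables(mesh)
  cnt <- tabulate(match(et$und, unique(et$und)))
  sum(cnt == 1)
}

#' Validate a mesh for printability
#'
#' Checks the properties slicers rely on: closedness (no boundary edges),
#' edge-manifoldness (no undirected edge on more than two triangles),
#' consistent orientation (no directed edge repeated; every edge paired with
#' its reverse), and absence of degenerate (zero-area) triangles. Also reports
#' the signed volume. `is_watertight` is the conjunction of all checks.
#'
#' @param mesh a `loc_mesh`.
#' @return an object of class `loc_validation` with fields `is_closed`,
#'   `is_consistently_oriented`, `n_boundary_edges`, `n_nonmanifold_edges`,
#'   `n_degenerate_triangles`, `volume_mm3`, `is_watertight`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "loc_mesh"))
  et <- edge_tables(mesh)
  u_und <- unique(et$und)
  cnt_und <- tabulate(match(et$und, u_und))
  n_boundary <- sum(cnt_und == 1)
  n_nonmanifold <- sum(cnt_und > 2)
  u_dir <- unique(et$dir)
  cnt_dir <- tabulate(match(et$dir, u_dir))
  oriented <- max(cnt_dir) == 1 && n_boundary == 0 && n_nonmanifold == 0

  tc <- tri_corners(mesh)
  u <- tc$b - tc$a; v <- tc$c - tc$a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area2 <- sqrt(rowSums(cr^2))                  # 2x triangle area
  diag2 <- sum((apply(mesh$vertices, 2, max) - apply(mesh$vertices, 2, min))^2)
  n_degenerate <- sum(area2 <= 1e-12 * max(diag2, 1e-300))

  structure(list(
    is_closed = n_boundary == 0,
    is_consistently_oriented = oriented,
    n_boundary_edges = n_boundary,
    n_nonmanifold_edges = n_nonmanifold,
    n_degenerate_triangles = n_degenerate,
    volume_mm3 = signed_volume(mesh),
    is_watertight = n_boundary == 0 && n_nonmanifold == 0 && oriented &&
      n_degenerate == 0
  ), class = "loc_validation")
}

#' @export
print.loc_validation <- function(x, ...) {
  cat("Mesh validation:",
      if (x$is_watertight) "watertight\n" else "NOT watertight\n")
  cat(sprintf("  closed: %s | oriented: %s | boundary edges: %d | non-manifold edges: %d | degenerate: %d\n",
              x$is_closed, x$is_consistently_oriented, x$n_boundary_edges,
              x$n_nonmanifold_edges, x$n_degenerate_triangles))
  cat(sprintf("  enclosed volume: %.6g mm^3\n", x$volume_mm3))
  invisible(x)
}

#' @export
print.loc_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox: [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}
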