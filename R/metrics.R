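#' Top-view structure mask of a voxel grid
#'
#' A pixel is "structure" when its voxel column rises above the base slab,
#' i.e., column height > `base_layers`. This is the top-view footprint used by
#' the mold overlap comparison.
#'
#' @param grid a `loc_voxelgrid`.
#' @return an object of class `loc_mask`: `mask` (`H x W` logical matrix) and
#'   `pixel_size_mm`.
#' @export
topview_mask <- function(grid) {
  stopifnot(inherits(grid, "loc_voxelgrid"))
  structure(list(mask = grid$heights > grid$base_layers,
                 pixel_size_mm = grid$voxel_size_mm),
            class = "loc_mask")
}

#' Construct a top-view mask from a logical matrix
#' @param mask logical matrix (`TRUE` = structure above the base).
#' @param pixel_size_mm physical pixel edge in mm.
#' @return a `loc_mask`.
#' @export
mask_spec <- function(mask, pixel_size_mm = 1) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  structure(list(mask = mask, pixel_size_mm = pixel_size_mm), class = "loc_mask")
}

#' Read a top-view mask from a PNG/TIFF image (nonzero = structure)
#' @param path image path.
#' @param pixel_size_mm physical pixel edge in mm.
#' @return a `loc_mask`.
#' @export
read_mask <- function(path, pixel_size_mm = 1) {
  img <- read_image(path)
  mask_spec(img[, , 1] + img[, , 2] + img[, , 3] > 0, pixel_size_mm)
}

#' Overlap report from raw region counts
#'
#' The core of the mold-comparison statistic. The error region is the area
#' (in top-view pixels) where the two molds disagree; the total region is the
#' rectangular base of the blueprint. Then
#' `area_error_rate = error_region / total_region` and
#' `area_accuracy = 1 - area_error_rate`. The associated length error treats
#' the area accuracy as the square of a per-axis scale factor:
#' `length_error_rate = 1 - sqrt(area_accuracy)`, and
#' `length_error = length_error_rate * diagonal_length`. (A linear reading of
#' the area ratio does not reproduce published worked values; the square-root
#' reading does, to about 0.1%.)
#'
#' @param error_region_px non-overlapping (symmetric-difference) pixel count.
#' @param total_region_px total rectangular-base pixel count.
#' @param diagonal_length_mm optional model diagonal in mm; when supplied, the
#'   length-error fields are populated.
#' @return an object of class `loc_overlap` with fields `error_region_px`,
#'   `total_region_px`, `area_error_rate`, `area_accuracy`,
#'   `length_error_rate`, `diagonal_length_mm`, `length_error_mm` (the last
#'   two `NA` unless a diagonal is given). Values are unrounded; printing
#'   rounds to 3 decimals.
#' @export
overlap_report <- function(error_region_px, total_region_px,
                           diagonal_length_mm = NA_real_) {
  if (total_region_px <= 0) stop("total_region_px must be positive")
  if (error_region_px < 0 || error_region_px > total_region_px)
    stop("error_region_px must lie in [0, total_region_px]")
  rate <- error_region_px / total_region_px
  acc <- 1 - rate
  ler <- 1 - sqrt(acc)
  structure(list(
    error_region_px = error_region_px,
    total_region_px = total_region_px,
    area_error_rate = rate,
    area_accuracy = acc,
    length_error_rate = ler,
    diagonal_length_mm = diagonal_length_mm,
    length_error_mm = if (is.na(diagonal_length_mm)) NA_real_
                      else ler * diagonal_length_mm
  ), class = "loc_overlap")
}

#' Area accuracy of two top-view masks
#'
#' Overlays two equally-sized masks and counts the symmetric difference as the
#' error region; the total region defaults to the full rectangular extent.
#'
#' @param mask_a,mask_b `loc_mask` objects (or logical matrices) of equal
#'   dimensions.
#' @param total_region_px total-region pixel count; defaults to `W * H`.
#' @param diagonal_length_mm optional model diagonal; defaults to the mask
#'   rectangle's diagonal when a pixel size is known.
#' @return a `loc_overlap` report.
#' @export
area_accuracy <- function(mask_a, mask_b, total_region_px = NULL,
                          diagonal_length_mm = NULL) {
  a <- if (inherits(mask_a, "loc_mask")) mask_a else mask_spec(mask_a)
  b <- if (inherits(mask_b, "loc_mask")) mask_b else mask_spec(mask_b)
  if (!identical(dim(a$mask), dim(b$mask)))
    stop(sprintf("mask dimensions differ: %dx%d vs %dx%d",
                 nrow(a$mask), ncol(a$mask), nrow(b$mask), ncol(b$mask)))
  err <- sum(a$mask != b$mask)
  total <- total_region_px %||% length(a$mask)
  if (is.null(diagonal_length_mm)) {
    ps <- a$pixel_size_mm
    diagonal_length_mm <- if (is.null(ps)) NA_real_
      else sqrt((ncol(a$mask) * ps)^2 + (nrow(a$mask) * ps)^2)
  }
  overlap_report(err, total, diagonal_length_mm)
}

#' Length error over a model diagonal
#'
#' Converts an overlap report's area accuracy into a physical length error:
#' `(1 - sqrt(area_accuracy)) * diagonal_length_mm`. With zero error region
#' this is 0; with a fully disagreeing mask it equals the diagonal.
#'
#' @param report a `loc_overlap`.
#' @param diagonal_length_mm model diagonal in mm (positive).
#' @return length error in mm.
#' @export
length_error <- function(report, diagonal_length_mm) {
  stopifnot(inherits(report, "loc_overlap"))
  if (!is.finite(diagonal_length_mm) || diagonal_length_mm <= 0)
    stop("diagonal_length_mm must be positive")
  report$length_error_rate * diagonal_length_mm
}

#' Rasterize a mesh to a top-view structure mask
#'
#' Samples column occupancy at pixel centers: for each pixel the height of the
#' highest upward-facing triangle covering its center is found, and the pixel
#' is structure when that height exceeds the base height. Intended for the
#' axis-aligned extruded molds this package produces; `base_height_mm`
#' defaults to the lowest covered top height (the base-slab top).
#'
#' @param mesh a `loc_mesh`.
#' @param pixel_size_mm raster pixel edge in mm.
#' @param bbox optional `list(xlim =, ylim =)` shared raster rectangle;
#'   defaults to the mesh's own xy bounding box.
#' @param base_height_mm height of the base-slab top in mm (optional).
#' @return a `loc_mask`.
#' @export
rasterize_topview <- function(mesh, pixel_size_mm, bbox = NULL,
                              base_height_mm = NULL) {
  stopifnot(inherits(mesh, "loc_mesh"))
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
  v <- mesh$vertices
  if (is.null(bbox))
    bbox <- list(xlim = range(v[, 1]), ylim = range(v[, 2]))
  ps <- pixel_size_mm
  nxp <- max(1L, as.integer(ceiling((bbox$xlim[2] - bbox$xlim[1]) / ps - 1e-9)))
  nyp <- max(1L, as.integer(ceiling((bbox$ylim[2] - bbox$ylim[1]) / ps - 1e-9)))
  tops <- matrix(-Inf, nyp, nxp)

  tc <- tri_corners(mesh)
  u <- tc$b - tc$a; w <- tc$c - tc$a
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]      # z of face normal
  up <- which(nz > 1e-12)
  for (t in up) {
    ax <- tc$a[t, 1]; ay <- tc$a[t, 2]
    bx <- tc$b[t, 1]; by <- tc$b[t, 2]
    cx <- tc$c[t, 1]; cy <- tc$c[t, 2]
    zt <- max(tc$a[t, 3], tc$b[t, 3], tc$c[t, 3])
    i0 <- max(1L, floor((min(ax, bx, cx) - bbox$xlim[1]) / ps - 0.5) + 1L)
    i1 <- min(nxp, ceiling((max(ax, bx, cx) - bbox$xlim[1]) / ps + 0.5))
    j0 <- max(1L, floor((min(ay, by, cy) - bbox$ylim[1]) / ps - 0.5) + 1L)
    j1 <- min(nyp, ceiling((max(ay, by, cy) - bbox$ylim[1]) / ps + 0.5))
    if (i0 > i1 || j0 > j1) next
    px <- bbox$xlim[1] + (i0:i1 - 0.5) * ps
    py <- bbox$ylim[1] + (j0:j1 - 0.5) * ps
    PX <- matrix(px, length(py), length(px), byrow = TRUE)
    PY <- matrix(py, length(py), length(px))
    # barycentric sign tests (CCW in xy since nz > 0)
    s1 <- (bx - ax) * (PY - ay) - (by - ay) * (PX - ax)
    s2 <- (cx - bx) * (PY - by) - (cy - by) * (PX - bx)
    s3 <- (ax - cx) * (PY - cy) - (ay - cy) * (PX - cx)
    inside <- s1 >= -1e-9 & s2 >= -1e-9 & s3 >= -1e-9
    blockv <- tops[j0:j1, i0:i1, drop = FALSE]
    blockv[inside & blockv < zt] <- zt
    tops[j0:j1, i0:i1] <- blockv
  }
  covered <- is.finite(tops)
  if (!any(covered)) stop("mesh projects onto no pixel center at this pixel size")
  base <- base_height_mm %||% min(tops[covered])
  tol <- max(1e-6, 1e-4 * ps)
  mask_spec(covered & tops > base + tol, ps)
}

#' Compare two molds by top-view overlap
#'
#' Rasterizes both meshes to top-view masks on a shared grid covering the
#' union of their bounding rectangles, then applies the overlap statistic
#' ([area_accuracy()] and the diagonal length error). Deterministic given
#' `pixel_size_mm`; both meshes must be closed.
#'
#' @param mesh_a,mesh_b closed `loc_mesh` objects.
#' @param pixel_size_mm raster pixel edge in mm (use the source voxel size
#'   when comparing two grid-born meshes, for exactness).
#' @param base_height_mm optional shared base-slab top height.
#' @return a `loc_overlap` report.
#' @export
compare_meshes <- function(mesh_a, mesh_b, pixel_size_mm,
                           base_height_mm = NULL) {
  for (m in list(mesh_a, mesh_b)) {
    nb <- n_boundary_edges(m)
    if (nb > 0) stop("open mesh (", nb, " boundary edges); close it before comparing")
  }
  va <- mesh_a$vertices; vb <- mesh_b$vertices
  bbox <- list(xlim = range(c(va[, 1], vb[, 1])),
               ylim = range(c(va[, 2], vb[, 2])))
  ma <- rasterize_topview(mesh_a, pixel_size_mm, bbox, base_height_mm)
  mb <- rasterize_topview(mesh_b, pixel_size_mm, bbox, base_height_mm)
  area_accuracy(ma, mb)
}

#' @export
print.loc_overlap <- function(x, ...) {
  cat(sprintf("Overlap: error region %d px of %d px total\n",
              x$error_region_px, x$total_region_px))
  cat(sprintf("  area error rate: %.3f | area accuracy: %.3f\n",
              x$area_error_rate, x$area_accuracy))
  if (!is.na(x$diagonal_length_mm))
    cat(sprintf("  length error: %.3f mm over %.3f mm diagonal (rate %.4f)\n",
                x$length_error_mm, x$diagonal_length_mm, x$length_error_rate))
  invisible(x)
}

#' @export
print.loc_mask <- function(x, ...) {
  cat(sprintf("Top-view mask %d x %d px (%g mm/px): %d structure px\n",
              ncol(x$mask), nrow(x$mask), x$pixel_size_mm, sum(x$mask)))
  invisible(x)
}

#' Serialize an overlap report to JSON
#' @param report a `loc_overlap`.
#' @param path output path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
overlap_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "loc_overlap"))
  x <- unclass(report)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
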