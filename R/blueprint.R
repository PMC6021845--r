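#' Read a raster image as an RGB array
#'
#' Reads PNG or TIFF into an `H x W x 3` numeric array with channels in 0-255.
#' An alpha channel, if present, is dropped; grayscale images are promoted to
#' RGB by channel replication.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @return numeric array `H x W x 3`, values in 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG and TIFF are supported)"))
  as_rgb255(img)
}

#' Write an RGB array as a PNG image
#'
#' @param img numeric array `H x W x 3` (0-255) or matrix (grayscale 0-255).
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_rgb255(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

# Normalize any supported in-memory raster to H x W x 3 in 0-255.
as_rgb255 <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (length(dim(img)) != 3) stop("image must be a matrix or H x W x C array")
  if (dim(img)[3] >= 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3))
  if (dim(img)[3] == 1) img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3))
  if (any(dim(img)[1:2] < 1)) stop("zero-sized image")
  img <- img * if (max(img) <= 1 + 1e-9) 255 else 1
  storage.mode(img) <- "double"
  img
}

#' Resize a blueprint image (nearest neighbor)
#'
#' Shrinks an image so its longest side is at most `max_dim` pixels, preserving
#' the aspect ratio to the nearest integer. Resampling is nearest-neighbor and
#' never interpolates, so the output contains only colors already present in
#' the input — interpolation would manufacture out-of-palette colors along
#' feature edges. Images already within the bound are returned unchanged.
#'
#' @param img numeric array `H x W x 3` (or a matrix), see [read_image()].
#' @param max_dim positive integer bound on the longest side; conversion
#'   pipelines conventionally use about 150 px.
#' @return resized image array.
#' @export
resize_blueprint <- function(img, max_dim = 150L) {
  img <- as_rgb255(img)
  if (max_dim < 1) stop("max_dim must be >= 1")
  h <- dim(img)[1]; w <- dim(img)[2]
  long <- max(h, w)
  if (long <= max_dim) return(img)
  nh <- max(1L, as.integer(round(h * max_dim / long)))
  nw <- max(1L, as.integer(round(w * max_dim / long)))
  if (h >= w) nh <- as.integer(max_dim) else nw <- as.integer(max_dim)
  ri <- pmin(h, floor((seq_len(nh) - 0.5) * h / nh) + 1L)
  ci <- pmin(w, floor((seq_len(nw) - 0.5) * w / nw) + 1L)
  img[ri, ci, , drop = FALSE]
}

#' Classify a blueprint image into a role grid
#'
#' Every pixel is classified against the palette by nearest RGB distance (see
#' [classify_pixel()]). In strict mode the first out-of-tolerance pixel aborts
#' the conversion with its coordinates; otherwise offenders map to the base
#' role and their count is recorded in the result.
#'
#' @param image an image array (see [read_image()]) or a file path.
#' @param palette a `loc_palette`; defaults to [default_palette()].
#' @return an object of class `loc_blueprint` with fields `roles` (`H x W`
#'   character matrix, row 1 = top of the blueprint), `width_px`, `height_px`,
#'   `palette`, and `n_unmatched`.
#' @export
load_blueprint <- function(image, palette = default_palette()) {
  stopifnot(inherits(palette, "loc_palette"))
  img <- if (is.character(image)) read_image(image) else as_rgb255(image)
  h <- dim(img)[1]; w <- dim(img)[2]
  cols <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  res <- classify_colors(cols, palette)
  if (res$n_unmatched > 0) {
    if (palette$strict) {
      first <- which(res$unmatched)[1]
      row <- (first - 1L) %% h + 1L
      col <- (first - 1L) %/% h + 1L
      stop(sprintf(
        "strict classification failed at pixel (row %d, col %d): color (%d,%d,%d) matches no palette color within tolerance %.3g",
        row, col, round(cols[first, 1]), round(cols[first, 2]),
        round(cols[first, 3]), palette$tolerance))
    }
    warning(res$n_unmatched, " out-of-tolerance pixel(s) mapped to base role")
  }
  structure(list(
    roles = matrix(res$roles, nrow = h, ncol = w),
    width_px = w, height_px = h,
    palette = palette,
    n_unmatched = res$n_unmatched
  ), class = "loc_blueprint")
}

#' Pixel-to-millimeter scale model
#'
#' The physical edge length of one block (voxel) is the ratio of the desired
#' mold size to the blueprint pixel count along the same axis: a 30 mm mold
#' drawn at 150 px gives 0.2 mm per block, so a 10 px channel prints 2 mm wide.
#'
#' @param target_size_mm desired physical size of the mold along the reference
#'   axis, in mm.
#' @param pixels blueprint pixel count along that axis.
#' @return an object of class `loc_scale` with fields `mm_per_pixel`,
#'   `target_size_mm`, `pixels`.
#' @export
compute_scale <- function(target_size_mm, pixels) {
  if (!is.finite(target_size_mm) || target_size_mm <= 0)
    stop("target_size_mm must be positive")
  if (!is.finite(pixels) || pixels <= 0 || pixels != as.integer(pixels))
    stop("pixels must be a positive integer")
  structure(list(mm_per_pixel = target_size_mm / pixels,
                 target_size_mm = target_size_mm,
                 pixels = as.integer(pixels)),
            class = "loc_scale")
}

#' Physical size of a blueprint feature
#'
#' @param pixels feature extent in pixels (non-negative).
#' @param scale a `loc_scale` from [compute_scale()].
#' @return feature size in mm.
#' @export
feature_size_mm <- function(pixels, scale) {
  stopifnot(inherits(scale, "loc_scale"))
  if (any(pixels < 0)) stop("pixels must be non-negative")
  pixels * scale$mm_per_pixel
}

#' Per-role pixel counts of a blueprint
#'
#' @param bp a `loc_blueprint`.
#' @return named integer vector of pixel counts by role.
#' @export
role_counts <- function(bp) {
  stopifnot(inherits(bp, "loc_blueprint"))
  tab <- table(bp$roles)
  structure(as.integer(tab), names = names(tab))
}

#' @export
print.loc_blueprint <- function(x, ...) {
  cat(sprintf("Blueprint %d x %d px", x$width_px, x$height_px))
  if (x$n_unmatched > 0) cat(sprintf(" (%d unmatched pixels)", x$n_unmatched))
  cat("\n")
  tab <- role_counts(x)
  cat(paste(sprintf("  %s: %d px", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.loc_scale <- function(x, ...) {
  cat(sprintf("Scale: %g mm target over %d px = %g mm per block\n",
              x$target_size_mm, x$pixels, x$mm_per_pixel))
  invisible(x)
}
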