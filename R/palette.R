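#' Build a blueprint color palette
#'
#' A palette maps blueprint colors to structural roles and extrusion heights.
#' Every pixel of a blueprint image is classified against the palette by
#' nearest Euclidean RGB distance; the matched role's `height_blocks` is the
#' number of voxel layers extruded for that pixel above the base slab.
#'
#' @param entries data.frame with columns `role` (character), `r`, `g`, `b`
#'   (integers 0-255) and `height_blocks` (non-negative integer). Exactly one
#'   entry must have role `"base"`, and the base entry must have
#'   `height_blocks = 0`.
#' @param tolerance maximum Euclidean RGB distance for a pixel to match a
#'   palette color. Must be less than half the minimum pairwise distance
#'   between palette colors so that classification is unambiguous.
#' @param strict if `TRUE`, pixels farther than `tolerance` from every palette
#'   color are an error; if `FALSE` they fall back to the base role and are
#'   counted as warnings.
#' @return an object of class `loc_palette`.
#' @seealso [default_palette()], [classify_pixel()], [read_palette()]
#' @export
palette_spec <- function(entries, tolerance = 32, strict = TRUE) {
  stopifnot(is.data.frame(entries),
            all(c("role", "r", "g", "b", "height_blocks") %in% names(entries)))
  entries$role <- as.character(entries$role)
  for (ch in c("r", "g", "b")) {
    v <- entries[[ch]]
    if (any(!is.finite(v)) || any(v < 0 | v > 255))
      stop("palette channel '", ch, "' must be within 0-255")
  }
  if (anyDuplicated(entries$role))
    stop("palette roles must be distinct")
  if (sum(entries$role == "base") != 1L)
    stop("palette must contain exactly one 'base' entry")
  if (entries$height_blocks[entries$role == "base"] != 0)
    stop("the base role must have height_blocks = 0")
  if (any(entries$height_blocks < 0))
    stop("height_blocks must be non-negative")
  cols <- as.matrix(entries[, c("r", "g", "b")])
  if (anyDuplicated(cols))
    stop("palette colors must be pairwise distinct")
  if (nrow(cols) > 1) {
    d <- as.matrix(stats::dist(cols))
    dmin <- min(d[upper.tri(d)])
    if (tolerance >= dmin / 2)
      stop(sprintf(
        "tolerance %.3g must be < half the minimum pairwise color distance (%.3g)",
        tolerance, dmin / 2))
  }
  if (tolerance < 0) stop("tolerance must be non-negative")
  structure(list(entries = entries, tolerance = tolerance, strict = strict),
            class = "loc_palette")
}

#' Default blueprint palette
#'
#' The conventional color code for chip blueprints: white pixels make only the
#' base slab, black draws channels, red draws culture chambers, yellow a small
#' in/outlet for a syringe and blue a large in/outlet for tubing. The numeric
#' heights (in voxel layers above the base slab) are package defaults chosen so
#' ports are taller than chambers and chambers taller than channels — tubing
#' and syringe ports need the most depth in the cast PDMS; override them via
#' [palette_spec()] or a YAML palette file for a specific device.
#'
#' @inheritParams palette_spec
#' @return an object of class `loc_palette`.
#' @export
default_palette <- function(tolerance = 32, strict = TRUE) {
  palette_spec(data.frame(
    role          = c("base", "channel", "chamber", "inlet_small", "inlet_large"),
    r             = c(255L, 0L, 255L, 255L, 0L),
    g             = c(255L, 0L, 0L,   255L, 0L),
    b             = c(255L, 0L, 0L,   0L,   255L),
    height_blocks = c(0L,   1L, 2L,   3L,   5L)
  ), tolerance = tolerance, strict = strict)
}

#' Read / write a palette configuration file
#'
#' The on-disk form is YAML (or JSON, which YAML subsumes): a mapping with
#' optional scalars `tolerance` and `strict` and a list `entries` of
#' `{color: [r,g,b], role: name, height_blocks: int}` records.
#'
#' @param path file path.
#' @return `read_palette()` returns a `loc_palette`; `write_palette()` returns
#'   `path` invisibly.
#' @export
read_palette <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$entries)) stop("palette file has no 'entries' list: ", path)
  entries <- do.call(rbind, lapply(cfg$entries, function(e) {
    if (length(e$color) != 3) stop("palette entry color must be [r,g,b]")
    data.frame(role = as.character(e$role),
               r = as.integer(e$color[[1]]), g = as.integer(e$color[[2]]),
               b = as.integer(e$color[[3]]),
               height_blocks = as.integer(e$height_blocks %||% 0L))
  }))
  palette_spec(entries,
               tolerance = cfg$tolerance %||% 32,
               strict = isTRUE(cfg$strict %||% TRUE))
}

#' @rdname read_palette
#' @param palette a `loc_palette`.
#' @export
write_palette <- function(palette, path) {
  stopifnot(inherits(palette, "loc_palette"))
  e <- palette$entries
  cfg <- list(
    tolerance = palette$tolerance,
    strict = palette$strict,
    entries = lapply(seq_len(nrow(e)), function(i) list(
      color = c(e$r[i], e$g[i], e$b[i]),
      role = e$role[i],
      height_blocks = e$height_blocks[i]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Classify one RGB color against a palette
#'
#' Returns the role of the palette entry at minimum Euclidean RGB distance,
#' provided that distance is within the palette tolerance. Ties are broken by
#' palette entry order (first entry wins), so classification is deterministic.
#'
#' @param rgb numeric vector of length 3, channels in 0-255.
#' @param palette a `loc_palette`.
#' @return a role label (character scalar). In strict mode an out-of-tolerance
#'   color is an error; otherwise it maps to `"base"` with a warning.
#' @export
classify_pixel <- function(rgb, palette) {
  stopifnot(inherits(palette, "loc_palette"), length(rgb) == 3)
  res <- classify_colors(matrix(as.numeric(rgb), 1, 3), palette)
  if (res$n_unmatched > 0) {
    if (palette$strict)
      stop(sprintf("color (%d,%d,%d) is farther than tolerance %.3g from every palette color",
                   rgb[1], rgb[2], rgb[3], palette$tolerance))
    warning("out-of-tolerance color mapped to base role")
  }
  res$roles
}

# Vectorized nearest-palette-color classification. cols: n x 3 matrix, 0-255.
# Returns roles (length n), and the unmatched mask resolved to base.
classify_colors <- function(cols, palette) {
  e <- palette$entries
  pal <- as.matrix(e[, c("r", "g", "b")])
  # squared distances n x k without loops
  d2 <- outer(rowSums(cols^2), rep(1, nrow(pal))) +
    outer(rep(1, nrow(cols)), rowSums(pal^2)) - 2 * cols %*% t(pal)
  d2[d2 < 0] <- 0  # numeric fuzz
  best <- max.col(-d2, ties.method = "first")
  unmatched <- d2[cbind(seq_len(nrow(cols)), best)] > palette$tolerance^2 + 1e-9
  roles <- e$role[best]
  roles[unmatched] <- "base"
  list(roles = roles, unmatched = unmatched, n_unmatched = sum(unmatched))
}

role_height <- function(palette, roles) {
  e <- palette$entries
  h <- e$height_blocks[match(roles, e$role)]
  if (anyNA(h)) stop("role(s) not present in palette: ",
                     paste(unique(roles[is.na(h)]), collapse = ", "))
  h
}

#' @export
print.loc_palette <- function(x, ...) {
  cat("Blueprint palette:", nrow(x$entries), "roles, tolerance",
      x$tolerance, if (x$strict) "(strict)\n" else "(lenient)\n")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
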