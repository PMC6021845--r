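#' Generate a demonstration chip blueprint
#'
#' Draws one of four parametric chip designs using only default-palette
#' colors, so the result always classifies with zero strict-mode failures:
#'
#' * `growth_chip` — two circular culture chambers (red) joined by a channel
#'   (black), with a large tubing port (blue) on the left and a small syringe
#'   port (yellow) on the right;
#' * `multiwidth_channel` — a single channel whose width steps up along its
#'   length, between a blue and a yellow port;
#' * `two_liquid_mixer` — two inlet ports converging into a serpentine mixing
#'   channel;
#' * `three_liquid_mixer` — the same with three inlets.
#'
#' The layouts imitate the topology of typical hand-drawn chip blueprints,
#' not any particular device's coordinates; geometry is deterministic (no
#' randomness), parametric only in the canvas size. Per-role pixel counts are
#' recorded in the returned spec and serve as independent oracles for the
#' classification and voxel-count stages downstream.
#'
#' @param design one of `"growth_chip"`, `"multiwidth_channel"`,
#'   `"two_liquid_mixer"`, `"three_liquid_mixer"`.
#' @param width_px,height_px canvas size in pixels (at least 20 x 20;
#'   default 150 x 100, the conventional working resolution).
#' @return list of class `loc_fixture`: `image` (`H x W x 3` array, 0-255),
#'   `spec` (list with `design`, `width_px`, `height_px`,
#'   `recorded_role_counts`), `roles` (the role matrix as drawn).
#' @export
generate_blueprint <- function(design = c("growth_chip", "multiwidth_channel",
                                          "two_liquid_mixer", "three_liquid_mixer"),
                               width_px = 150L, height_px = 100L) {
  design <- match.arg(design)
  W <- as.integer(width_px); H <- as.integer(height_px)
  if (W < 20 || H < 20) stop("design templates need at least a 20 x 20 canvas")
  roles <- matrix("base", H, W)

  disk <- function(cx, cy, r, role) {
    xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
    for (y in ys) {
      dx2 <- r^2 - (y - cy)^2
      if (dx2 < 0) next
      xr <- xs[abs(xs - cx) <= sqrt(dx2)]
      roles[y, xr] <<- role
    }
  }
  hline <- function(x1, x2, y, wdt, role) {
    ys <- max(1L, round(y - wdt / 2)):min(H, round(y + wdt / 2 - 1e-9))
    xs <- max(1L, round(min(x1, x2))):min(W, round(max(x1, x2)))
    roles[ys, xs] <<- role
  }
  vline <- function(y1, y2, x, wdt, role) {
    xs <- max(1L, round(x - wdt / 2)):min(W, round(x + wdt / 2 - 1e-9))
    ys <- max(1L, round(min(y1, y2))):min(H, round(max(y1, y2)))
    roles[ys, xs] <<- role
  }

  cw <- max(2L, round(min(W, H) / 30))  # channel width
  mid <- H / 2
  if (design == "growth_chip") {
    hline(0.10 * W, 0.90 * W, mid, cw, "channel")
    disk(0.35 * W, mid, 0.16 * H, "chamber")
    disk(0.65 * W, mid, 0.16 * H, "chamber")
    disk(0.08 * W, mid, 0.06 * min(W, H) + 2, "inlet_large")
    disk(0.92 * W, mid, 0.045 * min(W, H) + 1.5, "inlet_small")
  } else if (design == "multiwidth_channel") {
    seg <- (0.84 * W) / 4
    for (k in 1:4)
      hline(0.08 * W + (k - 1) * seg, 0.08 * W + k * seg, mid, cw * k, "channel")
    disk(0.06 * W, mid, 0.06 * min(W, H) + 2, "inlet_large")
    disk(0.94 * W, mid, 0.045 * min(W, H) + 1.5, "inlet_small")
  } else {
    n_in <- if (design == "two_liquid_mixer") 2L else 3L
    xin <- (seq_len(n_in)) * W / (n_in + 1)
    ytop <- 0.12 * H; yjoin <- 0.30 * H
    for (i in seq_len(n_in)) {
      vline(ytop, yjoin, xin[i], cw, "channel")
      hline(xin[i], W / 2, yjoin, cw, "channel")
    }
    # serpentine mixing channel below the junction
    ys <- seq(yjoin, 0.88 * H, length.out = 4)
    xl <- 0.15 * W; xr <- 0.85 * W
    vline(ys[1], ys[2], W / 2, cw, "channel")
    hline(xl, W / 2, ys[2], cw, "channel")
    vline(ys[2], ys[3], xl, cw, "channel")
    hline(xl, xr, ys[3], cw, "channel")
    vline(ys[3], ys[4], xr, cw, "channel")
    pr <- 0.035 * min(W, H) + 1.5
    for (i in seq_len(n_in))
      disk(xin[i], ytop, pr, if (i %% 2 == 1) "inlet_large" else "inlet_small")
  }

  pal <- default_palette()
  e <- pal$entries
  img <- array(0, dim = c(H, W, 3))
  idx <- match(roles, e$role)
  img[, , 1] <- matrix(e$r[idx], H, W)
  img[, , 2] <- matrix(e$g[idx], H, W)
  img[, , 3] <- matrix(e$b[idx], H, W)

  tab <- table(roles)
  structure(list(
    image = img,
    roles = roles,
    spec = list(design = design, width_px = W, height_px = H,
                recorded_role_counts = as.list(structure(as.integer(tab),
                                                         names = names(tab))))
  ), class = "loc_fixture")
}

#' Write a fixture to disk (PNG blueprint + JSON spec)
#'
#' @param fixture a `loc_fixture` from [generate_blueprint()].
#' @param dir output directory (created if missing).
#' @param name base file name; defaults to the design name.
#' @return character vector of the two paths written, invisibly.
#' @export
write_fixture <- function(fixture, dir, name = fixture$spec$design) {
  stopifnot(inherits(fixture, "loc_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  png_path <- file.path(dir, paste0(name, ".png"))
  json_path <- file.path(dir, paste0(name, ".json"))
  write_image(fixture$image, png_path)
  jsonlite::write_json(fixture$spec, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png_path, json_path))
}

#' Generate a synthetic striped marker photograph
#'
#' Emulates the striped patterned marker placed behind a culture chamber:
#' vertical square-wave stripes of the given period, optionally blurred by a
#' Gaussian of standard deviation `blur_sigma` (circular convolution — the
#' optical blur that growing broth turbidity causes), plus Gaussian sensor
#' noise. Deterministic for a fixed `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param width,height image size in px (default 128 x 128).
#' @param period_px stripe period in px (>= 2; default 8).
#' @param blur_sigma Gaussian blur sigma in px (default 0 = sharp marker).
#' @param noise_sd Gaussian noise standard deviation in intensity units
#'   (0-255 scale; default 2.5, about 1% sensor noise).
#' @param seed RNG seed for the noise (default 1).
#' @return grayscale matrix (`height x width`, nominally 0-255).
#' @export
generate_marker <- function(width = 128L, height = 128L, period_px = 8,
                            blur_sigma = 0, noise_sd = 2.5, seed = 1L) {
  if (period_px < 2) stop("period_px must be >= 2")
  if (blur_sigma < 0 || noise_sd < 0) stop("blur_sigma and noise_sd must be non-negative")
  x <- seq_len(width) - 1
  stripe <- ifelse((x %% period_px) < period_px / 2, 230, 25)
  img <- matrix(stripe, height, width, byrow = TRUE)
  if (blur_sigma > 0) img <- gaussian_blur_circular(img, blur_sigma)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), height, width)
  }
  img
}

# circular (wrap-around) Gaussian blur via the FFT; exact for the periodic
# stripe pattern and free of edge transients
gaussian_blur_circular <- function(img, sigma) {
  h <- nrow(img); w <- ncol(img)
  gk <- function(n) {
    d <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
    k <- exp(-d^2 / (2 * sigma^2)); k / sum(k)
  }
  K <- outer(gk(h), gk(w))
  Re(stats::fft(stats::fft(img) * stats::fft(K), inverse = TRUE)) / (h * w)
}

#' Toggle blueprint pixels between base and a flat role
#'
#' Creates a controlled error region for overlap-metric tests: exactly
#' `n_flips` distinct pixels are toggled between the base role and a non-base
#' role — base pixels take `role_color`, non-base pixels become white — so two
#' molds built from the original and perturbed blueprints (with flat role
#' heights) disagree on exactly `n_flips` top-view pixels. Deterministic per
#' seed; the caller's RNG state is left untouched.
#'
#' @param img blueprint image array (`H x W x 3`, 0-255).
#' @param n_flips number of pixels to toggle (at most `W * H`).
#' @param seed RNG seed selecting the flip set.
#' @param role_color RGB triple applied to flipped base pixels (default black,
#'   the channel role).
#' @return perturbed image array.
#' @export
perturb_blueprint <- function(img, n_flips, seed = 1L, role_color = c(0, 0, 0)) {
  img <- as_rgb255(img)
  npx <- prod(dim(img)[1:2])
  if (n_flips > npx) stop("n_flips exceeds the pixel count")
  if (n_flips == 0) return(img)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  pick <- sample.int(npx, n_flips)
  h <- dim(img)[1]
  rr <- (pick - 1L) %% h + 1L
  cc <- (pick - 1L) %/% h + 1L
  is_base <- img[cbind(rr, cc, 1L)] == 255 & img[cbind(rr, cc, 2L)] == 255 &
    img[cbind(rr, cc, 3L)] == 255
  for (ch in 1:3) {
    img[cbind(rr[is_base], cc[is_base], ch)] <- role_color[ch]
    img[cbind(rr[!is_base], cc[!is_base], ch)] <- 255
  }
  img
}

#' @export
print.loc_fixture <- function(x, ...) {
  cat(sprintf("Fixture blueprint '%s' (%d x %d px)\n",
              x$spec$design, x$spec$width_px, x$spec$height_px))
  rc <- x$spec$recorded_role_counts
  cat(paste(sprintf("  %s: %d px", names(rc), unlist(rc)), collapse = "\n"), "\n")
  invisible(x)
}
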