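#' Count super-threshold pixels in the FFT spectrum of a marker photo
#'
#' Quantifies the sharpness of a striped marker photographed through culture
#' broth: bacterial turbidity blurs the stripes, which suppresses the high
#' spatial frequencies and shrinks the number of bright spectrum pixels.
#'
#' The statistic mirrors what a displayed FFT image shows: the 2D FFT
#' magnitude is centered, the DC peak and a small low-frequency disk are
#' excluded, the remainder is mapped through the display log curve
#' `log1p(255 * m / m_max) / log1p(255)` (exactly invariant under intensity
#' scaling of the input), quantized to 8 bits, and the pixels above
#' `threshold` are counted. A constant image yields count 0.
#'
#' @param image grayscale matrix (any intensity scale) or `H x W x 3` RGB
#'   array (converted by luma weights), at least 8 x 8.
#' @param threshold fraction of the normalized log-magnitude a pixel must
#'   exceed to be counted (default 0.5).
#' @param dc_radius radius in bins of the excluded low-frequency disk around
#'   DC (default 2).
#' @param window `"none"` (default; stripes are the dominant periodic signal)
#'   or `"hann"` to taper before transforming.
#' @param quantize quantize the normalized log-magnitude to 8 bits before
#'   thresholding (default `TRUE`), matching an 8-bit spectrum rendering.
#' @return an object of class `loc_spectrum`: `count` plus the
#'   `threshold_params` used.
#' @export
fft_count <- function(image, threshold = 0.5, dc_radius = 2,
                      window = c("none", "hann"), quantize = TRUE) {
  window <- match.arg(window)
  img <- as_gray(image)
  if (nrow(img) < 8 || ncol(img) < 8) stop("image must be at least 8 x 8")
  if (window == "hann") {
    hr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nrow(img)) - 1) / (nrow(img) - 1))
    hc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ncol(img)) - 1) / (ncol(img) - 1))
    img <- img * outer(hr, hc)
  }
  mag <- fftshift(Mod(stats::fft(img)))
  cy <- floor(nrow(img) / 2) + 1; cx <- floor(ncol(img) / 2) + 1
  dy <- outer(seq_len(nrow(img)) - cy, rep(1, ncol(img)))
  dx <- outer(rep(1, nrow(img)), seq_len(ncol(img)) - cx)
  mag[dy^2 + dx^2 <= dc_radius^2] <- 0
  mx <- max(mag)
  count <- if (mx <= 0) 0L else {
    L <- log1p(255 * mag / mx) / log1p(255)
    if (quantize) L <- floor(L * 255) / 255
    sum(L > threshold)
  }
  structure(list(count = as.integer(count),
                 threshold_params = list(threshold = threshold,
                                         dc_radius = dc_radius,
                                         window = window,
                                         quantize = quantize)),
            class = "loc_spectrum")
}

# center the zero-frequency bin of a 2D spectrum
fftshift <- function(m) {
  r <- nrow(m); c <- ncol(m)
  m[c((floor(r / 2) + 1):r, 1:floor(r / 2)),
    c((floor(c / 2) + 1):c, 1:floor(c / 2))]
}

as_gray <- function(image) {
  if (is.matrix(image)) return(image * 1.0)
  if (length(dim(image)) == 3) {
    img <- as_rgb255(image)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  stop("image must be a grayscale matrix or an RGB array")
}

#' Marker visibility ratio
#'
#' The visibility of the striped marker is the current spectrum pixel count
#' divided by the count before the culture started. A clear chamber gives 1;
#' a saturated broth (count 1 against a starting count of 63) gives 0.0159,
#' printed as 0.02 — nearly zero.
#'
#' @param count_now current spectrum count (or a `loc_spectrum`).
#' @param count_ref reference (pre-culture) count (or a `loc_spectrum`);
#'   must be positive.
#' @return visibility ratio (unrounded; round to 2 decimals for display).
#' @export
visibility <- function(count_now, count_ref) {
  if (inherits(count_now, "loc_spectrum")) count_now <- count_now$count
  if (inherits(count_ref, "loc_spectrum")) count_ref <- count_ref$count
  if (count_ref <= 0) stop("reference count must be positive (marker invisible at start?)")
  if (count_now < 0) stop("counts must be non-negative")
  count_now / count_ref
}

#' Visibility time series over a culture image sequence
#'
#' Applies [fft_count()] to every image and divides each count by the first
#' image's count (the pre-culture reference), so the first visibility is 1 by
#' construction.
#'
#' @param images list of grayscale matrices / RGB arrays, or a character
#'   vector of image paths; the first image is the reference.
#' @param ... passed to [fft_count()].
#' @return data.frame with columns `index`, `count`, `visibility`.
#' @export
growth_series <- function(images, ...) {
  if (is.character(images)) images <- lapply(images, read_image)
  if (length(images) < 1) stop("need at least one image")
  counts <- vapply(images, function(im) fft_count(im, ...)$count, integer(1))
  if (counts[1] <= 0)
    stop("reference count is 0: marker invisible in the first image")
  data.frame(index = seq_along(counts),
             count = counts,
             visibility = counts / counts[1])
}

#' @export
print.loc_spectrum <- function(x, ...) {
  p <- x$threshold_params
  cat(sprintf("FFT spectrum count: %d (threshold %.2f, DC radius %g, window %s)\n",
              x$count, p$threshold, p$dc_radius, p$window))
  invisible(x)
}
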