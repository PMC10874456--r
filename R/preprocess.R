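#' Preprocessing configuration for ECM binarization
#'
#' Parameters of the standardized operator chain that turns a trichrome RGB
#' image into the binary ECM pattern analyzed by the fractal module. The
#' defaults are the chain used throughout this package: rolling-ball radius
#' 20 px, contrast normalization with 0.1 % pixel saturation, unsharp mask
#' (radius 2, weight 0.6), median radius 1, moment-preserving ("Moments")
#' threshold, and a post-threshold despeckle.
#'
#' @param rolling_ball_radius Rolling-ball background radius in pixels.
#' @param saturation_percent Percent of pixels saturated during contrast
#'   enhancement, split equally between the two tails.
#' @param normalize Logical; stretch the clipped range to `[0, 255]`.
#' @param unsharp_radius Gaussian sigma of the unsharp mask, pixels.
#' @param unsharp_weight Mask weight in `(0, 1)`.
#' @param median_radius Median filter radius in pixels.
#' @param threshold_method Currently only `"moments"`.
#' @param despeckle Logical; apply a radius-1 median to the binary image.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(rolling_ball_radius = 20,
                              saturation_percent = 0.1,
                              normalize = TRUE,
                              unsharp_radius = 2,
                              unsharp_weight = 0.6,
                              median_radius = 1,
                              threshold_method = "moments",
                              despeckle = TRUE) {
  stopifnot(rolling_ball_radius > 0,
            saturation_percent >= 0, saturation_percent < 100,
            unsharp_radius > 0,
            unsharp_weight > 0, unsharp_weight < 1,
            median_radius > 0)
  threshold_method <- match.arg(threshold_method, "moments")
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 saturation_percent = saturation_percent,
                 normalize = normalize,
                 unsharp_radius = unsharp_radius,
                 unsharp_weight = unsharp_weight,
                 median_radius = median_radius,
                 threshold_method = threshold_method,
                 despeckle = despeckle),
            class = "preprocess_config")
}

#' Cyan channel of an RGB image
#'
#' Converts to CMYK with the naive (non-ICC) formula and returns the cyan
#' channel as an 8-bit grayscale matrix. Aniline blue, which stains the
#' extracellular matrix in Masson trichrome, has maximal cyan, so this
#' channel isolates the ECM signal. Per pixel `K = 1 - max(R,G,B)/255` and
#' `C = (1 - R/255 - K)/(1 - K)`, with `C = 0` when `K = 1` (pure black).
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @return Numeric matrix in `[0, 255]`.
#' @export
extract_cyan <- function(img) {
  assert_rgb(img, "extract_cyan")
  d <- dim(img)
  r <- matrix(img[, , 1], d[1], d[2]) / 255
  mx <- pmax(r, matrix(img[, , 2], d[1], d[2]) / 255,
             matrix(img[, , 3], d[1], d[2]) / 255)
  c <- ifelse(mx == 0, 0, (mx - r) / mx)  # (1 - R' - K)/(1 - K) with K = 1 - max
  round_half_up(255 * c)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image by a
#' ball-shaped (non-flat) structuring element of the given radius and
#' subtracts it, clamping at zero. A constant image maps to all zeros; thin
#' bright structures narrower than the ball are preserved because the ball
#' cannot roll into them.
#'
#' @param img Grayscale matrix in `[0, 255]`.
#' @param radius Ball radius in pixels (default 20).
#' @return Background-subtracted matrix in `[0, 255]`.
#' @export
subtract_background <- function(img, radius = 20) {
  assert_gray(img, "subtract_background")
  if (radius < 1) stop("subtract_background(): radius must be >= 1",
                       call. = FALSE)
  if (radius >= min(dim(img))) {
    stop(sprintf(
      "subtract_background(): radius %s >= minimum image dimension %d",
      format(radius), min(dim(img))), call. = FALSE)
  }
  bg <- rolling_ball_background_cpp(img, radius)
  clamp8(img - bg)
}

#' Histogram-based contrast enhancement
#'
#' Finds low/high cut intensities so that at most `saturation_percent / 2`
#' percent of pixels fall below/above them (cumulative histogram on rounded
#' 8-bit values), then linearly maps `[low, high]` to `[0, 255]` with
#' clamping outside. A constant image is returned unchanged with a warning.
#'
#' @param img Grayscale matrix in `[0, 255]`.
#' @param saturation_percent Total percent of saturated pixels, split
#'   equally between tails (default 0.1).
#' @param normalize Logical; if `FALSE` the image is returned unchanged
#'   (clipping without normalization is not part of this chain).
#' @return Contrast-stretched matrix in `[0, 255]`.
#' @export
enhance_contrast <- function(img, saturation_percent = 0.1,
                             normalize = TRUE) {
  assert_gray(img, "enhance_contrast")
  if (!normalize) return(img)
  v <- round_half_up(as.vector(img))
  if (min(v) == max(v)) {
    warning("enhance_contrast(): constant image, mapping undefined; unchanged")
    return(img)
  }
  n <- length(v)
  tail_n <- n * saturation_percent / 200
  h <- tabulate(v + 1L, nbins = 256L)
  cum <- cumsum(h)
  low <- min(which(cum > tail_n)) - 1L
  cum_top <- rev(cumsum(rev(h)))
  high <- max(which(cum_top > tail_n)) - 1L
  if (high <= low) {   # saturation swallowed the whole histogram
    low <- min(v); high <- max(v)
  }
  clamp8((img - low) * (255 / (high - low)))
}

#' Unsharp mask
#'
#' Sharpens by subtracting a weighted Gaussian blur:
#' `out = clamp((img - w * G) / (1 - w))` with `G` the Gaussian blur of the
#' image at `sigma = radius` (replicate-padded).
#'
#' @param img Grayscale matrix in `[0, 255]`.
#' @param radius Gaussian sigma in pixels (default 2).
#' @param weight Mask weight in `(0, 1)` (default 0.6).
#' @return Sharpened matrix in `[0, 255]`.
#' @export
unsharp_mask <- function(img, radius = 2, weight = 0.6) {
  assert_gray(img, "unsharp_mask")
  stopifnot(radius > 0, weight > 0, weight < 1)
  g <- gaussian_blur_cpp(img, radius)
  clamp8((img - weight * g) / (1 - weight))
}

#' Median filter
#'
#' Each pixel is replaced by the median of its `(2r+1) x (2r+1)`
#' neighborhood with replicate padding at the edges.
#'
#' @param img Grayscale matrix.
#' @param radius Neighborhood radius in pixels (default 1).
#' @return Filtered matrix.
#' @export
median_filter <- function(img, radius = 1) {
  assert_gray(img, "median_filter")
  stopifnot(radius >= 1)
  median_filter_cpp(img, as.integer(radius))
}

#' Moment-preserving (Tsai) threshold
#'
#' Chooses the cut `t` such that the two-level image (representative levels
#' `z0 < z1` with fractions `p0`, `p1`) preserves the first three gray-level
#' moments of the input. Computed deterministically from the 256-bin
#' histogram: the moment equations give `p0` in closed form and the
#' threshold is the gray level whose cumulative fraction is closest to
#' `p0`. Pixels strictly above the threshold are foreground.
#'
#' @param img Grayscale matrix in `[0, 255]` (values are rounded to 8-bit).
#' @return Integer threshold in `[0, 255)`, with attribute `p0`
#'   (the background fraction preserved by the moments).
#' @export
threshold_moments <- function(img) {
  assert_gray(img, "threshold_moments")
  v <- round_half_up(as.vector(img))
  if (min(v) == max(v)) {
    stop("threshold_moments(): degenerate histogram (constant image)",
         call. = FALSE)
  }
  h <- tabulate(v + 1L, nbins = 256L) / length(v)
  z <- 0:255
  m1 <- sum(h * z)
  m2 <- sum(h * z^2)
  m3 <- sum(h * z^3)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- sqrt(max(c1^2 - 4 * c0, 0))
  z0 <- 0.5 * (-c1 - disc)
  z1 <- 0.5 * (-c1 + disc)
  p0 <- if (z1 == z0) 0.5 else (z1 - m1) / (z1 - z0)
  p0 <- min(max(p0, 0), 1)
  cum <- cumsum(h)
  t <- which.min(abs(cum[1:255] - p0)) - 1L
  structure(as.integer(t), p0 = p0)
}

#' Despeckle a binary pattern
#'
#' Radius-1 median filter applied to the thresholded image, removing
#' isolated salt/pepper pixels.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
despeckle <- function(mask) {
  assert_pattern(mask, "despeckle")
  median_filter_cpp(mask * 255, 1L) > 127
}

#' Binarize the ECM pattern of a trichrome image
#'
#' The full standardized chain: cyan-channel extraction, rolling-ball
#' background subtraction, contrast enhancement, unsharp mask, median
#' filter, 8-bit conversion, moment-preserving threshold, despeckle.
#' Foreground is the high-cyan class, i.e. the aniline-blue-stained
#' extracellular matrix.
#'
#' An image whose processed histogram is constant (e.g. pure white — no
#' tissue) yields an all-background pattern flagged with attribute
#' `degenerate = TRUE` rather than an error, so batch runs complete.
#'
#' @param img `H x W x 3` RGB array in `[0, 255]`.
#' @param cfg A [preprocess_config()].
#' @return Logical matrix (`TRUE` = ECM foreground), possibly with
#'   attribute `degenerate`; attribute `threshold` records the cut used.
#' @export
binarize_ecm <- function(img, cfg = preprocess_config()) {
  assert_rgb(img, "binarize_ecm")
  g <- extract_cyan(img)
  g <- subtract_background(g, cfg$rolling_ball_radius)
  if (min(g) == max(g)) {
    warning("binarize_ecm(): degenerate (constant) image; ",
            "returning empty pattern")
    out <- matrix(FALSE, nrow(g), ncol(g))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  g <- enhance_contrast(g, cfg$saturation_percent, cfg$normalize)
  g <- unsharp_mask(g, cfg$unsharp_radius, cfg$unsharp_weight)
  g <- median_filter(g, cfg$median_radius)
  g <- round_half_up(clamp8(g))
  if (min(g) == max(g)) {
    warning("binarize_ecm(): degenerate (constant) image after filtering; ",
            "returning empty pattern")
    out <- matrix(FALSE, nrow(g), ncol(g))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  t <- threshold_moments(g)
  mask <- g > t
  if (isTRUE(cfg$despeckle)) mask <- despeckle(mask)
  attr(mask, "threshold") <- as.integer(t)
  mask
}
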