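#' Colour-threshold specification for ECM-fraction measurement
#'
#' Hue/saturation/value rules separating the aniline-blue-stained ECM from
#' the rest of the tissue and the near-white slide background. Trichrome
#' histomorphometry has no universal numeric colour window, so these
#' defaults are a declared convention, fully exposed here and
#' recorded in output metadata: blue hues span the cyan-blue band
#' 140-280 degrees; background is near-white (high value, low saturation).
#'
#' @param blue_hue_window Hue interval in degrees on the `[0, 360)` circle.
#' @param min_saturation Minimum saturation for a pixel to count as
#'   blue-stained ECM.
#' @param max_value_background Value (brightness, `[0,1]`) at or above
#'   which a low-saturation pixel is slide background.
#' @param min_tissue_saturation Saturation below which a bright pixel is
#'   background rather than pale tissue.
#' @return A list of class `color_threshold_spec`.
#' @export
color_threshold_spec <- function(blue_hue_window = c(140, 280),
                                 min_saturation = 0.15,
                                 max_value_background = 0.92,
                                 min_tissue_saturation = 0.08) {
  stopifnot(length(blue_hue_window) == 2,
            min_saturation >= 0, min_saturation <= 1,
            max_value_background >= 0, max_value_background <= 1,
            min_tissue_saturation >= 0, min_tissue_saturation <= 1)
  structure(list(blue_hue_window = blue_hue_window,
                 min_saturation = min_saturation,
                 max_value_background = max_value_background,
                 min_tissue_saturation = min_tissue_saturation),
            class = "color_threshold_spec")
}

rgb_to_hsv_planes <- function(img) {
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  hsv <- rgb2hsv(m, maxColorValue = 255)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

hue_in_window <- function(h, window) {
  lo <- window[1] %% 360
  hi <- window[2] %% 360
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

#' Total-tissue mask of a trichrome image
#'
#' Foreground is every pixel that is not slide background, background
#' being near-white: value at or above `max_value_background` with
#' saturation below `min_tissue_saturation`.
#'
#' @param img `H x W x 3` RGB array in `[0, 255]`.
#' @param spec A [color_threshold_spec()].
#' @return Logical matrix (`TRUE` = tissue).
#' @export
tissue_mask <- function(img, spec = color_threshold_spec()) {
  assert_rgb(img, "tissue_mask")
  hsv <- rgb_to_hsv_planes(img)
  !(hsv$v >= spec$max_value_background & hsv$s < spec$min_tissue_saturation)
}

#' Blue-stained ECM mask of a trichrome image
#'
#' Foreground is every tissue pixel whose hue falls in the blue window and
#' whose saturation reaches `min_saturation`. By construction the ECM mask
#' is a subset of the tissue mask.
#'
#' @inheritParams tissue_mask
#' @return Logical matrix (`TRUE` = blue-stained ECM).
#' @export
ecm_mask <- function(img, spec = color_threshold_spec()) {
  assert_rgb(img, "ecm_mask")
  hsv <- rgb_to_hsv_planes(img)
  tissue <- !(hsv$v >= spec$max_value_background &
              hsv$s < spec$min_tissue_saturation)
  tissue & hue_in_window(hsv$h, spec$blue_hue_window) &
    hsv$s >= spec$min_saturation
}

#' Proportionate ECM fraction
#'
#' Ratio of the blue-stained (ECM) area to the total tissue area — a
#' quantity-of-matrix measure, computed on the RGB image independently of
#' the fractal binarization chain. An image with no tissue yields `NA`
#' with a warning, not 0.
#'
#' @inheritParams tissue_mask
#' @return Ratio in `[0, 1]`, or `NA` if the tissue mask is empty.
#' @export
ecm_fraction <- function(img, spec = color_threshold_spec()) {
  assert_rgb(img, "ecm_fraction")
  tis <- tissue_mask(img, spec)
  n_tis <- sum(tis)
  if (n_tis == 0) {
    warning("ecm_fraction(): empty tissue mask (no tissue); value absent")
    return(NA_real_)
  }
  sum(ecm_mask(img, spec)) / n_tis
}
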