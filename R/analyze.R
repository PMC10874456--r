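#' Whole-image analysis configuration
#'
#' Bundles the parameters of the full measurement pipeline: the export
#' downsampling factor applied before binarization (whole-slide exports in
#' this workflow use 15; pass 1 for images already at analysis
#' resolution), the preprocessing chain, the fractal grid policy and the
#' colour thresholds for the ECM fraction.
#'
#' @param downsample_factor Positive integer (default 15).
#' @param preprocess A [preprocess_config()].
#' @param ecm A [color_threshold_spec()].
#' @param n_grids Number of box-counting grid origins (default 12).
#' @param max_caliber_fraction Largest box size as a fraction of the
#'   smaller pattern side (default 0.45).
#' @param stride Lacunarity window stride (default 1).
#' @param rng_seed Integer seed for grid origins (default 1).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(downsample_factor = 15,
                            preprocess = preprocess_config(),
                            ecm = color_threshold_spec(),
                            n_grids = 12,
                            max_caliber_fraction = 0.45,
                            stride = 1,
                            rng_seed = 1) {
  stopifnot(downsample_factor >= 1)
  structure(list(downsample_factor = as.integer(downsample_factor),
                 preprocess = preprocess, ecm = ecm,
                 n_grids = n_grids,
                 max_caliber_fraction = max_caliber_fraction,
                 stride = stride, rng_seed = rng_seed),
            class = "analysis_config")
}

#' Measure one trichrome image
#'
#' Runs the two independent measurement procedures on an RGB image: the
#' colour-threshold ECM fraction on the image as given, and fractal
#' dimension plus lacunarity on the binarized ECM pattern of the
#' downsampled image. Deterministic for a fixed configuration. Degenerate
#' images (no tissue, or an empty binarized pattern) produce a flagged
#' record with absent measurements rather than an error.
#'
#' @param img `H x W x 3` RGB array in `[0, 255]`.
#' @param cfg An [analysis_config()].
#' @return One-row `data.frame` with columns `ecm_fraction`,
#'   `fractal_dimension`, `lacunarity`, `fd_r2_mean`, `degenerate`.
#' @export
analyze_image <- function(img, cfg = analysis_config()) {
  assert_rgb(img, "analyze_image")
  frac <- suppressWarnings(ecm_fraction(img, cfg$ecm))
  ds <- downsample(img, min(cfg$downsample_factor, min(dim(img)[1:2])))
  pattern <- suppressWarnings(binarize_ecm(ds, cfg$preprocess))
  if (!any(pattern)) {
    warning("analyze_image(): empty binarized pattern; ",
            "fractal measurements absent")
    return(data.frame(ecm_fraction = frac,
                      fractal_dimension = NA_real_,
                      lacunarity = NA_real_,
                      fd_r2_mean = NA_real_,
                      degenerate = TRUE))
  }
  sizes <- default_box_sizes(nrow(pattern), ncol(pattern),
                             max_caliber_fraction = cfg$max_caliber_fraction)
  res <- suppressWarnings(
    analyze_pattern(pattern, sizes, cfg$n_grids, cfg$rng_seed, cfg$stride))
  data.frame(ecm_fraction = frac,
             fractal_dimension = res$fractal_dimension,
             lacunarity = res$lacunarity,
             fd_r2_mean = mean(res$per_grid_fit_r2),
             degenerate = FALSE)
}
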