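#' Read a raster image as an RGB array
#'
#' Reads a PNG or TIFF raster into an integer `H x W x 3` array with channel
#' values in `[0, 255]`. Grayscale sources are replicated across the three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An `H x W x 3` numeric array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' for '%s' (use PNG or TIFF)",
                 ext, path), call. = FALSE)
  )
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  d <- dim(raw)
  if (d[1] < 1L || d[2] < 1L) {
    stop(sprintf("zero-area image: '%s'", path), call. = FALSE)
  }
  nch <- d[3]
  if (nch == 1L || nch == 2L) {
    g <- raw[, , 1L, drop = TRUE]
    img <- array(rep(g, 3L), c(d[1], d[2], 3L))
  } else {
    img <- raw[, , 1:3, drop = FALSE]
  }
  round_half_up(img * 255)
}

#' Write an RGB array or grayscale matrix as PNG
#'
#' Audit helper for dumping intermediate images of the preprocessing chain.
#'
#' @param img `H x W x 3` array or matrix, values in `[0, 255]`.
#' @param path Output `.png` path.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp8(img) / 255, path)
  invisible(path)
}

#' Block-mean downsampling
#'
#' Reduces an RGB image by an integer factor using area (block-mean)
#' averaging, emulating the low-pass behavior of a scanner's export
#' downsampling. Output dimensions are `ceiling(dim / factor)`; edge blocks
#' are truncated; channel means are rounded half up to integers.
#'
#' @param img `H x W x 3` array, values in `[0, 255]`.
#' @param factor Positive integer; the linear downsampling factor
#'   (whole-slide exports in this workflow use 15).
#' @return Downsampled `H' x W' x 3` array.
#' @export
downsample <- function(img, factor) {
  assert_rgb(img, "downsample")
  d <- dim(img)
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != as.integer(factor)) {
    stop("downsample(): factor must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor > min(d[1], d[2])) {
    stop(sprintf(
      "downsample(): factor %d exceeds both image dimensions (%d x %d)",
      factor, d[1], d[2]), call. = FALSE)
  }
  if (factor == 1L) return(img)
  gi <- (seq_len(d[1]) - 1L) %/% factor
  gj <- (seq_len(d[2]) - 1L) %/% factor
  ni <- max(gi) + 1L
  nj <- max(gj) + 1L
  cnt <- tabulate(gi + 1L, ni) %o% tabulate(gj + 1L, nj)
  out <- array(0, c(ni, nj, 3L))
  for (ch in 1:3) {
    s <- rowsum(img[, , ch], gi, reorder = TRUE)
    s <- t(rowsum(t(s), gj, reorder = TRUE))
    out[, , ch] <- round_half_up(s / cnt)
  }
  out
}

#' Read a cohort metadata/results table
#'
#' Reads a comma-delimited table with mandatory columns `patient_id`,
#' `location` (margin/focus, case-insensitive) and `fibrosis_score`
#' (integer grade 0-4), plus any optional score, measurement or expression
#' columns. Unknown columns are preserved.
#'
#' @param path CSV path.
#' @return A validated `data.frame` (a cohort table).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read metadata: file '%s' does not exist", path),
         call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(df)
}

#' Validate a cohort table
#'
#' @param df A `data.frame` with at least `patient_id`, `location`,
#'   `fibrosis_score`.
#' @return The validated data frame with `location` normalized to
#'   lower case.
#' @export
validate_cohort <- function(df) {
  mandatory <- c("patient_id", "location", "fibrosis_score")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop(sprintf("cohort table is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$location <- tolower(as.character(df$location))
  bad_loc <- which(!df$location %in% c("margin", "focus"))
  if (length(bad_loc)) {
    stop(sprintf("invalid location '%s' in row %d (must be margin or focus)",
                 df$location[bad_loc[1]], bad_loc[1]), call. = FALSE)
  }
  fs <- df$fibrosis_score
  bad_fs <- which(!is.na(fs) & !(fs %in% 0:4))
  if (length(bad_fs)) {
    stop(sprintf("fibrosis_score %s in row %d outside the 0-4 grading scale",
                 fs[bad_fs[1]], bad_fs[1]), call. = FALSE)
  }
  for (col in c("alignment_score", "color_score")) {
    if (col %in% names(df)) {
      bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% 1:5))
      if (length(bad)) {
        stop(sprintf("%s %s in row %d outside the 1-5 scale",
                     col, df[[col]][bad[1]], bad[1]), call. = FALSE)
      }
    }
  }
  if ("ecm_fraction" %in% names(df)) {
    bad <- which(!is.na(df$ecm_fraction) &
                 (df$ecm_fraction < 0 | df$ecm_fraction > 1))
    if (length(bad)) {
      stop(sprintf("ecm_fraction %s in row %d outside [0, 1]",
                   format(df$ecm_fraction[bad[1]]), bad[1]), call. = FALSE)
    }
  }
  dup <- duplicated(df[, c("patient_id", "location")])
  if (any(dup)) {
    stop(sprintf("patient '%s' appears more than once at location '%s'",
                 df$patient_id[which(dup)[1]], df$location[which(dup)[1]]),
         call. = FALSE)
  }
  df
}

#' Write a cohort results table
#'
#' @param df Cohort table (`data.frame`).
#' @param path Output CSV path.
#' @export
write_results <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Patient ids with a complete margin/focus pair
#'
#' @param df Cohort table.
#' @return Character vector of paired patient ids.
#' @export
paired_patients <- function(df) {
  m <- unique(df$patient_id[df$location == "margin"])
  f <- unique(df$patient_id[df$location == "focus"])
  as.character(intersect(m, f))
}
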