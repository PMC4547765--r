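#' Percent-area quantification of specific fluorescence labeling
#'
#' Segments an ROI of a grayscale micrograph against a background-derived
#' threshold: the background level is the median (or mean) intensity of a
#' user-supplied unlabeled reference ROI, and pixels of the analysis ROI
#' whose intensity is strictly greater than `multiplier x background`
#' (default 2x) count as specifically labeled. The result is the percent of
#' ROI pixels above threshold (% ROI). Because the threshold scales with the
#' background, the result is invariant under global intensity rescaling.
#'
#' @param image numeric matrix of pixel intensities.
#' @param roi_rect analysis ROI as `c(row0, col0, row1, col1)` (1-based,
#'   inclusive); `NULL` = whole image.
#' @param background_roi unlabeled reference ROI in the same format; `NULL`
#'   uses the whole image (sensible only for sparsely labeled images).
#' @param multiplier threshold multiple of background (default 2).
#' @param background_stat `"median"` (robust default) or `"mean"`.
#' @param region label carried into the result.
#' @return one-row tibble of class `histo_quant`: `region`, `background`,
#'   `threshold`, `n_pixels`, `n_labeled`, `percent_roi`.
#' @export
quantify_labeling <- function(image, roi_rect = NULL, background_roi = NULL,
                              multiplier = 2, background_stat = c("median", "mean"),
                              region = "roi") {
  background_stat <- match.arg(background_stat)
  assert_scalar_num(multiplier, "multiplier", lower = 1e-12)
  image <- as.matrix(image)
  crop <- function(rect) {
    if (is.null(rect)) return(image)
    rect <- as.integer(rect)
    if (length(rect) != 4L || rect[1L] < 1L || rect[2L] < 1L ||
        rect[3L] > nrow(image) || rect[4L] > ncol(image) ||
        rect[1L] > rect[3L] || rect[2L] > rect[4L]) {
      abort("ROI rectangle falls outside the image (use c(row0, col0, row1, col1))")
    }
    image[rect[1L]:rect[3L], rect[2L]:rect[4L], drop = FALSE]
  }
  bg_px <- crop(background_roi)
  background <- if (background_stat == "median") median(bg_px) else mean(bg_px)
  if (background <= 0) abort("background level is 0: threshold degenerate")
  threshold <- multiplier * background
  roi_px <- crop(roi_rect)
  n_lab <- sum(roi_px > threshold)
  out <- tibble::tibble(
    region = region,
    background = background,
    threshold = threshold,
    n_pixels = length(roi_px),
    n_labeled = n_lab,
    percent_roi = 100 * n_lab / length(roi_px)
  )
  class(out) <- c("histo_quant", class(out))
  out
}

#' Read a grayscale micrograph
#'
#' Reads an 8/16-bit grayscale TIFF or PNG into a numeric intensity matrix
#' (16-bit scale, 0..65535). Multi-channel images are averaged to grayscale.
#'
#' @param path image file (.tif/.tiff/.png).
#' @return numeric matrix.
#' @export
read_micrograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(sprintf("unsupported image format '%s' (use TIFF or PNG)", ext))
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img * 65535
}

#' Write a grayscale micrograph
#'
#' Writes a numeric intensity matrix as grayscale TIFF (16-bit) or PNG
#' (8-bit). Intensities are interpreted on the 16-bit scale (0..65535) and
#' clipped; PNG output is quantized to 256 levels.
#'
#' @param image numeric matrix.
#' @param path output file (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path) {
  scaled <- pmin(pmax(image / 65535, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16L),
    png = png::writePNG(scaled, path),
    abort(sprintf("unsupported image format '%s' (use TIFF or PNG)", ext))
  )
  invisible(path)
}
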