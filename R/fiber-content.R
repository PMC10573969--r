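#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle: columns `x0 <= x < x1`, rows
#' `y0 <= y < y1` (x across, y down, image origin top-left).
#'
#' @param x0,y0 Top-left corner (0-based, inclusive).
#' @param x1,y1 Bottom-right corner (exclusive).
#' @return An object of class `"roi"` (subtype rectangle).
#' @export
roi_rect <- function(x0, y0, x1, y1) {
  if (!(x1 > x0 && y1 > y0))
    stop("ROI rectangle must have positive area", call. = FALSE)
  structure(list(type = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "roi")
}

#' Polygonal region of interest
#'
#' Vertices in 0-based pixel coordinates; a pixel belongs to the ROI when
#' its center `(x + 0.5, y + 0.5)` lies inside the polygon (even-odd rule).
#'
#' @param x,y Vertex coordinate vectors (equal length >= 3).
#' @return An object of class `"roi"` (subtype polygon).
#' @export
roi_polygon <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("polygon needs >= 3 vertices", call. = FALSE)
  structure(list(type = "polygon", x = as.numeric(x), y = as.numeric(y)),
            class = "roi")
}

# logical HxW mask of pixels inside the ROI; errors if outside image bounds
roi_mask <- function(roi, dim_hw) {
  stopifnot(inherits(roi, "roi"))
  H <- dim_hw[1L]; W <- dim_hw[2L]
  if (roi$type == "rect") {
    if (roi$x0 < 0 || roi$y0 < 0 || roi$x1 > W || roi$y1 > H)
      stop("ROI extends outside the image bounds", call. = FALSE)
    m <- matrix(FALSE, H, W)
    m[(roi$y0 + 1L):roi$y1, (roi$x0 + 1L):roi$x1] <- TRUE
    return(m)
  }
  if (any(roi$x < 0) || any(roi$y < 0) || any(roi$x > W) || any(roi$y > H))
    stop("ROI extends outside the image bounds", call. = FALSE)
  # even-odd crossing test at pixel centers, vectorized over rows
  xs <- seq_len(W) - 0.5
  ys <- seq_len(H) - 0.5
  m <- matrix(FALSE, H, W)
  vx <- roi$x; vy <- roi$y; nv <- length(vx)
  jprev <- nv
  for (j in seq_len(nv)) {
    x1 <- vx[jprev]; y1 <- vy[jprev]; x2 <- vx[j]; y2 <- vy[j]
    if (y1 != y2) {
      tmask <- ((y1 <= ys) & (ys < y2)) | ((y2 <= ys) & (ys < y1))
      if (any(tmask)) {
        xint <- x1 + (ys[tmask] - y1) / (y2 - y1) * (x2 - x1)
        m[tmask, ] <- xor(m[tmask, , drop = FALSE],
                          outer(xint, xs, function(xi, xc) xc < xi))
      }
    }
    jprev <- j
  }
  m
}

#' Segment collagen-positive pixels in a Masson-stained image
#'
#' Masson trichrome renders collagen blue/green and muscle/cytoplasm red.
#' The default classifier thresholds in HSV space: a pixel is
#' collagen-positive when its hue lies in `hue_window` (fractions of the
#' color circle; the default `[0.45, 0.75]` covers cyan through blue-violet)
#' and its saturation is at least `sat_min`. The rule is deterministic for
#' fixed parameters, and is a package choice -- report it alongside any
#' measured fiber content.
#'
#' @param img RGB image array `H x W x 3`, values in `[0, 1]` (as returned
#'   by [read_stained_image()] or [generate_masson_image()]).
#' @param roi An ROI ([roi_rect()] / [roi_polygon()]); `NULL` uses the whole
#'   frame.
#' @param hue_window Length-2 hue interval in `[0, 1]`.
#' @param sat_min Minimum saturation.
#' @return Logical `H x W` matrix: `TRUE` = collagen-positive, `FALSE`
#'   elsewhere (pixels outside the ROI are `FALSE`).
#' @export
segment_collagen <- function(img, roi = NULL, hue_window = c(0.45, 0.75),
                             sat_min = 0.15) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] < 3L)
    stop("'img' must be an H x W x 3 RGB array", call. = FALSE)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  rgb <- rbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
               as.vector(img[, , 3L]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  pos <- hsv[1L, ] >= hue_window[1L] & hsv[1L, ] <= hue_window[2L] &
    hsv[2L, ] >= sat_min
  mask <- matrix(pos, H, W)
  if (!is.null(roi)) mask <- mask & roi_mask(roi, c(H, W))
  mask
}

#' Collagen fiber content of an ROI
#'
#' `Vf (%) = collagen area (px) / ROI area (px) * 100`, an exact integer
#' ratio.
#'
#' @param mask Logical collagen mask (`H x W`), `TRUE` inside collagen.
#' @param roi ROI over which to measure; `NULL` uses the whole frame.
#' @return An object of class `"fiber_content_measurement"`: list with
#'   `collagen_px`, `roi_px`, `vf` (percent).
#' @examples
#' m <- matrix(FALSE, 10, 20); m[1:5, 1:10] <- TRUE
#' measure_vf(m)$vf  # 25
#' @export
measure_vf <- function(mask, roi = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("'mask' must be a logical matrix", call. = FALSE)
  inroi <- if (is.null(roi)) matrix(TRUE, nrow(mask), ncol(mask))
           else roi_mask(roi, dim(mask))
  roi_px <- sum(inroi)
  if (roi_px == 0L) stop("ROI has zero area", call. = FALSE)
  collagen_px <- sum(mask & inroi)
  structure(list(collagen_px = collagen_px, roi_px = roi_px,
                 vf = 100 * collagen_px / roi_px),
            class = "fiber_content_measurement")
}

#' @export
print.fiber_content_measurement <- function(x, ...) {
  cat(sprintf("Vf = %.4g%% (%d / %d px)\n", x$vf, x$collagen_px, x$roi_px))
  invisible(x)
}

#' Aggregate per-slice fiber content for a region
#'
#' Arithmetic mean of per-slice Vf values, reported at full precision.
#'
#' @param vf_values Numeric vector of per-slice Vf percentages (>= 1 value).
#' @param region Region label.
#' @return An object of class `"region_content_summary"`: list with
#'   `region`, `per_slice_vf`, `mean_vf`.
#' @examples
#' summarize_region(c(62.198, 59.01, 41.2, 51.417, 46.116), "apex")$mean_vf
#' @export
summarize_region <- function(vf_values, region = NA_character_) {
  if (length(vf_values) == 0L || !is.numeric(vf_values))
    stop("'vf_values' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(vf_values)) || any(vf_values < 0) || any(vf_values > 100))
    stop("Vf values must be finite percentages in [0, 100]", call. = FALSE)
  structure(list(region = region, per_slice_vf = vf_values,
                 mean_vf = mean(vf_values)),
            class = "region_content_summary")
}

#' @export
print.region_content_summary <- function(x, ...) {
  cat(sprintf("Region %s: mean Vf = %g%% over %d slices\n",
              x$region, x$mean_vf, length(x$per_slice_vf)))
  invisible(x)
}

#' Read a stained histology image
#'
#' Reads a PNG (or TIFF, if the tiff package is installed) into an
#' `H x W x 3` array in `[0, 1]`. Grayscale images are replicated across
#' channels; an alpha channel is dropped.
#'
#' @param path Image file path (.png, .tif/.tiff).
#' @return RGB array.
#' @export
read_stained_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB array as PNG
#'
#' @param img RGB array, values in `[0, 1]`.
#' @param path Output path.
#' @export
write_stained_image <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
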