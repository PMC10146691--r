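#' Otsu segmentation of a coflow frame
#'
#' Global Otsu threshold (maximizing between-class variance over a 256-bin
#' histogram) of the grayscale frame, with blood identified as the darker
#' class under bright-field illumination (set `dark_is_blood = FALSE` for
#' the opposite polarity).
#'
#' @param frame numeric matrix of intensities; rows run across the channel
#'   width, columns along the flow. Values may be on any affine scale
#'   (0-1, 0-255, ...): the threshold is computed on the frame's own range.
#' @param roi optional list with integer vectors `rows` and `cols`
#'   restricting the analysis region.
#' @param dark_is_blood logical; blood is the darker phase by default.
#' @param levels histogram bins for the threshold search.
#' @return logical matrix (TRUE = blood) over the ROI, with attribute
#'   `"threshold"` on the original intensity scale.
#' @export
otsu_threshold <- function(frame, roi = NULL, dark_is_blood = TRUE,
                           levels = 256) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  if (!is.null(roi)) frame <- frame[roi$rows, roi$cols, drop = FALSE]
  rng <- range(frame)
  if (rng[1] == rng[2]) {
    stop("segmentation failure: frame has a single intensity level",
         call. = FALSE)
  }
  scaled <- (frame - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(scaled, range = c(0, 1), levels = levels)
  mask <- if (dark_is_blood) scaled < thr else scaled > thr
  attr(mask, "threshold") <- thr * (rng[2] - rng[1]) + rng[1]
  mask
}

#' Interface fraction from a binary mask
#'
#' Counts blood pixels per column (i.e. per along-flow position), averages
#' the per-column blood-filled widths over the ROI, and divides by the
#' channel width in pixels. Counting foreground pixels rather than the
#' longest run makes the estimate robust to isolated speckle, but a blood
#' region that is not contiguous from the blood-channel wall (row 1) is
#' flagged as a possible segmentation artifact.
#'
#' @param mask logical matrix (TRUE = blood), rows across the channel.
#' @param width_px channel width in pixels; defaults to `nrow(mask)`.
#' @return alpha, with attribute `"contiguity_flag"` (TRUE when more than
#'   1\% of columns have non-contiguous blood).
#' @export
interface_fraction <- function(mask, width_px = nrow(mask)) {
  stopifnot(is.logical(mask), is.matrix(mask))
  widths <- colSums(mask)
  # contiguous-from-wall check: first `widths[j]` rows should all be blood
  contig <- vapply(seq_len(ncol(mask)), function(j) {
    wj <- widths[j]
    wj == 0 || all(mask[seq_len(wj), j])
  }, logical(1))
  a <- mean(widths) / width_px
  attr(a, "contiguity_flag") <- mean(!contig) > 0.01
  a
}

#' Render a synthetic coflow frame
#'
#' Draws a two-stream frame for testing the extraction pipeline: a dark
#' blood band of width `alpha * width_px` anchored at the blood-channel
#' wall (row 1), a light reference band, a smooth (Gaussian-profile)
#' intensity transition of scale `blur_sigma` at the interface, and
#' additive Gaussian pixel noise. Deterministic for a fixed seed. The
#' default pixel grid maps the 250 um channel width to 150 px at
#' 1.67 um/px and the 330 um ROI length to 198 px.
#'
#' @param alpha true interface fraction (0 < alpha < 1).
#' @param width_px,length_px frame size (rows = width, cols = length).
#' @param dark,light intensity levels (gray values) of blood/reference.
#' @param blur_sigma interface blur scale, px.
#' @param noise_sd pixel noise sd, gray levels.
#' @param seed RNG seed for the noise.
#' @return numeric matrix with attributes `"alpha_true"` and
#'   `"pixel_pitch"`.
#' @export
render_coflow_frame <- function(alpha, width_px = 150, length_px = 198,
                                dark = 40, light = 200, blur_sigma = 1,
                                noise_sd = 5, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (alpha * width_px < 2) {
    stop("blood band narrower than 2 px: insufficient resolution", call. = FALSE)
  }
  edge <- alpha * width_px  # continuous row coordinate of the interface
  rows <- seq_len(width_px) - 0.5
  profile <- if (blur_sigma > 0) {
    dark + (light - dark) * stats::pnorm((rows - edge) / blur_sigma)
  } else {
    ifelse(rows < edge, dark, light)
  }
  frame <- matrix(profile, nrow = width_px, ncol = length_px)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    frame <- frame + matrix(rnorm(length(frame), 0, noise_sd),
                            nrow = width_px)
  }
  frame <- pmin(pmax(frame, 0), 255)
  attr(frame, "alpha_true") <- alpha
  attr(frame, "pixel_pitch") <- 1.67
  frame
}

#' Interface series from an image stack
#'
#' Runs [otsu_threshold()] and [interface_fraction()] on every frame.
#' Frames whose segmentation fails are recorded as gaps (attribute
#' `"gaps"`: their indices) and dropped from the series.
#'
#' @param stack a list of matrices, a 3D array (row, col, frame), or a
#'   character vector of TIFF/PNG paths (multi-page TIFFs are expanded).
#' @param timestamps one time (s) per frame.
#' @param roi optional ROI (see [otsu_threshold()]).
#' @param dark_is_blood blood polarity flag.
#' @return an [interface_series()] with attribute `"gaps"`.
#' @export
series_from_stack <- function(stack, timestamps, roi = NULL,
                              dark_is_blood = TRUE) {
  if (is.character(stack)) stack <- read_image_stack(stack)
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  }
  if (length(stack) == 0) stop("empty image stack", call. = FALSE)
  if (length(stack) != length(timestamps)) {
    stop(sprintf("stack has %d frames but %d timestamps", length(stack),
                 length(timestamps)), call. = FALSE)
  }
  alpha <- vapply(stack, function(fr) {
    tryCatch({
      m <- otsu_threshold(fr, roi = roi, dark_is_blood = dark_is_blood)
      as.numeric(interface_fraction(m))
    }, error = function(e) NA_real_)
  }, numeric(1))
  gaps <- which(!is.finite(alpha) | alpha <= 0 | alpha >= 1)
  keep <- setdiff(seq_along(alpha), gaps)
  if (length(keep) == 0) stop("all frames failed segmentation", call. = FALSE)
  ser <- interface_series(timestamps[keep], alpha[keep])
  attr(ser, "gaps") <- gaps
  ser
}

#' Read a stack of grayscale images
#'
#' Reads single- or multi-page TIFF and PNG files into a list of intensity
#' matrices (RGB planes are averaged to grayscale).
#'
#' @param paths character vector of file paths.
#' @return list of numeric matrices.
#' @export
read_image_stack <- function(paths) {
  frames <- list()
  to_gray <- function(img) {
    if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                            c(1, 2), mean)
    img
  }
  for (p in paths) {
    if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      img <- tiff::readTIFF(p, all = TRUE)
      if (!is.list(img)) img <- list(img)
      frames <- c(frames, lapply(img, to_gray))
    } else if (grepl("\\.png$", p, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("reading PNG requires the 'png' package", call. = FALSE)
      }
      frames <- c(frames, list(to_gray(png::readPNG(p))))
    } else {
      stop("unsupported image format: ", p, call. = FALSE)
    }
  }
  frames
}
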