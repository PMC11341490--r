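#' Construct a slice stack
#'
#' An ordered set of transverse grayscale slices, proximal first, with the
#' spatial metadata the morphometry needs: in-plane pixel spacing and the
#' distance between consecutive slices.
#'
#' @param images list of numeric matrices, all with identical dimensions;
#'   rows run along the image height (`b`), columns along the width (`a`).
#' @param pixel_spacing mm per pixel (> 0).
#' @param slice_interval mm between slices (> 0).
#' @param provenance free-text source description.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(images, pixel_spacing, slice_interval,
                        provenance = "unknown") {
  if (!is.list(images) || length(images) == 0L) {
    stop("images must be a non-empty list of matrices")
  }
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all slices must share identical dimensions")
  }
  if (!(pixel_spacing > 0) || !(slice_interval > 0)) {
    stop("pixel_spacing and slice_interval must be positive")
  }
  structure(list(images = images,
                 pixel_spacing = pixel_spacing,
                 slice_interval = slice_interval,
                 provenance = provenance),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf(
    "slice_stack: %d slices of %d x %d px, %.3g mm/px, %.3g mm interval (%s)\n",
    length(x$images), d[2], d[1], x$pixel_spacing, x$slice_interval,
    x$provenance))
  invisible(x)
}

#' @export
length.slice_stack <- function(x) length(x$images)

#' Preprocessing parameters for region extraction
#'
#' Defaults follow the reference operating point for proximal-femur CT
#' extraction: a 7 x 7 Gaussian window with sigma = 3 and a low-cut
#' threshold T0 = 117 on the 8-bit gray scale. Canny hysteresis thresholds
#' default to an automatic median-based rule (`high = 2 * low`,
#' `low = 0.66 * median` of the positive gradient magnitudes).
#'
#' @param sigma Gaussian standard deviation in pixels.
#' @param window Gaussian window size in pixels (odd, >= 1).
#' @param t0 low-cut threshold gray level; pixels at or below it are zeroed.
#' @param canny_low,canny_high hysteresis thresholds in gray-levels/pixel of
#'   gradient magnitude, or `NULL` for the automatic rule.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(sigma = 3, window = 7, t0 = 117,
                              canny_low = NULL, canny_high = NULL) {
  if (window %% 2 == 0 || window < 1) stop("window must be odd and >= 1")
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(canny_low) && !is.null(canny_high) &&
        !(canny_low < canny_high)) {
    stop("canny_low must be < canny_high")
  }
  structure(list(sigma = sigma, window = as.integer(window), t0 = t0,
                 canny_low = canny_low, canny_high = canny_high),
            class = "preprocess_params")
}

#' Discrete isotropic Gaussian kernel
#'
#' The product of two identical 1-D Gaussians evaluated on the window grid
#' and renormalized to sum 1, so convolution preserves constant images
#' exactly.
#'
#' @param sigma standard deviation in pixels.
#' @param window kernel size (odd).
#' @return `window x window` numeric matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, window) {
  if (window %% 2 == 0) stop("window must be odd")
  h <- (window - 1) / 2
  d <- seq(-h, h)
  g1 <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Gaussian smoothing of a slice
#'
#' Convolves the image with [gaussian_kernel()] using replicate edge
#' padding; output has the input's dimensions.
#'
#' @param image numeric matrix of gray levels.
#' @param sigma,window kernel parameters, see [gaussian_kernel()].
#' @return Smoothed numeric matrix.
#' @export
gaussian_smooth <- function(image, sigma = 3, window = 7) {
  k <- gaussian_kernel(sigma, window)
  if (window == 1) return(image)
  cpp_convolve2d(image, k)
}

#' Low-cut intensity threshold
#'
#' Retains pixel values strictly greater than `t0` and zeroes the rest;
#' values are kept, not binarized, so the subsequent gradient still sees
#' the intensity ramp. Idempotent for fixed `t0`.
#'
#' @param image numeric matrix.
#' @param t0 threshold gray level.
#' @return Matrix with sub-threshold pixels set to 0.
#' @export
threshold_low_cut <- function(image, t0) {
  image[image <= t0] <- 0
  image
}

#' Canny edge detection
#'
#' Sobel gradient, non-maximum suppression along the quantized gradient
#' direction, and double-threshold hysteresis. The input is expected to be
#' already smoothed (and usually low-cut thresholded); no extra smoothing is
#' applied here.
#'
#' @param image numeric matrix.
#' @param params a [preprocess_params()]; only the Canny thresholds are
#'   used.
#' @return Logical edge map of the input's dimensions.
#' @export
detect_edges <- function(image, params = preprocess_params()) {
  lo <- params$canny_low
  hi <- params$canny_high
  if (is.null(lo) || is.null(hi)) {
    mag <- cpp_sobel(image)$mag
    pos <- mag[mag > 0]
    if (length(pos) == 0L) return(matrix(FALSE, nrow(image), ncol(image)))
    if (is.null(lo)) lo <- 0.66 * stats::median(pos)
    if (is.null(hi)) hi <- 2 * lo
  }
  cpp_canny(image, lo, hi) == 1L
}

#' Extract the femoral region masks from one slice
#'
#' Runs the full per-slice pipeline: Gaussian smoothing, low-cut
#' thresholding, Canny edge detection, then contour filling and
#' subtraction. The largest closed edge contour (by filled area) becomes
#' the overall femoral region; the largest closed contour nested strictly
#' inside it bounds the medullary cavity; cortical = overall minus
#' medullary.
#'
#' The one-pixel Canny contour straddles the tissue transition, so its
#' pixels are assigned by the low-cut image itself: contour pixels that
#' survive the threshold are cortical bone, sub-threshold contour pixels
#' belong to the region on their dark side (medullary for the inner
#' contour, background for the outer one). This keeps the extracted masks
#' free of a systematic half-pixel ring bias.
#'
#' Slices with no closed outer contour are flagged `"no_femur"`; slices
#' without a nested inner contour are flagged `"no_cavity"` (distal slices
#' may legitimately lack a resolvable cavity). Flagged slices carry empty
#' masks and are excluded from per-slice statistics downstream.
#'
#' @param image numeric matrix of gray levels.
#' @param params a [preprocess_params()].
#' @param slice_index bookkeeping index stored in the result.
#' @return An object of class `region_masks` with logical matrices
#'   `overall`, `cortical`, `medullary`, the `slice_index`, and `flag`
#'   (`NA` when the slice is accepted).
#' @export
extract_masks <- function(image, params = preprocess_params(),
                          slice_index = NA_integer_) {
  sm <- gaussian_smooth(image, params$sigma, params$window)
  th <- threshold_low_cut(sm, params$t0)
  edges <- detect_edges(th, params)

  b <- nrow(image); a <- ncol(image)
  empty <- matrix(FALSE, b, a)
  flagged <- function(flag) {
    structure(list(overall = empty, cortical = empty, medullary = empty,
                   slice_index = slice_index, flag = flag),
              class = "region_masks")
  }
  if (!any(edges)) return(flagged("no_femur"))

  labs <- cpp_label(matrix(as.integer(edges), b, a), 8L)
  nlab <- max(labs)
  comp_px <- tabulate(labs[labs > 0L], nbins = nlab)
  filled <- vector("list", nlab)
  filled_px <- integer(nlab)
  for (l in seq_len(nlab)) {
    filled[[l]] <- cpp_fill_holes(matrix(as.integer(labs == l), b, a)) == 1L
    filled_px[l] <- sum(filled[[l]])
  }
  closed <- filled_px > comp_px  # open curves enclose nothing
  if (!any(closed)) return(flagged("no_femur"))

  outer_l <- which(closed)[which.max(filled_px[closed])]
  # sub-threshold pixels on the outer contour are background, not femur
  overall <- filled[[outer_l]] & !((labs == outer_l) & th <= 0)

  interior <- overall & !(labs == outer_l)
  inner_l <- 0L
  inner_best <- 0L
  for (l in seq_len(nlab)) {
    if (l == outer_l || !closed[l]) next
    if (all(interior[labs == l]) && filled_px[l] > inner_best) {
      inner_l <- l
      inner_best <- filled_px[l]
    }
  }
  if (inner_l == 0L) {
    res <- flagged("no_cavity")
    res$overall <- overall
    return(res)
  }
  # sub-threshold pixels on the inner contour are marrow, the rest cortical
  medullary <- filled[[inner_l]] & !((labs == inner_l) & th > 0)
  medullary <- medullary & overall
  cortical <- overall & !medullary
  structure(list(overall = overall, cortical = cortical,
                 medullary = medullary, slice_index = slice_index,
                 flag = NA_character_),
            class = "region_masks")
}

#' Extract region masks for every slice of a stack
#'
#' @param stack a [slice_stack()].
#' @param params a [preprocess_params()].
#' @param slice_range optional integer vector `c(start, end)` restricting
#'   the slices analysed (1-based, inclusive), emulating a clinically
#'   selected slice range.
#' @return A list of class `region_masks_stack`: `masks` (one
#'   `region_masks` per analysed slice), `flags` (character, `NA` for
#'   accepted slices), `accepted` (logical), and the stack metadata.
#' @export
extract_masks_stack <- function(stack, params = preprocess_params(),
                                slice_range = NULL) {
  stopifnot(inherits(stack, "slice_stack"))
  idx <- seq_along(stack$images)
  if (!is.null(slice_range)) {
    if (length(slice_range) != 2L || slice_range[1] < 1 ||
          slice_range[2] > length(idx) || slice_range[1] > slice_range[2]) {
      stop("invalid slice_range")
    }
    idx <- idx[slice_range[1]:slice_range[2]]
  }
  masks <- lapply(idx, function(i) {
    extract_masks(stack$images[[i]], params, slice_index = i)
  })
  flags <- vapply(masks, function(m) m$flag, character(1))
  structure(list(masks = masks, flags = flags, accepted = is.na(flags),
                 slice_indices = idx,
                 pixel_spacing = stack$pixel_spacing,
                 slice_interval = stack$slice_interval),
            class = "region_masks_stack")
}
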