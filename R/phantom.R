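#' Specification of a synthetic femur phantom
#'
#' Describes a fully synthetic stack of transverse slices through a
#' trumpet-shaped femoral canal: a bright elliptical cortical annulus around
#' a dark medullary interior, on a darker background. The inner (medullary)
#' semi-axes narrow from the proximal end to a unique minimum at the isthmus
#' slice and widen again distally; a localized medial bump on the outer
#' boundary marks the lesser-trochanter slice so that the most prominent
#' cross section has a well-defined ground truth.
#'
#' Radius profiles are given in millimetres as per-slice semi-axes. A vector
#' is interpreted as circular cross sections; an \code{n_slices x 2} matrix
#' gives distinct x (medial-lateral) and y semi-axes. When profiles are
#' omitted, a default trumpet geometry is built: the inner semi-axis falls
#' linearly from 30 mm proximally to 8 mm at the isthmus and rises linearly
#' to 12 mm distally, while cortical thickness grows from 4 mm proximally
#' to 10 mm at the isthmus (proximal cortex thin, shaft cortex thick).
#'
#' Default intensities (background 30, marrow 34, cortical 200 on the 8-bit
#' scale) place both tissue transition midpoints at the default low-cut
#' threshold 117. This emulates a CT window/level under which the operating
#' threshold was calibrated to sit mid-transition -- the condition that
#' makes a fixed gray threshold an unbiased boundary locator -- while
#' keeping the compact/spongy bone contrast strong and both dark tissues
#' far below threshold.
#'
#' @param image_width_px,image_height_px image dimensions `a` and `b` in
#'   pixels.
#' @param pixel_spacing mm per pixel.
#' @param slice_interval mm between consecutive slices.
#' @param n_slices number of slices, proximal first.
#' @param outer_radius_profile,inner_radius_profile per-slice semi-axes in
#'   mm (vector or `n_slices x 2` matrix), or `NULL` for the default
#'   trumpet geometry.
#' @param isthmus_slice_index slice (1-based) where the inner profile
#'   attains its unique minimum.
#' @param trochanter_slice_index slice carrying the outer-boundary bump.
#' @param trochanter_bump_amplitude mm added to the outer medial (x)
#'   semi-axis at the trochanter slice, with a Gaussian falloff of 1.5
#'   slices.
#' @param intensity_background,intensity_marrow,intensity_cortical gray
#'   levels on \[0, 255\]; cortical must be the brightest.
#' @param noise_sd standard deviation of the additive Gaussian noise (gray
#'   levels).
#' @param seed integer seed controlling the noise.
#' @return An object of class `phantom_spec` with the effective (bumped)
#'   per-slice semi-axes in the `outer_semiaxes` and `inner_semiaxes`
#'   fields (mm, `n_slices x 2` matrices).
#' @export
phantom_spec <- function(image_width_px = 240L,
                         image_height_px = 240L,
                         pixel_spacing = 0.5,
                         slice_interval = 5,
                         n_slices = 60L,
                         outer_radius_profile = NULL,
                         inner_radius_profile = NULL,
                         isthmus_slice_index = 40L,
                         trochanter_slice_index = 12L,
                         trochanter_bump_amplitude = 10,
                         intensity_background = 30,
                         intensity_marrow = 34,
                         intensity_cortical = 200,
                         noise_sd = 5,
                         seed = 1L) {
  n <- as.integer(n_slices)
  if (n < 1L) stop("n_slices must be >= 1")
  k <- as.integer(isthmus_slice_index)
  j <- as.integer(trochanter_slice_index)
  if (k < 1L || k > n) stop("isthmus_slice_index outside the stack")
  if (j < 1L || j > n) stop("trochanter_slice_index outside the stack")

  if (is.null(inner_radius_profile)) {
    inner_radius_profile <- default_trumpet_inner(n, k)
  }
  if (is.null(outer_radius_profile)) {
    thick <- 4 + 6 * pmin(1, (seq_len(n) - 1) / max(1, k - 1))
    outer_radius_profile <- as_semiaxes(inner_radius_profile, n) + thick
  }
  inner <- as_semiaxes(inner_radius_profile, n)
  outer <- as_semiaxes(outer_radius_profile, n)

  # localized medial prominence on the outer boundary
  bump <- trochanter_bump_amplitude * exp(-0.5 * ((seq_len(n) - j) / 1.5)^2)
  outer[, 1L] <- outer[, 1L] + bump

  spec <- structure(list(
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    pixel_spacing = pixel_spacing,
    slice_interval = slice_interval,
    n_slices = n,
    outer_semiaxes = outer,
    inner_semiaxes = inner,
    isthmus_slice_index = k,
    trochanter_slice_index = j,
    trochanter_bump_amplitude = trochanter_bump_amplitude,
    intensity_background = intensity_background,
    intensity_marrow = intensity_marrow,
    intensity_cortical = intensity_cortical,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# linear (conical) trumpet: inner radius falls to a sharp minimum at the
# isthmus slice and rises again distally, so adjacent-slice areas are well
# separated everywhere
default_trumpet_inner <- function(n, k) {
  r_prox <- 30; r_min <- 8; r_dist <- 12
  i <- seq_len(n)
  r <- numeric(n)
  up <- i <= k
  r[up] <- r_min + (r_prox - r_min) * (k - i[up]) / max(1, k - 1)
  if (any(!up)) {
    r[!up] <- r_min + (r_dist - r_min) * (i[!up] - k) / max(1, n - k)
  }
  r
}

as_semiaxes <- function(p, n) {
  if (is.matrix(p)) {
    if (nrow(p) != n || ncol(p) != 2L) stop("radius profile must be n_slices x 2")
    unname(p)
  } else {
    if (length(p) != n) stop("radius profile length must equal n_slices")
    cbind(as.numeric(p), as.numeric(p))
  }
}

validate_phantom_spec <- function(spec) {
  bad <- which(spec$inner_semiaxes[, 1L] >= spec$outer_semiaxes[, 1L] |
                 spec$inner_semiaxes[, 2L] >= spec$outer_semiaxes[, 2L])
  if (length(bad)) {
    stop("degenerate annulus (inner semi-axis >= outer) at slice(s): ",
         paste(bad, collapse = ", "))
  }
  inner_size <- spec$inner_semiaxes[, 1L] * spec$inner_semiaxes[, 2L]
  if (which.min(inner_size) != spec$isthmus_slice_index ||
      sum(inner_size == min(inner_size)) != 1L) {
    # constant or custom profiles are allowed, but isthmus ground truth is
    # then not trustworthy
    warning("inner radius profile does not attain a unique minimum at ",
            "isthmus_slice_index; ground-truth c_m1 may be meaningless")
  }
  with(spec, {
    if (!(intensity_cortical > intensity_marrow &&
            intensity_marrow >= intensity_background)) {
      stop("intensities must satisfy cortical > marrow >= background")
    }
  })
  invisible(spec)
}

#' Rasterize an ellipse on the pixel grid
#'
#' A pixel belongs to the ellipse iff its centre (integer coordinates,
#' 0-based, x along the width, y along the height) satisfies
#' `((x - cx)/A)^2 + ((y - cy)/B)^2 <= 1`.
#'
#' @param a,b image width and height in pixels.
#' @param cx,cy ellipse centre in pixel coordinates.
#' @param A,B semi-axes in pixels along x and y.
#' @return Logical matrix (`b` rows, `a` columns).
#' @export
rasterize_ellipse <- function(a, b, cx, cy, A, B) {
  x <- matrix(rep(0:(a - 1L), each = b), nrow = b)
  y <- matrix(rep(0:(b - 1L), times = a), nrow = b)
  ((x - cx) / A)^2 + ((y - cy) / B)^2 <= 1
}

#' Generate a synthetic femoral slice stack with ground truth
#'
#' Renders each slice as background intensity everywhere except an
#' elliptical cortical annulus and an inner medullary ellipse, both centred,
#' then adds independent Gaussian noise clipped to \[0, 255\] and rounded to
#' 8-bit gray levels. Ground-truth masks are the noise-free rasterizations;
#' analytic areas use the exact ellipse formula pi * A * B.
#'
#' @param spec a [phantom_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{stack}{a [slice_stack()] of noisy 8-bit images.}
#'     \item{truth}{a `phantom_truth` list: `cortical_masks` and
#'       `medullary_masks` (logical matrices), `cortical_px` /
#'       `medullary_px` exact pixel counts, `cortical_mm2` / `medullary_mm2`
#'       analytic areas, and `key_sections` (true `c_m0`, `c_m0_plus20`,
#'       `c_m0_minus20`, `c_m1` slice indices).}
#'   }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  a <- spec$image_width_px
  b <- spec$image_height_px
  cx <- (a - 1) / 2
  cy <- (b - 1) / 2
  px <- spec$pixel_spacing

  images <- vector("list", spec$n_slices)
  cort_masks <- vector("list", spec$n_slices)
  med_masks <- vector("list", spec$n_slices)
  cort_px <- integer(spec$n_slices)
  med_px <- integer(spec$n_slices)

  old_seed <- set_local_seed(spec$seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  for (i in seq_len(spec$n_slices)) {
    Aout <- spec$outer_semiaxes[i, 1L] / px
    Bout <- spec$outer_semiaxes[i, 2L] / px
    Ain <- spec$inner_semiaxes[i, 1L] / px
    Bin <- spec$inner_semiaxes[i, 2L] / px
    outer <- rasterize_ellipse(a, b, cx, cy, Aout, Bout)
    inner <- rasterize_ellipse(a, b, cx, cy, Ain, Bin)
    cort <- outer & !inner
    img <- matrix(spec$intensity_background, nrow = b, ncol = a)
    img[cort] <- spec$intensity_cortical
    img[inner] <- spec$intensity_marrow
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(a * b, sd = spec$noise_sd),
                          nrow = b, ncol = a)
    }
    img <- round(pmin(pmax(img, 0), 255))
    images[[i]] <- img
    cort_masks[[i]] <- cort
    med_masks[[i]] <- inner
    cort_px[i] <- sum(cort)
    med_px[i] <- sum(inner)
  }

  offs <- as.integer(round(20 / spec$slice_interval))
  key <- list(
    c_m0 = spec$trochanter_slice_index,
    c_m0_plus20 = spec$trochanter_slice_index - offs,
    c_m0_minus20 = spec$trochanter_slice_index + offs,
    c_m1 = spec$isthmus_slice_index
  )

  truth <- structure(list(
    cortical_masks = cort_masks,
    medullary_masks = med_masks,
    cortical_px = cort_px,
    medullary_px = med_px,
    cortical_mm2 = pi * (spec$outer_semiaxes[, 1L] * spec$outer_semiaxes[, 2L] -
                           spec$inner_semiaxes[, 1L] * spec$inner_semiaxes[, 2L]),
    medullary_mm2 = pi * spec$inner_semiaxes[, 1L] * spec$inner_semiaxes[, 2L],
    key_sections = key,
    spec = spec
  ), class = "phantom_truth")

  stack <- slice_stack(images, pixel_spacing = px,
                       slice_interval = spec$slice_interval,
                       provenance = sprintf("phantom(seed=%d)", spec$seed))
  list(stack = stack, truth = truth)
}

# Seed handling: run a block under a given seed without disturbing the
# caller's RNG stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
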