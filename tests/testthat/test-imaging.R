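test_that("gaussian kernel and smoothing match direct evaluation", {
  # direct double-loop evaluation of the 2-D Gaussian product formula
  direct_kernel <- function(sigma, window) {
    h <- (window - 1) / 2
    k <- matrix(0, window, window)
    for (i in seq_len(window)) {
      for (j in seq_len(window)) {
        x <- j - 1 - h; y <- i - 1 - h
        k[i, j] <- exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
      }
    }
    k / sum(k)
  }
  expect_equal(gaussian_kernel(3, 7), direct_kernel(3, 7))
  expect_equal(sum(gaussian_kernel(3, 7)), 1)

  # impulse response embeds the kernel
  img <- matrix(0, 5, 5); img[3, 3] <- 1
  out <- gaussian_smooth(img, sigma = 3, window = 3)
  expect_equal(out[2:4, 2:4], direct_kernel(3, 3))

  # constants preserved; window 1 is the identity
  cimg <- matrix(7.5, 11, 13)
  expect_equal(gaussian_smooth(cimg, 3, 7), cimg)
  rimg <- matrix(runif(30), 5, 6)
  expect_equal(gaussian_smooth(rimg, 2, 1), rimg)

  expect_error(gaussian_smooth(cimg, 3, 4), "odd")
  expect_error(preprocess_params(window = 6), "odd")
})

test_that("low-cut threshold is strict, idempotent, and value-preserving", {
  img <- matrix(c(117, 118, 0, 200), 2, 2)
  out <- threshold_low_cut(img, 117)
  expect_equal(out, matrix(c(0, 118, 0, 200), 2, 2))

  z <- matrix(0, 4, 4)
  expect_equal(threshold_low_cut(z, 50), z)
  pos <- matrix(1:12, 3, 4)
  expect_equal(threshold_low_cut(pos, 0), pos)

  # idempotence for arbitrary images/thresholds
  set.seed(1)
  for (t0 in c(0, 50, 117)) {
    r <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    once <- threshold_low_cut(r, t0)
    expect_identical(threshold_low_cut(once, t0), once)
  }
})

test_that("canny edges: empty on constants, two closed curves on nested circles", {
  expect_false(any(detect_edges(matrix(5, 50, 50))))

  masks <- disk_masks(a = 120L, b = 120L, r_in = 20, r_out = 35)
  img <- matrix(30, 120, 120)
  img[masks$cortical] <- 200
  img[masks$medullary] <- 34
  th <- threshold_low_cut(gaussian_smooth(img, 3, 7), 117)
  ed <- detect_edges(th)
  labs <- canalmorph:::cpp_label(matrix(as.integer(ed), 120, 120), 8L)
  expect_identical(max(labs), 2L)
  # both curves are closed: each encloses interior pixels
  for (l in 1:2) {
    comp <- labs == l
    filled <- canalmorph:::cpp_fill_holes(matrix(as.integer(comp), 120, 120)) == 1L
    expect_gt(sum(filled), sum(comp))
  }
})

test_that("canny edges on a noise-free phantom lie within 1 px of the true boundaries", {
  ana <- default_phantom_analysis(noise_sd = 0)
  spec <- ana$gen$truth$spec
  i <- 30L
  img <- ana$gen$stack$images[[i]]
  th <- threshold_low_cut(gaussian_smooth(img, 3, 7), 117)
  ed <- detect_edges(th)
  cx <- (spec$image_width_px - 1) / 2
  cy <- (spec$image_height_px - 1) / 2
  x <- col(ed)[ed] - 1; y <- row(ed)[ed] - 1
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  # circular slice: distance to inner or outer radius (in px)
  r_in <- spec$inner_semiaxes[i, 1] / spec$pixel_spacing
  r_out <- spec$outer_semiaxes[i, 1] / spec$pixel_spacing
  d <- pmin(abs(r - r_in), abs(r - r_out))
  expect_lte(max(d), 1)
})

test_that("extract_masks recovers phantom ground truth and flags bad slices", {
  for (noise in c(0, 5)) {
    tol <- if (noise == 0) 0.02 else 0.05
    ana <- default_phantom_analysis(noise_sd = noise)
    tr <- ana$gen$truth
    ms <- ana$masks
    expect_true(all(ms$accepted))
    for (i in seq_along(ms$masks)) {
      m <- ms$masks[[i]]
      expect_lte(abs(sum(m$cortical) - tr$cortical_px[i]),
                 tol * tr$cortical_px[i])
      expect_lte(abs(sum(m$medullary) - tr$medullary_px[i]),
                 tol * tr$medullary_px[i])
      # mask partition invariants
      expect_false(any(m$cortical & m$medullary))
      expect_true(all(m$overall[m$cortical | m$medullary]))
      expect_lte(sum(m$overall), prod(dim(m$overall)))
    }
  }
})

test_that("uniform background is flagged no_femur; solid disk no_cavity", {
  flat <- matrix(30, 120, 120)
  m <- extract_masks(flat)
  expect_identical(m$flag, "no_femur")
  expect_false(any(m$overall))

  solid <- matrix(30, 120, 120)
  solid[rasterize_ellipse(120L, 120L, 59.5, 59.5, 30, 30)] <- 200
  m2 <- extract_masks(solid)
  expect_identical(m2$flag, "no_cavity")
  expect_true(any(m2$overall))
  expect_false(any(m2$medullary))
})

test_that("slice_stack validates dimensions and metadata", {
  imgs <- list(matrix(0, 4, 5), matrix(0, 4, 5))
  expect_s3_class(slice_stack(imgs, 0.5, 5), "slice_stack")
  expect_error(slice_stack(list(matrix(0, 4, 5), matrix(0, 5, 4)), 0.5, 5),
               "identical dimensions")
  expect_error(slice_stack(imgs, 0, 5), "positive")
  expect_error(slice_stack(list(), 0.5, 5), "non-empty")
  expect_error(extract_masks_stack(slice_stack(imgs, 0.5, 5),
                                   slice_range = c(0, 2)),
               "slice_range")
})
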