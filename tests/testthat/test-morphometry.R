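test_that("find_isthmus takes the global minimum with proximal tie-break", {
  expect_identical(find_isthmus(c(5, 3, 4, 8)), 2L)
  # strictly decreasing profile: last slice
  expect_identical(find_isthmus(c(9, 7, 5, 3)), 4L)
  # tie resolves to the more proximal index
  expect_identical(find_isthmus(c(4, 2, 2, 5)), 2L)
  # NA (flagged) entries ignored; slice index mapping respected
  expect_identical(find_isthmus(c(NA, 7, 3, NA), slice_indices = 11:14), 13L)
  expect_error(find_isthmus(c(NA_real_, NA_real_)), "no accepted")
})

test_that("find_trochanter_section picks the designed bump and honours overrides", {
  gen <- generate_phantom(small_spec())
  ms <- extract_masks_stack(gen$stack)
  expect_identical(find_trochanter_section(ms), 5L)
  expect_identical(find_trochanter_section(ms, window = c(2, 9)), 5L)
  expect_identical(find_trochanter_section(ms, override = 7L), 7L)
  expect_error(find_trochanter_section(ms, window = c(100, 120)), "empty")

  # constant geometry: tie resolves to the first slice of the window
  spec <- suppressWarnings(phantom_spec(
    image_width_px = 120L, image_height_px = 120L, pixel_spacing = 1,
    n_slices = 4L, inner_radius_profile = rep(20, 4),
    outer_radius_profile = rep(30, 4), isthmus_slice_index = 1L,
    trochanter_slice_index = 1L, trochanter_bump_amplitude = 0,
    noise_sd = 0))
  msc <- extract_masks_stack(suppressWarnings(generate_phantom(spec))$stack)
  expect_identical(find_trochanter_section(msc, window = c(2, 4)), 2L)
})

test_that("offset_section converts mm to slices with rounding", {
  expect_identical(offset_section(10L, 20, 5, "proximal"), 6L)
  expect_identical(offset_section(10L, 20, 5, "distal"), 14L)
  expect_identical(offset_section(10L, 0, 5, "proximal"), 10L)
  # round(20/3) = round(6.67) = 7
  expect_identical(offset_section(10L, 20, 3, "distal"), 17L)
  expect_error(offset_section(3L, 20, 5, "proximal"), "outside")
  expect_error(offset_section(10L, 20, 5, "distal", n_slices = 12L),
               "outside")
})

test_that("section diameters match the analytic phantom geometry", {
  gen <- generate_phantom(small_spec())
  ms <- extract_masks_stack(gen$stack)
  spec <- gen$truth$spec
  px <- spec$pixel_spacing
  for (i in c(1L, 5L, 10L)) {
    d <- section_diameters(ms$masks[[i]], px)
    expect_lte(abs(d$inner_mm - 2 * spec$inner_semiaxes[i, 1]), px)
    expect_lte(abs(d$outer_mm - 2 * spec$outer_semiaxes[i, 1]), px)
  }
  # doubling pixel_spacing doubles all mm values for fixed masks
  d1 <- section_diameters(ms$masks[[10]], 1)
  d2 <- section_diameters(ms$masks[[10]], 2)
  expect_equal(d2$inner_mm, 2 * d1$inner_mm)
  expect_equal(d2$outer_mm, 2 * d1$outer_mm)
  expect_equal(d2$thickness_mm, 2 * d1$thickness_mm)

  # empty medullary mask: inner diameter undefined
  e <- matrix(FALSE, 20, 20); o <- matrix(TRUE, 20, 20)
  m <- structure(list(overall = o, cortical = o, medullary = e,
                      slice_index = 1L, flag = NA_character_),
                 class = "region_masks")
  expect_true(is.na(section_diameters(m, 1)$inner_mm))
})

test_that("lengths follow the slice arithmetic", {
  ks <- suppressWarnings(key_sections(10L, 32L, 5, n_slices = 40L))
  l <- compute_lengths(ks, n_slices = 40L, slice_interval = 5)
  expect_equal(l$ih_mm, 110)
  expect_equal(l$lh_mm, 195)
  expect_equal(compute_lengths(ks, 40L, 5, lh = 446.96)$lh_mm, 446.96)
  ks0 <- suppressWarnings(key_sections(10L, 10L, 5, n_slices = 40L))
  expect_equal(compute_lengths(ks0, 40L, 5)$ih_mm, 0)
  expect_error(compute_lengths(list(c_m0 = NA, c_m1 = 3L), 40L, 5),
               "missing")
})

test_that("canal_ratios reproduces the algebraic identities", {
  set.seed(7)
  for (k in 1:10) {
    d <- sort(runif(3, 5, 60))   # t_mi < t_minus20 < t_plus20
    cr <- canal_ratios(t_plus20 = d[3], t_minus20 = d[2], t_mi = d[1],
                       t_mo = d[1] + 10, ih = 100, lh = 400,
                       s_m0_plus20 = 3000, s_m0_minus20 = 2500, s_m1 = 500)
    expect_equal(cr$cfi, cr$mcfi * cr$dcfi)
    expect_equal(cr$cfi, d[3] / d[1])
    expect_equal(cr$ci, 10 / (d[1] + 10))
  }
  # q2 = q1 / (1 - q1) per-slice identity on phantom output
  gen <- generate_phantom(small_spec())
  ms <- extract_masks_stack(gen$stack)
  mc <- mc_area_stack(ms, n = 57600, seed = 2)
  morph <- compute_morphometry(ms, mc)
  ps <- morph$per_slice
  expect_equal(ps$q2, ps$q1 / (1 - ps$q1))
  expect_true(all(ps$q1 > 0 & ps$q1 < 1))
  # undefined denominators flagged as NA
  expect_true(is.na(canal_ratios(t_plus20 = 40, t_mi = 0)$cfi))
  expect_true(is.na(canal_ratios(s_m0_plus20 = 10, s_m1 = 0)$r2))
})

test_that("canal classification follows the CFI bands", {
  expect_identical(classify_canal(2.999), "chimney")
  expect_identical(classify_canal(3.0), "normal")
  expect_identical(classify_canal(4.09), "normal")
  expect_identical(classify_canal(4.7), "champagne")
  expect_identical(classify_canal(6.5), "unclassified")
  expect_error(classify_canal(0), "positive")
  expect_error(classify_canal(-1), "positive")
})

test_that("compute_morphometry recovers the phantom parameters end to end", {
  gen <- generate_phantom(small_spec())
  ms <- extract_masks_stack(gen$stack)
  mc <- mc_area_stack(ms, n = 57600, seed = 3)
  morph <- compute_morphometry(ms, mc, use_traversal = TRUE)
  ks <- gen$truth$key_sections
  expect_identical(morph$key$c_m0, ks$c_m0)
  expect_identical(morph$key$c_m1, ks$c_m1)
  expect_identical(morph$key$c_m0_plus20, ks$c_m0_plus20)
  expect_identical(morph$key$c_m0_minus20, ks$c_m0_minus20)
  spec <- gen$truth$spec
  expect_lte(abs(morph$lengths$ih_mm -
                   abs(ks$c_m1 - ks$c_m0) * spec$slice_interval), 1e-9)
  expect_lte(abs(morph$diameters$t_mi - 2 * spec$inner_semiaxes[ks$c_m1, 1]),
             spec$pixel_spacing)
})
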