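test_that("estimator identities hold exactly for raw counts", {
  # direct substitution: n = 1000, n1 = 300, n2 = 800
  r <- mc_result(n = 1000, n1 = 300, n2 = 800, a = 240, b = 240)
  expect_identical(r$alpha_c, 0.2)
  expect_identical(r$alpha_m, 0.1)
  expect_identical(r$s_c, 0.2 * 240 * 240)
  expect_identical(r$s_m, 0.1 * 240 * 240)
  expect_error(mc_result(1000, 300, 100, 240, 240), "inconsistent")
})

test_that("saturated cortical mask gives alpha_c = 1", {
  full <- matrix(TRUE, 60, 80)
  masks <- structure(list(overall = full, cortical = full,
                          medullary = !full, slice_index = 1L,
                          flag = NA_character_), class = "region_masks")
  r <- mc_area(masks, n = 5000, seed = 1)
  expect_identical(r$n2, 0L)
  expect_identical(r$n1, 5000L)
  expect_identical(r$alpha_c, 1)
  expect_identical(r$alpha_m, 0)
  expect_identical(r$s_c, 60 * 80)
})

test_that("mc_area is reproducible and satisfies the algebraic identities", {
  masks <- disk_masks()
  r1 <- mc_area(masks, n = 10000, seed = 99)
  r2 <- mc_area(masks, n = 10000, seed = 99)
  expect_identical(r1, r2)
  expect_identical(r1$alpha_c, (r1$n - r1$n2) / r1$n)
  expect_identical(r1$alpha_m, (r1$n1 - (r1$n - r1$n2)) / r1$n)
  expect_identical(r1$s_m, r1$alpha_m * 240 * 240)
  expect_lte(r1$alpha_c + r1$alpha_m, 1)
})

test_that("traversal counts equal independent brute-force enumeration", {
  # empty and full masks
  e <- matrix(FALSE, 40, 40); f <- matrix(TRUE, 40, 40)
  empty <- structure(list(overall = e, cortical = e, medullary = e,
                          slice_index = 1L, flag = NA_character_),
                     class = "region_masks")
  t0 <- traversal_area(empty)
  expect_identical(t0$cortical_count, 0L)
  expect_identical(t0$alpha_mt, 0)
  fullm <- structure(list(overall = f, cortical = f, medullary = e,
                          slice_index = 1L, flag = NA_character_),
                     class = "region_masks")
  expect_identical(traversal_area(fullm)$alpha_ct, 1)

  # rasterized disk r = 50 against the double-loop oracle
  masks <- disk_masks(r_in = 50, r_out = 60)
  tv <- traversal_area(masks)
  expect_identical(tv$medullary_count,
                   brute_ellipse_count(240L, 240L, 119.5, 119.5, 50, 50))
  expect_identical(tv$alpha_mt, tv$medullary_count / (240 * 240))
})

test_that("mc estimates are unbiased and within the binomial band", {
  masks <- disk_masks(r_in = 50, r_out = 55)
  tv <- traversal_area(masks)
  n <- 57600
  am <- vapply(1:40, function(s) mc_area(masks, n, seed = s)$alpha_m,
               numeric(1))
  se <- sqrt(tv$alpha_mt * (1 - tv$alpha_mt) / n)
  # unbiasedness: mean over seeds close to exact proportion
  expect_lt(abs(mean(am) - tv$alpha_mt), 3 * se / sqrt(40))
  # individual draws inside 3 sigma almost always
  expect_gte(mean(abs(am - tv$alpha_mt) <= 3 * se), 0.95)
})

test_that("stack batching ties seeds to slice indices and skips flags", {
  gen <- generate_phantom(small_spec())
  ms <- extract_masks_stack(gen$stack)
  mc <- mc_area_stack(ms, n = 20000, seed = 5)
  expect_length(mc$results, 14L)
  tab <- mc_area_table(mc)
  expect_identical(nrow(tab), 14L)
  expect_named(tab, c("slice_index", "n", "n1", "n2", "alpha_c", "alpha_m",
                      "s_c", "s_m", "alpha_ct", "alpha_mt"))

  # permuting the mask list permutes results identically
  perm <- c(3, 1, 2, 14:4)
  mcp <- mc_area_stack(ms$masks[perm], n = 20000, seed = 5)
  for (i in seq_along(perm)) {
    expect_identical(mcp$results[[i]], mc$results[[perm[i]]])
  }

  # flagged slices are skipped and reported
  flat <- ms
  flat$masks[[2]]$flag <- "no_femur"
  mcf <- mc_area_stack(flat$masks, n = 1000, seed = 5)
  expect_null(mcf$results[[2]])
  expect_identical(mcf$skipped, 2L)

  expect_length(mc_area_stack(list(), n = 100, seed = 1)$results, 0L)
})
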