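# Shared fixtures, built in code at test time.

# Independent brute-force pixel counter: explicit double loop over integer
# pixel centres, deliberately naive so it stays independent of the
# vectorised rasterizer it checks.
brute_ellipse_count <- function(a, b, cx, cy, A, B) {
  count <- 0L
  for (x in 0:(a - 1L)) {
    for (y in 0:(b - 1L)) {
      if (((x - cx) / A)^2 + ((y - cy) / B)^2 <= 1) count <- count + 1L
    }
  }
  count
}

# hand-built region_masks: cortical annulus (r_in, r_out) with medullary
# disk of radius r_in, centred
disk_masks <- function(a = 240L, b = 240L, r_in = 50, r_out = 60,
                       slice_index = 1L) {
  cx <- (a - 1) / 2
  cy <- (b - 1) / 2
  outer <- rasterize_ellipse(a, b, cx, cy, r_out, r_out)
  inner <- rasterize_ellipse(a, b, cx, cy, r_in, r_in)
  structure(list(overall = outer, cortical = outer & !inner,
                 medullary = inner, slice_index = slice_index,
                 flag = NA_character_),
            class = "region_masks")
}

# small fast phantom for stack-level unit tests (1 mm pixels, 14 slices)
small_spec <- function(noise_sd = 0, seed = 1L, ...) {
  n <- 14L
  inner <- 10 + 14 * abs(seq_len(n) - 10L) / 9   # V-profile, min 10 mm at slice 10
  phantom_spec(image_width_px = 120L, image_height_px = 120L,
               pixel_spacing = 1, slice_interval = 5, n_slices = n,
               inner_radius_profile = inner,
               outer_radius_profile = inner + 8,
               isthmus_slice_index = 10L, trochanter_slice_index = 5L,
               trochanter_bump_amplitude = 10,
               noise_sd = noise_sd, seed = seed, ...)
}

# default 60-slice phantom analysed once and cached for the whole test run
default_phantom_analysis <- local({
  cache <- NULL
  function(noise_sd = 0) {
    key <- as.character(noise_sd)
    if (is.null(cache[[key]])) {
      gen <- generate_phantom(phantom_spec(noise_sd = noise_sd))
      masks <- extract_masks_stack(gen$stack)
      cache[[key]] <<- list(gen = gen, masks = masks)
    }
    cache[[key]]
  }
})
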