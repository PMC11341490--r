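#' Locate the isthmus section
#'
#' The isthmus is the narrowest point of the medullary canal; its slice is
#' the global minimum of the per-slice medullary area `s_m`. Ties resolve
#' to the most proximal (smallest) index.
#'
#' @param s_m numeric vector of per-slice medullary areas over accepted
#'   slices; `NA` entries (flagged slices) are ignored.
#' @param slice_indices optional integer vector mapping positions of `s_m`
#'   to slice indices; defaults to `seq_along(s_m)`.
#' @return The isthmus slice index `C_m1`.
#' @export
find_isthmus <- function(s_m, slice_indices = seq_along(s_m)) {
  ok <- !is.na(s_m)
  if (!any(ok)) stop("no accepted slices: isthmus undefined")
  slice_indices[ok][which.min(s_m[ok])]
}

#' Locate the lesser-trochanter section
#'
#' Proxy for the most prominent proximal cross section: the slice whose
#' overall-region medial-lateral (x-axis) extent is maximal within the
#' proximal search window. Ties resolve to the first (most proximal) slice
#' of the window. A manual override takes precedence when provided, since
#' "most prominent point" is ultimately an anatomical judgement.
#'
#' @param masks_stack a `region_masks_stack` (see [extract_masks_stack()])
#'   or list of `region_masks`.
#' @param window optional integer vector `c(start, end)` of slice indices
#'   to search; defaults to all accepted slices.
#' @param override optional slice index returned verbatim.
#' @return The trochanter slice index `C_m0`.
#' @export
find_trochanter_section <- function(masks_stack, window = NULL,
                                    override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  masks <- if (inherits(masks_stack, "region_masks_stack")) {
    masks_stack$masks
  } else masks_stack
  idx <- vapply(masks, function(m) m$slice_index, integer(1))
  acc <- vapply(masks, function(m) is.na(m$flag), logical(1))
  keep <- acc
  if (!is.null(window)) keep <- keep & idx >= window[1] & idx <= window[2]
  if (!any(keep)) stop("empty trochanter search window")
  ext <- vapply(masks[keep], function(m) mask_extent_px(m$overall),
                numeric(1))
  idx[keep][which.max(ext)]
}

# medial-lateral (column) extent of a mask in pixels
mask_extent_px <- function(mask) {
  cols <- which(colSums(mask) > 0)
  if (length(cols) == 0L) return(0)
  max(cols) - min(cols) + 1
}

#' Offset a reference section by a physical distance
#'
#' Converts a millimetre offset to a slice offset (`round(offset_mm /
#' slice_interval)`), proximal meaning a smaller index.
#'
#' @param c_m0 reference slice index.
#' @param offset_mm distance in mm (e.g. 20).
#' @param slice_interval mm between slices.
#' @param direction `"proximal"` (towards slice 1) or `"distal"`.
#' @param n_slices optional stack length for range checking.
#' @return Offset slice index.
#' @export
offset_section <- function(c_m0, offset_mm, slice_interval,
                           direction = c("proximal", "distal"),
                           n_slices = NULL) {
  direction <- match.arg(direction)
  k <- round(offset_mm / slice_interval)
  idx <- if (direction == "proximal") c_m0 - k else c_m0 + k
  if (idx < 1 || (!is.null(n_slices) && idx > n_slices)) {
    stop(sprintf(
      "offset section %d outside stack range [1, %s] (c_m0 = %d, %g mm %s)",
      idx, if (is.null(n_slices)) "?" else n_slices, c_m0, offset_mm,
      direction))
  }
  as.integer(idx)
}

#' Bundle the four key cross sections
#'
#' @param c_m0 lesser-trochanter midpoint slice.
#' @param c_m1 isthmus slice.
#' @param slice_interval mm between slices.
#' @param n_slices stack length, for range checking.
#' @param offset_mm reference offset above/below the trochanter (default
#'   20 mm).
#' @return An object of class `key_sections` with `c_m0`, `c_m0_plus20`
#'   (proximal), `c_m0_minus20` (distal), `c_m1`.
#' @export
key_sections <- function(c_m0, c_m1, slice_interval, n_slices = NULL,
                         offset_mm = 20) {
  ks <- structure(list(
    c_m0 = as.integer(c_m0),
    c_m0_plus20 = offset_section(c_m0, offset_mm, slice_interval,
                                 "proximal", n_slices),
    c_m0_minus20 = offset_section(c_m0, offset_mm, slice_interval,
                                  "distal", n_slices),
    c_m1 = as.integer(c_m1)
  ), class = "key_sections")
  if (!(ks$c_m0_plus20 < ks$c_m0 && ks$c_m0 < ks$c_m0_minus20 &&
          ks$c_m0_minus20 < ks$c_m1)) {
    warning("key sections are not in the expected proximal-first order ",
            "(c_m0+20 < c_m0 < c_m0-20 < c_m1)")
  }
  ks
}

#' Inner/outer diameters and cortical thickness of one slice
#'
#' Diameters are medial-lateral (x-axis) extents measured through the
#' mask's centroid row and converted to mm; cortical thickness is
#' `(outer - inner) / 2`.
#'
#' @param masks a `region_masks` object.
#' @param pixel_spacing mm per pixel.
#' @return List with `inner_mm`, `outer_mm`, `thickness_mm`; `inner_mm` is
#'   `NA` (and the slice unusable for canal diameters) when the medullary
#'   mask is empty.
#' @export
section_diameters <- function(masks, pixel_spacing) {
  stopifnot(inherits(masks, "region_masks"))
  outer_mm <- row_extent_mm(masks$overall, pixel_spacing)
  if (!any(masks$medullary)) {
    return(list(inner_mm = NA_real_, outer_mm = outer_mm,
                thickness_mm = NA_real_))
  }
  inner_mm <- row_extent_mm(masks$medullary, pixel_spacing)
  list(inner_mm = inner_mm, outer_mm = outer_mm,
       thickness_mm = (outer_mm - inner_mm) / 2)
}

# x-extent (in mm) of a mask along its centroid row
row_extent_mm <- function(mask, pixel_spacing) {
  if (!any(mask)) return(NA_real_)
  rows <- row(mask)[mask]
  r0 <- round(mean(rows))
  cols <- which(mask[r0, ])
  if (length(cols) == 0L) {  # centroid row can miss a thin annulus
    cols <- which(colSums(mask) > 0)
  }
  (max(cols) - min(cols) + 1) * pixel_spacing
}

#' Isthmus height and femur length
#'
#' `IH` is the vertical distance between the trochanter and isthmus planes;
#' `LH` is the full stack extent unless supplied externally (a cropped
#' stack does not span the whole femur).
#'
#' @param key a [key_sections()] object.
#' @param n_slices number of slices in the stack.
#' @param slice_interval mm between slices.
#' @param lh optional externally measured femur length in mm.
#' @return List with `ih_mm` and `lh_mm`.
#' @export
compute_lengths <- function(key, n_slices, slice_interval, lh = NULL) {
  if (is.null(key$c_m0) || is.null(key$c_m1) ||
        is.na(key$c_m0) || is.na(key$c_m1)) {
    stop("key sections missing: cannot compute lengths")
  }
  ih <- abs(key$c_m1 - key$c_m0) * slice_interval
  lh <- if (is.null(lh)) (n_slices - 1) * slice_interval else lh
  list(ih_mm = ih, lh_mm = lh)
}

#' Canal ratio parameters from diameters, lengths, and key-section areas
#'
#' Computes the classical flare indices and the area growth rates:
#' `CFI = T+20 / T_mi`, `MCFI = T+20 / T-20`, `DCFI = T-20 / T_mi`,
#' `CI = (T_mo - T_mi) / T_mo`, `IH/LH`,
#' `r1 = (s_m0+20 - s_m0-20) / s_m0-20`, and
#' `r2 = (s_m0+20 - s_m1) / s_m1`. Full-precision values are returned with
#' conventionally rounded companions (diameter ratios 2 dp, `IH/LH` and
#' `r1` 3 dp, `r2` 2 dp). Ratios with an unusable denominator come back
#' `NA`.
#'
#' @param t_plus20,t_minus20,t_mi,t_mo diameters in mm (see
#'   [section_diameters()]).
#' @param ih,lh lengths in mm.
#' @param s_m0_plus20,s_m0_minus20,s_m1 medullary areas (pixels) at the
#'   corresponding key sections.
#' @return List of class `canal_ratios`: elements `cfi`, `mcfi`, `dcfi`,
#'   `ci`, `ih_lh`, `r1`, `r2`, a `rounded` sub-list, and `canal_class`.
#' @export
canal_ratios <- function(t_plus20 = NA, t_minus20 = NA, t_mi = NA,
                         t_mo = NA, ih = NA, lh = NA,
                         s_m0_plus20 = NA, s_m0_minus20 = NA, s_m1 = NA) {
  safe_div <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  cfi <- safe_div(t_plus20, t_mi)
  mcfi <- safe_div(t_plus20, t_minus20)
  dcfi <- safe_div(t_minus20, t_mi)
  ci <- safe_div(t_mo - t_mi, t_mo)
  ih_lh <- safe_div(ih, lh)
  r1 <- safe_div(s_m0_plus20 - s_m0_minus20, s_m0_minus20)
  r2 <- safe_div(s_m0_plus20 - s_m1, s_m1)
  structure(list(
    cfi = cfi, mcfi = mcfi, dcfi = dcfi, ci = ci, ih_lh = ih_lh,
    r1 = r1, r2 = r2,
    rounded = list(cfi = round(cfi, 2), mcfi = round(mcfi, 2),
                   dcfi = round(dcfi, 2), ci = round(ci, 2),
                   ih_lh = round(ih_lh, 3), r1 = round(r1, 3),
                   r2 = round(r2, 2)),
    canal_class = if (is.na(cfi) || cfi <= 0) NA_character_
                  else classify_canal(cfi)
  ), class = "canal_ratios")
}

#' Classify the proximal canal shape from the canal flare index
#'
#' Chimney for `CFI < 3.0`, normal for `3.0 <= CFI < 4.7`, champagne for
#' `4.7 <= CFI < 6.5`; values of 6.5 and above fall outside the defined
#' bands and are reported `"unclassified"`.
#'
#' @param cfi canal flare index (> 0).
#' @return One of `"chimney"`, `"normal"`, `"champagne"`,
#'   `"unclassified"`.
#' @export
classify_canal <- function(cfi) {
  if (is.na(cfi) || cfi <= 0) stop("cfi must be positive")
  if (cfi < 3.0) "chimney"
  else if (cfi < 4.7) "normal"
  else if (cfi < 6.5) "champagne"
  else "unclassified"
}

#' Full morphometry report for an analysed stack
#'
#' Combines the extracted masks and per-slice area estimates into the
#' complete parameter set: key sections, diameters, lengths, per-slice
#' areas and ratios (`s_c`, `s_m`, `s`, `q1`, `q2`, cortical thickness),
#' flare indices, growth rates, and the canal classification.
#'
#' @param masks_stack a `region_masks_stack` from [extract_masks_stack()].
#' @param mc a `mc_area_stack` from [mc_area_stack()] computed on the same
#'   masks.
#' @param use_traversal use exact traversal counts instead of the Monte
#'   Carlo estimates for the per-slice areas.
#' @param trochanter_window,trochanter_override passed to
#'   [find_trochanter_section()].
#' @param lh optional externally measured femur length in mm.
#' @param offset_mm reference offset for the trochanter sections (default
#'   20 mm).
#' @return List of class `morphometry_report`: `key` (key sections),
#'   `diameters` (`t_plus20`, `t_minus20`, `t_0`, `t_mi`, `t_mo` in mm),
#'   `lengths`, `ratios` (a [canal_ratios()]), `per_slice` (data frame of
#'   `slice_index`, `s_c`, `s_m`, `s`, `q1`, `q2`, `t_c_mm`), and
#'   `canal_class`.
#' @export
compute_morphometry <- function(masks_stack, mc, use_traversal = FALSE,
                                trochanter_window = NULL,
                                trochanter_override = NULL,
                                lh = NULL, offset_mm = 20) {
  stopifnot(inherits(masks_stack, "region_masks_stack"),
            inherits(mc, "mc_area_stack"))
  masks <- masks_stack$masks
  px <- masks_stack$pixel_spacing
  dz <- masks_stack$slice_interval
  idx <- masks_stack$slice_indices
  n_slices <- max(idx)

  s_c <- s_m <- rep(NA_real_, length(masks))
  for (i in seq_along(masks)) {
    if (is.null(mc$results[[i]])) next
    if (use_traversal) {
      s_c[i] <- mc$traversal[[i]]$cortical_count
      s_m[i] <- mc$traversal[[i]]$medullary_count
    } else {
      s_c[i] <- mc$results[[i]]$s_c
      s_m[i] <- mc$results[[i]]$s_m
    }
  }

  t_c <- vapply(masks, function(m) {
    if (!is.na(m$flag)) return(NA_real_)
    section_diameters(m, px)$thickness_mm
  }, numeric(1))

  per_slice <- data.frame(
    slice_index = idx, s_c = s_c, s_m = s_m, s = s_c + s_m,
    q1 = s_m / (s_c + s_m), q2 = s_m / s_c, t_c_mm = t_c
  )

  c_m1 <- find_isthmus(s_m, idx)
  c_m0 <- find_trochanter_section(masks_stack, window = trochanter_window,
                                  override = trochanter_override)
  key <- key_sections(c_m0, c_m1, dz, n_slices = n_slices,
                      offset_mm = offset_mm)

  at <- function(slice) {
    pos <- match(slice, idx)
    if (is.na(pos)) stop("key section ", slice, " not in analysed range")
    pos
  }
  d0 <- section_diameters(masks[[at(key$c_m0)]], px)
  dp <- section_diameters(masks[[at(key$c_m0_plus20)]], px)
  dm <- section_diameters(masks[[at(key$c_m0_minus20)]], px)
  di <- section_diameters(masks[[at(key$c_m1)]], px)
  diameters <- list(t_plus20 = dp$inner_mm, t_minus20 = dm$inner_mm,
                    t_0 = d0$inner_mm, t_mi = di$inner_mm,
                    t_mo = di$outer_mm)

  lengths <- compute_lengths(key, n_slices, dz, lh = lh)
  ratios <- canal_ratios(
    t_plus20 = diameters$t_plus20, t_minus20 = diameters$t_minus20,
    t_mi = diameters$t_mi, t_mo = diameters$t_mo,
    ih = lengths$ih_mm, lh = lengths$lh_mm,
    s_m0_plus20 = s_m[at(key$c_m0_plus20)],
    s_m0_minus20 = s_m[at(key$c_m0_minus20)],
    s_m1 = s_m[at(key$c_m1)]
  )

  structure(list(key = key, diameters = diameters, lengths = lengths,
                 ratios = ratios, per_slice = per_slice,
                 canal_class = ratios$canal_class,
                 pixel_spacing = px, slice_interval = dz),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  r <- x$ratios$rounded
  cat("Femoral canal morphometry\n")
  cat(sprintf("  key sections: C_m0+20=%d  C_m0=%d  C_m0-20=%d  C_m1=%d\n",
              x$key$c_m0_plus20, x$key$c_m0, x$key$c_m0_minus20,
              x$key$c_m1))
  cat(sprintf("  T+20=%.2f  T-20=%.2f  T0=%.2f  T_mi=%.2f  T_mo=%.2f mm\n",
              x$diameters$t_plus20, x$diameters$t_minus20,
              x$diameters$t_0, x$diameters$t_mi, x$diameters$t_mo))
  cat(sprintf("  IH=%.2f mm  LH=%.2f mm  IH/LH=%.3f\n",
              x$lengths$ih_mm, x$lengths$lh_mm, r$ih_lh))
  cat(sprintf("  CFI=%.2f  MCFI=%.2f  DCFI=%.2f  CI=%.2f  (%s canal)\n",
              r$cfi, r$mcfi, r$dcfi, r$ci, x$canal_class))
  cat(sprintf("  r1=%.3f  r2=%.2f\n", r$r1, r$r2))
  invisible(x)
}
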