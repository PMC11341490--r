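#' Assemble a Monte Carlo area result from raw counts
#'
#' Implements the estimator identities exactly: with `n` uniform points in
#' the `a x b` rectangle, `n1` of which fall in the overall femoral region
#' and `n2` of which fall outside the cortical region,
#' `alpha_c = (n - n2)/n`, `alpha_m = (n1 - (n - n2))/n`, and the area
#' estimates are `s_c = alpha_c * a * b`, `s_m = alpha_m * a * b` (pixels).
#'
#' @param n total number of random points.
#' @param n1 points inside the overall femoral region.
#' @param n2 points outside the cortical region (anywhere in the
#'   rectangle).
#' @param a,b rectangle width and height in pixels.
#' @param seed seed used to draw the points (bookkeeping).
#' @return An object of class `mc_area`.
#' @export
mc_result <- function(n, n1, n2, a, b, seed = NA_integer_) {
  if (!(n >= 1)) stop("n must be >= 1")
  if (n - n2 < 0 || n1 > n || n - n2 > n1) {
    stop("inconsistent counts: need 0 <= n - n2 <= n1 <= n")
  }
  alpha_c <- (n - n2) / n
  alpha_m <- (n1 - (n - n2)) / n
  structure(list(n = n, n1 = n1, n2 = n2,
                 alpha_c = alpha_c, alpha_m = alpha_m,
                 s_c = alpha_c * a * b, s_m = alpha_m * a * b,
                 a = a, b = b, seed = seed),
            class = "mc_area")
}

#' Monte Carlo area estimate for one slice
#'
#' Draws `n` points with integer coordinates uniform (with replacement) on
#' `[0, a-1] x [0, b-1]` and classifies each by mask lookup: `n1` counts
#' hits in the overall femoral region and `n2` counts points landing
#' outside the cortical mask. Reproducible for a given seed.
#'
#' @param masks a `region_masks` object (see [extract_masks()]).
#' @param n number of random points (>= 1).
#' @param seed integer seed.
#' @return An `mc_area` object, see [mc_result()].
#' @export
mc_area <- function(masks, n, seed = 1L) {
  stopifnot(inherits(masks, "region_masks"))
  n <- as.integer(n)
  b <- nrow(masks$overall); a <- ncol(masks$overall)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  x <- sample.int(a, n, replace = TRUE)        # column index, 1-based
  y <- sample.int(b, n, replace = TRUE)        # row index, 1-based
  lin <- (x - 1L) * b + y
  n1 <- sum(masks$overall[lin])
  n2 <- n - sum(masks$cortical[lin])
  mc_result(n, n1, n2, a, b, seed = seed)
}

#' Exact region proportions by exhaustive traversal
#'
#' Visits every pixel of each mask exactly once and reports the exact
#' counts and proportions; this is the deterministic oracle the Monte
#' Carlo estimate is validated against.
#'
#' @param masks a `region_masks` object.
#' @return An object of class `traversal_area` with `cortical_count`,
#'   `medullary_count`, `alpha_ct`, `alpha_mt`, and the rectangle
#'   dimensions.
#' @export
traversal_area <- function(masks) {
  stopifnot(inherits(masks, "region_masks"))
  b <- nrow(masks$overall); a <- ncol(masks$overall)
  cc <- sum(masks$cortical)
  mm <- sum(masks$medullary)
  structure(list(cortical_count = cc, medullary_count = mm,
                 alpha_ct = cc / (a * b), alpha_mt = mm / (a * b),
                 a = a, b = b),
            class = "traversal_area")
}

#' Monte Carlo areas for a whole stack of masks
#'
#' One [mc_area()] per accepted slice; flagged slices are skipped and
#' reported. Per-slice seeds are derived deterministically from the master
#' seed and the slice index, so results are independent of processing
#' order.
#'
#' @param masks_stack a `region_masks_stack` from [extract_masks_stack()],
#'   or a plain list of `region_masks`.
#' @param n random points per slice.
#' @param seed master integer seed.
#' @return List of class `mc_area_stack`: `results` (one `mc_area` or
#'   `NULL` per slice), `traversal` (matching `traversal_area` objects),
#'   `skipped` (slice indices of flagged slices).
#' @export
mc_area_stack <- function(masks_stack, n, seed = 1L) {
  masks <- if (inherits(masks_stack, "region_masks_stack")) {
    masks_stack$masks
  } else masks_stack
  results <- vector("list", length(masks))
  traversal <- vector("list", length(masks))
  slice_idx <- integer(length(masks))
  skipped <- integer(0)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    sl <- if (is.na(m$slice_index)) i else m$slice_index
    slice_idx[i] <- sl
    if (!is.na(m$flag)) {
      skipped <- c(skipped, sl)
      next
    }
    results[[i]] <- mc_area(m, n, seed = slice_seed(seed, sl))
    traversal[[i]] <- traversal_area(m)
  }
  structure(list(results = results, traversal = traversal,
                 slice_indices = slice_idx,
                 skipped = skipped, n = n, seed = seed),
            class = "mc_area_stack")
}

# Deterministic per-slice seed stream, kept inside 32-bit integer range.
slice_seed <- function(master, slice_index) {
  as.integer((as.double(master) * 69621 + as.double(slice_index) * 1013)
             %% 2147483647)
}

#' Per-slice area table from a stack of Monte Carlo results
#'
#' @param mc a `mc_area_stack`.
#' @return `data.frame` with columns `slice_index`, `n`, `n1`, `n2`,
#'   `alpha_c`, `alpha_m`, `s_c`, `s_m`, `alpha_ct`, `alpha_mt`.
#' @export
mc_area_table <- function(mc) {
  stopifnot(inherits(mc, "mc_area_stack"))
  keep <- !vapply(mc$results, is.null, logical(1))
  rows <- lapply(which(keep), function(i) {
    r <- mc$results[[i]]
    t <- mc$traversal[[i]]
    data.frame(slice_index = mc$slice_indices[i], n = r$n, n1 = r$n1, n2 = r$n2,
               alpha_c = r$alpha_c, alpha_m = r$alpha_m,
               s_c = r$s_c, s_m = r$s_m,
               alpha_ct = t$alpha_ct, alpha_mt = t$alpha_mt)
  })
  do.call(rbind, rows)
}
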