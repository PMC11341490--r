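#' Write a grayscale image as PGM
#'
#' Portable graymap is the plain-text image format used throughout this
#' package (P2 ASCII by default); it keeps fixtures and outputs fully
#' text-based and readable by any imaging toolkit.
#'
#' @param img numeric matrix of gray levels in \[0, maxval\].
#' @param path output file path.
#' @param maxval maximum gray value (default 255).
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  img <- round(img)
  if (any(img < 0) || any(img > maxval)) {
    stop("pixel values outside [0, ", maxval, "]")
  }
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
             con)
  # one image row per line
  writeLines(apply(img, 1L, paste, collapse = " "), con)
}

#' Read a PGM image
#'
#' Supports plain (P2) and binary 8-bit (P5) portable graymaps.
#'
#' @param path file path.
#' @return Numeric matrix of gray levels.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)

  header <- integer(0)
  buf <- character(0)
  # token scanner that skips comments
  next_token <- function() {
    repeat {
      if (length(buf) == 0L) {
        line <- readLines(con, n = 1L)
        if (length(line) == 0L) stop("truncated PGM header")
        line <- sub("#.*$", "", line)
        buf <<- strsplit(trimws(line), "[[:space:]]+")[[1]]
        buf <<- buf[nzchar(buf)]
      } else {
        tok <- buf[1L]
        buf <<- buf[-1L]
        return(tok)
      }
    }
  }
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())

  if (magic == "P2") {
    vals <- numeric(0)
    while (length(vals) < w * h) {
      line <- readLines(con, n = 1L)
      if (length(line) == 0L) stop("truncated PGM data")
      line <- sub("#.*$", "", line)
      v <- as.numeric(strsplit(trimws(line), "[[:space:]]+")[[1]])
      vals <- c(vals, v[!is.na(v)])
    }
    matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
  } else {
    if (maxval > 255L) stop("16-bit P5 not supported")
    raw <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
    matrix(raw, nrow = h, ncol = w, byrow = TRUE)
  }
}

#' Write a slice stack to a directory
#'
#' One zero-padded PGM per slice plus a `manifest.json` holding the
#' spatial metadata (and any extra fields, e.g. phantom ground-truth key
#' sections).
#'
#' @param stack a [slice_stack()].
#' @param dir output directory (created if needed).
#' @param extra named list merged into the manifest.
#' @return The directory, invisibly.
#' @export
write_stack <- function(stack, dir, extra = list()) {
  stopifnot(inherits(stack, "slice_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nd <- max(3L, nchar(length(stack$images)))
  for (i in seq_along(stack$images)) {
    write_pgm(stack$images[[i]],
              file.path(dir, sprintf(paste0("slice_%0", nd, "d.pgm"), i)))
  }
  manifest <- c(list(
    n_slices = length(stack$images),
    image_width_px = ncol(stack$images[[1]]),
    image_height_px = nrow(stack$images[[1]]),
    pixel_spacing = stack$pixel_spacing,
    slice_interval = stack$slice_interval,
    provenance = stack$provenance
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a slice stack from a directory
#'
#' Expects the layout written by [write_stack()]: ordered PGM files and a
#' `manifest.json` sidecar with `pixel_spacing` and `slice_interval`.
#'
#' @param dir directory path.
#' @return A [slice_stack()].
#' @export
read_stack <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) == 0L) stop("no slices (PGM files) in ", dir)
  images <- lapply(files, read_pgm)
  slice_stack(images, pixel_spacing = mf$pixel_spacing,
              slice_interval = mf$slice_interval,
              provenance = paste0("dir:", dir))
}

#' Write extracted masks and per-slice flags
#'
#' Each accepted slice yields `overall`, `cortical`, and `medullary` mask
#' images (PGM, 0/255); a `flags.csv` records the per-slice acceptance
#' status.
#'
#' @param masks_stack a `region_masks_stack`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_masks <- function(masks_stack, dir) {
  stopifnot(inherits(masks_stack, "region_masks_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nd <- max(3L, nchar(max(masks_stack$slice_indices)))
  for (m in masks_stack$masks) {
    if (!is.na(m$flag)) next
    for (nm in c("overall", "cortical", "medullary")) {
      write_pgm(m[[nm]] * 255L,
                file.path(dir, sprintf(paste0("%s_%0", nd, "d.pgm"),
                                       nm, m$slice_index)))
    }
  }
  utils::write.csv(
    data.frame(slice_index = masks_stack$slice_indices,
               flag = ifelse(is.na(masks_stack$flags), "accepted",
                             masks_stack$flags)),
    file.path(dir, "flags.csv"), row.names = FALSE)
  invisible(dir)
}
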