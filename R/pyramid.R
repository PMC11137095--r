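# Multi-resolution slide pyramids and level-1 -> level-L coordinate mapping.
#
# A slide pyramid holds RGB rasters Q^l for levels l = 1 (lowest
# magnification, smallest raster) ... L (highest magnification, full
# resolution), with an integer downsample factor between consecutive levels.
# Coordinates are 0-based; patch regions are half-open [x, x+size) x
# [y, y+size). Rasters are numeric H x W x 3 arrays in [0, 255]; x indexes
# columns, y indexes rows.

#' Construct a slide pyramid
#'
#' @param levels list of H x W x 3 RGB arrays ordered from lowest to highest
#'   magnification.
#' @param patient_id slide/patient identifier.
#' @param per_level_downsample integer scale factor between consecutive
#'   levels (default 2).
#' @return Object of class `slide_pyramid` with fields `levels`,
#'   `patient_id`, `per_level_downsample`, `L`.
#' @export
slide_pyramid <- function(levels, patient_id = NA_character_,
                          per_level_downsample = 2L) {
  stopifnot(is.list(levels), length(levels) >= 1L)
  ds <- as.integer(per_level_downsample)
  stopifnot(ds >= 1L)
  for (l in seq_along(levels)) {
    d <- dim(levels[[l]])
    if (length(d) != 3L || d[3] != 3L || any(d[1:2] < 1L)) {
      stop("level ", l, " is not a non-empty H x W x 3 raster")
    }
  }
  # consecutive levels must differ by the stated factor, within 1 px rounding
  for (l in seq_len(length(levels) - 1L)) {
    lo <- dim(levels[[l]])[1:2]
    hi <- dim(levels[[l + 1L]])[1:2]
    if (any(abs(lo - hi / ds) > 1)) {
      stop("levels ", l, " and ", l + 1L,
           " do not differ by the per-level downsample factor")
    }
  }
  structure(list(levels = levels, patient_id = patient_id,
                 per_level_downsample = ds, L = length(levels)),
            class = "slide_pyramid")
}

#' @export
print.slide_pyramid <- function(x, ...) {
  dims <- vapply(x$levels, function(q) paste(dim(q)[1:2], collapse = "x"),
                 character(1))
  cat("slide_pyramid", if (!is.na(x$patient_id)) paste0("[", x$patient_id, "]"),
      "L =", x$L, "levels (HxW):", paste(dims, collapse = ", "), "\n")
  invisible(x)
}

#' Cumulative scale factor from level 1 to level L
#'
#' With `L` levels and a constant per-level factor `f`, a level-1 pixel spans
#' `f^(L-1)` level-L pixels.
#' @param pyramid a [slide_pyramid()].
#' @return integer scale factor.
#' @export
pyramid_scale <- function(pyramid) {
  pyramid$per_level_downsample^(pyramid$L - 1L)
}

#' Read a slide into a pyramid
#'
#' Multi-page TIFFs are taken as pre-built pyramids (pages sorted by area).
#' Flat PNG or single-page TIFF images are auto-pyramidized by repeated
#' block-mean downsampling until the next level would fall below
#' `min_edge` pixels on its shorter side.
#'
#' @param path image file (`.tif`/`.tiff` or `.png`).
#' @param per_level_downsample integer factor between levels.
#' @param min_edge minimum shorter-edge length of the lowest level.
#' @param patient_id identifier attached to the pyramid.
#' @return A [slide_pyramid()]; level 1 is the lowest magnification.
#' @export
read_pyramid <- function(path, per_level_downsample = 2L, min_edge = 128L,
                         patient_id = NA_character_) {
  if (!file.exists(path)) stop("cannot read slide: ", path)
  ext <- tolower(tools::file_ext(path))
  to255 <- function(img) {
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    img * 255
  }
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, to255)
    areas <- vapply(pages, function(p) prod(dim(p)[1:2]), numeric(1))
    if (any(areas == 0)) stop("zero-area image: ", path)
    pages <- pages[order(areas)]
    if (length(pages) > 1L) {
      return(slide_pyramid(pages, patient_id, per_level_downsample))
    }
    full <- pages[[1L]]
  } else if (ext == "png") {
    full <- to255(png::readPNG(path))
  } else {
    stop("unsupported slide format: ", ext)
  }
  if (prod(dim(full)[1:2]) == 0) stop("zero-area image: ", path)
  build_pyramid(full, per_level_downsample, min_edge, patient_id)
}

#' Build a pyramid from a full-resolution raster
#'
#' @param full H x W x 3 RGB array at the highest magnification.
#' @inheritParams read_pyramid
#' @return A [slide_pyramid()].
#' @export
build_pyramid <- function(full, per_level_downsample = 2L, min_edge = 128L,
                          patient_id = NA_character_) {
  ds <- as.integer(per_level_downsample)
  levels <- list(full)
  while (min(dim(levels[[1L]])[1:2]) %/% ds >= min_edge) {
    levels <- c(list(block_downsample(levels[[1L]], ds)), levels)
  }
  slide_pyramid(levels, patient_id, ds)
}

#' Write a pyramid to a multi-page TIFF
#'
#' Pages are written highest magnification first, quantized to 8-bit.
#' @param pyramid a [slide_pyramid()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_pyramid <- function(pyramid, path) {
  pages <- rev(lapply(pyramid$levels, function(q) {
    round(clamp(q, 0, 255)) / 255
  }))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Reference to a square patch at a pyramid level
#'
#' @param patch_id integer id.
#' @param level pyramid level the coordinates refer to.
#' @param x,y 0-based top-left corner (x = column, y = row).
#' @param size edge length in pixels.
#' @return One-row data frame with class `patch_ref` columns.
#' @export
patch_ref <- function(patch_id, level, x, y, size) {
  data.frame(patch_id = as.integer(patch_id), level = as.integer(level),
             x = as.integer(x), y = as.integer(y), size = as.integer(size))
}

#' Map a level-1 coordinate to a level-L patch region
#'
#' Forward mapping from the low-magnification foreground plane to the raw
#' data at the highest level: a level-1 origin `(x, y)` maps to the level-L
#' region `<x*s, y*s, size, size>` with `s` the cumulative scale factor.
#' Regions extending past the level-L bounds are rejected (never clipped):
#' downstream score denominators assume complete `size^2` patches.
#'
#' @param coord_low numeric length-2 `(x, y)`, 0-based, at level 1.
#' @param pyramid a [slide_pyramid()].
#' @param size patch edge at level L (default 512).
#' @param patch_id id to stamp on the resulting reference.
#' @return A [patch_ref()] at level L, or `NULL` (with a message) if the
#'   mapped region does not fit.
#' @export
map_region <- function(coord_low, pyramid, size = 512L, patch_id = 1L) {
  x <- coord_low[[1]]; y <- coord_low[[2]]
  d1 <- dim(pyramid$levels[[1L]])
  if (x < 0 || y < 0 || x >= d1[2] || y >= d1[1]) {
    stop("level-1 coordinate out of bounds")
  }
  s <- pyramid_scale(pyramid)
  X <- x * s; Y <- y * s
  dL <- dim(pyramid$levels[[pyramid$L]])
  if (X + size > dL[2] || Y + size > dL[1]) {
    message("map_region: patch at (", x, ",", y, ") rejected (exceeds level-",
            pyramid$L, " bounds)")
    return(NULL)
  }
  patch_ref(patch_id, pyramid$L, X, Y, size)
}

#' Extract the exact pixel block a patch reference describes
#'
#' No resampling: the returned raster is the raw `size x size` block.
#' @param pyramid a [slide_pyramid()].
#' @param ref a [patch_ref()].
#' @return `size x size x 3` RGB array.
#' @export
extract_patch <- function(pyramid, ref) {
  q <- pyramid$levels[[ref$level]]
  d <- dim(q)
  if (ref$x < 0 || ref$y < 0 || ref$x + ref$size > d[2] || ref$y + ref$size > d[1]) {
    stop("patch reference out of bounds")
  }
  q[ref$y + seq_len(ref$size), ref$x + seq_len(ref$size), , drop = FALSE]
}

#' Read / write patch-reference tables as CSV
#'
#' Columns: `patient_id, patch_id, level, x, y, size`.
#' @param refs data frame of patch references.
#' @param patient_id identifier stamped on each row.
#' @param path CSV path.
#' @return `write_patch_refs` returns `path` invisibly; `read_patch_refs`
#'   the data frame.
#' @export
write_patch_refs <- function(refs, path, patient_id = NA_character_) {
  out <- cbind(patient_id = patient_id, refs)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_refs
#' @export
read_patch_refs <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
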