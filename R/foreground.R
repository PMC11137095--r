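# Foreground patch selection (FPS): locate tissue with substantial cytoplasm
# on the level-1 thumbnail via the eosin OD channel, exclude pen-marker ink
# and noise, and emit non-overlapping high-resolution patch references.

#' Foreground-selection configuration
#'
#' Defaults: the low threshold is Otsu's threshold over the positive eosin
#' values, the high threshold the 99.5th percentile (cuts saturated ink and
#' specks); despeckle/fill by morphological opening then closing with a disk
#' of radius 2 px at level 1, then removal of connected components under
#' 64 px. Marker ink is flagged where HSV saturation exceeds `marker_sat` and
#' the hue falls outside the pink-purple H&E band, or where pixels are dark
#' and achromatic (black ink); the flag is dilated by `marker_dilate` px.
#' A candidate patch is accepted when at least `coverage` of its level-1
#' footprint lies in the foreground mask.
#'
#' @param t_low,t_high eosin-OD thresholds; `NULL` = data-driven defaults.
#' @param morph_radius disk radius (px) for opening/closing.
#' @param min_component minimum connected-component area (px).
#' @param coverage fraction of the level-1 footprint that must be foreground.
#' @param marker_sat minimum HSV saturation for chromatic ink.
#' @param hue_band numeric length 2 `(lo, hi)`: hues in `[lo, 1] U [0, hi]`
#'   (wrap-around through red) are treated as H&E tissue colors.
#' @param dark_value,dark_sat thresholds for dark achromatic (black-ink)
#'   pixels.
#' @param marker_dilate dilation radius (px) applied to the marker mask.
#' @return Named list of class `fps_config`.
#' @export
fps_config <- function(t_low = NULL, t_high = NULL, morph_radius = 2L,
                       min_component = 64L, coverage = 0.5,
                       marker_sat = 0.4, hue_band = c(0.68, 0.06),
                       dark_value = 0.2, dark_sat = 0.35,
                       marker_dilate = 3L) {
  structure(list(t_low = t_low, t_high = t_high,
                 morph_radius = as.integer(morph_radius),
                 min_component = as.integer(min_component),
                 coverage = coverage, marker_sat = marker_sat,
                 hue_band = hue_band, dark_value = dark_value,
                 dark_sat = dark_sat, marker_dilate = as.integer(marker_dilate)),
            class = "fps_config")
}

# Otsu's threshold over a numeric vector (histogram with `levels` bins).
# Computed in-package because the FPS rule applies Otsu to the *positive*
# eosin values only, a masked subset no image-level helper accepts.
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L || diff(range(v)) == 0) return(ifelse(length(v), v[1], 0))
  breaks <- seq(min(v), max(v), length.out = levels + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Detect pen-marker ink on a level-1 thumbnail
#'
#' Pen inks (blue, green, black) are chromatic or achromatic outliers
#' relative to the pink-purple transmitted colors of H&E tissue. Flagged:
#' saturated pixels whose hue lies outside the configured H&E band, plus
#' dark low-saturation pixels; the union is dilated to cover stroke fringes.
#'
#' @param level1_rgb H x W x 3 RGB array in `[0, 255]`.
#' @param cfg an [fps_config()].
#' @return H x W logical matrix (TRUE = marker).
#' @export
detect_markers <- function(level1_rgb, cfg = fps_config()) {
  px <- t(flatten_px(level1_rgb))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  in_band <- h >= cfg$hue_band[1] | h <= cfg$hue_band[2]
  flag <- (s > cfg$marker_sat & !in_band) |
    (v < cfg$dark_value & s < cfg$dark_sat)
  m <- matrix(flag, nrow = dim(level1_rgb)[1])
  if (any(m) && cfg$marker_dilate > 0L) {
    m <- EBImage::dilate(EBImage::Image(m * 1), disk_brush(cfg$marker_dilate)) > 0
    m <- matrix(as.logical(m), nrow = nrow(m))
  }
  m
}

#' Compute the level-1 foreground mask from the eosin channel
#'
#' Dual thresholding on the eosin OD amounts (`t_low <= eosin <= t_high`),
#' marker exclusion, morphological opening then closing, and removal of
#' small connected components. Deterministic given the configuration.
#'
#' @param eosin H x W matrix of non-negative eosin amounts at level 1.
#' @param marker H x W logical marker mask (or `NULL`).
#' @param cfg an [fps_config()].
#' @return H x W logical mask with attribute `provenance` recording the
#'   thresholds and morphology actually used.
#' @export
foreground_mask <- function(eosin, marker = NULL, cfg = fps_config()) {
  if (is.null(marker)) marker <- matrix(FALSE, nrow(eosin), ncol(eosin))
  stopifnot(all(dim(eosin) == dim(marker)))
  if (!is.null(cfg$t_low) && !is.null(cfg$t_high) && cfg$t_low >= cfg$t_high) {
    stop("t_low must be below t_high")
  }
  if (!any(eosin > 0)) {
    out <- matrix(FALSE, nrow(eosin), ncol(eosin))
    attr(out, "provenance") <- list(t_low = NA_real_, t_high = NA_real_,
                                    morph_radius = cfg$morph_radius,
                                    min_component = cfg$min_component,
                                    marker_px = sum(marker))
    return(out)
  }
  # Otsu over the zero-clipped channel: the background mode at zero makes
  # the histogram bimodal, the cap comes from the stained pixels only
  t_low <- cfg$t_low %||% otsu_threshold(as.vector(eosin))
  t_high <- cfg$t_high %||% stats::quantile(eosin[eosin > 0], 0.995,
                                            names = FALSE)
  m <- eosin >= t_low & eosin <= t_high & !marker
  if (any(m) && cfg$morph_radius > 0L) {
    br <- disk_brush(cfg$morph_radius)
    img <- EBImage::Image(m * 1)
    img <- EBImage::closing(EBImage::opening(img, br), br)
    m <- matrix(as.logical(img), nrow = nrow(m))
  }
  if (any(m) && cfg$min_component > 0L) {
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= cfg$min_component)
    m <- matrix(as.integer(lab) %in% keep, nrow = nrow(m))
  }
  m <- m & !marker
  attr(m, "provenance") <- list(t_low = t_low, t_high = t_high,
                                morph_radius = cfg$morph_radius,
                                min_component = cfg$min_component,
                                marker_px = sum(marker))
  m
}

#' Select non-overlapping high-resolution foreground patches
#'
#' Runs the full FPS chain on a pyramid: eosin deconvolution of the level-1
#' thumbnail, marker detection, foreground masking, then a row-major scan of
#' the level-L grid of `size x size` tiles, accepting tiles whose level-1
#' footprint is covered by the mask above `cfg$coverage`.
#'
#' @param pyramid a [slide_pyramid()].
#' @param size patch edge at level L (default 512).
#' @param cfg an [fps_config()].
#' @param matrix stain basis for the eosin deconvolution.
#' @return List with `refs` (data frame: patch_id, level, x, y, size, gx, gy
#'   — grid indices in patch units), `mask`, `marker`, `eosin`. Empty
#'   foreground yields zero rows and a warning.
#' @export
select_foreground_patches <- function(pyramid, size = 512L, cfg = fps_config(),
                                      matrix = he_stain_matrix()) {
  lvl1 <- pyramid$levels[[1L]]
  od <- rgb_to_od(lvl1)
  amounts <- deconvolve(od, matrix)
  eosin <- eosin_channel(amounts, clip = TRUE)
  marker <- detect_markers(lvl1, cfg)
  mask <- foreground_mask(eosin, marker, cfg)
  s <- pyramid_scale(pyramid)
  dL <- dim(pyramid$levels[[pyramid$L]])
  nx <- dL[2] %/% size
  ny <- dL[1] %/% size
  rows <- list()
  id <- 0L
  if (nx > 0 && ny > 0) {
    for (gy in seq_len(ny) - 1L) {       # row-major: y outer, x inner
      for (gx in seq_len(nx) - 1L) {
        X <- gx * size; Y <- gy * size
        # level-1 footprint of the half-open level-L region
        r0 <- Y %/% s; r1 <- ceiling((Y + size) / s)
        c0 <- X %/% s; c1 <- ceiling((X + size) / s)
        fr <- (r0 + 1L):min(r1, nrow(mask))
        fc <- (c0 + 1L):min(c1, ncol(mask))
        cov <- mean(mask[fr, fc])
        # marking areas are excluded outright, not merely down-weighted
        if (cov >= cfg$coverage && !any(marker[fr, fc])) {
          id <- id + 1L
          rows[[id]] <- cbind(patch_ref(id, pyramid$L, X, Y, size),
                              gx = gx, gy = gy)
        }
      }
    }
  }
  refs <- if (id > 0L) do.call(rbind, rows) else
    cbind(patch_ref(integer(), integer(), integer(), integer(), integer()),
          gx = integer(), gy = integer())
  if (nrow(refs) == 0L) warning("no foreground patches found")
  list(refs = refs, mask = mask, marker = marker, eosin = eosin)
}

#' Export a binary mask as a PNG (0/255)
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
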