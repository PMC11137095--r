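# Seeded synthetic H&E slides with planted ground truth, plus mock
# segmenter/classifier backends. The forward model is the Beer-Lambert
# inverse of the deconvolution: planted per-pixel hematoxylin/eosin amounts
# are rendered to transmitted RGB through the reference stain basis, so
# deconvolving a noiseless slide recovers the planted amounts exactly.
# Everything is deterministic under the spec seed.

#' Specification of a synthetic slide
#'
#' Tissue is a union of random discs; tumor regions are discs planted fully
#' inside tissue discs (so the tumor mask is always a subset of the tissue
#' mask); pen-marker strokes are thick line segments drawn over the rendered
#' image. Stain amounts: tumor regions are hematoxylin-dense (crowded
#' nuclei), non-tumor tissue eosin-dominant (cytoplasm); optional Gaussian
#' amount noise. The planted label drives only the mock classifier, via the
#' signal strength `beta` carried in the cohort.
#'
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   slide and ground truth.
#' @param size level-L canvas edge in pixels.
#' @param levels number of pyramid levels L.
#' @param downsample per-level downsample factor.
#' @param n_tissue,tissue_radius number and radius range (fraction of
#'   `size`) of tissue discs.
#' @param n_tumor,tumor_radius number and radius range (fraction of `size`)
#'   of tumor discs; each is kept inside its host tissue disc.
#' @param amounts named list of stain amounts: `tissue_h`, `tissue_e`,
#'   `tumor_h`, `tumor_e` (optical-density units).
#' @param noise_sd per-pixel Gaussian noise SD on stain amounts (0 =
#'   noiseless).
#' @param n_markers number of pen strokes.
#' @param marker_colors list of RGB triplets cycled over strokes.
#' @param marker_width stroke width at level L, pixels.
#' @param label planted slide label, `"MSI-High"` or `"MSI-Low"`.
#' @return Named list of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(seed = 1L, size = 1024L, levels = 4L,
                                 downsample = 2L,
                                 n_tissue = 3L, tissue_radius = c(0.18, 0.30),
                                 n_tumor = 2L, tumor_radius = c(0.12, 0.20),
                                 amounts = list(tissue_h = 0.45, tissue_e = 0.55,
                                                tumor_h = 0.90, tumor_e = 0.45),
                                 noise_sd = 0.05,
                                 n_markers = 1L,
                                 marker_colors = list(c(20, 20, 160),
                                                      c(30, 30, 30)),
                                 marker_width = 24L,
                                 label = "MSI-Low") {
  stopifnot(label %in% c("MSI-High", "MSI-Low"),
            size >= downsample^(levels - 1L), noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_slide_spec")
}

# pixel-center coordinate grids for an n x n canvas (built once per slide)
coord_grids <- function(n) {
  list(xs = matrix(seq_len(n) - 0.5, n, n, byrow = TRUE),
       ys = matrix(seq_len(n) - 0.5, n, n))
}

# disc mask (TRUE inside)
disc_mask <- function(g, cx, cy, r) {
  (g$xs - cx)^2 + (g$ys - cy)^2 <= r^2
}

# thick-segment mask: pixels within w/2 of the segment (x0,y0)-(x1,y1)
segment_mask <- function(g, x0, y0, x1, y1, w) {
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else clamp(((g$xs - x0) * vx + (g$ys - y0) * vy) / len2, 0, 1)
  (g$xs - (x0 + t * vx))^2 + (g$ys - (y0 + t * vy))^2 <= (w / 2)^2
}

#' Render a synthetic slide
#'
#' Level-L pixels follow `I_c = I0 * 10^(-(a_H M_H + a_E M_E))_c` from the
#' planted amounts; lower pyramid levels are block-mean downsampled; marker
#' strokes overwrite the rendered RGB. Ground-truth masks are produced at
#' level L and level 1 (level-1 pixel set when at least half its block is
#' set). Intensities stay continuous; quantization happens only on file
#' output.
#'
#' @param spec a [synthetic_slide_spec()].
#' @param patient_id identifier for the pyramid.
#' @return List of class `synthetic_slide`: `pyramid`
#'   ([slide_pyramid()]), `label`, `spec`, and `truth` with level-L masks
#'   (`tissue`, `tumor`, `marker`, `class_map`: 0 background / 1 non-tumor
#'   tissue / 2 tumor), their level-1 counterparts, and the planted
#'   amount fields `h`, `e`.
#' @export
render_slide <- function(spec, patient_id = NA_character_) {
  n <- as.integer(spec$size)
  with_seed(spec$seed, {
    g <- coord_grids(n)
    tissue <- matrix(FALSE, n, n)
    discs <- list()
    for (i in seq_len(spec$n_tissue)) {
      r <- stats::runif(1, spec$tissue_radius[1], spec$tissue_radius[2]) * n
      cx <- stats::runif(1, r, n - r)
      cy <- stats::runif(1, r, n - r)
      discs[[i]] <- c(cx, cy, r)
      tissue <- tissue | disc_mask(g, cx, cy, r)
    }
    if (!any(tissue)) stop("degenerate geometry: zero-area tissue")
    tumor <- matrix(FALSE, n, n)
    for (i in seq_len(spec$n_tumor)) {
      host <- discs[[sample.int(length(discs), 1L)]]
      r <- min(stats::runif(1, spec$tumor_radius[1], spec$tumor_radius[2]) * n,
               0.8 * host[3])
      slack <- host[3] - r
      ang <- stats::runif(1, 0, 2 * pi)
      off <- stats::runif(1, 0, slack)
      tumor <- tumor | disc_mask(g, host[1] + off * cos(ang),
                                 host[2] + off * sin(ang), r)
    }
    tumor <- tumor & tissue
    a_h <- matrix(0, n, n)
    a_e <- matrix(0, n, n)
    a_h[tissue] <- spec$amounts$tissue_h
    a_e[tissue] <- spec$amounts$tissue_e
    a_h[tumor] <- spec$amounts$tumor_h
    a_e[tumor] <- spec$amounts$tumor_e
    if (spec$noise_sd > 0) {
      idx <- which(tissue)
      a_h[idx] <- pmax(a_h[idx] + stats::rnorm(length(idx), 0, spec$noise_sd), 0)
      a_e[idx] <- pmax(a_e[idx] + stats::rnorm(length(idx), 0, spec$noise_sd), 0)
    }
    amounts <- array(0, dim = c(n, n, 3))
    amounts[, , 1] <- a_h
    amounts[, , 2] <- a_e
    full <- render_rgb(amounts, he_stain_matrix())
    marker <- matrix(FALSE, n, n)
    if (spec$n_markers > 0L) {
      for (i in seq_len(spec$n_markers)) {
        p <- stats::runif(4, 0.05, 0.95) * n
        stroke <- segment_mask(g, p[1], p[2], p[3], p[4], spec$marker_width)
        marker <- marker | stroke
        col <- spec$marker_colors[[(i - 1L) %% length(spec$marker_colors) + 1L]]
        for (k in 1:3) {
          plane <- full[, , k]
          plane[stroke] <- col[k]
          full[, , k] <- plane
        }
      }
    }
    lv <- list(full)
    for (l in seq_len(spec$levels - 1L)) {
      lv <- c(list(block_downsample(lv[[1L]], spec$downsample)), lv)
    }
    s <- spec$downsample^(spec$levels - 1L)
    to_l1 <- function(m) block_downsample(m * 1, s) >= 0.5
    class_map <- matrix(0L, n, n)
    class_map[tissue] <- 1L
    class_map[tumor] <- 2L
    structure(list(
      pyramid = slide_pyramid(lv, patient_id, spec$downsample),
      label = spec$label, spec = spec,
      truth = list(tissue = tissue, tumor = tumor, marker = marker,
                   class_map = class_map, h = a_h, e = a_e,
                   tissue_l1 = to_l1(tissue), tumor_l1 = to_l1(tumor),
                   marker_l1 = to_l1(marker))),
      class = "synthetic_slide")
  })
}

#' Mock per-pixel segmenter backend
#'
#' Emits one-hot ground-truth classes read from the patch context
#' (`info$class_map`), with each pixel independently reassigned to a
#' uniformly random wrong class with probability `flip_rate`. Deterministic
#' per (patch coordinates, seed) regardless of evaluation order.
#'
#' @param flip_rate per-pixel corruption probability in `[0, 0.5)`.
#' @param seed backend seed.
#' @return A segmenter backend function (see [segment_patch()]).
#' @export
mock_segmenter <- function(flip_rate = 0, seed = 1L) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5)
  f <- function(patch, info) {
    truth <- info$class_map
    if (is.null(truth)) stop("mock_segmenter needs info$class_map ground truth")
    m <- nrow(truth)
    cls <- as.integer(truth)
    if (flip_rate > 0) {
      with_seed(subseed(seed, info$x %||% 0, info$y %||% 0,
                        info$patient_id %||% 0), {
        flip <- stats::runif(length(cls)) < flip_rate
        if (any(flip)) {
          shift <- sample.int(2L, sum(flip), replace = TRUE)
          cls[flip] <- (cls[flip] + shift) %% 3L
        }
      })
    }
    probs <- array(0, dim = c(m, ncol(truth), 3L))
    probs[cbind(rep(seq_len(m), ncol(truth)),
                rep(seq_len(ncol(truth)), each = m),
                cls + 1L)] <- 1
    probs
  }
  attr(f, "name") <- sprintf("mock_segmenter(flip_rate=%g)", flip_rate)
  f
}

#' Mock patch classifier backend
#'
#' Emits `gamma = clip(base + Normal(0, noise_sd))` with
#' `base = 0.5 + beta/2` for MSI-Low-labelled slides and `0.5 - beta/2` for
#' MSI-High, reading the planted label from the patch context. Deterministic
#' per (patch coordinates, seed).
#'
#' @param beta label-signal strength in `[0, 1]` (0 = no signal, 1 = perfect
#'   separation).
#' @param noise_sd Gaussian noise SD on gamma.
#' @param seed backend seed.
#' @return A classifier backend function (see [classify_patch()]).
#' @export
mock_classifier <- function(beta = 1, noise_sd = 0, seed = 1L) {
  stopifnot(beta >= 0, beta <= 1, noise_sd >= 0)
  f <- function(patch, info) {
    label <- info$label
    if (is.null(label)) stop("mock_classifier needs info$label ground truth")
    base <- if (label == "MSI-Low") 0.5 + beta / 2 else 0.5 - beta / 2
    g <- base
    if (noise_sd > 0) {
      g <- with_seed(subseed(seed, info$x %||% 0, info$y %||% 0,
                             info$patient_id %||% 0, 7L),
                     base + stats::rnorm(1, 0, noise_sd))
    }
    clamp(g, 0, 1)
  }
  attr(f, "name") <- sprintf("mock_classifier(beta=%g, noise_sd=%g)",
                             beta, noise_sd)
  f
}

#' Simulate a labelled cohort of synthetic slides
#'
#' Label imbalance presets mirror the endometrioid carcinoma strata:
#' `"G1G2-like"` plants 30% MSI-High / 70% MSI-Low, `"G3-like"` 41% / 59%.
#' Slides are specified (not rendered) so cohorts stay lightweight; the
#' pipeline renders them one at a time.
#'
#' @param n number of patients (one slide each).
#' @param preset `"G1G2-like"` or `"G3-like"`.
#' @param seed cohort seed; per-slide seeds derive from it.
#' @param dir optional directory: when given, slides are rendered and
#'   written as multi-page TIFFs plus level-1 mask PNGs and a `labels.csv`.
#' @param ... overrides forwarded to [synthetic_slide_spec()].
#' @return Data frame (`patient_id`, `label`, `subtype`) with a `spec`
#'   list-column, and a `slide_path` column when `dir` is given.
#' @export
simulate_cohort <- function(n = 40L, preset = c("G1G2-like", "G3-like"),
                            seed = 1L, dir = NULL, ...) {
  preset <- match.arg(preset)
  frac_h <- if (preset == "G1G2-like") 0.30 else 0.41
  n_h <- round(n * frac_h)
  labels <- with_seed(subseed(seed, 11L),
                      sample(c(rep("MSI-High", n_h), rep("MSI-Low", n - n_h))))
  ids <- sprintf("P%03d", seq_len(n))
  specs <- lapply(seq_len(n), function(i) {
    synthetic_slide_spec(seed = subseed(seed, i), label = labels[i], ...)
  })
  cohort <- data.frame(patient_id = ids, label = labels, subtype = preset,
                       stringsAsFactors = FALSE)
  cohort$spec <- I(specs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(n)
    cm_paths <- character(n)
    for (i in seq_len(n)) {
      sl <- render_slide(specs[[i]], ids[i])
      paths[i] <- file.path(dir, paste0(ids[i], ".tif"))
      write_pyramid(sl$pyramid, paths[i])
      write_mask_png(sl$truth$tissue_l1, file.path(dir, paste0(ids[i], "_tissue.png")))
      write_mask_png(sl$truth$tumor_l1, file.path(dir, paste0(ids[i], "_tumor.png")))
      write_mask_png(sl$truth$marker_l1, file.path(dir, paste0(ids[i], "_marker.png")))
      # full-resolution class map (0 bg / 1 tissue / 2 tumor), for mock
      # backends replayed from files
      cm_paths[i] <- file.path(dir, paste0(ids[i], "_classmap.png"))
      png::writePNG(sl$truth$class_map / 2, cm_paths[i])
    }
    cohort$slide_path <- paths
    cohort$class_map_path <- cm_paths
    utils::write.csv(cbind(cohort[, c("patient_id", "label", "subtype")],
                           slide_path = paths, class_map_path = cm_paths,
                           seed = seed),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  }
  cohort
}
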