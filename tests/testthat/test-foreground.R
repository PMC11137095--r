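# Foreground patch selection: marker detection, dual-threshold masking,
# patch selection.

# Build a pyramid whose level-L content is a rendered eosin disc of radius r
# centered on the canvas; deterministic, no RNG involved.
disc_slide <- function(n = 256L, r = 64L, amount_e = 0.6, levels = 3L) {
  amounts <- array(0, dim = c(n, n, 3))
  xs <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - 0.5, n, n)
  disc <- (xs - n / 2)^2 + (ys - n / 2)^2 <= r^2
  e <- matrix(0, n, n); e[disc] <- amount_e
  amounts[, , 2] <- e
  full <- render_rgb(amounts, he_stain_matrix())
  list(pyramid = build_pyramid(full, min_edge = n / 2^(levels - 1L)),
       disc = disc)
}

test_that("pen strokes are recalled and marker-free tissue is not flagged", {
  # strokes over tissue and background: planted stroke pixels recalled
  sl <- render_slide(small_spec(seed = 21L, n_markers = 2L), "mk")
  det <- detect_markers(sl$pyramid$levels[[1L]])
  planted <- sl$truth$marker_l1
  expect_gte(sum(det & planted) / sum(planted), 0.95)
  # marker-free H&E tissue: under 5% of tissue pixels flagged
  clean <- render_slide(small_spec(seed = 22L, noise_sd = 0.05), "cl")
  det2 <- detect_markers(clean$pyramid$levels[[1L]])
  tissue <- clean$truth$tissue_l1
  expect_lte(sum(det2 & tissue) / sum(tissue), 0.05)
  # slide with no markers at all: (almost) empty mask
  expect_lte(mean(det2), 0.05)
})

test_that("foreground mask recovers a planted tissue disc and drops markers", {
  sl <- disc_slide()
  fg <- select_foreground_patches(sl$pyramid, size = 64L)
  got <- fg$mask
  truth <- block_downsample(sl$disc * 1, 4L) >= 0.5
  jac <- sum(got & truth) / sum(got | truth)
  expect_gte(jac, 0.95)
  # an all-white slide yields an empty mask and no patches, with a warning
  white <- build_pyramid(solid_raster(256L, c(255, 255, 255)), min_edge = 64L)
  expect_warning(fgw <- select_foreground_patches(white, size = 64L),
                 "no foreground")
  expect_false(any(fgw$mask))
  expect_equal(nrow(fgw$refs), 0L)
  # marker strokes punch holes in the mask
  mk <- render_slide(small_spec(seed = 23L, n_markers = 1L,
                                marker_width = 40L), "mk")
  fgm <- suppressWarnings(select_foreground_patches(mk$pyramid, size = 64L))
  expect_equal(sum(fgm$mask & mk$truth$marker_l1), 0L)
})

test_that("explicit thresholds are validated and drive the mask deterministically", {
  sl <- disc_slide()
  eosin <- fg_eosin <- matrix(0, 64, 64)
  expect_error(foreground_mask(eosin, cfg = fps_config(t_low = 0.5, t_high = 0.2)),
               "t_low")
  fg1 <- select_foreground_patches(sl$pyramid, size = 64L)
  fg2 <- select_foreground_patches(sl$pyramid, size = 64L)
  expect_identical(fg1$mask, fg2$mask)
  expect_identical(fg1$refs, fg2$refs)
})

test_that("a foreground that exactly tiles k footprints yields exactly k patches", {
  n <- 256L
  amounts <- array(0, dim = c(n, n, 3))
  e <- matrix(0, n, n)
  e[1:64, 1:64] <- 0.6        # tile (gx 0, gy 0)
  e[65:128, 129:192] <- 0.6   # tile (gx 2, gy 1)
  amounts[, , 2] <- e
  full <- render_rgb(amounts, he_stain_matrix())
  p <- build_pyramid(full, min_edge = 64L)
  cfg <- fps_config(t_low = 0.3, t_high = 1, morph_radius = 0L,
                    min_component = 0L)
  fg <- select_foreground_patches(p, size = 64L, cfg = cfg)
  expect_equal(nrow(fg$refs), 2L)
  expect_equal(fg$refs[, c("gx", "gy")], data.frame(gx = c(0L, 2L), gy = c(0L, 1L)),
               ignore_attr = TRUE)
})

test_that("selected patches are in bounds, non-overlapping and row-major ordered", {
  sl <- render_slide(small_spec(seed = 24L, noise_sd = 0.05), "ob")
  fg <- select_foreground_patches(sl$pyramid, size = 64L)
  refs <- fg$refs
  expect_gt(nrow(refs), 0L)
  dL <- dim(sl$pyramid$levels[[sl$pyramid$L]])
  expect_true(all(refs$x >= 0 & refs$x + refs$size <= dL[2]))
  expect_true(all(refs$y >= 0 & refs$y + refs$size <= dL[1]))
  expect_false(any(duplicated(refs[, c("gx", "gy")])))
  ord <- order(refs$gy, refs$gx)
  expect_identical(ord, seq_len(nrow(refs)))
})

test_that("enlarging the tissue region never decreases the patch count", {
  cfg <- fps_config(t_low = 0.3, t_high = 1)
  counts <- vapply(c(40L, 60L, 80L, 100L), function(r) {
    nrow(suppressWarnings(
      select_foreground_patches(disc_slide(r = r)$pyramid, size = 64L,
                                cfg = cfg))$refs)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[4], counts[1])
})

test_that("selected patch footprints avoid the planted marker mask", {
  sl <- render_slide(small_spec(seed = 25L, n_markers = 2L, noise_sd = 0.05),
                     "mx")
  fg <- select_foreground_patches(sl$pyramid, size = 64L)
  s <- pyramid_scale(sl$pyramid)
  planted <- sl$truth$marker_l1
  for (i in seq_len(nrow(fg$refs))) {
    rows <- (fg$refs$y[i] %/% s + 1L):ceiling((fg$refs$y[i] + 64L) / s)
    cols <- (fg$refs$x[i] %/% s + 1L):ceiling((fg$refs$x[i] + 64L) / s)
    expect_equal(sum(planted[rows, cols]), 0L)
  }
})
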