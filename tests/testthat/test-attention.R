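# Attention scoring: segmenter contract, patch cleaning, score exactness,
# validation filter.

one_hot_backend <- function(class_map) {
  f <- function(patch, info) {
    probs <- array(0, dim = c(dim(class_map), 3L))
    probs[cbind(rep(seq_len(nrow(class_map)), ncol(class_map)),
                rep(seq_len(ncol(class_map)), each = nrow(class_map)),
                as.integer(class_map) + 1L)] <- 1
    probs
  }
  attr(f, "name") <- "one_hot"
  f
}

test_that("segment_patch validates the backend contract", {
  cm <- matrix(c(0L, 1L, 2L, 2L), 2, 2)
  patch <- solid_raster(2L, c(100, 100, 100))
  probs <- segment_patch(patch, one_hot_backend(cm))
  expect_equal(dim(probs), c(2L, 2L, 3L))
  expect_true(all(abs(rowSums(matrix(probs, ncol = 3)) - 1) < 1e-12))
  expect_equal(probs[2, 2, 3], 1)
  bad_shape <- function(patch, info) array(1, dim = c(3, 3, 3))
  attr(bad_shape, "name") <- "bad_shape"
  expect_error(segment_patch(patch, bad_shape), "bad_shape.*dimensions")
  bad_norm <- function(patch, info) array(0.5, dim = c(2, 2, 3))
  expect_error(segment_patch(patch, bad_norm), "sum to 1")
  bad_neg <- function(patch, info) {
    p <- array(c(1.5, -0.5, 0), dim = c(2, 2, 3)) * 0
    p[, , 1] <- 1.5; p[, , 2] <- -0.5
    p
  }
  expect_error(segment_patch(patch, bad_neg), "negative")
})

test_that("mock segmenter flips classes at the configured rate", {
  cm <- matrix(1L, 320L, 320L)  # ~1e5 pixels, all non-tumor tissue
  patch <- array(0, dim = c(320L, 320L, 3L))
  probs <- segment_patch(patch, mock_segmenter(0.1, seed = 3L),
                         info = list(class_map = cm, x = 0, y = 0))
  argmax <- max.col(matrix(probs, ncol = 3), ties.method = "first") - 1L
  rate <- mean(argmax != as.integer(cm))
  expect_lt(abs(rate - 0.1), 0.02)
  # zero flip rate reproduces the truth; same seed reproduces the flips
  p0 <- segment_patch(patch, mock_segmenter(0, 1L),
                      info = list(class_map = cm, x = 0, y = 0))
  expect_true(all(max.col(matrix(p0, ncol = 3)) - 1L == 1L))
  p1 <- segment_patch(patch, mock_segmenter(0.1, seed = 3L),
                      info = list(class_map = cm, x = 0, y = 0))
  expect_identical(probs, p1)
})

test_that("clean_patch keeps tumor-like pixels and suppresses the rest", {
  n <- 4L
  patch <- solid_raster(n, c(120, 60, 140))
  all_tumor <- matrix(2L, n, n)
  cl <- clean_patch(patch, segment_patch(patch, one_hot_backend(all_tumor)))
  expect_true(all(cl$mask))
  expect_identical(cl$cleaned, patch)
  all_bg <- matrix(0L, n, n)
  cl0 <- clean_patch(patch, segment_patch(patch, one_hot_backend(all_bg)))
  expect_false(any(cl0$mask))
  expect_true(all(cl0$cleaned == 255))
  # planted half-tumor: mask equals the planted half exactly
  half <- matrix(0L, n, n); half[, 1:2] <- 2L
  clh <- clean_patch(patch, segment_patch(patch, one_hot_backend(half)))
  expect_identical(clh$mask, half == 2L)
  expect_true(all(clh$cleaned[, 1:2, 1] == 120))
  expect_true(all(clh$cleaned[, 3:4, 1] == 255))
})

test_that("argmax ties resolve toward the lower class: ambiguity is not tumor", {
  probs <- array(0, dim = c(1, 1, 3))
  probs[1, 1, ] <- c(0, 0.5, 0.5)  # tie between non-tumor and tumor
  cl <- clean_patch(solid_raster(1L, c(10, 10, 10)), probs)
  expect_false(cl$mask[1, 1])
})

test_that("attention score is the exact pixel-count ratio", {
  expect_identical(attention_score(matrix(TRUE, 8, 8)), 1)
  expect_identical(attention_score(matrix(FALSE, 8, 8)), 0)
  m <- matrix(FALSE, 512, 512)
  m[seq_len(131072)] <- TRUE
  expect_identical(attention_score(m), 0.5)
  # no floating drift: score times area is an exact integer
  set.seed(31)
  for (rep in 1:20) {
    mm <- matrix(stats::runif(64 * 64) < stats::runif(1), 64, 64)
    expect_identical(attention_score(mm) * 64^2, as.numeric(sum(mm)))
  }
})

test_that("validation is a strict threshold and monotone in alpha", {
  expect_true(validate_patch(0.5, 0.1))
  expect_false(validate_patch(0.1, 0.1))  # boundary: strict inequality
  expect_false(validate_patch(0, 0))
  set.seed(17)
  xi <- stats::runif(200)
  n_valid <- vapply(c(0, 0.1, 0.3, 0.6, 0.9),
                    function(a) sum(validate_patch(xi, a)), integer(1))
  expect_true(all(diff(n_valid) <= 0))
})

test_that("under the noiseless mock, xi equals the planted tumor fraction", {
  sl <- render_slide(small_spec(seed = 41L), "xt")
  fg <- select_foreground_patches(sl$pyramid, size = 64L)
  sc <- score_patches(sl$pyramid, fg$refs, mock_segmenter(0, 1L),
                      info_base = list(patient_id = "xt", label = sl$label,
                                       class_map = sl$truth$class_map))
  expect_gt(nrow(sc$scores), 0L)
  for (i in seq_len(nrow(sc$scores))) {
    r <- sc$scores[i, ]
    planted <- sl$truth$tumor[r$y + seq_len(r$size), r$x + seq_len(r$size)]
    expect_identical(r$xi, sum(planted) / r$size^2)
  }
  # cleaned rasters are retained exactly for the valid patches
  expect_setequal(names(sc$cleaned),
                  as.character(sc$scores$patch_id[sc$scores$valid]))
})
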