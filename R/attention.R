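# Tumor-attention scoring: run a pluggable per-pixel segmenter over each
# foreground patch, keep only pixels argmax-classified as tumor-like (the
# "data cleaning" step), and score each patch by the fraction of pixels kept.
#
# Segmenter backend contract: a function `f(patch, info)` mapping a
# size x size x 3 RGB patch to a size x size x (H+1) array of per-pixel
# class probabilities, planes ordered h = 0 (background), 1 (non-tumor
# tissue), 2 (tumor-like), ... The `info` list carries patch context
# (coordinates, patient id, and for mock backends the planted ground truth).

#' Run a segmenter backend and validate its contract
#'
#' @param patch `size x size x 3` RGB array.
#' @param backend segmenter function `f(patch, info)`.
#' @param info context list passed through to the backend.
#' @return `size x size x (H+1)` probability array.
#' @export
segment_patch <- function(patch, backend, info = list()) {
  probs <- backend(patch, info)
  nm <- attr(backend, "name") %||% "segmenter backend"
  d <- dim(probs)
  if (length(d) != 3L || any(d[1:2] != dim(patch)[1:2])) {
    stop(nm, ": output raster dimensions must match the input patch")
  }
  if (any(probs < 0)) stop(nm, ": negative class probabilities")
  sums <- rowSums(matrix(probs, ncol = d[3]))
  if (any(abs(sums - 1) > 1e-6)) {
    stop(nm, ": per-pixel probabilities must sum to 1")
  }
  probs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clean a patch: keep tumor-like pixels, suppress the rest
#'
#' A pixel is kept iff the argmax class index exceeds 1, i.e. it is the
#' tumor-like class (h = 2) or beyond. Argmax ties resolve toward the lower
#' class index, so an ambiguous pixel never counts as tumor. Suppressed
#' pixels are set to `fill` in the cleaned raster handed to the classifier.
#'
#' @param patch RGB array.
#' @param probs matching probability array from [segment_patch()].
#' @param fill RGB fill for suppressed pixels (default white).
#' @return List: `mask` (logical matrix of kept pixels), `cleaned` (RGB
#'   array).
#' @export
clean_patch <- function(patch, probs, fill = c(255, 255, 255)) {
  d <- dim(probs)
  cls <- max.col(matrix(probs, ncol = d[3]), ties.method = "first") # 1-based
  keep <- matrix(cls > 2L, nrow = d[1])  # class index h = cls - 1 > 1
  cleaned <- patch
  for (k in 1:3) {
    plane <- cleaned[, , k]
    plane[!keep] <- fill[k]
    cleaned[, , k] <- plane
  }
  list(mask = keep, cleaned = cleaned)
}

#' Tumor-attention score of a cleaned patch
#'
#' The exact count ratio `card(clean) / size^2`: integer arithmetic over the
#' patch-area denominator, so there is no floating-point drift.
#'
#' @param clean_mask logical `size x size` matrix.
#' @param size patch edge; defaults to `nrow(clean_mask)`.
#' @return Score in `[0, 1]`.
#' @export
attention_score <- function(clean_mask, size = nrow(clean_mask)) {
  stopifnot(nrow(clean_mask) == size, ncol(clean_mask) == size)
  sum(clean_mask) / (as.numeric(size)^2)
}

#' Validate a patch against the minimum attention level
#'
#' A patch is valid iff its attention score strictly exceeds `alpha`
#' (default 0.1): patches at or below the floor carry too little tumor-like
#' signal to inform the slide decision.
#'
#' @param xi attention score(s) in `[0, 1]`.
#' @param alpha minimum attention level in `[0, 1)`.
#' @return Logical vector.
#' @export
validate_patch <- function(xi, alpha = 0.1) {
  stopifnot(all(xi >= 0 & xi <= 1), alpha >= 0, alpha < 1)
  xi > alpha
}

#' Score all foreground patches of a slide
#'
#' Extracts each referenced patch, segments it, cleans it and scores it.
#' Cleaned rasters are retained only for valid patches (the ones eligible
#' for sampling and classification).
#'
#' @param pyramid a [slide_pyramid()].
#' @param refs patch-reference data frame from
#'   [select_foreground_patches()].
#' @param backend segmenter backend.
#' @param alpha minimum attention level.
#' @param fill fill value for suppressed pixels.
#' @param info_base context fields common to all patches (e.g. `patient_id`,
#'   `label`, `class_map` for mock backends).
#' @return List: `scores` data frame (patch_id, x, y, gx, gy, xi, valid) and
#'   `cleaned` (named list of cleaned rasters for valid patches, keyed by
#'   patch_id).
#' @export
score_patches <- function(pyramid, refs, backend, alpha = 0.1,
                          fill = c(255, 255, 255), info_base = list()) {
  n <- nrow(refs)
  xi <- numeric(n)
  cleaned <- list()
  for (i in seq_len(n)) {
    ref <- refs[i, ]
    patch <- extract_patch(pyramid, ref)
    info <- c(info_base, list(x = ref$x, y = ref$y, size = ref$size))
    if (!is.null(info_base$class_map)) {
      info$class_map <- info_base$class_map[ref$y + seq_len(ref$size),
                                            ref$x + seq_len(ref$size)]
    }
    probs <- segment_patch(patch, backend, info)
    cl <- clean_patch(patch, probs, fill)
    xi[i] <- attention_score(cl$mask, ref$size)
    if (validate_patch(xi[i], alpha)) {
      cleaned[[as.character(ref$patch_id)]] <- cl$cleaned
    }
  }
  scores <- cbind(refs, xi = xi, valid = validate_patch(xi, alpha))
  list(scores = scores, cleaned = cleaned)
}

#' Write a per-patch score table as CSV
#'
#' Columns: `patient_id, patch_id, x, y, xi, valid`.
#' @param scores score data frame from [score_patches()].
#' @param path CSV path.
#' @param patient_id identifier stamped on each row.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, patient_id = NA_character_) {
  out <- cbind(patient_id = patient_id,
               scores[, c("patch_id", "x", "y", "xi", "valid")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
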