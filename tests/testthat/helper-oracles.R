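# Independent oracles and small fixture builders shared across tests.

# Brute-force greedy spaced sampler: plain O(n^2) loops, kept deliberately
# separate from the package implementation so the two can disagree.
brute_ips <- function(cand, delta, max_n = Inf, metric = "euclidean") {
  slide <- if ("slide" %in% names(cand)) cand$slide else rep("s", nrow(cand))
  chosen <- integer(0)
  while (length(chosen) < max_n) {
    best <- NA_integer_
    for (i in seq_len(nrow(cand))) {
      if (i %in% chosen) next
      ok <- TRUE
      for (j in chosen) {
        if (slide[i] != slide[j]) next
        dx <- cand$gx[i] - cand$gx[j]
        dy <- cand$gy[i] - cand$gy[j]
        d <- if (metric == "euclidean") sqrt(dx^2 + dy^2) else max(abs(dx), abs(dy))
        if (d < delta) { ok <- FALSE; break }
      }
      if (!ok) next
      if (is.na(best)) { best <- i; next }
      better <- cand$xi[i] > cand$xi[best] ||
        (cand$xi[i] == cand$xi[best] && (cand$gy[i] < cand$gy[best] ||
          (cand$gy[i] == cand$gy[best] && cand$gx[i] < cand$gx[best])))
      if (better) best <- i
    }
    if (is.na(best)) break
    chosen <- c(chosen, best)
  }
  cand[chosen, , drop = FALSE]
}

# Random candidate set on a g x g patch grid (positions unique).
random_candidates <- function(n, g = 20L) {
  pos <- sample.int(g * g, n)
  data.frame(patch_id = seq_len(n),
             gx = (pos - 1L) %% g,
             gy = (pos - 1L) %/% g,
             x = ((pos - 1L) %% g) * 64L,
             y = ((pos - 1L) %/% g) * 64L,
             xi = round(runif(n), 3))
}

# Plain confusion-matrix counter, independent of compute_metrics().
brute_confusion <- function(pred, truth, positive) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == positive && truth[i] == positive) tp <- tp + 1L
    if (pred[i] == positive && truth[i] != positive) fp <- fp + 1L
    if (pred[i] != positive && truth[i] != positive) tn <- tn + 1L
    if (pred[i] != positive && truth[i] == positive) fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# A small flat raster whose level-L pixel value encodes its position, so
# extraction results can be predicted without touching the pyramid code.
position_coded_raster <- function(n) {
  r <- outer(seq_len(n) - 1L, rep(1L, n)) %% 251
  c_ <- outer(rep(1L, n), seq_len(n) - 1L) %% 241
  array(c(r, c_, (r + c_) %% 255), dim = c(n, n, 3))
}

# Tiny uniform-color raster.
solid_raster <- function(n, rgb) {
  array(rep(rgb, each = n * n), dim = c(n, n, 3))
}

# Compact synthetic spec for fast unit tests (256 px canvas, 3 levels).
small_spec <- function(seed = 1L, ...) {
  args <- list(seed = seed, size = 256L, levels = 3L,
               n_tissue = 2L, n_tumor = 1L,
               tumor_radius = c(0.15, 0.22), noise_sd = 0, n_markers = 0L)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_slide_spec, args)
}
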