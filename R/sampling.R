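# Iterative patch sampling (IPS): greedy selection of representative patches
# by descending attention score under a minimum-spacing constraint.
#
# The first pick is the global score argmax; each later pick is the argmax
# among candidates at grid distance >= delta from ALL previous picks.
# Distances are measured between patch-grid indices (patch units, matching
# the magnitude of the default delta = 3), Euclidean by default. Score ties
# break row-major (smaller gy, then smaller gx) for determinism. Candidates
# from different slides of one patient never constrain each other
# (cross-slide distance is infinite).

#' Greedily sample spaced representative patches
#'
#' @param candidates data frame of valid scored patches with columns `xi`,
#'   `gx`, `gy` (patch-grid indices) and optionally `slide` (for
#'   multi-slide patients) plus any carry-along columns.
#' @param delta minimum spacing in patch-grid units (default 3).
#' @param max_n selection cap per patient (default 50).
#' @param metric `"euclidean"` (default) or `"chebyshev"` grid distance.
#' @return The selected rows, ordered by selection rank, with a `rank`
#'   column prepended. Scores along the ranking are non-increasing. An empty
#'   candidate set returns zero rows with a warning (the slide is then
#'   unclassifiable).
#' @export
ips_sample <- function(candidates, delta = 3, max_n = 50L,
                       metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  stopifnot(delta >= 0)
  if (is.null(candidates) || nrow(candidates) == 0L) {
    warning("ips_sample: no valid candidates; slide will be unclassifiable")
    out <- candidates[integer(0), , drop = FALSE]
    return(cbind(rank = integer(0), out))
  }
  slide <- if ("slide" %in% names(candidates)) candidates$slide else
    rep("s", nrow(candidates))
  # deterministic candidate order: score desc, then row-major position
  ord <- order(-candidates$xi, candidates$gy, candidates$gx)
  cand <- candidates[ord, , drop = FALSE]
  slide <- slide[ord]
  feasible <- rep(TRUE, nrow(cand))
  picked <- integer(0)
  while (length(picked) < max_n && any(feasible)) {
    i <- which(feasible)[1L]   # best remaining under the sort order
    picked <- c(picked, i)
    same <- feasible & slide == slide[i]
    if (any(same)) {
      dx <- cand$gx[same] - cand$gx[i]
      dy <- cand$gy[same] - cand$gy[i]
      d <- if (metric == "euclidean") sqrt(dx^2 + dy^2) else pmax(abs(dx), abs(dy))
      feasible[which(same)[d < delta]] <- FALSE
    }
    feasible[i] <- FALSE
  }
  out <- cand[picked, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_along(picked), out)
}

#' Write a selected representative set as CSV
#'
#' Columns: `patient_id, rank, slide, x, y, xi`.
#' @param selected output of [ips_sample()].
#' @param path CSV path.
#' @param patient_id identifier stamped on each row.
#' @return `path`, invisibly.
#' @export
write_representative_set <- function(selected, path,
                                     patient_id = NA_character_) {
  slide <- if ("slide" %in% names(selected)) selected$slide else NA_character_
  out <- data.frame(patient_id = patient_id, rank = selected$rank,
                    slide = slide, x = selected$x, y = selected$y,
                    xi = selected$xi)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
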