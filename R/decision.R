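# Weighted softmax integrated decision (WSID): per-patch classifier
# probabilities are pooled into a slide probability by softmax weighting of
# per-patch decision weights derived from the attention scores, then
# thresholded for the MSI call.
#
# Classifier backend contract: a function `f(patch, info)` mapping a
# size x size x 3 RGB (cleaned) patch to a probability gamma in [0, 1] of
# the MSI-Low class. The threshold rule calls MSI-High when the slide
# probability falls below delta, so gamma is oriented toward MSI-Low;
# MSI-High is the positive class for evaluation.

#' Classify one patch through a pluggable backend
#'
#' @param patch `size x size x 3` RGB array (cleaned by default in the
#'   pipeline).
#' @param backend classifier function `f(patch, info)`.
#' @param info context list passed through to the backend.
#' @return Probability of the MSI-Low class, in `[0, 1]`.
#' @export
classify_patch <- function(patch, backend, info = list()) {
  g <- backend(patch, info)
  nm <- attr(backend, "name") %||% "classifier backend"
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0 || g > 1) {
    stop(nm, ": output must be a single probability in [0, 1]")
  }
  as.numeric(g)
}

#' Decision weight of a representative patch
#'
#' Piecewise in the attention score: patches with under half their area
#' tumor-like get a floor weight of 0.01; fully tumor-like patches get 0.95;
#' in between, the weight is the midpoint of the two adjacent score deciles,
#' `((floor(10 xi) + ceiling(10 xi)) / 2) / 10`. Non-decreasing on [0, 1]
#' with range {0.01} U [0.5, 0.95]. Vectorized.
#'
#' @param xi attention score(s) in `[0, 1]`.
#' @return Decision weight(s).
#' @export
decision_weight <- function(xi) {
  if (any(!is.finite(xi)) || any(xi < 0 | xi > 1)) {
    stop("attention score must lie in [0, 1]")
  }
  t <- xi * 10
  # guard against binary representation of exact decile scores (e.g. 0.7*10)
  near <- abs(t - round(t)) < 1e-9
  t[near] <- round(t[near])
  mid <- (floor(t) + ceiling(t)) / 2 / 10
  ifelse(xi < 0.5, 0.01, ifelse(xi == 1, 0.95, mid))
}

#' Aggregate patch probabilities into a slide probability
#'
#' Softmax-of-weights pooling: `gamma' = sum(gamma_j exp(omega_j)) /
#' sum(exp(omega_j))` — a convex combination, so the result is bounded by
#' the extreme patch probabilities and equals the plain mean when all
#' weights agree.
#'
#' @param gamma per-patch MSI-Low probabilities.
#' @param omega matching decision weights.
#' @return Slide probability `gamma'` in `[min(gamma), max(gamma)]`.
#' @export
wsid_aggregate <- function(gamma, omega) {
  if (length(gamma) == 0L) {
    stop("unclassifiable slide: no representative patches to aggregate")
  }
  stopifnot(length(gamma) == length(omega))
  if (length(gamma) == 1L) return(as.numeric(gamma))
  w <- exp(omega)
  sum(gamma * w) / sum(w)
}

#' Final MSI call from the slide probability
#'
#' MSI-High iff `gamma' < delta`; the boundary `gamma' == delta` is called
#' MSI-Low. Default threshold 0.5.
#'
#' @param gamma_prime slide probability in `[0, 1]`.
#' @param delta decision threshold.
#' @return `"MSI-High"` or `"MSI-Low"`.
#' @export
msi_call <- function(gamma_prime, delta = 0.5) {
  stopifnot(gamma_prime >= 0, gamma_prime <= 1)
  if (gamma_prime < delta) "MSI-High" else "MSI-Low"
}

#' Full slide-level decision from a representative set
#'
#' Classifies each representative patch, derives its decision weight from
#' its attention score, aggregates, and thresholds. Slides without
#' representative patches yield an explicit unclassifiable status, never a
#' default call.
#'
#' @param selected output of [ips_sample()].
#' @param cleaned named list of cleaned rasters keyed by patch_id.
#' @param backend classifier backend.
#' @param delta decision threshold.
#' @param info_base context fields passed to the backend (plus per-patch
#'   coordinates).
#' @return List of class `slide_decision`: `patient_id`, `status`
#'   (`"classified"` or `"unclassifiable"`), `gamma_prime`, `delta`, `call`,
#'   and `patches` (data frame rank/patch_id/xi/omega/gamma).
#' @export
decide_slide <- function(selected, cleaned, backend, delta = 0.5,
                         info_base = list()) {
  pid <- info_base$patient_id %||% NA_character_
  if (is.null(selected) || nrow(selected) == 0L) {
    return(structure(list(patient_id = pid, status = "unclassifiable",
                          gamma_prime = NA_real_, delta = delta,
                          call = NA_character_,
                          patches = data.frame()),
                     class = "slide_decision"))
  }
  n <- nrow(selected)
  gamma <- numeric(n)
  for (j in seq_len(n)) {
    key <- as.character(selected$patch_id[j])
    patch <- cleaned[[key]]
    if (is.null(patch)) stop("missing cleaned raster for patch ", key)
    info <- c(info_base, list(x = selected$x[j], y = selected$y[j]))
    gamma[j] <- classify_patch(patch, backend, info)
  }
  omega <- decision_weight(selected$xi)
  gp <- wsid_aggregate(gamma, omega)
  structure(list(patient_id = pid, status = "classified",
                 gamma_prime = gp, delta = delta,
                 call = msi_call(gp, delta),
                 patches = data.frame(rank = selected$rank,
                                      patch_id = selected$patch_id,
                                      xi = selected$xi, omega = omega,
                                      gamma = gamma)),
            class = "slide_decision")
}

#' @export
print.slide_decision <- function(x, ...) {
  if (x$status == "unclassifiable") {
    cat("slide_decision [", x$patient_id, "]: unclassifiable\n", sep = "")
  } else {
    cat(sprintf("slide_decision [%s]: %s (gamma' = %.4f, delta = %g, %d patches)\n",
                x$patient_id, x$call, x$gamma_prime, x$delta, nrow(x$patches)))
  }
  invisible(x)
}

#' Provenance record for a trained classifier backend
#'
#' Immutable metadata describing how an external backend was trained; never
#' consumed by the pipeline math.
#'
#' @param optimizer optimizer name.
#' @param learning_rate initial learning rate.
#' @param weight_decay weight decay.
#' @param rms_decay RMS decay.
#' @param batch_size batch size.
#' @param loss loss name.
#' @return Named list of class `training_config`.
#' @export
training_config <- function(optimizer = "RMSProp", learning_rate = 3e-3,
                            weight_decay = 3e-4, rms_decay = 0.9,
                            batch_size = 6L, loss = "cross-entropy") {
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 weight_decay = weight_decay, rms_decay = rms_decay,
                 batch_size = as.integer(batch_size), loss = loss),
            class = "training_config")
}

#' Serialize slide decisions to JSON
#'
#' One object per patient: `{patient_id, status, gamma_prime, delta, call,
#' patches: [{rank, xi, omega, gamma}]}`.
#' @param decisions list of `slide_decision` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decisions_json <- function(decisions, path) {
  payload <- lapply(decisions, function(d) {
    list(patient_id = d$patient_id, status = d$status,
         gamma_prime = d$gamma_prime, delta = d$delta, call = d$call,
         patches = if (nrow(d$patches)) d$patches[, c("rank", "xi", "omega", "gamma")]
                   else list())
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
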