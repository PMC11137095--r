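# Cohort orchestration: stratified patient split, end-to-end pipeline runs,
# confusion-matrix metrics.

#' Stratified patient split
#'
#' Samples `train_frac` of each label stratum (rounded) into the training
#' set, the complement into the test set; patient-disjoint and deterministic
#' under the seed.
#'
#' @param cohort data frame with `patient_id` and `label` columns.
#' @param train_frac training fraction (default 2/3).
#' @param seed split seed.
#' @return List with `train` and `test` cohort subsets.
#' @export
stratified_split <- function(cohort, train_frac = 2 / 3, seed = 1L) {
  stopifnot(all(c("patient_id", "label") %in% names(cohort)),
            !anyDuplicated(cohort$patient_id))
  idx_tr <- integer(0)
  for (lab in unique(cohort$label)) {
    idx <- which(cohort$label == lab)
    if (length(idx) < 2L) stop("label stratum '", lab, "' has fewer than 2 patients")
    k <- round(length(idx) * train_frac)
    k <- min(max(k, 1L), length(idx) - 1L)   # both subsets non-empty
    idx_tr <- c(idx_tr, with_seed(subseed(seed, lab), sample(idx, k)))
  }
  list(train = cohort[sort(idx_tr), , drop = FALSE],
       test = cohort[setdiff(seq_len(nrow(cohort)), idx_tr), , drop = FALSE])
}

#' Run the full pipeline over a cohort
#'
#' For each patient: obtain the slide (render its synthetic spec or read its
#' file), select foreground patches, score them through the segmenter
#' backend, sample representatives, classify and aggregate. A failure in one
#' patient is recorded and the run continues. Slides without representative
#' patches come back with status `"unclassifiable"`.
#'
#' @param cohort cohort data frame; slides come from a `spec` list-column
#'   ([synthetic_slide_spec()]) or a `slide_path` column.
#' @param segmenter segmenter backend.
#' @param classifier classifier backend.
#' @param cfg configuration list from [default_config()].
#' @return List: `decisions` (list of `slide_decision`), `calls` (data
#'   frame patient_id / status / gamma_prime / call), `log` (per-patient
#'   stage counts).
#' @export
run_pipeline <- function(cohort, segmenter, classifier,
                         cfg = default_config()) {
  fps_cfg <- do.call(fps_config, cfg$fps[names(cfg$fps) != "patch_size"])
  decisions <- vector("list", nrow(cohort))
  log <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    rec <- list(patient_id = pid)
    decisions[[i]] <- tryCatch({
      if (!is.null(cohort$spec) && !is.null(cohort$spec[[i]])) {
        slide <- render_slide(cohort$spec[[i]], pid)
        pyramid <- slide$pyramid
        info <- list(patient_id = pid, label = slide$label,
                     class_map = slide$truth$class_map)
      } else {
        pyramid <- read_pyramid(cohort$slide_path[i], patient_id = pid)
        info <- list(patient_id = pid,
                     label = if (!is.null(cohort$label)) cohort$label[i])
        if (!is.null(cohort$class_map_path) &&
            !is.na(cohort$class_map_path[i]) &&
            file.exists(cohort$class_map_path[i])) {
          cm <- png::readPNG(cohort$class_map_path[i])
          info$class_map <- matrix(as.integer(round(cm * 2)), nrow(cm), ncol(cm))
        }
      }
      fg <- withCallingHandlers(
        select_foreground_patches(pyramid, size = cfg$fps$patch_size,
                                  cfg = fps_cfg),
        warning = function(w) invokeRestart("muffleWarning"))
      rec$n_foreground <- nrow(fg$refs)
      sc <- score_patches(pyramid, fg$refs, segmenter,
                          alpha = cfg$attention$alpha,
                          fill = cfg$attention$fill, info_base = info)
      rec$n_valid <- sum(sc$scores$valid)
      cand <- sc$scores[sc$scores$valid, , drop = FALSE]
      sel <- withCallingHandlers(
        ips_sample(cand, delta = cfg$ips$delta, max_n = cfg$ips$max_n,
                   metric = cfg$ips$metric),
        warning = function(w) invokeRestart("muffleWarning"))
      rec$n_representative <- nrow(sel)
      inputs <- sc$cleaned
      if (!isTRUE(cfg$wsid$use_cleaned) && nrow(sel) > 0L) {
        inputs <- lapply(stats::setNames(seq_len(nrow(sel)), sel$patch_id),
                         function(j) extract_patch(pyramid, sel[j, ]))
      }
      decide_slide(sel, inputs, classifier, delta = cfg$wsid$delta,
                   info_base = info)
    }, error = function(e) {
      rec$error <<- conditionMessage(e)
      structure(list(patient_id = pid, status = "error",
                     gamma_prime = NA_real_, delta = cfg$wsid$delta,
                     call = NA_character_, patches = data.frame(),
                     error = conditionMessage(e)),
                class = "slide_decision")
    })
    log[[i]] <- rec
  }
  calls <- data.frame(
    patient_id = vapply(decisions, `[[`, character(1), "patient_id"),
    status = vapply(decisions, `[[`, character(1), "status"),
    gamma_prime = vapply(decisions, `[[`, numeric(1), "gamma_prime"),
    call = vapply(decisions, `[[`, character(1), "call"),
    stringsAsFactors = FALSE)
  list(decisions = decisions, calls = calls, log = log)
}

#' Confusion-matrix metrics for slide calls
#'
#' MSI-High is the positive class by default (the clinical screening
#' framing). Unclassifiable or errored patients are excluded from the
#' confusion matrix and reported separately, never forced into a class.
#'
#' @param calls data frame with `patient_id` and `call` (from
#'   [run_pipeline()]'s `calls`, or any prediction table).
#' @param truths data frame with `patient_id` and `label`; a `subtype`
#'   column adds a per-subtype breakdown.
#' @param positive_class label counted as positive.
#' @return List of class `metrics_report`: counts (TP, FP, TN, FN),
#'   `accuracy`, `precision`, `sensitivity`, `f_measure`,
#'   `n_unclassified`, and `by_subtype` when available.
#' @export
compute_metrics <- function(calls, truths, positive_class = "MSI-High") {
  m <- merge(calls, truths, by = "patient_id")
  if (nrow(m) == 0L) stop("no patients shared between calls and truths")
  usable <- !is.na(m$call)
  if ("status" %in% names(m)) usable <- usable & m$status == "classified"
  one <- function(sub) {
    tp <- sum(sub$call == positive_class & sub$label == positive_class)
    fp <- sum(sub$call == positive_class & sub$label != positive_class)
    tn <- sum(sub$call != positive_class & sub$label != positive_class)
    fn <- sum(sub$call != positive_class & sub$label == positive_class)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    list(TP = tp, FP = fp, TN = tn, FN = fn,
         accuracy = (tp + tn) / nrow(sub), precision = prec,
         sensitivity = sens, f_measure = f)
  }
  rep <- one(m[usable, , drop = FALSE])
  rep$positive_class <- positive_class
  rep$n_unclassified <- sum(!usable)
  if ("subtype" %in% names(m)) {
    rep$by_subtype <- lapply(split(m[usable, , drop = FALSE],
                                   m$subtype[usable]), one)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics (positive = %s): accuracy %.3f, precision %.3f, ",
                     "sensitivity %.3f, F %.3f  [TP %d FP %d TN %d FN %d; ",
                     "%d unclassified]\n"),
              x$positive_class, x$accuracy, x$precision, x$sensitivity,
              x$f_measure, x$TP, x$FP, x$TN, x$FN, x$n_unclassified))
  invisible(x)
}
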