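# Cohort orchestration: stratified split, pipeline runs, metrics.

test_that("stratified split respects strata, rounding and determinism", {
  cohort <- data.frame(patient_id = sprintf("P%03d", 1:100),
                       label = rep(c("MSI-High", "MSI-Low"), c(30, 70)))
  sp <- stratified_split(cohort, seed = 4L)
  expect_equal(sum(sp$train$label == "MSI-High"), 20L)
  expect_true(sum(sp$train$label == "MSI-Low") %in% c(46L, 47L))
  # partition: disjoint, union is the cohort
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0L)
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id),
                  cohort$patient_id)
  sp2 <- stratified_split(cohort, seed = 4L)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)
  tiny <- data.frame(patient_id = c("a", "b", "c"),
                     label = c("MSI-High", "MSI-Low", "MSI-Low"))
  expect_error(stratified_split(tiny), "fewer than 2")
})

test_that("metrics match hand arithmetic and the brute-force counter", {
  perfect <- data.frame(patient_id = letters[1:4],
                        call = c("MSI-High", "MSI-High", "MSI-Low", "MSI-Low"))
  truth <- data.frame(patient_id = letters[1:4],
                      label = c("MSI-High", "MSI-High", "MSI-Low", "MSI-Low"))
  m <- compute_metrics(perfect, truth)
  expect_equal(unlist(m[c("accuracy", "precision", "sensitivity", "f_measure")]),
               c(accuracy = 1, precision = 1, sensitivity = 1, f_measure = 1))
  # TP 9, FP 1, FN 0, TN 10
  pred20 <- data.frame(patient_id = sprintf("p%02d", 1:20),
                       call = rep(c("MSI-High", "MSI-Low"), c(10, 10)))
  truth20 <- data.frame(patient_id = sprintf("p%02d", 1:20),
                        label = c(rep("MSI-High", 9), rep("MSI-Low", 11)))
  m2 <- compute_metrics(pred20, truth20)
  expect_equal(m2$precision, 0.9)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$accuracy, 0.95)
  expect_equal(m2$f_measure, 2 * 0.9 / 1.9)
  # all-one-class predictions on balanced truth: accuracy one half
  allhi <- data.frame(patient_id = letters[1:4], call = rep("MSI-High", 4))
  expect_equal(compute_metrics(allhi, truth)$accuracy, 0.5)
  # agreement with an independent confusion counter on random vectors
  set.seed(64)
  for (trial in 1:100) {
    n <- sample(5:40, 1)
    pred <- sample(c("MSI-High", "MSI-Low"), n, replace = TRUE)
    lab <- sample(c("MSI-High", "MSI-Low"), n, replace = TRUE)
    calls <- data.frame(patient_id = seq_len(n), call = pred)
    tr <- data.frame(patient_id = seq_len(n), label = lab)
    got <- compute_metrics(calls, tr)
    want <- brute_confusion(pred, lab, "MSI-High")
    expect_equal(c(TP = got$TP, FP = got$FP, TN = got$TN, FN = got$FN), want)
  }
  expect_error(compute_metrics(perfect, data.frame(patient_id = "zz",
                                                   label = "MSI-Low")),
               "no patients")
})

test_that("a blank-slide cohort is unclassifiable without crashes", {
  co <- simulate_cohort(2L, seed = 13L, size = 256L, levels = 3L,
                        n_markers = 0L, noise_sd = 0,
                        amounts = list(tissue_h = 0, tissue_e = 0,
                                       tumor_h = 0, tumor_e = 0))
  cfg <- default_config(); cfg$fps$patch_size <- 64L
  res <- run_pipeline(co, mock_segmenter(0, 1L), mock_classifier(1, 0, 1L), cfg)
  expect_true(all(res$calls$status == "unclassifiable"))
  expect_true(all(is.na(res$calls$call)))
  m <- compute_metrics(res$calls, co)
  expect_equal(m$n_unclassified, 2L)
})

test_that("pipeline decisions serialize to stable JSON", {
  co <- simulate_cohort(2L, seed = 29L, size = 256L, levels = 3L,
                        n_tumor = 1L, tumor_radius = c(0.15, 0.22))
  cfg <- default_config(); cfg$fps$patch_size <- 64L
  res <- run_pipeline(co, mock_segmenter(0.05, 3L),
                      mock_classifier(0.8, 0.05, 3L), cfg)
  f1 <- withr::local_tempfile(fileext = ".json")
  write_decisions_json(res$decisions, f1)
  doc <- jsonlite::read_json(f1)
  expect_length(doc, 2L)
  expect_identical(doc[[1]]$patient_id, "P001")
  expect_true(all(c("gamma_prime", "call", "patches") %in% names(doc[[1]])))
})

test_that("per-patient failures are contained, not fatal", {
  co <- data.frame(patient_id = c("ok", "broken"), label = "MSI-Low",
                   stringsAsFactors = FALSE)
  co$spec <- I(list(small_spec(seed = 3L, n_tumor = 1L), NULL))
  co$slide_path <- c(NA, "/nonexistent/slide.tif")
  cfg <- default_config(); cfg$fps$patch_size <- 64L
  res <- run_pipeline(co, mock_segmenter(0, 1L), mock_classifier(1, 0, 1L), cfg)
  expect_identical(res$calls$status, c("classified", "error"))
  expect_identical(res$calls$call[1], "MSI-Low")
})

test_that("yaml configuration overlays the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ips:", "  delta: 5", "fps:", "  patch_size: 64"), path)
  cfg <- read_config(path)
  expect_equal(cfg$ips$delta, 5)
  expect_equal(cfg$fps$patch_size, 64)
  expect_equal(cfg$ips$max_n, 50L)          # untouched defaults survive
  expect_equal(cfg$wsid$delta, 0.5)
})
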