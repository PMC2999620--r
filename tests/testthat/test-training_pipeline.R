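test_that("stratified folds balance class counts within one", {
  ann <- tiny_annotations(rep(c("case", "control"), c(20, 80)))
  f <- stratified_folds(ann, 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  tab <- table(f, ann$class_label)
  expect_true(all(tab[, "case"] == 2))
  expect_true(all(tab[, "control"] == 8))

  ann2 <- tiny_annotations(rep(c("case", "control"), c(213, 772)))
  f2 <- stratified_folds(ann2, 10, seed = 2)
  tab2 <- table(f2, ann2$class_label)
  expect_true(all(tab2[, "case"] %in% c(21, 22)))
  expect_true(all(tab2[, "control"] %in% c(77, 78)))
  expect_equal(length(f2), 985)
  expect_identical(f2, stratified_folds(ann2, 10, seed = 2))
  expect_error(stratified_folds(tiny_annotations(rep(c("case", "control"),
                                                     c(5, 50))), 10),
               "smaller than k")
})

test_that("cross-validation of a null panel sits at chance level", {
  cfg <- two_site_config(n_analytes = 5, n_cases = 107, n_controls = 386,
                         seed = 40)  # 985 samples, no signal anywhere
  co <- generate_cohort(cfg)
  cv <- cross_validate(co$matrix, co$annotations, c("A0001", "A0002", "A0003"),
                       k = 10, seed = 41)
  expect_lt(abs(cv$score - 1), 0.1)
})

test_that("cross-validation does not leak training optimism", {
  # 8 replicates at 60/210 (scaled down from 20 replicates at full size)
  worst <- -Inf
  for (r in 1:8) {
    cfg <- two_site_config(n_analytes = 4, n_cases = 30, n_controls = 105,
                           disease_markers = data.frame(analyte = 1:3,
                                                        delta = c(1, 0.8, 1.2)),
                           seed = 500 + r)
    co <- generate_cohort(cfg)
    panel <- c("A0001", "A0002", "A0003")
    clf <- train_panel(co$matrix, co$annotations, panel)
    tr <- evaluate_classifier(clf, co$matrix, co$annotations)$score
    cv <- cross_validate(co$matrix, co$annotations, panel, k = 10,
                         seed = r)$score
    worst <- max(worst, cv - tr)
  }
  expect_lt(worst, 0.05)
})

test_that("the criteria cascade counts survivors stage by stage", {
  panels <- data.frame(
    size = c(8, 9, 10, 11, 12, 12),
    panel_str = sprintf("P%d", 1:6),
    cv_score = c(1.75, 1.72, 1.80, 1.78, 1.80, 1.60),
    training_score = c(1.65, 1.75, 1.85, 1.90, 1.95, 1.92),
    training_stage1_sensitivity = c(0.9, 0.8, 0.9, 0.95, 0.9, 0.9),
    cv_stage1_sensitivity = c(0.9, 0.9, 0.86, 0.9, 0.88, 0.9),
    severe_copd_specificity = c(0.7, 0.7, 0.7, 0.6, 0.7, 0.7),
    stringsAsFactors = FALSE
  )
  res <- apply_criteria(panels, criteria_gate())
  # hand enumeration: P1 fails training score; P2 fails stage-I sens;
  # P6 fails CV score; P4 fails severe-COPD specificity; P3, P5 survive
  expect_equal(unname(res$stage_counts),
               c(6, 5, 4, 3, 3, 2))
  expect_setequal(res$survivors$panel_str, c("P3", "P5"))
  expect_true(all(diff(res$stage_counts) <= 0))
  # an empty gate keeps everything
  empty <- criteria_gate(data.frame(metric = character(0), cmp = character(0),
                                    threshold = numeric(0)))
  expect_equal(nrow(apply_criteria(panels, empty)$survivors), 6)
  expect_error(apply_criteria(panels[, -3],
                              criteria_gate()), "cv_score")
})

test_that("choose_final prefers CV score, then smaller panels, then ids", {
  s <- data.frame(cv_score = c(1.80, 1.78), size = c(12, 12),
                  panel_str = c("A;B", "C;D"), stringsAsFactors = FALSE)
  expect_equal(choose_final(s)$panel_str, "A;B")
  s2 <- data.frame(cv_score = c(1.8, 1.8), size = c(13, 12),
                   panel_str = c("A;B", "C;D"), stringsAsFactors = FALSE)
  expect_equal(choose_final(s2)$panel_str, "C;D")
  s3 <- data.frame(cv_score = c(1.8, 1.8), size = c(12, 12),
                   panel_str = c("B;C", "A;D"), stringsAsFactors = FALSE)
  expect_equal(choose_final(s3)$panel_str, "A;D")
  expect_error(choose_final(s3[0, ]), "no surviving")
})

test_that("model files freeze, round-trip, and detect tampering", {
  cfg <- two_site_config(n_analytes = 3, n_cases = 20, n_controls = 40,
                         seed = 50)
  co <- generate_cohort(cfg)
  clf <- train_panel(co$matrix, co$annotations, c("A0001", "A0003"),
                     prior_case = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(clf, path)
  back <- read_model(path)
  expect_equal(back$panel, clf$panel)
  expect_equal(back$case_models$mu, clf$case_models$mu)
  expect_equal(back$prior_case, 0.3)
  txt <- gsub("0.3", "0.9", readLines(path), fixed = TRUE)
  writeLines(txt, path)
  expect_error(read_model(path), "hash mismatch")
})

test_that("blinded verification equals unblinded evaluation and audits", {
  cfg <- two_site_config(n_analytes = 4, n_cases = 60, n_controls = 120,
                         disease_markers = data.frame(analyte = 1:2,
                                                      delta = c(1.2, 1)),
                         seed = 51)
  co <- generate_cohort(cfg)
  split <- split_samples(co$annotations, 0.25, seed = 52)
  tr <- split$role == "training"
  clf <- train_panel(co$matrix[tr, ], co$annotations[tr, ],
                     c("A0001", "A0002"))
  model_path <- withr::local_tempfile(fileext = ".json")
  write_model(clf, model_path)
  key <- make_blinding_key(co$annotations, split)
  key_path <- withr::local_tempfile(fileext = ".tsv")
  write_blinding_key(key, key_path)
  ver <- !tr
  met <- verify_blinded(model_path, co$matrix[ver, ],
                        co$annotations$barcode[ver], key_path)
  ref <- evaluate_classifier(clf, co$matrix, co$annotations, subset = ver)
  expect_equal(met$sensitivity, ref$sensitivity)
  expect_equal(met$specificity, ref$specificity)
  expect_equal(met$auc, ref$auc)
  audit <- attr(met, "audit")
  expect_equal(audit$model_hash, unname(tools::md5sum(model_path)))
  expect_equal(audit$model_content_hash,
               jsonlite::read_json(model_path)$content_hash)
  # a key missing one barcode refuses to unblind
  write_blinding_key(key[-1, ], key_path)
  expect_error(verify_blinded(model_path, co$matrix[ver, ],
                              co$annotations$barcode[ver], key_path),
               "absent from blinding key")
})

test_that("label-shuffled training scores at chance on verification", {
  cfg <- two_site_config(n_analytes = 4, n_cases = 75, n_controls = 250,
                         disease_markers = data.frame(analyte = 1:2,
                                                      delta = c(1.2, 1)),
                         seed = 53)
  co <- generate_cohort(cfg)
  split <- split_samples(co$annotations, 0.25, seed = 54)
  tr <- split$role == "training"
  ann_shuffled <- co$annotations
  withr::with_seed(55, {
    ann_shuffled$class_label[tr] <- sample(ann_shuffled$class_label[tr])
  })
  ann_shuffled$stage <- ifelse(ann_shuffled$class_label == "case", "unknown",
                               "not_applicable")
  ann_shuffled$control_subtype <- ifelse(ann_shuffled$class_label == "control",
                                         "benign_nodule", "not_applicable")
  clf <- train_panel(co$matrix[tr, ], ann_shuffled[tr, ], c("A0001", "A0002"))
  met <- evaluate_classifier(clf, co$matrix, co$annotations, subset = !tr)
  expect_lt(abs(met$score - 1), 0.25)
})

test_that("subgroup metrics mirror the overall evaluation structure", {
  cfg <- two_site_config(n_analytes = 3, n_cases = 40, n_controls = 80,
                         disease_markers = data.frame(analyte = 1, delta = 1),
                         seed = 56)
  co <- generate_cohort(cfg)
  ann <- co$annotations
  clf <- train_panel(co$matrix, ann, "A0001")
  # single-level grouping equals the overall evaluation
  ann$smoking_status <- "current"
  single <- subgroup_metrics(clf, co$matrix, ann, "smoking_status")
  expect_length(single, 1)
  overall <- evaluate_classifier(clf, co$matrix, ann)
  expect_equal(single$current$score, overall$score)
  # gold-grade groups contain no cases: sensitivity absent, specificity not
  gg <- subgroup_metrics(clf, co$matrix, co$annotations, "gold_grade")
  ctrl_only <- gg[setdiff(names(gg), "unknown")]
  for (m in ctrl_only) {
    expect_true(is.na(m$sensitivity))
    expect_false(is.na(m$specificity))
  }
  # median splits produce two complementary levels
  ages <- subgroup_metrics(clf, co$matrix, co$annotations, "age")
  expect_length(ages, 2)
})
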