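# Final classifier construction: stratified cross-validation, the
# pre-specified criteria cascade, final panel choice, model freezing, and
# blinded verification scoring.

#' Class-stratified fold assignment
#'
#' Shuffles each class independently and deals its members cyclically over
#' the k folds, so per-fold class counts differ from exact proportionality
#' by at most one. Seed-deterministic.
#'
#' @param ann Annotation data.frame.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per annotation row.
#' @export
stratified_folds <- function(ann, k = 10L, seed = 1L) {
  classes <- split(seq_len(nrow(ann)), ann$class_label)
  small <- names(classes)[lengths(classes) < k]
  if (length(small))
    stop("class smaller than k folds: ", paste(small, collapse = ", "))
  folds <- integer(nrow(ann))
  withr::with_seed(seed, {
    for (idx in classes)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  })
  folds
}

#' Pooled k-fold cross-validation of a panel
#'
#' For each fold, the per-class marginals of every panel analyte are re-fit
#' on the other k-1 folds and the held-out samples are scored; pooled
#' metrics come from pooled confusion counts (micro-average), so a single
#' sensitivity/specificity pair is reported.
#'
#' @param values Analyte matrix (training samples).
#' @param ann Annotations covering the matrix samples.
#' @param panel Character vector of analyte ids.
#' @param k Number of folds (default 10).
#' @param prior_case Class prior.
#' @param seed Integer seed for the fold assignment.
#' @return List of class `cv_result`: `folds` (assignment), `per_fold`
#'   (data.frame of fold confusion counts), and pooled `sensitivity`,
#'   `specificity`, `score`, `stage1_sensitivity`, `auc`.
#' @export
cross_validate <- function(values, ann, panel, k = 10L, prior_case = 0.5,
                           seed = 1L) {
  check_matrix_annotations(values, ann)
  ann <- ann[match(rownames(values), ann$sample_id), ]
  folds <- stratified_folds(ann, k, seed)
  post <- numeric(nrow(values))
  per_fold <- data.frame(fold = seq_len(k), tp = 0L, fn = 0L,
                         tn = 0L, fp = 0L)
  for (f in seq_len(k)) {
    train <- folds != f
    clf <- train_panel(values[train, , drop = FALSE],
                       ann[train, , drop = FALSE], panel, prior_case)
    held <- folds == f
    post[held] <- posterior_case(clf, values[held, , drop = FALSE])
    is_case <- ann$class_label[held] == "case"
    call <- post[held] > 0.5
    per_fold[f, 2:5] <- c(sum(is_case & call), sum(is_case & !call),
                          sum(!is_case & !call), sum(!is_case & call))
  }
  tp <- sum(per_fold$tp); fn <- sum(per_fold$fn)
  tn <- sum(per_fold$tn); fp <- sum(per_fold$fp)
  is_case <- ann$class_label == "case"
  stage1 <- is_case & ann$stage == "I"
  structure(list(
    folds = folds,
    per_fold = per_fold,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    score = tp / (tp + fn) + tn / (tn + fp),
    stage1_sensitivity = if (any(stage1))
      sum(stage1 & post > 0.5) / sum(stage1) else NA_real_,
    auc = auc_concordance(post[is_case], post[!is_case])
  ), class = "cv_result")
}

#' Pre-specified criteria gate
#'
#' Ordered cascade of (metric, comparator, threshold) criteria. The
#' defaults mirror the study's pre-specified cascade: training score >=
#' 1.7, training stage-I sensitivity >= 0.85, cross-validated score >=
#' 1.7, cross-validated stage-I sensitivity >= 0.85, and specificity >=
#' 0.65 among controls with severe airflow obstruction.
#'
#' @param criteria Data frame with columns `metric`, `cmp` (`">="` or
#'   `"<="`), `threshold`.
#' @return Data frame of class `criteria_gate`.
#' @export
criteria_gate <- function(criteria = NULL) {
  if (is.null(criteria))
    criteria <- data.frame(
      metric = c("training_score", "training_stage1_sensitivity",
                 "cv_score", "cv_stage1_sensitivity",
                 "severe_copd_specificity"),
      cmp = ">=",
      threshold = c(1.7, 0.85, 1.7, 0.85, 0.65),
      stringsAsFactors = FALSE
    )
  stopifnot(all(c("metric", "cmp", "threshold") %in% colnames(criteria)),
            all(criteria$cmp %in% c(">=", "<=")))
  structure(criteria, class = c("criteria_gate", "data.frame"))
}

#' Apply a criteria cascade to candidate panels
#'
#' Criteria are applied in order; the number of panels surviving each
#' stage is recorded (the cascade pattern is monotone non-increasing).
#'
#' @param panels Data frame with one row per panel whose columns include
#'   every gate metric.
#' @param gate A [criteria_gate()].
#' @return List with `survivors` (rows of `panels` passing every
#'   criterion) and `stage_counts` (named integer vector, starting with
#'   `"initial"`).
#' @export
apply_criteria <- function(panels, gate = criteria_gate()) {
  counts <- c(initial = nrow(panels))
  keep <- panels
  for (i in seq_len(nrow(gate))) {
    metric <- gate$metric[i]
    if (!metric %in% colnames(keep))
      stop("gate metric missing from panels: ", metric)
    v <- keep[[metric]]
    if (anyNA(v))
      stop("gate metric has missing values: ", metric)
    pass <- if (gate$cmp[i] == ">=") v >= gate$threshold[i]
            else v <= gate$threshold[i]
    keep <- keep[pass, , drop = FALSE]
    counts[paste(metric, gate$cmp[i], gate$threshold[i])] <- nrow(keep)
  }
  list(survivors = keep, stage_counts = counts)
}

#' Choose the final panel among gate survivors
#'
#' Maximal cross-validated score; ties broken by smaller panel, then
#' lexicographically on the sorted analyte ids.
#'
#' @param survivors Data frame with columns `cv_score`, `size`,
#'   `panel_str`.
#' @return The selected row (single-row data frame).
#' @export
choose_final <- function(survivors) {
  if (!nrow(survivors)) stop("no surviving panel to choose from")
  o <- order(-survivors$cv_score, survivors$size, survivors$panel_str)
  survivors[o[1], , drop = FALSE]
}

#' Freeze a trained classifier to a JSON model file
#'
#' The file carries the panel, the per-class marginal parameters, the
#' prior, and a content hash over those fields, so the verification stage
#' can prove it scored the pre-registered model.
#'
#' @param clf A `panel_classifier`.
#' @param path Output path.
#' @param extra Optional named list echoed into the file (config, seeds).
#' @return `path`, invisibly.
#' @export
write_model <- function(clf, path, extra = NULL) {
  payload <- list(
    panel = clf$panel,
    case_models = clf$case_models,
    control_models = clf$control_models,
    prior_case = clf$prior_case
  )
  payload$content_hash <- model_content_hash(payload)
  if (!is.null(extra)) payload$run_info <- extra
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @keywords internal
model_content_hash <- function(payload) {
  core <- payload[c("panel", "case_models", "control_models", "prior_case")]
  txt <- jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA)
  f <- tempfile(); on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Read a frozen model file back into a classifier
#'
#' Verifies the stored content hash before returning.
#'
#' @param path Path to a model JSON written by [write_model()].
#' @return A `panel_classifier`.
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  clf <- structure(list(panel = m$panel,
                        case_models = m$case_models,
                        control_models = m$control_models,
                        prior_case = m$prior_case),
                   class = "panel_classifier")
  if (!identical(unname(m$content_hash), unname(model_content_hash(clf))))
    stop("model file content hash mismatch: file was altered after freezing")
  clf
}

#' Score blinded verification samples against a frozen model
#'
#' The only operation that accepts a blinding key. The classifier must
#' arrive as a frozen model file (so it cannot have seen the key), the
#' samples are identified by barcode only, and the key supplies the true
#' class labels after scoring. An audit record with the model and key
#' hashes is attached.
#'
#' @param model_path Path to a frozen model JSON ([write_model()]).
#' @param values Analyte matrix of the verification samples (rows named by
#'   sample id).
#' @param barcodes Character vector of barcodes, one per matrix row.
#' @param key_path Path to the blinding key TSV (barcode, class_label).
#' @return `classifier_metrics` with an `audit` attribute (model hash, key
#'   hash, timestamp).
#' @export
verify_blinded <- function(model_path, values, barcodes, key_path) {
  clf <- read_model(model_path)
  validate_analyte_matrix(values)
  if (length(barcodes) != nrow(values))
    stop("need one barcode per verification sample")
  key <- read_blinding_key(key_path)
  missing <- setdiff(barcodes, key$barcode)
  if (length(missing))
    stop("barcode(s) absent from blinding key: ",
         paste(utils::head(missing, 5), collapse = ", "))
  truth <- key$class_label[match(barcodes, key$barcode)]
  post <- posterior_case(clf, values)
  is_case <- truth == "case"
  call <- post > 0.5
  tp <- sum(is_case & call); fn <- sum(is_case & !call)
  tn <- sum(!is_case & !call); fp <- sum(!is_case & call)
  metrics <- structure(list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    score = tp / (tp + fn) + tn / (tn + fp),
    auc = auc_concordance(post[is_case], post[!is_case]),
    stage1_sensitivity = NA_real_,
    sens_ci = wilson_ci(tp, tp + fn),
    spec_ci = wilson_ci(tn, tn + fp),
    tp = tp, fn = fn, tn = tn, fp = fp
  ), class = "classifier_metrics")
  attr(metrics, "audit") <- list(
    model_hash = unname(tools::md5sum(model_path)),
    model_content_hash = model_content_hash(clf),
    key_hash = unname(tools::md5sum(key_path)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  metrics
}

#' Classifier metrics within demographic subgroups
#'
#' Splits samples by age (median split), smoking status, pack-years
#' (median split), or airflow-obstruction grade and evaluates the
#' classifier in each level. Subgroups lacking a class report that metric
#' as `NA`, mirroring e.g. specificity-only reporting when spirometry is
#' unavailable for cases.
#'
#' @param clf A `panel_classifier`.
#' @param values Analyte matrix.
#' @param ann Annotations covering the matrix samples.
#' @param grouping One of `"age"`, `"smoking_status"`, `"pack_years"`,
#'   `"gold_grade"`.
#' @return Named list of `classifier_metrics`, one per subgroup level.
#' @export
subgroup_metrics <- function(clf, values, ann,
                             grouping = c("age", "smoking_status",
                                          "pack_years", "gold_grade")) {
  grouping <- match.arg(grouping)
  check_matrix_annotations(values, ann)
  ann <- ann[match(rownames(values), ann$sample_id), ]
  groups <- switch(grouping,
    age = {
      med <- stats::median(ann$age, na.rm = TRUE)
      ifelse(is.na(ann$age), NA,
             ifelse(ann$age <= med, sprintf("age<=%g", med),
                    sprintf("age>%g", med)))
    },
    pack_years = {
      med <- stats::median(ann$pack_years, na.rm = TRUE)
      ifelse(is.na(ann$pack_years), NA,
             ifelse(ann$pack_years <= med, sprintf("pack_years<=%g", med),
                    sprintf("pack_years>%g", med)))
    },
    smoking_status = ann$smoking_status,
    gold_grade = ann$gold_grade
  )
  levels <- sort(unique(groups[!is.na(groups)]))
  out <- lapply(stats::setNames(levels, levels), function(g)
    evaluate_classifier(clf, values, ann, subset = !is.na(groups) & groups == g))
  out
}
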