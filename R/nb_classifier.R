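# Diagonal-covariance (naive Bayes) classifier over log concentrations.
#
# Each class is modelled as a multivariate normal in log-RFU with diagonal
# covariance, i.e. independent log-normal marginals per marker; the
# marginal parameters come from the Gauss-Newton CDF fit. The classifier
# score for a panel is its sensitivity plus specificity at the posterior
# 0.5 operating point.

#' Train a naive Bayes panel classifier
#'
#' Fits per-class log-normal marginals ([fit_lognormal_cdf()]) for every
#' panel analyte and stores them with the class prior. Fit non-convergence
#' is not fatal: the moment estimates are used and flagged in the stored
#' `converged` column.
#'
#' @param values Analyte matrix (training samples only).
#' @param ann Annotations covering the matrix samples.
#' @param panel Character vector of analyte ids.
#' @param prior_case Prior probability of the case class, in (0, 1).
#' @return Object of class `panel_classifier`: list with `panel`,
#'   `case_models`, `control_models` (data.frames analyte_id/mu/sigma/
#'   converged) and `prior_case`.
#' @export
train_panel <- function(values, ann, panel, prior_case = 0.5) {
  check_matrix_annotations(values, ann)
  stopifnot(prior_case > 0, prior_case < 1)
  if (!all(panel %in% colnames(values)))
    stop("panel analytes missing from matrix: ",
         paste(setdiff(panel, colnames(values)), collapse = ", "))
  ann <- ann[match(rownames(values), ann$sample_id), ]
  is_case <- ann$class_label == "case"
  if (!sum(is_case) || !sum(!is_case))
    stop("both classes must be present to train")
  fit_class <- function(mask) {
    fits <- lapply(panel, function(a) fit_lognormal_cdf(values[mask, a]))
    data.frame(
      analyte_id = panel,
      mu = vapply(fits, `[[`, numeric(1), "mu"),
      sigma = vapply(fits, `[[`, numeric(1), "sigma"),
      converged = vapply(fits, function(f) f$diagnostics$converged, logical(1)),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    panel = panel,
    case_models = fit_class(is_case),
    control_models = fit_class(!is_case),
    prior_case = prior_case
  ), class = "panel_classifier")
}

#' @export
print.panel_classifier <- function(x, ...) {
  cat(sprintf("naive Bayes panel classifier: %d marker(s), prior_case = %g\n",
              length(x$panel), x$prior_case))
  cat("panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Log-likelihood ratio (case vs control) for samples
#'
#' Sum over panel markers of the difference of normal log densities of the
#' log value under the case and control marginals; additive in markers.
#'
#' @param clf A `panel_classifier`.
#' @param values Analyte matrix containing every panel analyte (one row per
#'   sample to score).
#' @return Named numeric vector of LLRs, one per sample row.
#' @export
log_likelihood_ratio <- function(clf, values) {
  if (!all(clf$panel %in% colnames(values)))
    stop("sample values missing panel analyte(s): ",
         paste(setdiff(clf$panel, colnames(values)), collapse = ", "))
  x <- log(values[, clf$panel, drop = FALSE])
  cm <- clf$case_models; km <- clf$control_models
  llr <- rep(0, nrow(x))
  for (j in seq_along(clf$panel)) {
    llr <- llr +
      stats::dnorm(x[, j], cm$mu[j], cm$sigma[j], log = TRUE) -
      stats::dnorm(x[, j], km$mu[j], km$sigma[j], log = TRUE)
  }
  names(llr) <- rownames(values)
  llr
}

#' Posterior probability of the case class
#'
#' `logistic(LLR + log(prior / (1 - prior)))`; a sample is called a case
#' when its posterior exceeds 0.5.
#'
#' @inheritParams log_likelihood_ratio
#' @return Named numeric vector of posteriors in (0, 1).
#' @export
posterior_case <- function(clf, values) {
  llr <- log_likelihood_ratio(clf, values)
  stats::plogis(llr + stats::qlogis(clf$prior_case))
}

#' Area under the ROC curve by pairwise concordance
#'
#' Fraction of (case, control) pairs in which the case scores higher; ties
#' count one half. Computed from mid-ranks, which is exactly the pairwise
#' count.
#'
#' @param case_scores,control_scores Numeric score vectors.
#' @return AUC in [0, 1].
#' @export
auc_concordance <- function(case_scores, control_scores) {
  n1 <- length(case_scores); n0 <- length(control_scores)
  if (!n1 || !n0) return(NA_real_)
  r <- rank(c(case_scores, control_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wilson 95% score interval for a binomial proportion
#' @param k Successes. @param n Trials.
#' @return Length-2 vector (lower, upper), or NAs when `n` is 0.
#' @keywords internal
wilson_ci <- function(k, n, conf = 0.95) {
  if (!n) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' Evaluate a classifier on annotated samples
#'
#' Sensitivity and specificity at the posterior 0.5 operating point, their
#' sum (the panel score), AUC by pairwise concordance, Wilson 95%
#' intervals, and stage-I-restricted sensitivity when stage data are
#' present. Metrics whose class is absent from the subset are `NA` rather
#' than 0.
#'
#' @param clf A `panel_classifier`.
#' @param values Analyte matrix.
#' @param ann Annotations covering the matrix samples.
#' @param subset Optional logical mask or character sample ids restricting
#'   evaluation.
#' @return List of class `classifier_metrics`: `sensitivity`,
#'   `specificity`, `score`, `auc`, `stage1_sensitivity`, `sens_ci`,
#'   `spec_ci`, and the confusion counts `tp`, `fn`, `tn`, `fp`.
#' @export
evaluate_classifier <- function(clf, values, ann, subset = NULL) {
  check_matrix_annotations(values, ann)
  ann <- ann[match(rownames(values), ann$sample_id), ]
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- rownames(values) %in% subset
    values <- values[subset, , drop = FALSE]
    ann <- ann[subset, , drop = FALSE]
  }
  if (!nrow(values)) stop("subset selects no samples")
  post <- posterior_case(clf, values)
  is_case <- ann$class_label == "case"
  call_case <- post > 0.5
  tp <- sum(is_case & call_case); fn <- sum(is_case & !call_case)
  tn <- sum(!is_case & !call_case); fp <- sum(!is_case & call_case)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  stage1 <- is_case & ann$stage == "I"
  stage1_sens <- if (sum(stage1) > 0)
    sum(stage1 & call_case) / sum(stage1) else NA_real_
  structure(list(
    sensitivity = sens,
    specificity = spec,
    score = if (!is.na(sens) && !is.na(spec)) sens + spec else NA_real_,
    auc = auc_concordance(post[is_case], post[!is_case]),
    stage1_sensitivity = stage1_sens,
    sens_ci = wilson_ci(tp, tp + fn),
    spec_ci = wilson_ci(tn, tn + fp),
    tp = tp, fn = fn, tn = tn, fp = fp
  ), class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  cat(sprintf("sensitivity %s  specificity %s  score %s  AUC %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$score), fmt(x$auc)))
  invisible(x)
}
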