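# Shared fixtures and independent oracles, built in code at test time.

# Small two-site configuration; n_cases/n_controls are per site.
two_site_config <- function(n_analytes = 10, n_cases = 30, n_controls = 60,
                            disease_markers = NULL,
                            site_artifact_markers = NULL, seed = 1L) {
  sites <- data.frame(
    site = c("S1", "S2"),
    n_cases = n_cases,
    n_controls_benign_nodule = ceiling(n_controls / 2),
    n_controls_smoker = floor(n_controls / 2),
    stringsAsFactors = FALSE
  )
  synthetic_config(n_analytes = n_analytes, sites = sites,
                   disease_markers = disease_markers,
                   site_artifact_markers = site_artifact_markers,
                   seed = seed)
}

# Minimal hand-built annotation table.
tiny_annotations <- function(class_label, site = "S1",
                             control_subtype = NULL, stage = NULL,
                             gold_grade = "unknown") {
  n <- length(class_label)
  if (is.null(control_subtype))
    control_subtype <- ifelse(class_label == "case", "not_applicable",
                              "benign_nodule")
  if (is.null(stage))
    stage <- ifelse(class_label == "case", "I", "not_applicable")
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    class_label = class_label,
    site = rep_len(site, n),
    control_subtype = control_subtype,
    stage = stage,
    histology = "unknown",
    age = 60,
    sex = "unknown",
    smoking_status = "unknown",
    pack_years = 30,
    gold_grade = rep_len(gold_grade, n),
    barcode = sprintf("B%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

# Matrix with given per-sample values for each analyte column.
tiny_matrix <- function(values_by_analyte, sample_ids) {
  m <- do.call(cbind, values_by_analyte)
  rownames(m) <- sample_ids
  m
}

# Brute-force two-sample KS: sup over every pooled evaluation point of the
# right-continuous empirical CDF difference.
ks_brute <- function(x, y) {
  pts <- c(x, y)
  d <- vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1))
  max(d)
}

# Brute-force AUC: loop over all case-control pairs, ties count 1/2.
auc_brute <- function(case_scores, control_scores) {
  s <- 0
  for (a in case_scores) for (b in control_scores)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(case_scores) * length(control_scores))
}

# Exhaustive panel search oracle: score every subset of `candidates` up to
# `max_size` by training the classifier and evaluating on the same data.
exhaustive_best <- function(values, ann, candidates, max_size,
                            prior_case = 0.5) {
  out <- list()
  for (k in seq_len(max_size)) {
    combos <- utils::combn(sort(candidates), k, simplify = FALSE)
    scores <- vapply(combos, function(p) {
      clf <- train_panel(values, ann, p, prior_case)
      evaluate_classifier(clf, values, ann)$score
    }, numeric(1))
    best <- which(scores == max(scores))
    keys <- vapply(combos[best], paste, character(1), collapse = ";")
    pick <- best[order(keys)][1]
    out[[k]] <- list(size = k, panel = combos[[pick]], score = scores[pick])
  }
  out
}

# Hand-built one-marker classifier with stated normal parameters.
manual_classifier <- function(analyte = "A1", mu_case, sigma_case,
                              mu_ctrl, sigma_ctrl, prior_case = 0.5) {
  structure(list(
    panel = analyte,
    case_models = data.frame(analyte_id = analyte, mu = mu_case,
                             sigma = sigma_case, converged = TRUE,
                             stringsAsFactors = FALSE),
    control_models = data.frame(analyte_id = analyte, mu = mu_ctrl,
                                sigma = sigma_ctrl, converged = TRUE,
                                stringsAsFactors = FALSE),
    prior_case = prior_case
  ), class = "panel_classifier")
}
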