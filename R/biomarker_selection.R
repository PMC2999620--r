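# Six-analysis candidate-selection procedure.
#
# The training set is split into two case/control populations (cases vs
# benign-nodule controls; cases vs all other smoker controls). For each
# population three candidate sets are screened (KS >= threshold within
# every evaluable site; KS >= threshold with all sites pooled; both), each
# is explored by beam search, and analytes appearing in at least
# `frequency_threshold` retained panels scoring >= `score_threshold` are
# qualified. The final biomarker set is the union of the six qualified
# sets, with per-analyte provenance.

#' Selection configuration
#'
#' @param ks_threshold Minimum KS distance for a candidate (default 0.3).
#' @param frequency_threshold Minimum number of qualifying panels an
#'   analyte must appear in, per analysis (default 10).
#' @param score_threshold Minimum panel score for frequency counting
#'   (default 1.7).
#' @param exclusion_list Analyte ids dropped before screening (stands in
#'   for assay-internal QC exclusions, e.g. handling-sensitive analytes
#'   flagged by [site_variability()]).
#' @param min_panel_size Smallest panel size counted toward frequency
#'   (default 2).
#' @return List of class `selection_config`.
#' @export
selection_config <- function(ks_threshold = 0.3, frequency_threshold = 10L,
                             score_threshold = 1.7,
                             exclusion_list = character(0),
                             min_panel_size = 2L) {
  stopifnot(ks_threshold >= 0, ks_threshold <= 1,
            score_threshold >= 0, score_threshold <= 2,
            frequency_threshold >= 0)
  structure(list(ks_threshold = ks_threshold,
                 frequency_threshold = frequency_threshold,
                 score_threshold = score_threshold,
                 exclusion_list = exclusion_list,
                 min_panel_size = as.integer(min_panel_size)),
            class = "selection_config")
}

#' Define the two comparison populations
#'
#' Population 1: all cases plus benign-nodule controls. Population 2: all
#' cases plus all other (smoker) controls. The masks overlap only on
#' cases.
#'
#' @param ann Annotation data.frame.
#' @return List with logical masks `population1`, `population2` over the
#'   rows of `ann`.
#' @export
define_populations <- function(ann) {
  is_case <- ann$class_label == "case"
  nodule <- ann$control_subtype == "benign_nodule"
  smoker <- ann$class_label == "control" & !nodule
  if (!any(nodule)) stop("population 1 has no benign-nodule controls")
  if (!any(smoker)) stop("population 2 has no smoker controls")
  list(population1 = is_case | nodule, population2 = is_case | smoker)
}

#' Candidate analytes passing a KS screening criterion
#'
#' @param values Analyte matrix.
#' @param ann Annotations covering the matrix samples.
#' @param population Logical mask over the matrix rows.
#' @param criterion `"per_site"` requires KS >= threshold in every
#'   evaluable site (sites lacking a case or a control within the
#'   population are skipped with a warning); `"combined"` pools all sites;
#'   `"both"` is their intersection.
#' @param config A [selection_config()].
#' @return Character vector of analyte ids.
#' @export
candidate_set <- function(values, ann, population,
                          criterion = c("per_site", "combined", "both"),
                          config = selection_config()) {
  criterion <- match.arg(criterion)
  check_matrix_annotations(values, ann)
  ann <- ann[match(rownames(values), ann$sample_id), ]
  if (!any(population)) stop("population mask selects no samples")
  keep_analytes <- setdiff(colnames(values), config$exclusion_list)
  vals <- values[population, keep_analytes, drop = FALSE]
  pann <- ann[population, , drop = FALSE]
  is_case <- pann$class_label == "case"
  if (!any(is_case) || !any(!is_case))
    stop("population must contain both classes")

  ks_set <- function(mask) {
    sub_case <- is_case & mask
    sub_ctrl <- !is_case & mask
    d <- vapply(seq_len(ncol(vals)), function(j)
      ks_two_sample(vals[sub_case, j], vals[sub_ctrl, j]), numeric(1))
    colnames(vals)[d >= config$ks_threshold]
  }

  combined <- function() ks_set(rep(TRUE, nrow(vals)))
  per_site <- function() {
    sets <- list()
    for (s in unique(pann$site)) {
      m <- pann$site == s
      if (!any(is_case & m) || !any(!is_case & m)) {
        warning(sprintf("site '%s' lacks a class in this population; skipped", s))
        next
      }
      sets[[s]] <- ks_set(m)
    }
    if (!length(sets)) stop("no evaluable site for the per-site criterion")
    Reduce(intersect, sets)
  }
  switch(criterion,
         combined = combined(),
         per_site = per_site(),
         both = intersect(per_site(), combined()))
}

#' Run the six-analysis selection and return the biomarker union
#'
#' @param values Analyte matrix (training samples only).
#' @param ann Annotations covering the matrix samples.
#' @param config A [selection_config()].
#' @param beam_cfg A [beam_config()] used for each analysis's search.
#' @param prior_case Class prior for panel scoring.
#' @param seed Integer seed, recorded and passed to each search.
#' @return List of class `selection_report`: `analyses` (per-analysis list
#'   with `population`, `criterion`, `candidates`, `frequency`,
#'   `qualified`), `union` (character vector), `provenance` (analyte ->
#'   analysis labels), `config`, `seed`.
#' @export
select_biomarkers <- function(values, ann, config = selection_config(),
                              beam_cfg = beam_config(), prior_case = 0.5,
                              seed = 1L) {
  check_matrix_annotations(values, ann)
  ann <- ann[match(rownames(values), ann$sample_id), ]
  pops <- define_populations(ann)
  analyses <- list()
  for (p in 1:2) {
    mask <- pops[[p]]
    for (crit in c("per_site", "combined", "both")) {
      label <- sprintf("population%d_%s", p, crit)
      cand <- withCallingHandlers(
        candidate_set(values, ann, mask, crit, config),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!length(cand)) {
        analyses[[label]] <- list(population = p, criterion = crit,
                                  candidates = character(0),
                                  frequency = integer(0),
                                  qualified = character(0))
        next
      }
      panels <- beam_search(values[mask, , drop = FALSE],
                            ann[mask, , drop = FALSE],
                            cand, beam_cfg, prior_case, seed)
      freq <- marker_frequency(panels, config$score_threshold,
                               config$min_panel_size)
      qualified <- names(freq)[freq >= config$frequency_threshold]
      analyses[[label]] <- list(population = p, criterion = crit,
                                candidates = cand, frequency = freq,
                                qualified = qualified)
    }
  }
  qualified_sets <- lapply(analyses, `[[`, "qualified")
  union_set <- sort(unique(unlist(qualified_sets)))
  if (all(!lengths(lapply(analyses, `[[`, "candidates"))))
    stop("selection failure: all six candidate sets are empty")
  provenance <- lapply(stats::setNames(union_set, union_set), function(a)
    names(qualified_sets)[vapply(qualified_sets, function(s) a %in% s,
                                 logical(1))])
  structure(list(analyses = analyses, union = union_set,
                 provenance = provenance, config = config, seed = seed),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection report: %d analyses, union of %d biomarkers\n",
              length(x$analyses), length(x$union)))
  for (nm in names(x$analyses)) {
    a <- x$analyses[[nm]]
    cat(sprintf("  %-24s candidates %3d  qualified %3d\n",
                nm, length(a$candidates), length(a$qualified)))
  }
  invisible(x)
}
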