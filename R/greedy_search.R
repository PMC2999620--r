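# Greedy forward beam search over marker panels.
#
# All single-marker classifiers are scored; every retained panel is then
# extended by every unused candidate, keeping the best `beam_width` unique
# panels by sensitivity + specificity at each size, until the best score
# plateaus or deteriorates. Because the naive Bayes LLR is additive in
# markers, each candidate's per-sample LLR contribution is computed once
# and panel scores reduce to thresholded sums, which the C++ kernel counts.

#' Beam search configuration
#'
#' @param beam_width Panels retained per size (default 10000).
#' @param max_panel_size Largest panel size explored (default 15).
#' @param min_panel_size_for_output Smallest size included in the returned
#'   collection (default 1; the search always builds up from size 1).
#' @param scoring `"training"` scores panels on the data they were fit to;
#'   `"cross_validated"` scores each sample with marginals fit on the other
#'   folds (pooled k-fold CV), which is slower to set up but leak-free.
#' @param cv_folds Folds for cross-validated scoring (default 10).
#' @param plateau_tol Minimum improvement that counts as progress.
#' @param plateau_patience Consecutive non-improving sizes tolerated before
#'   stopping (default 2); any deterioration stops immediately.
#' @return List of class `beam_config`.
#' @export
beam_config <- function(beam_width = 10000L, max_panel_size = 15L,
                        min_panel_size_for_output = 1L,
                        scoring = c("training", "cross_validated"),
                        cv_folds = 10L, plateau_tol = 1e-6,
                        plateau_patience = 2L) {
  stopifnot(beam_width >= 1, max_panel_size >= 1)
  structure(list(beam_width = as.integer(beam_width),
                 max_panel_size = as.integer(max_panel_size),
                 min_panel_size_for_output = as.integer(min_panel_size_for_output),
                 scoring = match.arg(scoring),
                 cv_folds = as.integer(cv_folds),
                 plateau_tol = plateau_tol,
                 plateau_patience = as.integer(plateau_patience)),
            class = "beam_config")
}

# Per-candidate LLR contribution matrix (samples x candidates). In
# cross-validated mode each sample's contribution uses marginals fit with
# its fold held out.
#' @keywords internal
candidate_llr_matrix <- function(values, ann, candidates, config, seed) {
  is_case <- ann$class_label == "case"
  logx <- log(values[, candidates, drop = FALSE])
  L <- matrix(0, nrow(values), length(candidates))
  fill <- function(rows_fit, rows_score) {
    for (j in seq_along(candidates)) {
      fc <- fit_lognormal_cdf(values[rows_fit & is_case, candidates[j]])
      fk <- fit_lognormal_cdf(values[rows_fit & !is_case, candidates[j]])
      L[rows_score, j] <<-
        stats::dnorm(logx[rows_score, j], fc$mu, fc$sigma, log = TRUE) -
        stats::dnorm(logx[rows_score, j], fk$mu, fk$sigma, log = TRUE)
    }
  }
  if (config$scoring == "training") {
    fill(rep(TRUE, nrow(values)), rep(TRUE, nrow(values)))
  } else {
    folds <- stratified_folds(ann, k = config$cv_folds, seed = seed)
    for (f in seq_len(config$cv_folds))
      fill(folds != f, folds == f)
  }
  L
}

#' Greedy forward beam search for high-scoring marker panels
#'
#' @param values Analyte matrix (training samples).
#' @param ann Annotations covering the matrix samples.
#' @param candidates Character vector of candidate analyte ids (>= 1).
#' @param config A [beam_config()].
#' @param prior_case Class prior used for the decision threshold.
#' @param seed Integer seed; only consumed by cross-validated scoring (the
#'   search itself is deterministic) but always recorded.
#' @return Data frame of retained panels at every explored size with
#'   columns `size`, `panel` (list column of analyte-id vectors),
#'   `panel_str` (ids joined by ";"), `sensitivity`, `specificity`,
#'   `score`. Attribute `"seed"` records the seed.
#' @export
beam_search <- function(values, ann, candidates, config = beam_config(),
                        prior_case = 0.5, seed = 1L) {
  check_matrix_annotations(values, ann)
  if (!length(candidates)) stop("candidate set must be non-empty")
  if (!all(candidates %in% colnames(values)))
    stop("candidates missing from matrix")
  ann <- ann[match(rownames(values), ann$sample_id), ]
  if (!any(ann$class_label == "case") || !any(ann$class_label == "control"))
    stop("both classes must be present")
  candidates <- sort(unique(candidates))
  L <- candidate_llr_matrix(values, ann, candidates, config, seed)
  is_case <- ann$class_label == "case"
  thr <- -stats::qlogis(prior_case)

  beam <- matrix(integer(0), nrow = 0, ncol = 1)
  beam_llr <- matrix(0, nrow(values), 1)
  out <- list()
  best_prev <- -Inf
  stalls <- 0L
  for (size in seq_len(config$max_panel_size)) {
    step <- beam_step_cpp(L, is_case, beam, beam_llr, thr, config$beam_width)
    if (!length(step$score)) break
    beam <- step$beam
    beam_llr <- beam_llr[, step$from_b, drop = FALSE] +
      L[, step$from_j, drop = FALSE]
    out[[size]] <- data.frame(
      size = size,
      panel_str = vapply(seq_len(ncol(beam)), function(c)
        paste(candidates[beam[, c]], collapse = ";"), character(1)),
      sensitivity = step$sensitivity,
      specificity = step$specificity,
      score = step$score,
      stringsAsFactors = FALSE
    )
    out[[size]]$panel <- lapply(seq_len(ncol(beam)),
                                function(c) candidates[beam[, c]])
    best <- step$score[1]
    if (best < best_prev - config$plateau_tol) break       # deteriorating
    if (best > best_prev + config$plateau_tol) {
      stalls <- 0L
    } else {
      stalls <- stalls + 1L
      if (stalls >= config$plateau_patience) break         # plateau
    }
    best_prev <- max(best_prev, best)
    if (ncol(beam) == 0 || nrow(beam) >= length(candidates)) break
  }
  res <- do.call(rbind, out)
  res <- res[res$size >= config$min_panel_size_for_output, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}

#' Frequency of each analyte among high-scoring retained panels
#'
#' Counts, per analyte, the retained panels with score at or above the
#' threshold that contain it.
#'
#' @param panels Data frame returned by [beam_search()].
#' @param score_threshold Minimum panel score (default 1.7).
#' @param min_size Smallest panel size counted (default 1).
#' @return Named integer vector, analyte id -> count (analytes never seen
#'   in a qualifying panel are absent).
#' @export
marker_frequency <- function(panels, score_threshold = 1.7, min_size = 1L) {
  sel <- panels$score >= score_threshold & panels$size >= min_size
  if (!any(sel)) return(stats::setNames(integer(0), character(0)))
  tab <- table(unlist(panels$panel[sel]))
  stats::setNames(as.integer(tab), names(tab))
}
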