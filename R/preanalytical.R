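# Preanalytical (between-site, within-class) variability audit.
#
# For every analyte, the disease signal (case-vs-control KS with all sites
# pooled) is contrasted with the mean KS over the between-site
# within-class comparisons (with 4 sites: 6 site pairs x 2 classes = 12).
# Analytes whose mean between-site KS reaches the flag threshold are
# handling-sensitive; ordering by (mean site KS - disease KS) separates
# preanalytical artifacts from disease markers.

#' Audit between-site variability per analyte
#'
#' @param values Analyte matrix.
#' @param ann Annotations covering the matrix samples.
#' @param flag_threshold Mean between-site KS at or above which an analyte
#'   is flagged (default 0.4).
#' @param min_cell Minimum samples a site-class cell needs for its
#'   comparisons to count (default 2); smaller cells are skipped with a
#'   warning.
#' @return Data frame of class `site_variability_report` with columns
#'   `analyte_id`, `disease_ks`, `mean_site_ks`, `delta`
#'   (`mean_site_ks - disease_ks`), `flagged`.
#' @export
site_variability <- function(values, ann, flag_threshold = 0.4,
                             min_cell = 2L) {
  check_matrix_annotations(values, ann)
  ann <- ann[match(rownames(values), ann$sample_id), ]
  sites <- sort(unique(ann$site))
  if (length(sites) < 2) stop("need at least 2 sites")
  is_case <- ann$class_label == "case"

  # evaluable site-class cells
  cells <- expand.grid(site = sites, cls = c(TRUE, FALSE),
                       stringsAsFactors = FALSE)
  cells$rows <- lapply(seq_len(nrow(cells)), function(r)
    which(ann$site == cells$site[r] & is_case == cells$cls[r]))
  small <- lengths(cells$rows) < min_cell
  if (any(small))
    warning("skipping site-class cell(s) with fewer than ", min_cell,
            " samples: ",
            paste(sprintf("%s/%s", cells$site[small],
                          ifelse(cells$cls[small], "case", "control")),
                  collapse = ", "))

  pairs <- utils::combn(sites, 2, simplify = FALSE)
  comparisons <- list()
  for (pr in pairs) for (cls in c(TRUE, FALSE)) {
    a <- cells$rows[[which(cells$site == pr[1] & cells$cls == cls)]]
    b <- cells$rows[[which(cells$site == pr[2] & cells$cls == cls)]]
    if (length(a) >= min_cell && length(b) >= min_cell)
      comparisons[[length(comparisons) + 1L]] <- list(a = a, b = b)
  }
  if (!length(comparisons)) stop("no evaluable between-site comparison")

  case_rows <- which(is_case); ctrl_rows <- which(!is_case)
  res <- t(vapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    dks <- ks_two_sample(v[case_rows], v[ctrl_rows])
    sks <- mean(vapply(comparisons, function(cp)
      ks_two_sample(v[cp$a], v[cp$b]), numeric(1)))
    c(dks, sks)
  }, numeric(2)))
  out <- data.frame(
    analyte_id = colnames(values),
    disease_ks = res[, 1],
    mean_site_ks = res[, 2],
    delta = res[, 2] - res[, 1],
    flagged = res[, 2] >= flag_threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "flag_threshold") <- flag_threshold
  attr(out, "n_comparisons") <- length(comparisons)
  class(out) <- c("site_variability_report", "data.frame")
  out
}

#' Order a site-variability report for display
#'
#' Sorts by `delta = mean_site_ks - disease_ks` descending, so
#' artifact-like analytes come first and disease-like analytes last; ties
#' are stable by analyte id.
#'
#' @param report A `site_variability_report`.
#' @return Character vector of analyte ids in display order.
#' @export
order_for_display <- function(report) {
  report$analyte_id[order(-report$delta, report$analyte_id)]
}

#' Export the two-row heat-map table
#'
#' Writes the report as a TSV (analyte_id, disease_ks, mean_site_ks,
#' delta, flagged) in display order; rendering a heat map from it is a
#' thin optional layer.
#'
#' @param report A `site_variability_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_heatmap_table <- function(report, path) {
  ord <- order(-report$delta, report$analyte_id)
  out <- report[ord, c("analyte_id", "disease_ks", "mean_site_ks",
                       "delta", "flagged")]
  out$disease_ks <- sprintf("%.17g", out$disease_ks)
  out$mean_site_ks <- sprintf("%.17g", out$mean_site_ks)
  out$delta <- sprintf("%.17g", out$delta)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
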