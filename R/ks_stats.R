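# Two-sample Kolmogorov-Smirnov screening statistics.
#
# D = sup_t |Fx(t) - Fy(t)| over the two empirical CDFs, evaluated with the
# standard right-continuous convention at pooled unique values so that tied
# RFU values (common after rounding) are handled identically by the fast
# path and the brute-force oracle used in the tests.

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Distribution-free measure of separation between two samples, in [0, 1].
#' Invariant to any strictly monotone transform applied to both samples, so
#' raw RFU and log RFU give the same value.
#'
#' @param x,y Non-empty numeric samples.
#' @return The KS distance D.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  v <- sort(unique(c(x, y)))
  Fx <- findInterval(v, sort(x)) / length(x)
  Fy <- findInterval(v, sort(y)) / length(y)
  max(abs(Fx - Fy))
}

#' Asymptotic two-sample Kolmogorov p-value
#'
#' Evaluates the Kolmogorov series
#' `p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 ne D^2)` with effective sample
#' size `ne = n*m/(n+m)`, clipped to (0, 1]. Terms are accumulated until
#' they fall below machine precision.
#'
#' @param D KS distance in [0, 1].
#' @param n,m Sample sizes (>= 1).
#' @return Asymptotic p-value in (0, 1].
#' @export
ks_p_value <- function(D, n, m) {
  stopifnot(D >= 0, D <= 1, n >= 1, m >= 1)
  ne <- n * m / (n + m)
  lambda2 <- 2 * ne * D^2
  if (lambda2 < .Machine$double.eps) return(1)  # series is for D > 0
  s <- 0
  for (k in seq_len(1000L)) {
    term <- (-1)^(k - 1) * exp(-lambda2 * k^2)
    s <- s + term
    if (abs(term) < .Machine$double.eps) break
  }
  min(max(2 * s, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order of `p`.
#'
#' @param p P-values in (0, 1].
#' @return Q-values in input order.
#' @export
bh_qvalues <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Screen every analyte for case/control separation
#'
#' Computes, per analyte, the two-sample KS distance between the case and
#' control groups, its asymptotic p-value, the BH q-value over all screened
#' analytes, and the direction of regulation (sign of the difference of
#' median log values, case minus control).
#'
#' @param values Analyte matrix.
#' @param ann Annotation data.frame covering the matrix samples.
#' @param case_mask,control_mask Logical vectors over the matrix rows
#'   selecting disjoint non-empty groups. Defaults select by `class_label`.
#' @return Data frame with columns `analyte_id`, `ks`, `p_value`,
#'   `q_value`, `direction`.
#' @export
screen_markers <- function(values, ann, case_mask = NULL, control_mask = NULL) {
  check_matrix_annotations(values, ann)
  ann <- ann[match(rownames(values), ann$sample_id), ]
  if (is.null(case_mask)) case_mask <- ann$class_label == "case"
  if (is.null(control_mask)) control_mask <- ann$class_label == "control"
  if (!sum(case_mask) || !sum(control_mask))
    stop("both groups must be non-empty")
  if (any(case_mask & control_mask))
    stop("case and control masks must be disjoint")
  n <- sum(case_mask); m <- sum(control_mask)
  res <- vapply(seq_len(ncol(values)), function(j) {
    x <- values[case_mask, j]
    y <- values[control_mask, j]
    D <- ks_two_sample(x, y)
    c(D, stats::median(log(x)) - stats::median(log(y)))
  }, numeric(2))
  ks <- res[1, ]
  p <- vapply(ks, ks_p_value, numeric(1), n = n, m = m)
  data.frame(
    analyte_id = colnames(values),
    ks = ks,
    p_value = p,
    q_value = bh_qvalues(p),
    direction = ifelse(res[2, ] >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}
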