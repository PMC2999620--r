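# Synthetic multi-site case/control cohort generator.
#
# The generator states a simple world consistent with what the analysis
# assumes: every analyte is log-normal; a disease marker shifts the case
# log-mean by delta control log-SDs; a site-artifact analyte shifts both
# classes' log-mean by a per-site offset (handling effects are
# class-independent). Covariates (age, smoking, stage, ...) are drawn
# independently of the analyte values, so the generated world contains no
# confounding by design.

#' Construct and validate a synthetic cohort configuration
#'
#' @param n_analytes Number of analytes (columns).
#' @param sites Data frame with columns `site`, `n_cases`,
#'   `n_controls_benign_nodule`, `n_controls_smoker`, and optionally
#'   `smoker_subtype` (`"smoker_no_nodule"` or `"smoker_unknown_nodule"`,
#'   default no-nodule).
#' @param disease_markers Data frame with columns `analyte` (index) and
#'   `delta` (signed case shift of the log-mean in units of the control
#'   log-SD). May have zero rows.
#' @param site_artifact_markers Data frame with column `analyte` plus one
#'   numeric column per site giving the additive offset applied to both
#'   classes at that site, in units of the analyte's control log-SD (the
#'   same units as `delta`, so planted handling effects and planted disease
#'   effects are directly comparable). May have zero rows.
#' @param baseline_mu_range Range the per-analyte control log-means are
#'   drawn from, natural-log scale. Default spans 4 logs (base 10) of
#'   concentration, `c(0, 4 * log(10))`.
#' @param baseline_sigma_range Range for per-analyte control log-SDs.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_analytes = 813L,
                             sites,
                             disease_markers = NULL,
                             site_artifact_markers = NULL,
                             baseline_mu_range = c(0, 4 * log(10)),
                             baseline_sigma_range = c(0.2, 0.8),
                             seed = 1L) {
  stopifnot(n_analytes >= 1)
  req <- c("site", "n_cases", "n_controls_benign_nodule", "n_controls_smoker")
  if (!all(req %in% colnames(sites)))
    stop("sites must have columns: ", paste(req, collapse = ", "))
  if (is.null(sites$smoker_subtype))
    sites$smoker_subtype <- "smoker_no_nodule"
  counts <- sites[, c("n_cases", "n_controls_benign_nodule", "n_controls_smoker")]
  if (any(unlist(counts) < 0)) stop("site counts must be non-negative")
  if (sum(sites$n_cases) < 1 ||
      sum(sites$n_controls_benign_nodule + sites$n_controls_smoker) < 1)
    stop("need at least one case and one control overall")
  if (is.null(disease_markers))
    disease_markers <- data.frame(analyte = integer(0), delta = numeric(0))
  if (is.null(site_artifact_markers))
    site_artifact_markers <- data.frame(analyte = integer(0))
  if (length(intersect(disease_markers$analyte, site_artifact_markers$analyte)))
    stop("disease_markers and site_artifact_markers must index disjoint analytes")
  if (any(disease_markers$analyte < 1 | disease_markers$analyte > n_analytes) ||
      any(site_artifact_markers$analyte < 1 |
          site_artifact_markers$analyte > n_analytes))
    stop("marker analyte index out of range")
  structure(list(
    n_analytes = as.integer(n_analytes),
    sites = sites,
    disease_markers = disease_markers,
    site_artifact_markers = site_artifact_markers,
    baseline_mu_range = baseline_mu_range,
    baseline_sigma_range = baseline_sigma_range,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic cohort from a configuration
#'
#' For analyte j with control log-mean mu_j and log-SD sigma_j, values are
#' LogNormal(mu_j + offset_js + delta_j * sigma_j * case, sigma_j), where
#' offset_js is the site-artifact offset (0 for non-artifact analytes) and
#' delta_j is 0 unless j is a disease marker. Identical seeds give
#' identical output.
#'
#' @param config A `synthetic_config`.
#' @return List with elements `matrix` (analyte matrix) and `annotations`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

#' @keywords internal
generate_cohort_impl <- function(config) {
  p <- config$n_analytes
  sites <- config$sites
  mu <- stats::runif(p, config$baseline_mu_range[1], config$baseline_mu_range[2])
  sigma <- stats::runif(p, config$baseline_sigma_range[1],
                        config$baseline_sigma_range[2])
  delta <- numeric(p)
  delta[config$disease_markers$analyte] <- config$disease_markers$delta

  # per-site, per-analyte offsets (units of sigma_j), zero except artifact analytes
  offsets <- matrix(0, nrow = nrow(sites), ncol = p,
                    dimnames = list(sites$site, NULL))
  if (nrow(config$site_artifact_markers)) {
    art <- config$site_artifact_markers
    off_cols <- intersect(sites$site, colnames(art))
    if (length(off_cols) != nrow(sites))
      stop("site_artifact_markers must carry one offset column per site")
    for (r in seq_len(nrow(art)))
      offsets[, art$analyte[r]] <- as.numeric(art[r, sites$site])
  }

  rows <- list(); anns <- list(); idx <- 0L
  for (s in seq_len(nrow(sites))) {
    grp <- c(rep("case", sites$n_cases[s]),
             rep("benign_nodule", sites$n_controls_benign_nodule[s]),
             rep(sites$smoker_subtype[s], sites$n_controls_smoker[s]))
    if (!length(grp)) next
    n_s <- length(grp)
    is_case <- grp == "case"
    shift <- outer(as.numeric(is_case), delta * sigma)
    logx <- matrix(rep(mu + offsets[s, ] * sigma, each = n_s), nrow = n_s) + shift +
      matrix(stats::rnorm(n_s * p), nrow = n_s) *
        matrix(rep(sigma, each = n_s), nrow = n_s)
    rows[[s]] <- exp(logx)
    anns[[s]] <- synth_annotations(grp, sites$site[s], idx)
    idx <- idx + n_s
  }
  values <- do.call(rbind, rows)
  ann <- do.call(rbind, anns)
  rownames(values) <- ann$sample_id
  colnames(values) <- sprintf("A%04d", seq_len(p))
  validate_analyte_matrix(values)
  validate_annotations(ann)
  list(matrix = values, annotations = ann)
}

# Draw clinical covariates for one site's samples. Distributions emulate a
# tobacco-exposed screening cohort: cases older than controls, stage mix
# dominated by stage I and III, adenocarcinoma the commonest histology,
# airflow obstruction graded mostly mild. All draws are independent of the
# analyte values.
#' @keywords internal
synth_annotations <- function(grp, site, idx0) {
  n <- length(grp)
  is_case <- grp == "case"
  age <- ifelse(is_case, stats::rnorm(n, 67.6, 9.8), stats::rnorm(n, 59.0, 10.2))
  stage <- rep("not_applicable", n)
  stage[is_case] <- sample(c("I", "II", "III"), sum(is_case), replace = TRUE,
                           prob = c(0.465, 0.150, 0.385))
  histology <- rep("not_applicable", n)
  histology[is_case] <- sample(
    c("adenocarcinoma", "squamous", "large_cell", "nsclc_nos"),
    sum(is_case), replace = TRUE, prob = c(0.563, 0.333, 0.010, 0.094))
  smoking <- sample(c("current", "ex", "never", "unknown"), n, replace = TRUE,
                    prob = c(0.45, 0.38, 0.02, 0.15))
  pack_years <- pmax(stats::rnorm(n, ifelse(is_case, 47.1, 42.3),
                                  ifelse(is_case, 33.7, 24.2)), 10)
  pack_years[smoking == "never"] <- 0
  gold <- rep("unknown", n)
  ctrl <- !is_case
  gold[ctrl] <- sample(c("0/I", "II", "III/IV", "unknown"), sum(ctrl),
                       replace = TRUE, prob = c(0.55, 0.22, 0.05, 0.18))
  ids <- sprintf("S%05d", idx0 + seq_len(n))
  data.frame(
    sample_id = ids,
    class_label = ifelse(is_case, "case", "control"),
    site = site,
    control_subtype = ifelse(is_case, "not_applicable", grp),
    stage = stage,
    histology = histology,
    age = round(age, 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    smoking_status = smoking,
    pack_years = round(pack_years, 1),
    gold_grade = gold,
    barcode = sprintf("B%06d", idx0 + seq_len(n)),
    stringsAsFactors = FALSE
  )
}

#' Default configuration mimicking the four-site study cohort
#'
#' Sites and case/control counts follow the published cohort composition
#' (BS 43/0/63, RPCI 72/66/110, NYU 88/238/172, PITT 88/261/125; 1,326
#' samples, 291 cases, 1,035 controls), with 813 analytes, 44 planted
#' disease markers with |delta| drawn uniformly in [0.6, 1.4] (random
#' sign), and 7 site-artifact analytes with per-site offsets up to 1.5
#' control log-SDs. Smoker controls at BS and RPCI have unknown nodule
#' status; NYU and PITT smoker controls are nodule-free.
#'
#' @param seed Integer seed (drives both marker placement and, through the
#'   returned config, the cohort draw).
#' @param n_analytes,n_disease_markers,n_artifact_markers Scale overrides.
#' @param delta_range Range of |delta| for planted disease markers.
#' @return A `synthetic_config`.
#' @export
default_study_mimic <- function(seed = 1L, n_analytes = 813L,
                                n_disease_markers = 44L,
                                n_artifact_markers = 7L,
                                delta_range = c(0.6, 1.4)) {
  sites <- data.frame(
    site = c("BS", "RPCI", "NYU", "PITT"),
    n_cases = c(43L, 72L, 88L, 88L),
    n_controls_benign_nodule = c(0L, 66L, 238L, 261L),
    n_controls_smoker = c(63L, 110L, 172L, 125L),
    smoker_subtype = c("smoker_unknown_nodule", "smoker_unknown_nodule",
                       "smoker_no_nodule", "smoker_no_nodule"),
    stringsAsFactors = FALSE
  )
  withr::with_seed(seed, {
    picks <- sample.int(n_analytes, n_disease_markers + n_artifact_markers)
    dm <- data.frame(
      analyte = sort(picks[seq_len(n_disease_markers)]),
      delta = stats::runif(n_disease_markers, delta_range[1], delta_range[2]) *
        sample(c(-1, 1), n_disease_markers, replace = TRUE)
    )
    am_idx <- sort(picks[n_disease_markers + seq_len(n_artifact_markers)])
    am <- data.frame(analyte = am_idx)
    # Handling artifacts: each affected analyte has a systematic per-site
    # shift pattern (a random assignment of -1.5, -0.5, +0.5, +1.5 sigma to
    # the four sites, scaled by a per-analyte severity in [0.75, 1]), so
    # per-site offsets stay within 1.5 sigma while between-site separation
    # lands in the range observed for handling-sensitive serum proteins.
    pattern <- c(-1.5, -0.5, 0.5, 1.5)
    severity <- stats::runif(n_artifact_markers, 0.75, 1)
    offs <- t(vapply(seq_len(n_artifact_markers),
                     function(r) sample(pattern) * severity[r],
                     numeric(length(pattern))))
    for (k in seq_along(sites$site)) am[[sites$site[k]]] <- offs[, k]
  })
  synthetic_config(
    n_analytes = n_analytes, sites = sites,
    disease_markers = dm, site_artifact_markers = am,
    seed = seed
  )
}
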