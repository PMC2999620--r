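# Shared data model and tab-separated interchange formats.
#
# An analyte matrix is a plain numeric matrix: rows = serum samples, columns
# = protein analytes, values = relative fluorescence units (RFU, strictly
# positive so the log transform is always defined). Sample and analyte ids
# live in the dimnames. Annotations are a data.frame with one row per sample.

#' Allowed levels for closed categorical annotation fields
#'
#' @keywords internal
annotation_levels <- list(
  class_label     = c("case", "control"),
  control_subtype = c("benign_nodule", "smoker_no_nodule",
                      "smoker_unknown_nodule", "not_applicable"),
  stage           = c("I", "II", "III", "unknown", "not_applicable"),
  sex             = c("male", "female", "unknown"),
  smoking_status  = c("current", "ex", "never", "unknown"),
  gold_grade      = c("0/I", "II", "III/IV", "unknown")
)

#' Required annotation columns, in file order
#' @keywords internal
annotation_columns <- c(
  "sample_id", "class_label", "site", "control_subtype", "stage",
  "histology", "age", "sex", "smoking_status", "pack_years",
  "gold_grade", "barcode"
)

#' Validate an analyte matrix
#'
#' Checks the invariants every pipeline stage relies on: a numeric matrix
#' with unique sample ids (rows) and analyte ids (columns) and strictly
#' positive values.
#'
#' @param values Numeric matrix, samples x analytes, with dimnames.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_analyte_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("analyte matrix must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("analyte matrix must carry sample ids (rownames) and analyte ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in analyte matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate analyte ids in analyte matrix")
  if (anyNA(values) || any(!is.finite(values)))
    stop("analyte matrix contains missing or non-finite values")
  if (any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive RFU value at sample '%s', analyte '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  invisible(values)
}

#' Read an analyte matrix from a tab-separated file
#'
#' Expected layout: header row of analyte ids with a leading `sample_id`
#' column, then one row per sample with a numeric body of positive RFU
#' values.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (samples x analytes) with ids in the dimnames.
#' @export
read_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1]))
    stop("duplicate analyte id(s) in header: ",
         paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  colnames(df) <- header
  if (colnames(df)[1] != "sample_id")
    stop("matrix file must have a leading 'sample_id' column")
  ids <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                  dimnames = list(ids, colnames(body))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at sample '%s', analyte '%s'",
                 ids[bad[1]], colnames(vals)[bad[2]]))
  }
  validate_analyte_matrix(vals)
  vals
}

#' Write an analyte matrix to a tab-separated file
#'
#' Values are written with 17 significant digits so that
#' `read_matrix(write_matrix(m))` round-trips at full double precision.
#'
#' @param values Analyte matrix (see [validate_analyte_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(values, path) {
  validate_analyte_matrix(values)
  header <- paste(c("sample_id", colnames(values)), collapse = "\t")
  body <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], sprintf("%.17g", values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Validate a sample annotation table
#'
#' Enforces the closed categorical levels and the cross-field rules: cases
#' have no control subtype, controls have no stage.
#'
#' @param ann Data frame with the columns in `annotation_columns`.
#' @return `ann` with categorical columns as character, invisibly valid.
#' @export
validate_annotations <- function(ann) {
  missing_cols <- setdiff(annotation_columns, colnames(ann))
  if (length(missing_cols))
    stop("annotation table missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyNA(ann$sample_id) || anyDuplicated(ann$sample_id))
    stop("sample_id must be present and unique")
  for (col in names(annotation_levels)) {
    bad <- setdiff(unique(ann[[col]]), annotation_levels[[col]])
    if (length(bad))
      stop(sprintf("unknown level(s) in '%s': %s", col, paste(bad, collapse = ", ")))
  }
  if (!is.numeric(ann$age) || !is.numeric(ann$pack_years))
    stop("age and pack_years must be numeric (NA for unknown)")
  if (any(ann$pack_years < 0, na.rm = TRUE))
    stop("pack_years must be non-negative")
  bad_case <- ann$class_label == "case" & ann$control_subtype != "not_applicable"
  if (any(bad_case))
    stop("case samples must have control_subtype 'not_applicable': ",
         paste(ann$sample_id[bad_case], collapse = ", "))
  bad_ctrl <- ann$class_label == "control" & ann$stage != "not_applicable"
  if (any(bad_ctrl))
    stop("control samples must have stage 'not_applicable': ",
         paste(ann$sample_id[bad_ctrl], collapse = ", "))
  invisible(ann)
}

#' Read a sample annotation table from a tab-separated file
#'
#' Unknown numeric entries (age, pack-years) are encoded as `NA` in the
#' file; categorical unknowns use the explicit level `"unknown"`.
#'
#' @param path Path to a TSV file with the fixed annotation header.
#' @return Validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = character(0))
  ann$age <- suppressWarnings(as.numeric(ifelse(ann$age == "NA", NA, ann$age)))
  ann$pack_years <- suppressWarnings(
    as.numeric(ifelse(ann$pack_years == "NA", NA, ann$pack_years)))
  validate_annotations(ann)
  ann
}

#' Write a sample annotation table to a tab-separated file
#'
#' @param ann Validated annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  out <- ann[, annotation_columns]
  out$age <- ifelse(is.na(out$age), "NA", sprintf("%.17g", out$age))
  out$pack_years <- ifelse(is.na(out$pack_years), "NA",
                           sprintf("%.17g", out$pack_years))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Check that an annotation table covers an analyte matrix
#' @keywords internal
check_matrix_annotations <- function(values, ann) {
  validate_analyte_matrix(values)
  if (!setequal(rownames(values), ann$sample_id) ||
      nrow(ann) != nrow(values))
    stop("annotation table must cover each matrix sample exactly once")
  invisible(NULL)
}

#' Randomly split samples into training and verification roles
#'
#' Simple random sampling without stratification: `round(fraction * n)`
#' samples are assigned the verification role, the rest training. The draw
#' is seed-deterministic and leaves the caller's RNG state untouched.
#'
#' @param ann Annotation data.frame.
#' @param verification_fraction Fraction in (0, 1); default 0.25.
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `role`
#'   (`"training"`/`"verification"`).
#' @export
split_samples <- function(ann, verification_fraction = 0.25, seed = 1L) {
  if (!is.numeric(verification_fraction) ||
      verification_fraction <= 0 || verification_fraction >= 1)
    stop("verification_fraction must lie in (0, 1)")
  n <- nrow(ann)
  n_ver <- round(verification_fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_ver))
  role <- rep("training", n)
  role[idx] <- "verification"
  data.frame(sample_id = ann$sample_id, role = role,
             stringsAsFactors = FALSE)
}

#' Build a blinding key for the verification samples
#'
#' Maps each verification sample's opaque barcode to its true class label.
#' The key is the only object verification scoring may consult; training
#' operations never accept one.
#'
#' @param ann Annotation data.frame.
#' @param split Split assignment from [split_samples()].
#' @return Data frame with columns `barcode`, `class_label`.
#' @export
make_blinding_key <- function(ann, split) {
  ver <- split$sample_id[split$role == "verification"]
  sel <- ann[match(ver, ann$sample_id), , drop = FALSE]
  data.frame(barcode = sel$barcode, class_label = sel$class_label,
             stringsAsFactors = FALSE)
}

#' Read / write a blinding key file (TSV: barcode, class_label)
#'
#' @param path Path to the key file.
#' @return Data frame with columns `barcode`, `class_label`.
#' @export
read_blinding_key <- function(path) {
  key <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("barcode", "class_label") %in% colnames(key)))
    stop("blinding key must have columns barcode, class_label")
  if (anyDuplicated(key$barcode)) stop("duplicate barcodes in blinding key")
  bad <- setdiff(unique(key$class_label), annotation_levels$class_label)
  if (length(bad)) stop("unknown class label in key: ", paste(bad, collapse = ", "))
  key
}

#' @rdname read_blinding_key
#' @param key Data frame with columns `barcode`, `class_label`.
#' @export
write_blinding_key <- function(key, path) {
  utils::write.table(key[, c("barcode", "class_label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
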