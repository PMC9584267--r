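# Core data containers: expression matrices, sample metadata, titer tables,
# and the compendium bundle that ties them together with provenance.

VALUE_SCALES <- c("raw_intensity", "raw_count", "log2", "within_normalized",
                  "cross_normalized", "batch_corrected")
SPECIMEN_TYPES <- c("whole_blood", "pbmc")
PLATFORM_VENDORS <- c("affymetrix", "illumina", "rnaseq", "two_color", "other")
SEX_LEVELS <- c("female", "male", "unknown")
ASSAY_TYPES <- c("HAI", "NAb", "ELISA")

#' Construct an expression matrix container
#'
#' Wraps a numeric features-by-samples matrix together with a value-scale tag
#' that tracks which pipeline stage produced it (raw intensities, log2,
#' within-study normalized, cross-study normalized, batch corrected).
#'
#' @param values Numeric matrix, features in rows, samples in columns. Must
#'   have unique, non-empty rownames (feature ids) and colnames (sample ids).
#' @param value_scale One of `"raw_intensity"`, `"raw_count"`, `"log2"`,
#'   `"within_normalized"`, `"cross_normalized"`, `"batch_corrected"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, value_scale = "raw_intensity") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  value_scale <- match.arg(value_scale, VALUE_SCALES)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (value_scale != "raw_intensity" && value_scale != "raw_count" &&
      any(!is.finite(values)))
    stop("non-finite values are not allowed at scale '", value_scale, "'")
  structure(list(values = values, value_scale = value_scale),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$value_scale))
  invisible(x)
}

#' Extract the numeric matrix from an ExpressionMatrix
#' @param x An `ExpressionMatrix` (a bare matrix is passed through).
#' @return The underlying numeric matrix.
#' @export
em_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values else x
}

#' Value-scale tag of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character scalar scale tag.
#' @export
value_scale <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$value_scale
}

#' Replace values of an ExpressionMatrix, optionally retagging the scale
#' @param x An `ExpressionMatrix`.
#' @param values Replacement matrix (same dimnames discipline applies).
#' @param value_scale New scale tag; defaults to the current one.
#' @return A new `ExpressionMatrix`.
#' @export
em_update <- function(x, values, value_scale = x$value_scale) {
  expression_matrix(values, value_scale)
}

SAMPLE_REQUIRED_COLS <- c("sample_id", "participant_id", "study_accession",
                          "cohort_label", "matrix_name", "specimen_type",
                          "platform_vendor", "feature_set_name", "time_days",
                          "vaccine", "pathogen", "vaccine_type")
SAMPLE_OPTIONAL_COLS <- c("age_reported", "age_imputed", "sex_reported",
                          "y_present")

normalize_enum <- function(x, levels, field) {
  xl <- tolower(trimws(gsub("[ -]", "_", as.character(x))))
  bad <- !is.na(xl) & !(xl %in% levels)
  if (any(bad))
    stop("unknown ", field, " value(s): ",
         paste(unique(x[bad]), collapse = ", "))
  xl
}

#' Validate a sample metadata table
#'
#' Checks required columns, normalizes enum-like fields (specimen type,
#' platform vendor, reported sex) to lower-case canonical levels, and enforces
#' per-cohort consistency: each (study, cohort) pair must use exactly one
#' platform vendor and one specimen type. Extra columns are preserved.
#'
#' @param samples A data.frame of per-sample metadata.
#' @return The validated, normalized data.frame.
#' @export
validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  missing_cols <- setdiff(SAMPLE_REQUIRED_COLS, names(samples))
  if (length(missing_cols))
    stop("missing required sample columns: ",
         paste(missing_cols, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  samples$specimen_type <- normalize_enum(samples$specimen_type,
                                          SPECIMEN_TYPES, "specimen_type")
  samples$platform_vendor <- normalize_enum(samples$platform_vendor,
                                            PLATFORM_VENDORS, "platform_vendor")
  if ("sex_reported" %in% names(samples) && !all(is.na(samples$sex_reported)))
    samples$sex_reported <- normalize_enum(samples$sex_reported, SEX_LEVELS,
                                           "sex_reported")
  td <- suppressWarnings(as.numeric(samples$time_days))
  if (any(!is.finite(td)))
    stop("non-finite time_days in row(s): ",
         paste(which(!is.finite(td)), collapse = ", "))
  samples$time_days <- td
  for (agecol in c("age_reported", "age_imputed")) {
    if (agecol %in% names(samples)) {
      a <- suppressWarnings(as.numeric(samples[[agecol]]))
      if (any(!is.na(a) & (a < 0 | a > 120)))
        stop(agecol, " outside [0, 120]")
      samples[[agecol]] <- a
    }
  }
  key <- paste(samples$study_accession, samples$cohort_label, sep = "|")
  for (grp in split(samples, key)) {
    if (length(unique(grp$platform_vendor)) > 1L ||
        length(unique(grp$specimen_type)) > 1L)
      stop("cohort '", grp$cohort_label[1], "' of study '",
           grp$study_accession[1],
           "' mixes platform vendors or specimen types")
  }
  rownames(samples) <- NULL
  samples
}

#' Validate a long-format antibody titer table
#'
#' @param titers A data.frame with columns `participant_id`, `study_accession`,
#'   `assay` (HAI/NAb/ELISA), `analyte` (strain or antigen), `time_days`,
#'   `value` (positive raw titer).
#' @return The validated data.frame.
#' @export
validate_titers <- function(titers) {
  req <- c("participant_id", "study_accession", "assay", "analyte",
           "time_days", "value")
  missing_cols <- setdiff(req, names(titers))
  if (length(missing_cols))
    stop("missing titer columns: ", paste(missing_cols, collapse = ", "))
  titers <- as.data.frame(titers, stringsAsFactors = FALSE)
  if (!all(titers$assay %in% ASSAY_TYPES))
    stop("unknown assay value(s): ",
         paste(setdiff(unique(titers$assay), ASSAY_TYPES), collapse = ", "))
  titers$time_days <- as.numeric(titers$time_days)
  titers$value <- as.numeric(titers$value)
  if (any(!is.finite(titers$value)) || any(titers$value <= 0))
    stop("titer values must be positive and finite")
  key <- paste(titers$participant_id, titers$assay, titers$analyte,
               titers$time_days, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (participant, assay, analyte, time) titer rows")
  rownames(titers) <- NULL
  titers
}

new_provenance <- function() {
  data.frame(stage = character(), parameters = character(),
             n_in = integer(), n_out = integer(),
             stringsAsFactors = FALSE)
}

#' Append a provenance entry to a bundle
#'
#' Provenance is an append-only log of stage name, parameter string and
#' sample counts in/out; every pipeline stage records `n_in = n_out + removed`.
#'
#' @param bundle A `CompendiumBundle`.
#' @param stage Stage name.
#' @param parameters Named list of stage parameters (stored as compact JSON).
#' @param n_in,n_out Sample counts entering and leaving the stage.
#' @return The bundle with one more provenance row.
#' @export
add_provenance <- function(bundle, stage, parameters = list(), n_in, n_out) {
  stopifnot(inherits(bundle, "CompendiumBundle"))
  row <- data.frame(
    stage = stage,
    parameters = as.character(jsonlite::toJSON(parameters, auto_unbox = TRUE)),
    n_in = as.integer(n_in), n_out = as.integer(n_out),
    stringsAsFactors = FALSE)
  bundle$provenance <- rbind(bundle$provenance, row)
  bundle
}

#' Align an expression matrix with its sample metadata into a bundle
#'
#' Every matrix column id must appear exactly once in the sample table and
#' vice versa; columns are reordered to the metadata row order. This is the
#' entry point that every downstream stage assumes has been run.
#'
#' @param expression An `ExpressionMatrix` (or bare named matrix).
#' @param samples Sample metadata data.frame (validated with
#'   [validate_samples()]).
#' @param titers Optional titer table (validated with [validate_titers()]).
#' @return A `CompendiumBundle` with initialized provenance.
#' @export
align <- function(expression, samples, titers = NULL) {
  if (!inherits(expression, "ExpressionMatrix")) {
    if (ncol(expression) == 0L) stop("no samples in expression matrix")
    expression <- expression_matrix(expression)
  }
  samples <- validate_samples(samples)
  if (!is.null(titers)) titers <- validate_titers(titers)
  ids_mat <- colnames(expression$values)
  if (length(ids_mat) == 0L) stop("no samples in expression matrix")
  orphan_cols <- setdiff(ids_mat, samples$sample_id)
  orphan_meta <- setdiff(samples$sample_id, ids_mat)
  if (length(orphan_cols) || length(orphan_meta))
    stop("alignment error; matrix-only ids: [",
         paste(orphan_cols, collapse = ", "), "]; metadata-only ids: [",
         paste(orphan_meta, collapse = ", "), "]")
  expression$values <- expression$values[, samples$sample_id, drop = FALSE]
  bundle <- structure(list(expression = expression, samples = samples,
                           titers = titers, provenance = new_provenance()),
                      class = "CompendiumBundle")
  add_provenance(bundle, "align", list(), nrow(samples), nrow(samples))
}

#' @export
print.CompendiumBundle <- function(x, ...) {
  cat(sprintf(paste0("CompendiumBundle: %d features x %d samples, ",
                     "%d participants, %d studies [%s]%s\n"),
              nrow(x$expression$values), ncol(x$expression$values),
              length(unique(x$samples$participant_id)),
              length(unique(x$samples$study_accession)),
              x$expression$value_scale,
              if (is.null(x$titers)) "" else
                sprintf(", %d titer rows", nrow(x$titers))))
  invisible(x)
}

#' Subset a bundle to a set of sample ids
#'
#' Keeps expression columns, metadata rows and (by participant) titer rows;
#' appends a provenance entry.
#'
#' @param bundle A `CompendiumBundle`.
#' @param sample_ids Character vector of sample ids to keep.
#' @param stage Provenance label for the subsetting operation.
#' @return The subsetted bundle.
#' @export
subset_bundle <- function(bundle, sample_ids, stage = "subset") {
  stopifnot(inherits(bundle, "CompendiumBundle"))
  keep <- bundle$samples$sample_id %in% sample_ids
  if (!any(keep)) stop("all samples curated away at stage '", stage, "'")
  n_in <- nrow(bundle$samples)
  samples <- bundle$samples[keep, , drop = FALSE]
  rownames(samples) <- NULL
  bundle$expression$values <-
    bundle$expression$values[, samples$sample_id, drop = FALSE]
  if (!is.null(bundle$titers)) {
    bundle$titers <- bundle$titers[
      bundle$titers$participant_id %in% samples$participant_id, , drop = FALSE]
    rownames(bundle$titers) <- NULL
  }
  bundle$samples <- samples
  add_provenance(bundle, stage, list(), n_in, nrow(samples))
}
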