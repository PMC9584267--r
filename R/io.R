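# Readers and writers for the plain-text interchange formats (TSV matrices,
# metadata/titer/alias tables) and the serialized bundle container.

#' Read an expression matrix
#'
#' TSV dialect: tab-separated, UTF-8, header row of sample ids, first column
#' named `feature_id` holding unique feature ids, no quoting. The `container`
#' format is the bundle serialization written by [write_expression()] with
#' `format = "container"`.
#'
#' @param path File path.
#' @param format `"tsv_matrix"` or `"container"`.
#' @param value_scale Scale tag to stamp on the result (TSV carries none).
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, format = c("tsv_matrix", "container"),
                            value_scale = "raw_intensity") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "container") {
    x <- readRDS(path)
    if (!inherits(x, "ExpressionMatrix"))
      stop("container does not hold an ExpressionMatrix: ", path)
    return(x)
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "feature_id")
    stop("malformed header: first cell must be 'feature_id' in ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = c("character"),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$feature_id))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(tab$feature_id[duplicated(tab$feature_id)]),
               collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                     dimnames = list(tab$feature_id,
                                                     colnames(vals))))
  if (anyNA(storage)) {
    bad <- which(is.na(storage), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at feature '", rownames(storage)[bad[1]],
         "', sample '", colnames(storage)[bad[2]], "' in ", path)
  }
  expression_matrix(storage, value_scale)
}

#' Write an expression matrix
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @param format `"tsv_matrix"` or `"container"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv_matrix", "container")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (format == "container") {
    saveRDS(x, path)
    return(invisible(path))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(x$values)), collapse = "\t"), con)
  lines <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(rownames(x$values)[i],
            format(x$values[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a sample metadata table from TSV
#' @param path TSV path with the documented sample columns.
#' @return Validated sample data.frame.
#' @export
read_samples <- function(path) validate_samples(read_tsv_table(path))

#' Write a sample metadata table to TSV
#' @param samples Sample data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) write_tsv_table(samples, path)

#' Read a long-format titer table from TSV
#' @param path TSV path with columns participant_id, study_accession, assay,
#'   analyte, time_days, value.
#' @return Validated titer data.frame.
#' @export
read_titers <- function(path) validate_titers(read_tsv_table(path))

#' Write a titer table to TSV
#' @param titers Titer data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titers <- function(titers, path) write_tsv_table(titers, path)

#' Read a gene-alias map
#'
#' Two-column TSV (alias, symbol); an alias mapping to several symbols is
#' represented by repeated rows. Aliases and symbols are trimmed; alias
#' matching downstream is case-insensitive.
#'
#' @param path TSV path.
#' @param version Version tag for provenance (mandatory; e.g. the nomenclature
#'   release date).
#' @return An `AliasMap`: a list with `map` (named list alias -> character
#'   vector of candidate symbols, lower-case keys) and `version`.
#' @export
read_alias_map <- function(path, version) {
  if (missing(version) || !nzchar(version))
    stop("an alias map version tag is mandatory")
  tab <- read_tsv_table(path)
  if (!all(c("alias", "symbol") %in% names(tab)))
    stop("alias map needs columns 'alias' and 'symbol'")
  alias_map(tab$alias, tab$symbol, version)
}

#' Construct an alias map from vectors
#' @param alias Character vector of aliases (repeated for multi-mapping).
#' @param symbol Character vector of candidate symbols, same length.
#' @param version Version tag.
#' @return An `AliasMap`.
#' @export
alias_map <- function(alias, symbol, version) {
  stopifnot(length(alias) == length(symbol), nzchar(version))
  key <- tolower(trimws(alias))
  map <- lapply(split(trimws(symbol), key), unique)
  structure(list(map = map, version = version), class = "AliasMap")
}

#' Write a bundle container
#'
#' Serializes the full bundle (expression / samples / titers / provenance,
#' plus any attached models) to a single binary container file.
#'
#' @param bundle A `CompendiumBundle`.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "CompendiumBundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' Read a bundle container written by [write_bundle()]
#' @param path Container path.
#' @return A `CompendiumBundle`.
#' @export
read_bundle <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "CompendiumBundle"))
    stop("not a CompendiumBundle container: ", path)
  x
}
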