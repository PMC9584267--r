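# Gene-alias resolution and probe-to-gene collapsing.
#
# Alias resolution rules: an alias whose candidate symbol set contains the
# alias itself resolves to itself; an alias mapping to several symbols none of
# which is itself is dropped; a unique candidate wins; no candidate means
# unmapped. Collapsing keeps, per symbol, the single probe with the highest
# mean expression across the samples of the cohort matrix - never an average.

#' Resolve one gene alias against an alias map
#'
#' @param alias Non-empty alias string (matching is case-insensitive after
#'   trimming; the returned symbol keeps the map's case).
#' @param map An `AliasMap` from [alias_map()] / [read_alias_map()].
#' @return The resolved symbol, or `"DROPPED"` (multi-mapping without self),
#'   or `"UNMAPPED"` (no candidate).
#' @export
resolve_alias <- function(alias, map) {
  stopifnot(inherits(map, "AliasMap"), nzchar(alias))
  key <- tolower(trimws(alias))
  cand <- map$map[[key]]
  if (is.null(cand) || !length(cand)) return("UNMAPPED")
  self <- cand[tolower(cand) == key]
  if (length(self)) return(self[1])
  if (length(cand) > 1L) return("DROPPED")
  cand
}

#' Annotate matrix features with resolved gene symbols
#'
#' @param matrix `ExpressionMatrix` or bare matrix whose rownames are feature
#'   (probe) ids.
#' @param probe2alias Named character vector mapping feature id -> alias.
#'   Features absent from it are reported as unmapped.
#' @param map An `AliasMap`.
#' @return A `FeatureAnnotation` data.frame with columns `feature_id`,
#'   `alias`, `resolved_symbol` (NA unless mapped) and `status`
#'   (mapped/dropped/unmapped), plus attributes `counts` (named integer
#'   summary) and `alias_map_version`.
#' @export
annotate_features <- function(matrix, probe2alias, map) {
  x <- em_values(matrix)
  stopifnot(inherits(map, "AliasMap"))
  fid <- rownames(x)
  alias <- unname(probe2alias[fid])
  status <- character(length(fid))
  symbol <- rep(NA_character_, length(fid))
  for (i in seq_along(fid)) {
    if (is.na(alias[i])) { status[i] <- "unmapped"; next }
    r <- resolve_alias(alias[i], map)
    if (identical(r, "UNMAPPED")) status[i] <- "unmapped"
    else if (identical(r, "DROPPED")) status[i] <- "dropped"
    else { status[i] <- "mapped"; symbol[i] <- r }
  }
  if (!any(status == "mapped"))
    stop("no feature could be mapped to a gene symbol")
  ann <- data.frame(feature_id = fid, alias = alias,
                    resolved_symbol = symbol, status = status,
                    stringsAsFactors = FALSE)
  attr(ann, "counts") <- c(mapped = sum(status == "mapped"),
                           dropped = sum(status == "dropped"),
                           unmapped = sum(status == "unmapped"))
  attr(ann, "alias_map_version") <- map$version
  class(ann) <- c("FeatureAnnotation", "data.frame")
  ann
}

#' Collapse probe-level expression to gene-level
#'
#' For each resolved symbol, keeps the one feature row with the largest mean
#' across all samples of the matrix; exact mean ties are broken by the
#' lexicographically smallest feature id. Dropped/unmapped features never
#' reach the output. Output rows are keyed by symbol and every output row
#' equals some input row exactly.
#'
#' @param matrix `ExpressionMatrix` (one cohort matrix) or bare matrix.
#' @param annotation A `FeatureAnnotation` from [annotate_features()].
#' @return Gene-level `ExpressionMatrix` (same value scale as input when the
#'   input is an `ExpressionMatrix`, otherwise a bare matrix).
#' @export
collapse_to_genes <- function(matrix, annotation) {
  x <- em_values(matrix)
  mapped <- annotation[annotation$status == "mapped", , drop = FALSE]
  mapped <- mapped[mapped$feature_id %in% rownames(x), , drop = FALSE]
  if (!nrow(mapped)) stop("no mapped features present in the matrix")
  means <- rowMeans(x[mapped$feature_id, , drop = FALSE])
  ord <- order(mapped$resolved_symbol, -means, mapped$feature_id)
  mapped <- mapped[ord, , drop = FALSE]
  keep <- mapped[!duplicated(mapped$resolved_symbol), , drop = FALSE]
  out <- x[keep$feature_id, , drop = FALSE]
  rownames(out) <- keep$resolved_symbol
  out <- out[order(rownames(out)), , drop = FALSE]
  if (inherits(matrix, "ExpressionMatrix"))
    expression_matrix(out, value_scale(matrix))
  else out
}
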