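# Within-study quantile normalization, log transform, count transformation,
# and cross-study quantile normalization to an Affymetrix-derived target
# distribution, plus the gene intersection/merge.

#' Within-study quantile normalization
#'
#' Classic quantile normalization within one cohort matrix: each sample's
#' order statistics are replaced by the across-sample mean of order
#' statistics; rank ties receive the average of the corresponding target
#' values. Delegates to the standard limma implementation.
#'
#' @param matrix `ExpressionMatrix` or bare matrix for a single cohort matrix,
#'   with at least 2 samples (a single sample is returned unchanged with a
#'   warning).
#' @return Matrix of the same shape; samples share an identical sorted value
#'   vector afterwards.
#' @export
quantile_normalize_within <- function(matrix) {
  x <- em_values(matrix)
  if (ncol(x) < 2L) {
    warning("single sample: quantile normalization is a no-op")
    return(matrix)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  if (inherits(matrix, "ExpressionMatrix"))
    expression_matrix(out, "within_normalized")
  else out
}

#' Log2 transform with pseudocount
#'
#' @param matrix `ExpressionMatrix` or bare matrix, all values >= 0 (negative
#'   values raise an error: the input looks already logged).
#' @param pseudocount Added before the log (default 1).
#' @return log2(x + pseudocount); value scale retagged to `"log2"`.
#' @export
log2_transform <- function(matrix, pseudocount = 1) {
  x <- em_values(matrix)
  if (any(x < 0))
    stop("negative values: input appears to be log-scale already")
  out <- log2(x + pseudocount)
  if (inherits(matrix, "ExpressionMatrix")) expression_matrix(out, "log2")
  else out
}

#' Median-of-ratios size factors
#'
#' Reference = per-gene geometric mean across samples (genes with any zero
#' count are excluded from the reference, with a warning if that drops
#' everything); size factor of a sample = median of its counts over the
#' reference.
#'
#' @param counts Non-negative integer matrix (genes x samples).
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  x <- em_values(counts)
  if (any(x < 0)) stop("counts must be non-negative")
  log_geo <- rowMeans(log(x))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no gene has all-positive counts; cannot build size-factor reference")
  if (!all(usable))
    warning(sum(!usable), " gene(s) with zero counts excluded from the ",
            "size-factor reference")
  sf <- apply(x, 2, function(col)
    exp(stats::median(log(col[usable]) - log_geo[usable])))
  names(sf) <- colnames(x)
  sf
}

#' Transform raw counts to a log2 expression scale
#'
#' Simplified library-size normalization for RNA-seq: median-of-ratios size
#' factors followed by `log2(count / size_factor + 1)`. This is a deliberately
#' simple, pluggable stand-in for a full variance-stabilizing transformation:
#' it normalizes across samples by library size so counts can be merged with
#' log-scale microarray data.
#'
#' @param counts Non-negative count matrix (genes x samples) or
#'   `ExpressionMatrix` with scale `raw_count`.
#' @return Log-scale matrix (`ExpressionMatrix` tagged `"log2"` when the input
#'   was one).
#' @export
transform_counts <- function(counts) {
  x <- em_values(counts)
  sf <- size_factors(x)
  out <- log2(sweep(x, 2, sf, `/`) + 1)
  if (inherits(counts, "ExpressionMatrix")) expression_matrix(out, "log2")
  else out
}

#' Build a target quantile distribution from Affymetrix samples
#'
#' Per sample, the empirical quantile function is evaluated at `L` equispaced
#' midpoint probabilities `(r - 0.5)/L` (quantile type 5); the target is the
#' across-sample mean at each probability.
#'
#' @param matrices A matrix, `ExpressionMatrix`, or list of them, holding the
#'   Affymetrix-vendor samples (column-bound).
#' @param L Grid length (>= 2).
#' @return A `TargetDistribution`: list with `probabilities`, `quantiles`
#'   (non-decreasing), and `n_samples`.
#' @export
build_target <- function(matrices, L) {
  if (!is.list(matrices) || inherits(matrices, "ExpressionMatrix"))
    matrices <- list(matrices)
  cols <- do.call(cbind, lapply(matrices, em_values))
  if (is.null(cols) || ncol(cols) < 1L)
    stop("no Affymetrix samples available; supply an explicit target")
  stopifnot(L >= 2)
  probs <- (seq_len(L) - 0.5) / L
  qmat <- apply(cols, 2, stats::quantile, probs = probs, type = 5,
                names = FALSE)
  structure(list(probabilities = probs,
                 quantiles = rowMeans(as.matrix(qmat)),
                 n_samples = ncol(cols)),
            class = "TargetDistribution")
}

#' Read/write a target distribution as two-column TSV
#' @param path TSV with columns `probability`, `quantile`.
#' @return A `TargetDistribution`.
#' @export
read_target <- function(path) {
  tab <- read_tsv_table(path)
  stopifnot(all(c("probability", "quantile") %in% names(tab)))
  structure(list(probabilities = tab$probability, quantiles = tab$quantile,
                 n_samples = NA_integer_), class = "TargetDistribution")
}

#' @rdname read_target
#' @param target A `TargetDistribution`.
#' @export
write_target <- function(target, path) {
  write_tsv_table(data.frame(probability = target$probabilities,
                             quantile = target$quantiles), path)
}

#' Quantile normalize each sample to a target distribution
#'
#' The value at (average) rank r among n within a sample is mapped to the
#' target quantile function evaluated at probability `(r - 0.5)/n` by linear
#' interpolation over the target grid (clamped at the ends). Within-sample
#' rank order is preserved exactly; tied values stay tied.
#'
#' @param matrix `ExpressionMatrix` or bare matrix.
#' @param target A `TargetDistribution` from [build_target()].
#' @return Matrix on the target scale (`ExpressionMatrix` tagged
#'   `"cross_normalized"` when the input was one).
#' @export
normalize_to_target <- function(matrix, target) {
  stopifnot(inherits(target, "TargetDistribution"))
  x <- em_values(matrix)
  n <- nrow(x)
  out <- apply(x, 2, function(col) {
    p <- (rank(col, ties.method = "average") - 0.5) / n
    stats::approx(target$probabilities, target$quantiles, xout = p,
                  rule = 2)$y
  })
  dimnames(out) <- dimnames(x)
  if (inherits(matrix, "ExpressionMatrix"))
    expression_matrix(out, "cross_normalized")
  else out
}

#' Intersect gene sets and merge matrices column-wise
#'
#' Keeps only symbols present in every matrix, in sorted order, and
#' column-concatenates. Per-matrix dropped-gene counts are attached as
#' attribute `"dropped"`.
#'
#' @param gene_matrices List (>= 2) of gene-level matrices or
#'   `ExpressionMatrix` objects with symbol rownames.
#' @return Merged matrix (bare matrix, or `ExpressionMatrix` carrying the
#'   first input's scale when all inputs are `ExpressionMatrix`).
#' @export
intersect_genes <- function(gene_matrices) {
  stopifnot(is.list(gene_matrices), length(gene_matrices) >= 2L)
  vals <- lapply(gene_matrices, em_values)
  common <- Reduce(intersect, lapply(vals, rownames))
  if (!length(common)) stop("empty gene intersection across matrices")
  common <- sort(common)
  dropped <- vapply(vals, function(v) nrow(v) - length(common), integer(1))
  merged <- do.call(cbind, lapply(vals, function(v)
    v[common, , drop = FALSE]))
  attr(merged, "dropped") <- dropped
  if (all(vapply(gene_matrices, inherits, TRUE, "ExpressionMatrix"))) {
    out <- expression_matrix(merged, value_scale(gene_matrices[[1]]))
    attr(out, "dropped") <- dropped
    out
  } else merged
}
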