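# Per-array outlier statistics and the fail-all-three flagging rule.
#
# Three statistics per array a, computed on log-scale intensities within one
# cohort matrix: (i) d_a, the mean over other arrays of the mean absolute
# difference of values; (ii) K_a, the Kolmogorov-Smirnov distance between the
# array's intensity distribution and the pooled distribution of all arrays;
# (iii) D_a, Hoeffding's D measuring dependence between the array's A
# (average) and M (difference) values against a feature-wise median
# pseudo-array. An array is flagged as an outlier only if it fails all three.

#' Mean absolute pairwise difference scores
#'
#' For each array a, `d_a = mean_{b != a} mean_f |x[f,a] - x[f,b]|`. The
#' underlying symmetric distance matrix is returned as an attribute
#' `"distances"`.
#'
#' @param matrix Log-scale numeric matrix (features x arrays) or an
#'   `ExpressionMatrix`, restricted to one study/cohort matrix.
#' @return Named numeric vector of d_a scores with attribute `distances`.
#' @export
pairwise_distance_scores <- function(matrix) {
  x <- em_values(matrix)
  n <- ncol(x)
  if (n < 3L) stop("need at least 3 arrays for distance scoring")
  # Manhattan distance between columns / number of features
  d <- as.matrix(stats::dist(t(x), method = "manhattan")) / nrow(x)
  scores <- rowSums(d) / (n - 1)
  names(scores) <- colnames(x)
  attr(scores, "distances") <- d
  scores
}

#' Kolmogorov-Smirnov statistic of each array versus the pooled distribution
#'
#' `K_a = sup_x |ECDF_a(x) - ECDF_pooled(x)|`, where the pooled distribution
#' concatenates the values of all arrays (the array itself included).
#'
#' @param matrix Numeric matrix (features x arrays) or `ExpressionMatrix`.
#' @return Named numeric vector of K_a in [0, 1].
#' @export
ks_vs_pooled <- function(matrix) {
  x <- em_values(matrix)
  if (ncol(x) < 2L) stop("need at least 2 arrays")
  pooled <- sort(as.vector(x))
  N <- length(pooled)
  m <- nrow(x)
  scores <- apply(x, 2, function(col) {
    s <- sort(col)
    # evaluate both ECDFs at every jump point of either
    pts <- sort(unique(c(s, pooled)))
    fa <- findInterval(pts, s) / m
    fp <- findInterval(pts, pooled) / N
    max(abs(fa - fp))
  })
  names(scores) <- colnames(x)
  scores
}

# midrank comparator: 1 if a < b, 1/2 if a == b, 0 otherwise
.phi <- function(a, b) (a < b) + 0.5 * (a == b)

#' Hoeffding's D statistic of bivariate dependence
#'
#' Classical rank-based D with midranks for ties:
#' `D = 30 * ((n-2)(n-3) D1 + D2 - 2(n-2) D3) /
#'  (n(n-1)(n-2)(n-3)(n-4))` with `D1 = sum (Q-1)(Q-2)`,
#' `D2 = sum (R-1)(R-2)(S-1)(S-2)`, `D3 = sum (R-2)(S-2)(Q-1)`, where R and S
#' are the univariate midranks of x and y and Q the bivariate ranks
#' (`Q_i = 1 + sum_{j != i} phi(x_j, x_i) phi(y_j, y_i)` with
#' `phi(a,b) = 1` if `a < b`, `1/2` on ties, else 0). Ranges roughly in
#' [-0.5, 1]; near 0 under independence.
#'
#' @param x,y Numeric vectors of equal length `n >= 5`.
#' @return Scalar D.
#' @export
hoeffding_d <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (n < 5L) stop("undefined denominator: Hoeffding's D needs n >= 5")
  R <- rank(x, ties.method = "average")
  S <- rank(y, ties.method = "average")
  ux <- outer(x, x, .phi)   # ux[j, i] = phi(x_j, x_i)
  uy <- outer(y, y, .phi)
  Q <- 1 + colSums(ux * uy) - 0.25  # remove the j == i term (phi = 1/2 squared)
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Hoeffding's D of each array's (A, M) values against a median pseudo-array
#'
#' For array a with values `x_fa` and feature-wise median pseudo-array `m_f`:
#' `A = (x_fa + m_f) / 2`, `M = x_fa - m_f`; `D_a = hoeffding_d(A, M)`.
#'
#' @param matrix Numeric matrix (features x arrays) or `ExpressionMatrix`.
#' @return Named numeric vector of D_a.
#' @export
hoeffding_ma_scores <- function(matrix) {
  x <- em_values(matrix)
  m <- apply(x, 1, stats::median)
  scores <- apply(x, 2, function(col)
    hoeffding_d((col + m) / 2, col - m))
  names(scores) <- colnames(x)
  scores
}

boxplot_fence <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Flag outlier arrays by the fail-all-three rule
#'
#' Computes d_a, K_a and D_a for every array of one cohort matrix and flags an
#' array as an outlier only if it exceeds the threshold on all three
#' statistics. Default thresholds: boxplot upper fence (Q3 + 1.5 IQR across
#' arrays) for d_a and K_a, fixed 0.15 for D_a; any can be overridden with a
#' fixed number.
#'
#' @param matrix Log-scale numeric matrix (features x arrays) or
#'   `ExpressionMatrix` for one study/cohort matrix.
#' @param thresholds List with elements `distance`, `ks`, `hoeffding`; each
#'   either `"boxplot"` or a fixed numeric threshold.
#' @return An `ArrayQcReport` data.frame: one row per array with the three
#'   statistics, the thresholds used, per-statistic fail flags, and the
#'   overall `outlier` flag.
#' @export
flag_outliers <- function(matrix,
                          thresholds = list(distance = "boxplot",
                                            ks = "boxplot",
                                            hoeffding = 0.15)) {
  x <- em_values(matrix)
  d <- pairwise_distance_scores(x)
  k <- ks_vs_pooled(x)
  h <- hoeffding_ma_scores(x)
  resolve <- function(th, v) if (identical(th, "boxplot")) boxplot_fence(v)
    else as.numeric(th)
  th_d <- resolve(thresholds$distance, d)
  th_k <- resolve(thresholds$ks, k)
  th_h <- resolve(thresholds$hoeffding, h)
  report <- data.frame(
    array_id = colnames(x),
    distance_score = as.numeric(d), ks_score = as.numeric(k),
    hoeffding_score = as.numeric(h),
    distance_threshold = th_d, ks_threshold = th_k, hoeffding_threshold = th_h,
    distance_fail = as.numeric(d) > th_d,
    ks_fail = as.numeric(k) > th_k,
    hoeffding_fail = as.numeric(h) > th_h,
    stringsAsFactors = FALSE)
  report$outlier <- report$distance_fail & report$ks_fail &
    report$hoeffding_fail
  class(report) <- c("ArrayQcReport", "data.frame")
  report
}

#' Run QC per cohort matrix over a whole bundle
#'
#' Applies [flag_outliers()] within each `matrix_name` group (cohort x
#' specimen), since intensity distributions differ across platforms, and
#' optionally drops flagged arrays.
#'
#' @param bundle A `CompendiumBundle` (log-scale expression).
#' @param thresholds As in [flag_outliers()].
#' @param drop If TRUE, remove flagged arrays from the bundle.
#' @return List with `report` (row-bound `ArrayQcReport` with a `matrix_name`
#'   column) and `bundle` (unchanged, or with outliers removed).
#' @export
qc_bundle <- function(bundle, thresholds = list(distance = "boxplot",
                                                ks = "boxplot",
                                                hoeffding = 0.15),
                      drop = TRUE) {
  stopifnot(inherits(bundle, "CompendiumBundle"))
  groups <- split(bundle$samples$sample_id, bundle$samples$matrix_name)
  reports <- lapply(names(groups), function(mn) {
    rep <- flag_outliers(
      bundle$expression$values[, groups[[mn]], drop = FALSE], thresholds)
    rep$matrix_name <- mn
    rep
  })
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  out <- bundle
  flagged <- report$array_id[report$outlier]
  if (drop && length(flagged)) {
    out <- subset_bundle(bundle,
                         setdiff(bundle$samples$sample_id, flagged),
                         stage = "qc_outliers")
  } else {
    out <- add_provenance(bundle, "qc_outliers",
                          list(flagged = length(flagged), dropped = FALSE),
                          nrow(bundle$samples), nrow(bundle$samples))
  }
  list(report = report, bundle = out)
}
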