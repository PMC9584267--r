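# Sex imputation from a Y-chromosome gene panel (MDS + 2-means, higher mean
# Y expression = male) with per-participant reconciliation, and age imputation
# by correlation staging against a spline-interpolated reference.

#' Impute Y-chromosome presence per sample within one study
#'
#' Classical multidimensional scaling of Euclidean distances between samples
#' on the Y-gene panel, followed by k-means with k = 2 (multiple restarts,
#' seeded). The cluster with the higher mean Y-panel expression is labeled
#' male (Y present). If the standardized separation between the two clusters
#' (gap of cluster means of the per-sample mean Y expression, divided by the
#' pooled within-cluster SD) falls below `separation_threshold`, the study is
#' degenerate (e.g. single-sex) and all calls abstain as `"unknown"`.
#'
#' @param matrix Log-scale matrix or `ExpressionMatrix`, samples in columns;
#'   rows are intersected with `y_genes` (at least 3 must be present).
#' @param y_genes Y-panel gene symbols (default: the 13-gene panel
#'   [Y_GENE_PANEL]).
#' @param seed Integer seed for the k-means restarts.
#' @param separation_threshold Abstention threshold (default 2).
#' @return A `SexCall` data.frame: `sample_id`, `cluster`, `mean_y`, `label`,
#'   with attribute `separation`.
#' @export
impute_sex_study <- function(matrix, y_genes = Y_GENE_PANEL, seed = 1,
                             separation_threshold = 2) {
  x <- em_values(matrix)
  panel <- intersect(y_genes, rownames(x))
  if (length(panel) < 3L)
    stop("fewer than 3 Y-panel genes available (",
         length(panel), ")")
  if (ncol(x) < 2L) stop("need at least 2 samples")
  xp <- x[panel, , drop = FALSE]
  mean_y <- colMeans(xp)
  dmat <- stats::dist(t(xp))
  if (max(dmat) == 0) {
    # all samples identical on the panel: clustering is undefined, abstain
    out <- data.frame(sample_id = colnames(x), cluster = 1L,
                      mean_y = mean_y, label = "unknown",
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "separation") <- 0
    class(out) <- c("SexCall", "data.frame")
    return(out)
  }
  k <- min(2L, ncol(x) - 1L)
  mds <- stats::cmdscale(dmat, k = min(2L, ncol(x) - 1L))
  set.seed(seed)
  km <- stats::kmeans(mds, centers = 2L, nstart = 25L)
  cl <- km$cluster
  m1 <- mean(mean_y[cl == 1]); m2 <- mean(mean_y[cl == 2])
  male_cluster <- if (m1 >= m2) 1L else 2L
  gap <- abs(m1 - m2)
  wss <- c(stats::var(mean_y[cl == 1]) * (sum(cl == 1) - 1),
           stats::var(mean_y[cl == 2]) * (sum(cl == 2) - 1))
  wss[is.na(wss)] <- 0
  pooled_sd <- sqrt(sum(wss) / max(length(cl) - 2, 1))
  separation <- if (pooled_sd == 0) {
    if (gap == 0) 0 else Inf
  } else gap / pooled_sd
  label <- if (separation < separation_threshold)
    rep("unknown", length(cl))
  else ifelse(cl == male_cluster, "male", "female")
  out <- data.frame(sample_id = colnames(x), cluster = cl, mean_y = mean_y,
                    label = label, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "separation") <- separation
  class(out) <- c("SexCall", "data.frame")
  out
}

#' Reconcile per-sample sex calls to one label per participant
#'
#' If all of a participant's timepoints agree, that imputed label is used.
#' On disagreement, the reported sex wins when available; otherwise a strict
#' majority decides, and an exact tie yields `"unknown"`.
#'
#' @param calls Data.frame with `sample_id` and `label`
#'   (e.g. a [impute_sex_study()] result) plus a `participant_id` column, or
#'   supply `participant_id` separately as a vector aligned with `calls`.
#' @param reported Optional named character vector participant -> reported sex
#'   (`"female"`/`"male"`; NA or missing names mean unreported).
#' @param participant_id Optional vector overriding `calls$participant_id`.
#' @return Data.frame with one row per participant: `participant_id`, `label`,
#'   `source` (`imputed`, `reported`, `majority`).
#' @export
reconcile_sex <- function(calls, reported = NULL, participant_id = NULL) {
  pid <- participant_id %||% calls$participant_id
  stopifnot(!is.null(pid), length(pid) == nrow(calls))
  res <- lapply(split(calls$label, pid), function(lab) {
    lab <- lab[lab != "unknown"]
    if (!length(lab)) return(c("unknown", "imputed"))
    if (length(unique(lab)) == 1L) return(c(lab[1], "imputed"))
    c(NA_character_, "conflict")
  })
  out <- data.frame(participant_id = names(res),
                    label = vapply(res, `[`, "", 1),
                    source = vapply(res, `[`, "", 2),
                    stringsAsFactors = FALSE, row.names = NULL)
  conflict <- out$source == "conflict"
  for (i in which(conflict)) {
    p <- out$participant_id[i]
    rep_sex <- if (!is.null(reported)) reported[p] else NA_character_
    if (!is.na(rep_sex) && rep_sex %in% c("female", "male")) {
      out$label[i] <- rep_sex
      out$source[i] <- "reported"
    } else {
      lab <- calls$label[pid == p & calls$label != "unknown"]
      tab <- sort(table(lab), decreasing = TRUE)
      if (length(tab) > 1L && tab[1] == tab[2]) {
        out$label[i] <- "unknown"
      } else {
        out$label[i] <- names(tab)[1]
      }
      out$source[i] <- "majority"
    }
  }
  out
}

#' Impute sex across a bundle, study by study
#'
#' Runs [impute_sex_study()] within each study and reconciles per participant
#' against any reported sex, writing `y_present` (present/absent/unknown) and
#' `sex_imputed` back into the sample table.
#'
#' @param bundle A `CompendiumBundle` with log-scale expression.
#' @param y_genes Y-panel gene symbols.
#' @param seed Integer seed.
#' @param separation_threshold Abstention threshold per study.
#' @return The bundle with `sex_imputed`, `sex_source`, `y_present` columns.
#' @export
impute_sex <- function(bundle, y_genes = Y_GENE_PANEL, seed = 1,
                       separation_threshold = 2) {
  stopifnot(inherits(bundle, "CompendiumBundle"))
  s <- bundle$samples
  all_calls <- do.call(rbind, lapply(split(seq_len(nrow(s)),
                                           s$study_accession),
    function(idx) {
      calls <- impute_sex_study(
        bundle$expression$values[, s$sample_id[idx], drop = FALSE],
        y_genes = y_genes, seed = seed,
        separation_threshold = separation_threshold)
      calls$participant_id <- s$participant_id[idx]
      calls
    }))
  reported <- tapply(s$sex_reported, s$participant_id, function(v) {
    v <- v[!is.na(v) & v %in% c("female", "male")]
    if (length(v)) v[1] else NA_character_
  })
  rec <- reconcile_sex(all_calls, reported = reported)
  lab <- stats::setNames(rec$label, rec$participant_id)
  src <- stats::setNames(rec$source, rec$participant_id)
  bundle$samples$sex_imputed <- unname(lab[s$participant_id])
  bundle$samples$sex_source <- unname(src[s$participant_id])
  bundle$samples$y_present <- c(male = "present", female = "absent",
                                unknown = "unknown")[
                                  bundle$samples$sex_imputed]
  add_provenance(bundle, "impute_sex",
                 list(n_unknown = sum(rec$label == "unknown")),
                 nrow(s), nrow(s))
}

#' Build an interpolated age reference from known-age baseline samples
#'
#' Per gene, expression is fitted as a smooth function of age (natural cubic
#' spline, default 4 df) plus optional additive covariate terms, then the
#' covariate-adjusted fit is evaluated on a fine age grid (covariates held at
#' their reference level / mean).
#'
#' @param matrix Gene-level matrix or `ExpressionMatrix` of baseline samples
#'   with known age.
#' @param age Numeric vector of ages, one per sample.
#' @param covariates Optional data.frame of additional additive covariates.
#' @param grid_step Age grid step in years (default 0.25).
#' @param spline_df Spline degrees of freedom (default 4).
#' @return An `AgeReference`: list with `grid` (years), `profile` (genes x
#'   grid), `covariates` (names used), `genes`.
#' @export
build_age_reference <- function(matrix, age, covariates = NULL,
                                grid_step = 0.25, spline_df = 4) {
  x <- em_values(matrix)
  stopifnot(length(age) == ncol(x), all(is.finite(age)))
  if (ncol(x) < 20L) stop("need at least 20 known-age samples")
  if (diff(range(age)) < 15) stop("ages must span at least 15 years")
  grid <- seq(min(age), max(age), by = grid_step)
  basis <- splines::ns(age, df = spline_df)
  X <- cbind(1, basis)
  cov_names <- character()
  if (!is.null(covariates) && ncol(as.data.frame(covariates))) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  keep <- rank_filter(X)
  X <- X[, keep, drop = FALSE]
  fit <- stats::lm.fit(X, t(x))
  coefs <- t(fit$coefficients)              # genes x columns
  grid_basis <- stats::predict(basis, grid)
  Xg <- cbind(1, grid_basis)
  # covariate columns held at zero (reference level / centered)
  n_spline_cols <- 1 + ncol(basis)
  spline_keep <- keep[seq_len(n_spline_cols)]
  profile <- coefs[, seq_len(sum(spline_keep)), drop = FALSE] %*%
    t(Xg[, spline_keep, drop = FALSE])
  dimnames(profile) <- list(rownames(x), NULL)
  rng <- apply(profile, 1, function(r) diff(range(r)))
  structure(list(grid = grid, profile = profile, covariates = cov_names,
                 genes = rownames(x), dynamic_range = rng),
            class = "AgeReference")
}

#' Estimate age by correlation staging against a reference
#'
#' The point estimate is the grid age maximizing the Spearman correlation
#' between the sample profile and the reference column; the confidence
#' interval is the empirical 2.5/97.5 percentile of estimates over `n_boot`
#' random gene subsets of size `gene_fraction` of the staging genes.
#'
#' Staging is restricted to genes that actually move across the reference
#' grid: genes whose reference dynamic range is at least `min_range_factor`
#' times the median range (at least 50 genes are always retained, topped up by
#' range). Genes that are flat in the reference carry no age information and
#' only dilute the rank correlation.
#'
#' @param profile Named numeric vector of gene-level expression for one
#'   sample.
#' @param reference An `AgeReference`.
#' @param n_boot Bootstrap replicates (default 30).
#' @param gene_fraction Fraction of staging genes per bootstrap subset
#'   (default 0.5).
#' @param seed Integer seed.
#' @param min_range_factor Dynamic-range cutoff as a multiple of the median
#'   reference range (default 2; set to 0 to stage on all shared genes).
#' @return An `AgeEstimate` list: `estimate`, `lo`, `hi`, `n_boot`,
#'   `correlation` (at the optimum), `n_genes`.
#' @export
estimate_age <- function(profile, reference, n_boot = 30,
                         gene_fraction = 0.5, seed = 1,
                         min_range_factor = 2) {
  stopifnot(inherits(reference, "AgeReference"))
  shared <- intersect(names(profile), reference$genes)
  if (length(shared) < 50L)
    stop("need at least 50 genes shared with the reference (have ",
         length(shared), ")")
  rng <- reference$dynamic_range[shared]
  sel <- rng >= min_range_factor * stats::median(rng)
  if (sum(sel) < 50L)
    sel[order(rng, decreasing = TRUE)[seq_len(min(50L, length(rng)))]] <- TRUE
  shared <- shared[sel]
  q <- profile[shared]
  R <- reference$profile[shared, , drop = FALSE]
  stage <- function(idx) {
    cors <- suppressWarnings(
      stats::cor(q[idx], R[idx, , drop = FALSE], method = "spearman"))
    if (all(is.na(cors))) return(c(NA_real_, NA_real_))
    j <- which.max(cors)
    c(reference$grid[j], cors[j])
  }
  full <- stage(seq_along(shared))
  if (is.na(full[1])) {
    warning("degenerate correlation profile; age unknown")
    return(structure(list(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                          n_boot = n_boot, correlation = NA_real_,
                          n_genes = length(shared)), class = "AgeEstimate"))
  }
  set.seed(seed)
  m <- max(2L, floor(gene_fraction * length(shared)))
  boots <- vapply(seq_len(n_boot), function(b)
    stage(sample.int(length(shared), m))[1], numeric(1))
  boots <- boots[!is.na(boots)]
  ci <- if (length(boots)) stats::quantile(boots, c(0.025, 0.975),
                                           names = FALSE)
        else c(NA_real_, NA_real_)
  structure(list(estimate = full[1],
                 lo = min(ci[1], full[1]), hi = max(ci[2], full[1]),
                 n_boot = n_boot, correlation = full[2],
                 n_genes = length(shared)), class = "AgeEstimate")
}

#' @export
print.AgeEstimate <- function(x, ...) {
  cat(sprintf("AgeEstimate: %.1f years [%.1f, %.1f] (rho = %.3f, %d genes)\n",
              x$estimate, x$lo, x$hi, x$correlation, x$n_genes))
  invisible(x)
}

#' Select the best age-model covariate set by leave-one-study-out error
#'
#' Samples are split at age 50 into young (< 50) and old (>= 50) pools. For
#' each pool and candidate covariate set, each study is held out in turn, a
#' reference is built from the remaining studies, held-out reported ages are
#' estimated, and the candidate with the lowest RMSE wins (R-squared is also
#' reported). A pool with fewer than 2 studies is evaluated in-sample with a
#' warning.
#'
#' @param matrix Gene-level matrix of baseline samples.
#' @param samples Sample data.frame with `study_accession`, `age_reported`,
#'   and any candidate covariate columns.
#' @param candidates List of character vectors of covariate column names (use
#'   `character(0)` for the no-covariate model). A single candidate is
#'   returned directly.
#' @param split_age Pool boundary (default 50; a 50-year-old is "old").
#' @param grid_step,spline_df,seed Passed through to the reference builder and
#'   estimator.
#' @return List with per-pool elements `young` and `old`, each containing
#'   `best` (covariate set) and `metrics` (data.frame candidate/RMSE/R2).
#' @export
select_age_model <- function(matrix, samples, candidates, split_age = 50,
                             grid_step = 1, spline_df = 4, seed = 1) {
  x <- em_values(matrix)
  stopifnot(nrow(samples) == ncol(x), length(candidates) >= 1)
  age <- samples$age_reported
  pools <- list(young = which(age < split_age),
                old = which(age >= split_age))
  out <- list()
  for (pool_name in names(pools)) {
    idx <- pools[[pool_name]]
    if (length(idx) < 25L) {
      out[[pool_name]] <- list(best = candidates[[1]],
                               metrics = NULL, note = "pool too small")
      next
    }
    xs <- x[, idx, drop = FALSE]
    ss <- samples[idx, , drop = FALSE]
    metrics <- data.frame(candidate = I(candidates), rmse = NA_real_,
                          r2 = NA_real_)
    for (ci in seq_along(candidates)) {
      covs <- candidates[[ci]]
      pred <- rep(NA_real_, ncol(xs))
      studies <- unique(ss$study_accession)
      in_sample <- length(studies) < 2L
      if (in_sample)
        warning("pool '", pool_name,
                "' has < 2 studies; in-sample evaluation")
      for (study in studies) {
        test <- if (in_sample) seq_len(ncol(xs))
                else which(ss$study_accession == study)
        train <- if (in_sample) seq_len(ncol(xs)) else setdiff(
          seq_len(ncol(xs)), test)
        ref <- tryCatch(build_age_reference(
          xs[, train, drop = FALSE], ss$age_reported[train],
          covariates = if (length(covs))
            ss[train, covs, drop = FALSE] else NULL,
          grid_step = grid_step, spline_df = spline_df),
          error = function(e) NULL)
        if (is.null(ref)) next
        for (j in test)
          pred[j] <- estimate_age(xs[, j], ref, n_boot = 0,
                                  seed = seed)$estimate
        if (in_sample) break
      }
      ok <- !is.na(pred)
      if (sum(ok) >= 3) {
        err <- pred[ok] - ss$age_reported[ok]
        metrics$rmse[ci] <- sqrt(mean(err^2))
        sst <- sum((ss$age_reported[ok] - mean(ss$age_reported[ok]))^2)
        metrics$r2[ci] <- 1 - sum(err^2) / sst
      }
    }
    best <- which.min(metrics$rmse)
    out[[pool_name]] <- list(best = candidates[[best]], metrics = metrics)
  }
  out
}
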