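# Baseline-anchored batch model: per-gene OLS of expression on age,
# Y-presence, batch key (study x cohort), platform and specimen with treatment
# coding; aliased design columns are dropped deterministically (platform and
# specimen columns are absorbed into the batch key when fully confounded).
# Estimated batch terms are then subtracted from every sample at every
# timepoint; biological covariates (age, Y-presence) are never removed.

batch_key_of <- function(samples)
  paste(samples$study_accession, samples$cohort_label, sep = "|")

# Build the design in ordered blocks and keep columns greedily by rank, so
# confounded platform/specimen columns are the ones dropped.
build_design <- function(samples, levels_info = NULL) {
  key <- batch_key_of(samples)
  if (is.null(levels_info)) {
    levels_info <- list(
      batch = sort(unique(key)),
      platform = sort(unique(samples$platform_vendor)),
      specimen = sort(unique(samples$specimen_type)))
  } else {
    unseen <- setdiff(unique(key), levels_info$batch)
    if (length(unseen))
      stop("unseen batch level(s): ", paste(unseen, collapse = ", "))
  }
  n <- nrow(samples)
  dummies <- function(x, levs, block) {
    if (length(levs) < 2L)
      return(NULL)
    cols <- lapply(levs[-1], function(l) as.numeric(x == l))
    m <- do.call(cbind, cols)
    colnames(m) <- paste0(block, ":", levs[-1])
    m
  }
  age <- samples$age_reported
  if ("age_imputed" %in% names(samples))
    age <- ifelse(is.na(age), samples$age_imputed, age)
  if (all(is.na(age))) age <- NULL
  else age <- ifelse(is.na(age), mean(age, na.rm = TRUE), age)
  ycol <- if ("y_present" %in% names(samples)) samples$y_present
          else samples$sex_reported
  yblock <- NULL
  if (!is.null(ycol) && !all(is.na(ycol))) {
    ycol <- ifelse(is.na(ycol), "unknown", as.character(ycol))
    ylevs <- sort(unique(ycol))
    yblock <- dummies(ycol, ylevs, "y")
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  block <- "intercept"
  if (!is.null(age)) {
    X <- cbind(X, age = age - mean(age))
    block <- c(block, "covariate")
  }
  if (!is.null(yblock)) {
    X <- cbind(X, yblock)
    block <- c(block, rep("covariate", ncol(yblock)))
  }
  for (b in list(c("batch", "batch"), c("platform", "platform"),
                 c("specimen", "specimen"))) {
    vals <- switch(b[1], batch = key,
                   platform = samples$platform_vendor,
                   specimen = samples$specimen_type)
    d <- dummies(vals, levels_info[[b[1]]], b[1])
    if (!is.null(d)) {
      X <- cbind(X, d)
      block <- c(block, rep(b[2], ncol(d)))
    }
  }
  list(X = X, block = block, levels_info = levels_info)
}

# greedy rank filter in column order: earlier blocks win over later ones
rank_filter <- function(X) {
  keep <- logical(ncol(X))
  qr_rank <- 0L
  kept <- NULL
  for (j in seq_len(ncol(X))) {
    cand <- cbind(kept, X[, j])
    r <- qr(cand)$rank
    if (r > qr_rank) {
      keep[j] <- TRUE
      kept <- cand
      qr_rank <- r
    }
  }
  keep
}

#' Fit the per-gene batch model on baseline samples
#'
#' Restricts the bundle to pre-vaccination samples (`time_days <= 0`) and fits,
#' per gene, an ordinary-least-squares model of expression on intercept, age,
#' Y-presence, batch key (study x cohort), platform vendor and specimen type
#' with treatment coding. Collinear columns (typically platform, which is
#' constant within study) are detected by rank analysis and dropped in a fixed
#' order, so fully confounded platform effects are absorbed into the batch-key
#' coefficients. Multi-cohort studies contribute one batch level per cohort.
#'
#' @param bundle A `CompendiumBundle`; only its baseline samples are used.
#' @return A `BatchModel`: list with `coefficients` (genes x kept columns),
#'   `se` (matching standard errors), `blocks` (column block labels),
#'   `aliased` (dropped column names), `levels_info` (factor levels with the
#'   first level of each as reference), and `n_baseline`.
#' @export
fit_batch_model <- function(bundle) {
  stopifnot(inherits(bundle, "CompendiumBundle"))
  base <- bundle$samples$time_days <= 0
  if (!any(base)) stop("no baseline (time_days <= 0) samples")
  samples <- bundle$samples[base, , drop = FALSE]
  Y <- bundle$expression$values[, samples$sample_id, drop = FALSE]
  d <- build_design(samples)
  keep <- rank_filter(d$X)
  X <- d$X[, keep, drop = FALSE]
  if (ncol(X) == 0L || qr(X)$rank == 0L)
    stop("design rank 0 after aliasing")
  fit <- stats::lm.fit(X, t(Y))
  coefs <- t(fit$coefficients)        # genes x columns
  n <- nrow(X); p <- ncol(X)
  res <- fit$residuals                 # n x genes
  sigma2 <- colSums(res^2) / max(n - p, 1)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(outer(sigma2, diag(xtx_inv)))
  dimnames(se) <- dimnames(coefs)
  structure(list(coefficients = coefs, se = se, blocks = d$block[keep],
                 aliased = colnames(d$X)[!keep],
                 levels_info = d$levels_info,
                 n_baseline = n), class = "BatchModel")
}

#' Remove estimated batch effects from every sample
#'
#' Subtracts the fitted batch-key, platform and specimen terms from all
#' samples at all timepoints; age and Y-presence terms are left in place.
#' Samples whose batch level was unseen at fit time raise an error naming it.
#'
#' @param bundle A `CompendiumBundle` (all timepoints).
#' @param model A `BatchModel` from [fit_batch_model()].
#' @return The bundle with corrected expression (scale `"batch_corrected"`).
#' @export
remove_batch_effects <- function(bundle, model) {
  stopifnot(inherits(bundle, "CompendiumBundle"),
            inherits(model, "BatchModel"))
  d <- build_design(bundle$samples, model$levels_info)
  cols <- colnames(model$coefficients)
  batch_cols <- cols[model$blocks %in% c("batch", "platform", "specimen")]
  missing_cols <- setdiff(batch_cols, colnames(d$X))
  if (length(missing_cols))
    stop("batch design columns missing on new data: ",
         paste(missing_cols, collapse = ", "))
  Xb <- d$X[, batch_cols, drop = FALSE]
  B <- model$coefficients[, batch_cols, drop = FALSE]
  corrected <- bundle$expression$values - B %*% t(Xb)
  bundle$expression <- expression_matrix(corrected, "batch_corrected")
  add_provenance(bundle, "remove_batch_effects",
                 list(columns = length(batch_cols)),
                 nrow(bundle$samples), nrow(bundle$samples))
}

#' Principal component analysis of an expression matrix
#'
#' Genes are centered, samples are observations. Returns scores (samples x
#' components), eigenvalues of the sample covariance (non-increasing), and the
#' fraction of total variance per component.
#'
#' @param matrix `ExpressionMatrix` or bare matrix (genes x samples).
#' @param n_components Number of components (truncated to the rank, with a
#'   warning, when it exceeds it).
#' @return List with `scores`, `eigenvalues`, `var_explained`.
#' @export
compute_pca <- function(matrix, n_components = 10) {
  x <- em_values(matrix)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_components > rank) {
    warning("n_components exceeds rank ", rank, "; truncated")
    n_components <- rank
  }
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       eigenvalues = ev[seq_len(n_components)],
       var_explained = ev[seq_len(n_components)] / sum(ev))
}

# method-of-moments variance components: per factor, one-way ANOVA estimate
mom_components <- function(score, factors) {
  out <- vapply(factors, function(f) {
    f <- factor(f)
    ni <- tabulate(f)
    k <- nlevels(f); n <- length(score)
    gm <- mean(score)
    means <- tapply(score, f, mean)
    ssb <- sum(ni * (means[levels(f)] - gm)^2)
    ssw <- sum((score - means[f])^2)
    msb <- ssb / max(k - 1, 1)
    msw <- ssw / max(n - k, 1)
    n0 <- (n - sum(ni^2) / n) / max(k - 1, 1)
    max((msb - msw) / n0, 0)
  }, numeric(1))
  resid <- max(stats::var(score) - sum(out), 0)
  c(out, Residual = resid)
}

#' Principal variance component analysis (PVCA)
#'
#' Takes the leading principal components reaching a cumulative variance
#' threshold, fits per PC a random-effects model with every supplied factor as
#' a random intercept (REML via lme4; a method-of-moments fall-back is used,
#' with a warning, if the mixed model fails), converts the variance components
#' of each PC to proportions, and averages them across PCs weighted by
#' eigenvalue share. Fractions are non-negative and sum to 1.
#'
#' @param matrix `ExpressionMatrix` or bare matrix (genes x samples).
#' @param sample_factors data.frame (one row per sample, matrix column order)
#'   of factors, e.g. study, platform, specimen. Factors with fewer than 2
#'   levels are dropped with a warning.
#' @param cum_var_threshold Cumulative variance cutoff selecting the number of
#'   PCs (default 0.6; at least one PC is always used).
#' @return A `VarianceDecomposition`: named numeric vector of fractions (one
#'   per factor plus `Residual`), with attributes `n_pcs` and
#'   `cum_var_threshold`.
#' @export
pvca <- function(matrix, sample_factors, cum_var_threshold = 0.6) {
  x <- em_values(matrix)
  stopifnot(is.data.frame(sample_factors),
            nrow(sample_factors) == ncol(x))
  usable <- vapply(sample_factors, function(f)
    length(unique(f)) >= 2L, logical(1))
  if (!all(usable)) {
    warning("dropping single-level factor(s): ",
            paste(names(sample_factors)[!usable], collapse = ", "))
    sample_factors <- sample_factors[, usable, drop = FALSE]
  }
  if (!ncol(sample_factors)) stop("no usable factors")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  prop <- ev / sum(ev)
  k <- max(1L, which(cumsum(prop) >= cum_var_threshold)[1])
  if (is.na(k)) k <- length(ev)
  w <- prop[seq_len(k)] / sum(prop[seq_len(k)])
  fnames <- names(sample_factors)
  per_pc <- matrix(0, k, length(fnames) + 1,
                   dimnames = list(NULL, c(fnames, "Residual")))
  dat <- as.data.frame(lapply(sample_factors, factor))
  for (i in seq_len(k)) {
    dat$.score <- pc$x[, i]
    form <- stats::as.formula(paste(".score ~",
      paste(sprintf("(1 | %s)", fnames), collapse = " + ")))
    vc <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(form, data = dat, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore"))))
      v <- as.data.frame(lme4::VarCorr(fit))
      comp <- stats::setNames(v$vcov, v$grp)
      c(comp[fnames], Residual = unname(comp["Residual"]))
    }, error = function(e) {
      warning("mixed model failed for PC", i,
              "; using method-of-moments components")
      mom_components(dat$.score, sample_factors)
    })
    vc[is.na(vc)] <- 0
    per_pc[i, ] <- vc / sum(vc)
  }
  fractions <- colSums(per_pc * w)
  fractions <- fractions / sum(fractions)
  structure(fractions, n_pcs = k, cum_var_threshold = cum_var_threshold,
            class = c("VarianceDecomposition", class(fractions)))
}

#' @export
print.VarianceDecomposition <- function(x, ...) {
  cat("PVCA variance fractions (", attr(x, "n_pcs"), " PCs):\n", sep = "")
  print(round(unclass(stats::setNames(as.numeric(x), names(x))), 4))
  invisible(x)
}
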