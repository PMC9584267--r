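# Stage orchestration: named stages with dependency ordering, and the
# end-to-end build that emits the standard variant grid
# {all, young, old, extendedOld} x {noNorm, norm} x {, withResponse}.

STAGE_ORDER <- c("qc", "normalize_within", "normalize_cross", "impute_sex",
                 "impute_age", "fit_batch", "correct", "endpoints")

#' Validate a pipeline configuration
#'
#' A configuration is a list (or YAML file path) with a mandatory integer
#' `seed`, an optional ordered `stages` character vector (subset of the
#' registry, in dependency order), an optional `out_dir`, and per-stage
#' parameter lists under the stage names.
#'
#' @param config List or path to a YAML file.
#' @return The normalized config list; errors enumerate schema violations.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  problems <- character()
  if (is.null(config$seed) || !is.finite(as.numeric(config$seed)))
    problems <- c(problems, "missing or non-numeric 'seed'")
  stages <- config$stages %||% STAGE_ORDER
  unknown <- setdiff(stages, STAGE_ORDER)
  if (length(unknown))
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(unknown, collapse = ", ")))
  pos <- match(stages, STAGE_ORDER)
  if (!length(unknown) && is.unsorted(pos))
    problems <- c(problems,
                  paste0("stage order violates dependencies: ",
                         paste(stages, collapse = " -> ")))
  if (length(problems))
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  config$stages <- stages
  config$seed <- as.integer(config$seed)
  config
}

#' Run one registered pipeline stage
#'
#' Applies the named stage to a bundle, appends a provenance entry (stage,
#' parameters, counts) and reports wall time on the message stream. Shared
#' artifacts (target distribution, batch model, endpoint table) travel in
#' `state`.
#'
#' @param name Stage name (see `STAGE_ORDER` in the package source).
#' @param bundle A `CompendiumBundle`.
#' @param params Stage parameter list.
#' @param state Named list of shared artifacts from earlier stages.
#' @return List with `bundle` and updated `state`.
#' @export
run_stage <- function(name, bundle, params = list(), state = list()) {
  t0 <- proc.time()[["elapsed"]]
  out <- switch(name,
    qc = {
      res <- qc_bundle(bundle,
                       thresholds = params$thresholds %||%
                         list(distance = "boxplot", ks = "boxplot",
                              hoeffding = 0.15))
      state$qc_report <- res$report
      list(bundle = res$bundle, state = state)
    },
    normalize_within = {
      s <- bundle$samples
      v <- bundle$expression$values
      for (ids in split(s$sample_id, s$matrix_name)) {
        if (length(ids) >= 2L)
          v[, ids] <- quantile_normalize_within(v[, ids, drop = FALSE])
      }
      bundle$expression <- expression_matrix(v, "within_normalized")
      bundle <- add_provenance(bundle, "normalize_within", list(),
                               nrow(s), nrow(s))
      list(bundle = bundle, state = state)
    },
    normalize_cross = {
      s <- bundle$samples
      affy <- s$sample_id[s$platform_vendor == "affymetrix"]
      target <- state$target %||% {
        if (!length(affy))
          stop("no Affymetrix samples; supply an explicit target in state")
        build_target(bundle$expression$values[, affy, drop = FALSE],
                     L = params$L %||% nrow(bundle$expression$values))
      }
      state$target <- target
      bundle$expression <- expression_matrix(
        normalize_to_target(bundle$expression$values, target),
        "cross_normalized")
      bundle <- add_provenance(bundle, "normalize_cross",
                               list(L = length(target$quantiles)),
                               nrow(s), nrow(s))
      list(bundle = bundle, state = state)
    },
    impute_sex = {
      bundle <- impute_sex(bundle, seed = params$seed %||% 1,
                           y_genes = params$y_genes %||% Y_GENE_PANEL)
      list(bundle = bundle, state = state)
    },
    impute_age = {
      known <- !is.na(bundle$samples$age_reported)
      base <- bundle$samples$time_days <= 0
      if (sum(known & base) >= 20 && any(!known)) {
        sex <- bundle$samples$sex_imputed %||% bundle$samples$sex_reported
        covs <- NULL
        if (!is.null(sex) &&
            length(unique(sex[known & base])) > 1L)
          covs <- data.frame(sex = sex[known & base])
        ref <- build_age_reference(
          bundle$expression$values[, bundle$samples$sample_id[known & base],
                                   drop = FALSE],
          bundle$samples$age_reported[known & base],
          covariates = covs,
          grid_step = params$grid_step %||% 0.5)
        state$age_reference <- ref
        est <- vapply(which(!known), function(j)
          estimate_age(bundle$expression$values[, j], ref,
                       n_boot = params$n_boot %||% 30,
                       seed = params$seed %||% 1)$estimate, numeric(1))
        bundle$samples$age_imputed[!known] <- est
      }
      bundle <- add_provenance(bundle, "impute_age",
                               list(n_imputed = sum(!known)),
                               nrow(bundle$samples), nrow(bundle$samples))
      list(bundle = bundle, state = state)
    },
    fit_batch = {
      fit_on <- params$fit_on %||% bundle$samples$sample_id
      sub <- subset_bundle(bundle, fit_on, stage = "fit_batch_subset")
      state$batch_model <- fit_batch_model(sub)
      bundle <- add_provenance(bundle, "fit_batch",
                               list(n_fit = length(fit_on)),
                               nrow(bundle$samples), nrow(bundle$samples))
      list(bundle = bundle, state = state)
    },
    correct = {
      if (is.null(state$batch_model))
        stop("dependency violation: 'correct' requires 'fit_batch' first")
      bundle <- remove_batch_effects(bundle, state$batch_model)
      list(bundle = bundle, state = state)
    },
    endpoints = {
      if (is.null(bundle$titers)) {
        state$endpoints <- NULL
      } else {
        pb <- tapply(bundle$samples$pathogen, bundle$samples$study_accession,
                     function(v) v[1])
        state$endpoints <- compute_endpoints(
          bundle$titers, pathogen_by_study = pb,
          post_window = params$post_window %||% c(21, 35))
      }
      bundle <- add_provenance(
        bundle, "endpoints",
        list(n_endpoints = if (is.null(state$endpoints)) 0
             else nrow(state$endpoints)),
        nrow(bundle$samples), nrow(bundle$samples))
      list(bundle = bundle, state = state)
    },
    stop("unknown stage '", name, "'")
  )
  message(sprintf("stage %s: %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

participant_age <- function(samples) {
  age <- samples$age_reported
  if ("age_imputed" %in% names(samples))
    age <- ifelse(is.na(age), samples$age_imputed, age)
  age
}

#' Run the full harmonization pipeline and emit the variant grid
#'
#' Starting from a bundle (or a `SimConfig`, which is generated first), runs
#' QC, within-study quantile normalization, cross-study normalization to the
#' Affymetrix target, sex (and optionally age) imputation, baseline batch
#' model fitting and correction, and endpoint computation. Emits the variant
#' grid: age pools `all`, `young` (18-50), `old` (60-90) and `extendedOld`
#' (50-90), each as `noNorm` (within-study log2-normalized) and `norm`
#' (cross-study normalized and batch corrected) expression, plus
#' `withResponse` counterparts restricted to endpoint-matched participants
#' when titers are present. Batch coefficients for the old/extendedOld `norm`
#' variants are estimated on the young pool.
#'
#' @param config A validated pipeline config list (see [validate_config()])
#'   with optional `sim` sub-list (passed to [sim_config()]) when no bundle is
#'   given.
#' @param bundle Optional input `CompendiumBundle`; default generates the
#'   synthetic compendium from `config$sim` and `config$seed`.
#' @return Named list of `CompendiumBundle` variants; attribute `"state"`
#'   carries the QC report, target, batch models and endpoint table. When
#'   `config$out_dir` is set, each variant is also written as a container
#'   under that directory.
#' @export
run_all <- function(config, bundle = NULL) {
  config <- validate_config(config)
  if (is.null(bundle)) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- config$seed
    bundle <- generate(do.call(sim_config, sim_args))$bundle
  }
  state <- list()
  stages <- config$stages
  pre <- intersect(stages, c("qc", "normalize_within", "impute_sex",
                             "impute_age", "endpoints"))
  for (st in pre) {
    res <- run_stage(st, bundle, config[[st]] %||% list(), state)
    bundle <- res$bundle; state <- res$state
  }
  no_norm <- bundle

  age <- participant_age(bundle$samples)
  pools <- list(
    all = rep(TRUE, nrow(bundle$samples)),
    young = !is.na(age) & age >= 18 & age < 50,
    old = !is.na(age) & age >= 60 & age <= 90,
    extendedOld = !is.na(age) & age >= 50 & age <= 90)

  norm <- bundle
  if ("normalize_cross" %in% stages) {
    res <- run_stage("normalize_cross", norm,
                     config$normalize_cross %||% list(), state)
    norm <- res$bundle; state <- res$state
  }
  variants <- list()
  if (any(c("fit_batch", "correct") %in% stages)) {
    base_ids <- norm$samples$sample_id[norm$samples$time_days <= 0]
    # model for 'all' and 'young': fitted on all baseline samples of the pool
    fit_all <- run_stage("fit_batch", norm, list(fit_on = base_ids), state)
    state <- fit_all$state
    corrected_all <- run_stage("correct", norm, list(), state)$bundle
    young_base <- intersect(base_ids,
                            norm$samples$sample_id[pools$young])
    state_young <- tryCatch(
      run_stage("fit_batch", norm, list(fit_on = young_base), state),
      error = function(e) NULL)
    corrected_young_model <- if (is.null(state_young)) corrected_all else
      tryCatch(run_stage("correct", norm, list(), state_young$state)$bundle,
               error = function(e) corrected_all)
    if (!is.null(state_young))
      state$batch_model_young <- state_young$state$batch_model
  } else {
    corrected_all <- norm
    corrected_young_model <- norm
  }

  for (pool in names(pools)) {
    keep <- pools[[pool]]
    if (!any(keep)) next
    ids <- bundle$samples$sample_id[keep]
    src_norm <- if (pool %in% c("old", "extendedOld"))
      corrected_young_model else corrected_all
    variants[[paste0(pool, "_noNorm")]] <-
      subset_bundle(no_norm, ids, stage = paste0("variant_", pool))
    variants[[paste0(pool, "_norm")]] <-
      subset_bundle(src_norm, ids, stage = paste0("variant_", pool))
  }
  if (!is.null(state$endpoints) && nrow(state$endpoints)) {
    for (nm in names(variants)) {
      wr <- tryCatch(
        suppressWarnings(attach_endpoints(variants[[nm]], state$endpoints)),
        error = function(e) NULL)
      if (!is.null(wr) && nrow(wr$samples))
        variants[[paste0(nm, "_withResponse")]] <- wr
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(variants))
      write_bundle(variants[[nm]],
                   file.path(config$out_dir, paste0(nm, "_bundle.rds")))
  }
  attr(variants, "state") <- state
  variants
}
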