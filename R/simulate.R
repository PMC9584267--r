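# Synthetic multi-study compendium generator with recorded ground truth.
#
# Expression is simulated additively on the log2 scale: per-gene baseline
# profile + per-batch (study x cohort) offsets + platform location shifts +
# specimen offsets + a Y-gene shift for males + linear age trends on an
# age-gene panel + a post-vaccination response kernel scaled by a
# participant-level responder score + noise. Titers follow, per strain,
# log2(post) = log2(base) + a - b*log2(base) + r + eps. The generator is the
# ground-truth oracle for batch recovery, QC flagging, sex/age imputation and
# endpoint tests.

#' Default Y-chromosome gene panel
#'
#' Thirteen genes commonly used to call Y-chromosome presence from blood
#' transcriptomes. The panel is a parameter throughout, not a constant.
#' @export
Y_GENE_PANEL <- c("RPS4Y1", "RPS4Y2", "KDM5D", "DDX3Y", "UTY", "USP9Y",
                  "EIF1AY", "NLGN4Y", "ZFY", "TMSB4Y", "PRKY", "TXLNGY", "SRY")

default_studies <- function() {
  list(
    list(name = "SDY01", n_participants = 20, platform = "affymetrix",
         specimen = "pbmc", timepoints = c(0, 7, 28), cohorts = 1,
         pathogen = "influenza", vaccine = "TIV", vaccine_type = "inactivated",
         assays = c("HAI", "NAb"), n_strains = 3),
    list(name = "SDY02", n_participants = 20, platform = "illumina",
         specimen = "whole_blood", timepoints = c(-7, 0, 7, 28), cohorts = 1,
         pathogen = "influenza", vaccine = "TIV", vaccine_type = "inactivated",
         assays = c("HAI", "NAb"), n_strains = 3),
    list(name = "SDY03", n_participants = 20, platform = "rnaseq",
         specimen = "pbmc", timepoints = c(0, 7, 28), cohorts = 1,
         pathogen = "yellow_fever", vaccine = "YF17D",
         vaccine_type = "live_attenuated", assays = "NAb", n_strains = 1)
  )
}

#' Build a simulation configuration
#'
#' Defaults describe a three-study compendium (20 participants each) on three
#' platforms with 200 genes, strong per-gene study offsets (SD 3 log2 units),
#' moderate specimen offsets, a +4 log2 Y-gene shift in males, a concentrated
#' linear aging signature, a day-7-peaking vaccination response, and titer
#' tables whose log fold change declines with log baseline titer.
#'
#' @param n_studies Number of studies (used only when `studies` is NULL, to
#'   truncate/recycle the default study list).
#' @param studies List of per-study descriptors (see `default_studies` in the
#'   package source for the shape); NULL uses the built-in three-study design.
#' @param n_genes Total genes, including the Y panel.
#' @param n_y_genes Number of Y-panel genes (<= 13 uses the default panel).
#' @param study_effect_sd SD (log2) of per-gene batch (study x cohort) offsets;
#'   the first batch is the reference with zero offset.
#' @param platform_shift Named numeric vector of per-vendor location shifts
#'   (log2); the reference vendor shift should be 0.
#' @param platform_scale Named numeric vector of per-vendor scale factors
#'   applied around the grand mean (1 = none); non-unit scales emulate the
#'   dissimilar intensity distributions that motivate cross-study
#'   normalization and are not removable by the additive batch model.
#' @param specimen_effect_sd SD (log2) of per-gene whole-blood-vs-PBMC offsets.
#' @param sex_effect_size Log2 shift added to Y-panel genes in males.
#' @param n_age_genes,age_slope Size of the aging panel and the typical
#'   magnitude of its trajectories in log2 units per decade. Each aging gene
#'   follows its own sigmoidal trajectory (random direction, onset age and
#'   transition width) whose total amplitude averages `age_slope` per decade
#'   over the age range; trajectory diversity mirrors real transcriptomic
#'   aging and is what makes correlation-based age staging identifiable.
#' @param n_response_genes,response_effect_size Size of the vaccination
#'   response panel and its peak (day 7) amplitude in log2 units per unit of
#'   responder score.
#' @param noise_sd Residual Gaussian noise SD (log2).
#' @param age_range Uniform sampling range for true ages (years).
#' @param titer Named list with elements `a` (mean log2 fold change at
#'   log2 baseline 0), `b` (slope on log2 baseline), `responder_sd`,
#'   `noise_sd`, `baseline_mean`, `baseline_sd` (log2 titer units),
#'   `post_day`.
#' @param n_corrupt Number of corrupt arrays to inject (shift + variance
#'   inflation + partial rank scrambling), for QC testing.
#' @param seed Mandatory integer seed; the whole bundle is a pure function of
#'   the configuration.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_studies = 3, studies = NULL, n_genes = 200,
                       n_y_genes = 13, study_effect_sd = 3,
                       platform_shift = c(affymetrix = 0, illumina = 1.5,
                                          rnaseq = -1, two_color = 0.5,
                                          other = 0),
                       platform_scale = c(affymetrix = 1, illumina = 1,
                                          rnaseq = 1, two_color = 1,
                                          other = 1),
                       specimen_effect_sd = 0.5, sex_effect_size = 4,
                       n_age_genes = 50, age_slope = 0.3,
                       n_response_genes = 30, response_effect_size = 1,
                       noise_sd = 0.3, age_range = c(18, 85),
                       titer = list(a = 3, b = 0.4, responder_sd = 1,
                                    noise_sd = 0.3, baseline_mean = 4.5,
                                    baseline_sd = 1, post_day = 28),
                       n_corrupt = 0, seed) {
  if (missing(seed) || !is.finite(seed)) stop("a seed is mandatory")
  if (is.null(studies)) {
    studies <- default_studies()
    studies <- studies[((seq_len(n_studies) - 1L) %% length(studies)) + 1L]
    for (i in seq_along(studies))
      studies[[i]]$name <- sprintf("SDY%02d", i)
  }
  stopifnot(n_y_genes <= n_genes, n_y_genes >= 1,
            study_effect_sd >= 0, specimen_effect_sd >= 0, noise_sd >= 0,
            n_age_genes + n_y_genes + n_response_genes <= n_genes)
  if (any(vapply(studies, function(s) s$n_participants, 1) < 1))
    stop("degenerate config: every study needs at least one participant")
  cfg <- list(studies = studies, n_genes = n_genes, n_y_genes = n_y_genes,
              study_effect_sd = study_effect_sd,
              platform_shift = platform_shift,
              platform_scale = platform_scale,
              specimen_effect_sd = specimen_effect_sd,
              sex_effect_size = sex_effect_size,
              n_age_genes = n_age_genes, age_slope = age_slope,
              n_response_genes = n_response_genes,
              response_effect_size = response_effect_size,
              noise_sd = noise_sd, age_range = age_range, titer = titer,
              n_corrupt = n_corrupt, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' Read a simulation configuration from YAML
#' @param path YAML file; fields as in [sim_config()] (`studies` as a list of
#'   maps). Missing fields take the defaults.
#' @return A `SimConfig`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("platform_shift", "platform_scale"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(sim_config, y)
}

sim_gene_ids <- function(cfg) {
  y_genes <- Y_GENE_PANEL[seq_len(min(cfg$n_y_genes, length(Y_GENE_PANEL)))]
  if (cfg$n_y_genes > length(Y_GENE_PANEL))
    y_genes <- c(y_genes, sprintf("YG%03d", seq_len(cfg$n_y_genes -
                                                      length(Y_GENE_PANEL))))
  autosomal <- sprintf("GENE%04d", seq_len(cfg$n_genes - length(y_genes)))
  c(y_genes, autosomal)
}

# Response kernel: 0 pre-vaccination, peaks at day 7, decays after.
response_kernel <- function(t) ifelse(t <= 0, 0, (t / 7) * exp(1 - t / 7))

#' Generate a synthetic compendium with ground truth
#'
#' @param config A `SimConfig` from [sim_config()].
#' @return A list with elements `bundle` (a `CompendiumBundle`, value scale
#'   log2, including titers) and `truth` (a `GroundTruth` list recording every
#'   injected effect: per-gene batch/specimen offsets, platform parameters,
#'   true sexes/ages, responder scores, gene panels, corrupt sample ids, and
#'   the batch-free expression matrix `clean`).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  set.seed(cfg$seed)
  genes <- sim_gene_ids(cfg)
  G <- cfg$n_genes
  y_idx <- seq_len(cfg$n_y_genes)
  age_idx <- cfg$n_y_genes + seq_len(cfg$n_age_genes)
  resp_idx <- cfg$n_y_genes + cfg$n_age_genes + seq_len(cfg$n_response_genes)

  baseline <- stats::runif(G, 4, 12)
  baseline[y_idx] <- stats::runif(length(y_idx), 3, 4)  # low in females
  # gene-specific sigmoidal aging trajectories: each aging gene ramps up or
  # down around its own onset age; trajectory diversity across genes is what
  # makes correlation staging identifiable (a uniform linear trend would make
  # all reference columns rank-equivalent)
  n_age <- cfg$n_age_genes
  span_decades <- diff(cfg$age_range) / 10
  age_amp <- rep(c(1, -1), length.out = n_age) *
    stats::runif(n_age, 0.5, 1.5) * cfg$age_slope * span_decades
  age_onset <- stats::runif(n_age, cfg$age_range[1] + 5, cfg$age_range[2] - 5)
  age_width <- stats::runif(n_age, 10, 30)
  age_profile <- function(a) {
    vapply(a, function(ai)
      age_amp * stats::plogis((ai - age_onset) / (age_width / 4)),
      numeric(n_age))
  }
  resp_dir <- rep(c(1, -1), length.out = cfg$n_response_genes)

  # per-batch (study x cohort) offsets; first batch is the zero reference
  batch_keys <- unlist(lapply(cfg$studies, function(s)
    paste(s$name, sprintf("cohort%d", seq_len(s$cohorts %||% 1)), sep = "|")))
  batch_offsets <- matrix(stats::rnorm(G * length(batch_keys), 0,
                                       cfg$study_effect_sd),
                          G, length(batch_keys),
                          dimnames = list(genes, batch_keys))
  batch_offsets[, 1] <- 0
  specimen_offsets <- stats::rnorm(G, 0, cfg$specimen_effect_sd)  # whole_blood

  samples <- list(); participants <- list()
  for (st in cfg$studies) {
    n_coh <- st$cohorts %||% 1
    coh_of <- rep(seq_len(n_coh), length.out = st$n_participants)
    for (p in seq_len(st$n_participants)) {
      pid <- sprintf("%s_P%03d", st$name, p)
      participants[[pid]] <- list(
        pid = pid, study = st$name,
        cohort = sprintf("cohort%d", coh_of[p]),
        platform = st$platform, specimen = st$specimen,
        pathogen = st$pathogen, vaccine = st$vaccine,
        vaccine_type = st$vaccine_type,
        sex = if (stats::runif(1) < 0.5) "male" else "female",
        age = stats::runif(1, cfg$age_range[1], cfg$age_range[2]),
        responder = stats::rnorm(1, 0, 1))
      for (t in st$timepoints) {
        sid <- sprintf("%s_T%g", pid, t)
        samples[[sid]] <- c(participants[[pid]],
                            list(sid = sid, time = t))
      }
    }
  }
  n <- length(samples)
  meta <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sid"),
    participant_id = vapply(samples, `[[`, "", "pid"),
    study_accession = vapply(samples, `[[`, "", "study"),
    cohort_label = vapply(samples, `[[`, "", "cohort"),
    specimen_type = vapply(samples, `[[`, "", "specimen"),
    platform_vendor = vapply(samples, `[[`, "", "platform"),
    time_days = vapply(samples, `[[`, 0, "time"),
    vaccine = vapply(samples, `[[`, "", "vaccine"),
    pathogen = vapply(samples, `[[`, "", "pathogen"),
    vaccine_type = vapply(samples, `[[`, "", "vaccine_type"),
    stringsAsFactors = FALSE)
  meta$matrix_name <- paste(meta$study_accession, meta$cohort_label,
                            meta$specimen_type, sep = "_")
  meta$feature_set_name <- paste0(meta$platform_vendor, "_featureset")
  meta$age_reported <- vapply(samples, `[[`, 0, "age")
  meta$sex_reported <- vapply(samples, `[[`, "", "sex")
  rownames(meta) <- NULL

  sex <- vapply(samples, `[[`, "", "sex")
  age <- vapply(samples, `[[`, 0, "age")
  resp <- vapply(samples, `[[`, 0, "responder")
  tt <- meta$time_days
  bkey <- paste(meta$study_accession, meta$cohort_label, sep = "|")

  clean <- matrix(baseline, G, n) +
    outer(rep(0, G), rep(0, n))  # biological signal accumulates below
  clean[y_idx, sex == "male"] <- clean[y_idx, sex == "male"] +
    cfg$sex_effect_size
  clean[age_idx, ] <- clean[age_idx, ] + age_profile(age)
  clean[resp_idx, ] <- clean[resp_idx, ] + cfg$response_effect_size *
    outer(resp_dir, resp * response_kernel(tt))
  noise <- matrix(stats::rnorm(G * n, 0, cfg$noise_sd), G, n)
  clean <- clean + noise
  dimnames(clean) <- list(genes, meta$sample_id)

  values <- clean + batch_offsets[, bkey, drop = FALSE] +
    rep(specimen_offsets, n) *
      rep(as.numeric(meta$specimen_type == "whole_blood"), each = G)
  shift <- cfg$platform_shift[meta$platform_vendor]
  scale <- cfg$platform_scale[meta$platform_vendor]
  center <- mean(values)
  values <- sweep(sweep(values, 2, scale, function(x, s)
    center + (x - center) * s), 2, shift, `+`)
  dimnames(values) <- list(genes, meta$sample_id)

  corrupt_ids <- character()
  if (cfg$n_corrupt > 0) {
    corrupt_ids <- meta$sample_id[seq_len(min(cfg$n_corrupt, n))]
    for (sid in corrupt_ids) {
      x <- values[, sid]
      scramble <- sample.int(G, floor(G / 2))
      x[scramble] <- x[sample(scramble)]
      values[, sid] <- 2 * (x - mean(x)) + mean(x) + 3
    }
  }

  titers <- simulate_titer_rows(cfg, participants)
  bundle <- align(expression_matrix(values, "log2"), meta,
                  titers = if (nrow(titers)) titers else NULL)
  bundle <- add_provenance(bundle, "simulate", list(seed = cfg$seed),
                           n, n)
  truth <- structure(list(
    batch_offsets = batch_offsets, specimen_offsets = specimen_offsets,
    platform_shift = cfg$platform_shift, platform_scale = cfg$platform_scale,
    sex = vapply(participants, `[[`, "", "sex"),
    age = vapply(participants, `[[`, 0, "age"),
    responder = vapply(participants, `[[`, 0, "responder"),
    y_genes = genes[y_idx], age_genes = genes[age_idx],
    age_trajectory = list(amplitude = stats::setNames(age_amp,
                                                      genes[age_idx]),
                          onset = age_onset, width = age_width,
                          profile = age_profile),
    response_genes = genes[resp_idx],
    corrupt_samples = corrupt_ids, clean = clean,
    noise_sd = cfg$noise_sd, config = cfg), class = "GroundTruth")
  list(bundle = bundle, truth = truth)
}

simulate_titer_rows <- function(cfg, participants) {
  tp <- cfg$titer
  rows <- list()
  for (p in participants) {
    st <- Filter(function(s) s$name == p$study, cfg$studies)[[1]]
    assays <- st$assays %||% character()
    for (assay in assays) {
      n_strains <- if (assay == "HAI" || p$pathogen == "influenza")
        st$n_strains %||% 1 else 1
      for (k in seq_len(n_strains)) {
        analyte <- sprintf("%s_strain%d", p$pathogen, k)
        lb <- stats::rnorm(1, tp$baseline_mean, tp$baseline_sd)
        lfc <- tp$a - tp$b * lb + tp$responder_sd * p$responder +
          stats::rnorm(1, 0, tp$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = p$pid, study_accession = p$study, assay = assay,
          analyte = analyte, time_days = c(0, tp$post_day),
          value = 2^c(lb, lb + lfc), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(participant_id = character(),
                      study_accession = character(), assay = character(),
                      analyte = character(), time_days = numeric(),
                      value = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Generate only a titer table (with ground truth)
#'
#' @param config A `SimConfig`.
#' @return List with `titers` (validated titer table) and `truth` (responder
#'   scores and the titer model parameters).
#' @export
generate_titers_only <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  participants <- list()
  for (st in config$studies) {
    for (p in seq_len(st$n_participants)) {
      pid <- sprintf("%s_P%03d", st$name, p)
      participants[[pid]] <- list(pid = pid, study = st$name,
                                  pathogen = st$pathogen,
                                  responder = stats::rnorm(1, 0, 1))
    }
  }
  titers <- validate_titers(simulate_titer_rows(config, participants))
  truth <- structure(list(
    responder = vapply(participants, `[[`, 0, "responder"),
    titer = config$titer, config = config), class = "GroundTruth")
  list(titers = titers, truth = truth)
}

FIXTURE_REGISTRY <- list(
  tiny = function() sim_config(n_studies = 2, n_genes = 60, n_age_genes = 15,
                               n_response_genes = 10, seed = 101,
                               studies = local({
                                 s <- default_studies()[1:2]
                                 s[[1]]$n_participants <- 4
                                 s[[2]]$n_participants <- 4
                                 s
                               })),
  threestudy = function() sim_config(seed = 202, studies = local({
    s <- default_studies()
    for (i in 1:3) s[[i]]$n_participants <- 8
    s
  })),
  multicohort = function() sim_config(seed = 303, n_genes = 120,
                                      n_age_genes = 30,
                                      n_response_genes = 15,
                                      studies = local({
                                        s <- default_studies()[1:2]
                                        s[[1]]$n_participants <- 8
                                        s[[1]]$cohorts <- 2
                                        s[[2]]$n_participants <- 6
                                        s
                                      }))
)

#' Deterministic small reference fixtures
#'
#' A registry of named, frozen simulation configurations for documentation
#' and tests. Names: `"tiny"`, `"threestudy"`, `"multicohort"`.
#'
#' @param name Fixture name, or `NULL` to list available names.
#' @return The generated `(bundle, truth)` list, or names if `name` is NULL.
#' @export
reference_fixture <- function(name = NULL) {
  if (is.null(name)) return(names(FIXTURE_REGISTRY))
  if (!name %in% names(FIXTURE_REGISTRY))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(FIXTURE_REGISTRY), collapse = ", "))
  generate(FIXTURE_REGISTRY[[name]]())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
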