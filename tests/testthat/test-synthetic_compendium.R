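# Generator determinism, null cases, titer model closed forms, fixtures.

test_that("identical seeds give byte-identical bundles", {
  cfg <- two_study_config(seed = 7)
  a <- generate(cfg)
  b <- generate(cfg)
  expect_identical(serialize(a$bundle, NULL), serialize(b$bundle, NULL))
  c <- generate(two_study_config(seed = 8))
  expect_false(identical(a$bundle$expression$values,
                         c$bundle$expression$values))
})

test_that("zero sex effect removes the Y-gene sex difference", {
  # compare within study, so per-gene batch offsets cancel
  per_study_gap <- function(out) {
    b <- out$bundle
    sex <- out$truth$sex[b$samples$participant_id]
    vapply(unique(b$samples$study_accession), function(st) {
      i <- b$samples$study_accession == st
      ym <- colMeans(b$expression$values[out$truth$y_genes, i])
      mean(ym[sex[i] == "male"]) - mean(ym[sex[i] == "female"])
    }, numeric(1))
  }
  null_gap <- per_study_gap(generate(two_study_config(
    seed = 3, sex_effect_size = 0, n_participants = 30)))
  expect_lt(max(abs(null_gap)), 0.2)
  real_gap <- per_study_gap(generate(two_study_config(
    seed = 3, n_participants = 30)))
  expect_gt(min(real_gap), 3)
})

test_that("degenerate configs are rejected", {
  st <- list(list(name = "SDY01", n_participants = 0,
                  platform = "affymetrix", specimen = "pbmc",
                  timepoints = 0, cohorts = 1, pathogen = "influenza",
                  vaccine = "x", vaccine_type = "x",
                  assays = character(), n_strains = 0))
  expect_error(sim_config(studies = st, seed = 1), "at least one participant")
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, n_genes = 10, n_y_genes = 13),
               "n_y_genes")
})

test_that("titer model follows its closed form", {
  # b = 0, responder_sd = 0, noise 0: every log2 fold change equals a
  cfg <- two_study_config(seed = 5,
                          titer = list(a = 2.5, b = 0, responder_sd = 0,
                                       noise_sd = 0, baseline_mean = 4,
                                       baseline_sd = 1, post_day = 28))
  tt <- generate_titers_only(cfg)$titers
  ep <- compute_endpoints(tt)
  fcs <- unlist(lapply(unique(tt$participant_id), function(p)
    vapply(unique(tt$analyte[tt$participant_id == p]), function(a)
      fold_change(tt, p, a), numeric(1))))
  expect_equal(unname(fcs), rep(2.5, length(fcs)), tolerance = 1e-12)
  expect_equal(ep$MFC, rep(2.5, nrow(ep)), tolerance = 1e-12)

  # b = 1 exactly cancels baseline dependence of log2(post)
  cfg2 <- two_study_config(seed = 6,
                           titer = list(a = 2, b = 1, responder_sd = 0,
                                        noise_sd = 0, baseline_mean = 4,
                                        baseline_sd = 1.5, post_day = 28))
  tt2 <- generate_titers_only(cfg2)$titers
  post <- log2(tt2$value[tt2$time_days > 0])
  base <- log2(tt2$value[tt2$time_days <= 0])
  slope <- stats::coef(stats::lm(post ~ base))[2]
  expect_lt(abs(slope), 1e-10)
})

test_that("single-strain MFC equals that strain's fold change", {
  cfg <- sim_config(seed = 9, studies = list(
    list(name = "SDY01", n_participants = 6, platform = "affymetrix",
         specimen = "pbmc", timepoints = c(0, 28), cohorts = 1,
         pathogen = "yellow_fever", vaccine = "YF17D",
         vaccine_type = "live_attenuated", assays = "NAb", n_strains = 1)))
  tt <- generate_titers_only(cfg)$titers
  ep <- compute_endpoints(tt)
  for (i in seq_len(nrow(ep))) {
    fc <- fold_change(tt, ep$participant_id[i],
                      unique(tt$analyte), assay = "NAb")
    expect_equal(ep$MFC[i], fc)
  }
})

test_that("injected effects are recoverable by regression on the true design", {
  out <- generate(two_study_config(seed = 21, n_participants = 12))
  b <- out$bundle; tr <- out$truth
  base <- b$samples$time_days <= 0
  study2 <- b$samples$study_accession == "SDY02"
  # observed SDY02 - SDY01 baseline difference per gene vs injected truth
  diff_hat <- rowMeans(b$expression$values[, base & study2]) -
    rowMeans(b$expression$values[, base & !study2])
  truth <- tr$batch_offsets[, "SDY02|cohort1"] + 1.5 + tr$specimen_offsets
  n1 <- sum(base & !study2); n2 <- sum(base & study2)
  # biological terms (sex/age) differ between groups; allow their spread
  se <- sqrt(tr$noise_sd^2 * (1 / n1 + 1 / n2)) + 0.6
  expect_gt(mean(abs(diff_hat - truth) <= 3 * se), 0.98)
})

test_that("Affymetrix samples share their marginal distribution up to noise", {
  out <- generate(two_study_config(seed = 31))
  b <- out$bundle
  base <- b$samples$time_days <= 0
  affy <- base & b$samples$platform_vendor == "affymetrix"
  ilmn <- base & b$samples$platform_vendor == "illumina"
  med <- apply(b$expression$values, 2, median)
  # within-vendor spread (biological noise) stays well below the
  # between-vendor location shift that cross-study normalization must fix
  gap <- abs(mean(med[ilmn]) - mean(med[affy]))
  expect_lt(sd(med[affy]), gap / 2)
  expect_gt(gap, 1)
})

test_that("fixture registry is deterministic and aligned", {
  expect_gte(length(reference_fixture()), 3)
  f1 <- reference_fixture("tiny")
  f2 <- reference_fixture("tiny")
  expect_identical(serialize(f1$bundle, NULL), serialize(f2$bundle, NULL))
  # align() accepts the fixture's own pieces
  expect_silent(align(f1$bundle$expression, f1$bundle$samples,
                      f1$bundle$titers))
  expect_error(reference_fixture("nope"), "unknown fixture")
})
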