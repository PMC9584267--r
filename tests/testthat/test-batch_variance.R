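# Batch model estimation/removal, PCA, and PVCA variance decomposition.

test_that("single-study designs carry no batch columns", {
  cfg <- sim_config(seed = 2, n_genes = 60, n_age_genes = 10,
                    n_response_genes = 10, studies = list(
    list(name = "SDY01", n_participants = 8, platform = "affymetrix",
         specimen = "pbmc", timepoints = c(0, 7), cohorts = 1,
         pathogen = "influenza", vaccine = "TIV",
         vaccine_type = "inactivated", assays = character(), n_strains = 0)))
  m <- fit_batch_model(generate(cfg)$bundle)
  expect_false(any(m$blocks %in% c("batch", "platform", "specimen")))
  # removal is then the identity
  b <- generate(cfg)$bundle
  expect_equal(remove_batch_effects(b, m)$expression$values,
               b$expression$values)
})

test_that("injected study offsets are recovered within 3 SE and removed", {
  out <- generate(two_study_config(seed = 13, n_participants = 15))
  b <- out$bundle; tr <- out$truth
  m <- fit_batch_model(b)
  expect_true("batch:SDY02|cohort1" %in% colnames(m$coefficients))
  # platform fully confounded with study: absorbed into the batch key
  expect_true(any(grepl("^platform", m$aliased)))
  truth <- tr$batch_offsets[, "SDY02|cohort1"] +
    tr$platform_shift["illumina"] + tr$specimen_offsets
  z <- (m$coefficients[, "batch:SDY02|cohort1"] - truth) /
    m$se[, "batch:SDY02|cohort1"]
  expect_gt(mean(abs(z) <= 3), 0.98)

  corrected <- remove_batch_effects(b, m)
  expect_equal(value_scale(corrected$expression), "batch_corrected")
  # refit on corrected data: batch coefficients collapse to zero
  m2 <- fit_batch_model(corrected)
  expect_lt(max(abs(m2$coefficients[, m2$blocks == "batch"])), 1e-8)
  # corrected matrix approaches the batch-free truth
  rmse <- sqrt(mean((corrected$expression$values - tr$clean)^2))
  expect_lt(rmse, tr$noise_sd * 1.1)
  # idempotence: a second correction subtracts ~0
  again <- remove_batch_effects(corrected, m2)
  expect_lt(max(abs(again$expression$values -
                      corrected$expression$values)), 1e-8)
})

test_that("correction preserves within-participant longitudinal differences", {
  out <- generate(two_study_config(seed = 17))
  b <- out$bundle
  corrected <- remove_batch_effects(b, fit_batch_model(b))
  s <- b$samples
  p <- s$participant_id[1]
  ids <- s$sample_id[s$participant_id == p]
  d_before <- b$expression$values[, ids[2]] - b$expression$values[, ids[1]]
  d_after <- corrected$expression$values[, ids[2]] -
    corrected$expression$values[, ids[1]]
  expect_equal(d_after, d_before, tolerance = 1e-10)
})

test_that("multi-cohort studies get separate batch levels", {
  out <- reference_fixture("multicohort")
  m <- fit_batch_model(out$bundle)
  cols <- colnames(m$coefficients)[m$blocks == "batch"]
  expect_true("batch:SDY01|cohort2" %in% cols)
  expect_true("batch:SDY02|cohort1" %in% cols)
})

test_that("unseen batch levels are rejected by name", {
  out <- generate(two_study_config(seed = 19))
  b <- out$bundle
  keep <- b$samples$study_accession == "SDY01"
  sub <- subset_bundle(b, b$samples$sample_id[keep])
  m <- fit_batch_model(sub)
  expect_error(remove_batch_effects(b, m), "SDY02")
})

test_that("PCA matches a direct covariance eigensolve", {
  set.seed(23)
  x <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  pc <- compute_pca(x, n_components = 5)
  # eigenvalue sum equals total variance of the centered data
  centered <- x - rowMeans(x)
  total_var <- sum(apply(t(centered), 2, var))
  ev_all <- prcomp(t(x))$sdev^2
  expect_equal(sum(ev_all), total_var, tolerance = 1e-12)
  # scores orthogonal
  g <- crossprod(pc$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-10)
  # against eigen() on the sample covariance
  eig <- eigen(cov(t(centered)), symmetric = TRUE)
  expect_equal(pc$eigenvalues, eig$values[1:5], tolerance = 1e-10)
  for (j in 1:5) {
    sc <- t(centered) %*% eig$vectors[, j]
    expect_equal(as.numeric(abs(cor(sc, pc$scores[, j]))), 1,
                 tolerance = 1e-8)
  }
  expect_warning(compute_pca(x, n_components = 10), "exceeds rank")
})

test_that("PVCA separates dominant factors from noise", {
  set.seed(29)
  # pure noise: residual dominates
  noise <- matrix(rnorm(120 * 45), 120, 45,
                  dimnames = list(paste0("g", 1:120), paste0("s", 1:45)))
  fr <- pvca(noise, data.frame(study = rep(c("A", "B", "C"), each = 15)))
  expect_gt(fr["Residual"], 0.9)

  # dominant injected study effect
  out <- generate(two_study_config(seed = 29, study_effect_sd = 3,
                                   noise_sd = 0.3))
  b <- out$bundle
  base <- b$samples$time_days <= 0
  fr2 <- pvca(b$expression$values[, base],
              data.frame(study = b$samples$study_accession[base]))
  expect_gt(fr2["study"], 0.8)
  expect_equal(sum(fr2), 1, tolerance = 1e-9)
  expect_true(all(fr2 >= 0))

  # correction reduces the study fraction
  corrected <- remove_batch_effects(b, fit_batch_model(b))
  fr3 <- pvca(corrected$expression$values[, base],
              data.frame(study = b$samples$study_accession[base]))
  expect_lt(fr3["study"], fr2["study"])

  # invariance to gene-wise mean shifts
  shifted <- b$expression$values[, base] +
    rnorm(nrow(b$expression$values))
  fr4 <- pvca(shifted,
              data.frame(study = b$samples$study_accession[base]))
  expect_equal(as.numeric(fr4),
               as.numeric(pvca(b$expression$values[, base],
                               data.frame(
                                 study = b$samples$study_accession[base]))),
               tolerance = 1e-6)

  expect_warning(
    pvca(noise, data.frame(study = rep(c("A", "B", "C"), each = 15),
                           one = "x")), "single-level")
})
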