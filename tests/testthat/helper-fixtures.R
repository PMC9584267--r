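# Shared fixtures: small simulation configs and hand-built tables.

two_study_config <- function(seed = 101, n_participants = 8, n_genes = 80,
                             ...) {
  studies <- list(
    list(name = "SDY01", n_participants = n_participants,
         platform = "affymetrix", specimen = "pbmc",
         timepoints = c(0, 7, 28), cohorts = 1, pathogen = "influenza",
         vaccine = "TIV", vaccine_type = "inactivated",
         assays = c("HAI", "NAb"), n_strains = 3),
    list(name = "SDY02", n_participants = n_participants,
         platform = "illumina", specimen = "whole_blood",
         timepoints = c(-7, 0, 7, 28), cohorts = 1, pathogen = "influenza",
         vaccine = "TIV", vaccine_type = "inactivated",
         assays = c("HAI", "NAb"), n_strains = 3))
  sim_config(studies = studies, n_genes = n_genes, n_age_genes = 20,
             n_response_genes = 10, seed = seed, ...)
}

tiny_samples <- function(n = 4, study = "SDY10") {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    participant_id = sprintf("p%02d", rep(seq_len(ceiling(n / 2)),
                                          each = 2))[seq_len(n)],
    study_accession = study,
    cohort_label = "c1",
    matrix_name = paste0(study, "_c1_pbmc"),
    specimen_type = "pbmc",
    platform_vendor = "affymetrix",
    feature_set_name = "fs1",
    time_days = rep(c(0, 7), length.out = n),
    vaccine = "TIV", pathogen = "influenza", vaccine_type = "inactivated",
    age_reported = 30, sex_reported = "female",
    stringsAsFactors = FALSE)
}

tiny_matrix <- function(n_genes = 6, n = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n, 8, 1), n_genes, n,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  m
}

# independent nested-loop oracle for Hoeffding's D (midranks)
hoeffding_oracle <- function(x, y) {
  n <- length(x)
  R <- rank(x); S <- rank(y)
  phi <- function(a, b) if (a < b) 1 else if (a == b) 0.5 else 0
  Q <- numeric(n)
  for (i in seq_len(n)) {
    q <- 1
    for (j in seq_len(n)) {
      if (j == i) next
      q <- q + phi(x[j], x[i]) * phi(y[j], y[i])
    }
    Q[i] <- q
  }
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}
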