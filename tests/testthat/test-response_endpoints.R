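# Fold change, MFC, maxRBA, assay preference, endpoint correlation and
# bundle matching.

make_titers <- function(df) validate_titers(df)

test_that("fold change uses the baseline and the post day closest to 28", {
  tt <- make_titers(data.frame(
    participant_id = "p1", study_accession = "S", assay = "HAI",
    analyte = "strainA", time_days = c(0, 21, 28, 35), value = c(10, 20, 40, 80)))
  expect_equal(fold_change(tt, "p1", "strainA"), 2)   # day 28 wins
  tt2 <- make_titers(data.frame(
    participant_id = "p1", study_accession = "S", assay = "HAI",
    analyte = "strainA", time_days = c(0, 28), value = c(10, 10)))
  expect_equal(fold_change(tt2, "p1", "strainA"), 0)
  # no baseline: unavailable, not an error
  tt3 <- make_titers(data.frame(
    participant_id = "p1", study_accession = "S", assay = "HAI",
    analyte = "strainA", time_days = 28, value = 40))
  expect_true(is.na(fold_change(tt3, "p1", "strainA")))
})

test_that("MFC is the maximum per-strain fold change", {
  expect_equal(mfc(c(0, 2, 3)), 3)
  expect_equal(mfc(1.7), 1.7)
  expect_equal(mfc(c(2, 2, 2)), 2)
  expect_error(mfc(numeric()), "no per-strain")
})

test_that("maxRBA matches the closed-form OLS residual oracle", {
  # 5 participants x 2 strains with known baselines and fold changes
  set.seed(71)
  pids <- paste0("p", 1:5)
  lb1 <- c(2, 3, 4, 5, 6); lfc1 <- c(4.1, 3.4, 2.2, 1.6, 1.2)
  lb2 <- c(3, 3, 4, 6, 5); lfc2 <- c(3.0, 3.3, 2.1, 0.5, 1.9)
  rows <- list()
  for (i in 1:5) {
    rows[[i]] <- data.frame(
      participant_id = pids[i], study_accession = "S", assay = "HAI",
      analyte = rep(c("A", "B"), each = 2), time_days = rep(c(0, 28), 2),
      value = 2^c(lb1[i], lb1[i] + lfc1[i], lb2[i], lb2[i] + lfc2[i]))
  }
  tt <- make_titers(do.call(rbind, rows))
  got <- max_rba(tt)
  # normal-equations oracle per strain
  ols_resid <- function(x, y) {
    bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ahat <- mean(y) - bhat * mean(x)
    y - ahat - bhat * x
  }
  r1 <- ols_resid(lb1, lfc1); r2 <- ols_resid(lb2, lfc2)
  expect_equal(unname(got[pids]), pmax(r1, r2), tolerance = 1e-10)
  # residuals sum to ~0 per strain
  ps <- attr(got, "per_strain")
  expect_lt(abs(mean(ps[["A"]])), 1e-10)
  expect_lt(abs(mean(ps[["B"]])), 1e-10)

  # invariance: rescaling raw titers by a positive constant
  tt_scaled <- tt; tt_scaled$value <- tt_scaled$value * 7
  expect_equal(unname(max_rba(tt_scaled)[pids]), unname(got[pids]),
               tolerance = 1e-10)

  # exactly linear fold change in baseline: all residuals zero
  lin <- tt[tt$analyte == "A", ]
  lin$value[lin$time_days > 0] <- 2^(log2(
    lin$value[lin$time_days <= 0]) + 5 - 0.5 * log2(
      lin$value[lin$time_days <= 0]))
  expect_lt(max(abs(max_rba(make_titers(lin)))), 1e-10)

  # zero-variance baseline: residuals are the centered fold changes
  cz <- tt[tt$analyte == "A", ]
  cz$value[cz$time_days <= 0] <- 16
  rz <- max_rba(make_titers(cz))
  fcz <- log2(cz$value[cz$time_days > 0] / 16)
  expect_equal(unname(rz[pids]), fcz - mean(fcz), tolerance = 1e-10)

  # fewer than 3 participants for a strain: both strains skipped with warnings
  w <- capture_warnings(small <- max_rba(tt[tt$participant_id %in%
                                              pids[1:2], ]))
  expect_true(all(grepl("fewer than 3", w)))
  expect_true(all(is.na(small)))
})

test_that("assay preference follows HAI > NAb > ELISA for influenza and
           NAb > ELISA otherwise", {
  expect_equal(select_endpoint(c("HAI", "NAb"), "influenza"), "HAI")
  expect_equal(select_endpoint(c("NAb", "ELISA"), "influenza"), "NAb")
  expect_equal(select_endpoint("ELISA", "influenza"), "ELISA")
  expect_equal(select_endpoint(c("NAb", "ELISA"), "yellow_fever"), "NAb")
  expect_equal(select_endpoint("ELISA", "tuberculosis"), "ELISA")
  expect_true(is.na(select_endpoint(character(), "influenza")))
})

test_that("endpoint correlation matches the rank-formula oracle", {
  x <- setNames(c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8), paste0("p", 1:8))
  y <- setNames(c(2, 0.5, 5, 1.2, 7, 3.1, 4.9, 6.2), paste0("p", 1:8))
  expect_equal(correlate_endpoints(x, x)$rho, 1)
  expect_equal(correlate_endpoints(x, setNames(-x, names(x)))$rho, -1)
  got <- correlate_endpoints(x, y)
  d <- rank(x) - rank(y)
  oracle <- 1 - 6 * sum(d^2) / (8 * (8^2 - 1))   # no ties
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_equal(got$n, 8)
  const <- setNames(rep(1, 8), names(x))
  expect_true(is.na(correlate_endpoints(x, const)$rho))
  expect_error(correlate_endpoints(x[1:2], y[1:2]), "at least 3")
})

test_that("endpoints attach to bundles with conserved counts", {
  out <- generate(two_study_config(seed = 73))
  b <- out$bundle
  ep <- compute_endpoints(b$titers)
  expect_true(all(ep$assay_used == "HAI"))   # influenza prefers HAI
  expect_equal(ep$n_strains, rep(3, nrow(ep)))
  wr <- attach_endpoints(b, ep)
  expect_true(all(wr$samples$participant_id %in% ep$participant_id))
  expect_false(any(is.na(wr$samples$MFC)))
  # all matched here: identical sample set
  expect_setequal(wr$samples$sample_id, b$samples$sample_id)
  # none matched: empty withResponse bundle plus a warning
  ep2 <- ep; ep2$participant_id <- paste0("zz", seq_len(nrow(ep2)))
  expect_warning(empty <- attach_endpoints(b, ep2), "no participant")
  expect_equal(nrow(empty$samples), 0)
  # partial: counts in = matched + unmatched
  half <- ep[ep$participant_id %in% unique(ep$participant_id)[1:5], ]
  part <- suppressWarnings(attach_endpoints(b, half))
  expect_equal(length(unique(part$samples$participant_id)), 5)
})

test_that("MFC dominates every per-strain fold change with equality", {
  out <- generate(two_study_config(seed = 79))
  tt <- out$bundle$titers
  ep <- compute_endpoints(tt)
  for (i in seq_len(min(nrow(ep), 10))) {
    sa <- tt[tt$participant_id == ep$participant_id[i] &
               tt$assay == ep$assay_used[i], ]
    fcs <- vapply(unique(sa$analyte), function(a)
      fold_change(sa, ep$participant_id[i], a), numeric(1))
    expect_true(all(ep$MFC[i] >= fcs - 1e-12))
    expect_equal(ep$MFC[i], max(fcs))
  }
})
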