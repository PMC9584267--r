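# Quantile normalization (within-study and to a target), log/count
# transforms, and the gene intersection.

test_that("within-study quantile normalization matches the order-statistic
           definition and is idempotent", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantile_normalize_within(m)
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  set.seed(5)
  r <- matrix(rexp(60), 12, 5,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  qn1 <- quantile_normalize_within(r)
  # all samples share the identical sorted vector
  sorted <- apply(qn1, 2, sort)
  expect_equal(max(apply(sorted, 1, function(x) diff(range(x)))), 0,
               tolerance = 1e-12)
  # oracle: mean of order statistics
  expect_equal(unname(sort(qn1[, 1])), unname(rowMeans(apply(r, 2, sort))),
               tolerance = 1e-12)
  # idempotence
  expect_equal(quantile_normalize_within(qn1), qn1, tolerance = 1e-12)

  # ties: column means equal the mean of the target vector
  tied <- cbind(s1 = c(1, 1, 5, 7), s2 = c(2, 4, 4, 9))
  rownames(tied) <- paste0("g", 1:4)
  qt <- quantile_normalize_within(tied)
  target_mean <- mean(rowMeans(apply(tied, 2, sort)))
  expect_equal(unname(colMeans(qt)), rep(target_mean, 2), tolerance = 1e-12)

  expect_warning(quantile_normalize_within(tied[, 1, drop = FALSE]),
                 "single sample")
})

test_that("log2 transform handles the pseudocount and rejects negatives", {
  m <- cbind(s1 = c(0, 3, 7))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(log2_transform(m, 1)), cbind(c(0, 2, 3)))
  expect_error(log2_transform(m - 1), "negative")
  # rank preservation
  set.seed(2)
  r <- matrix(rexp(20), 5, 4, dimnames = list(paste0("g", 1:5),
                                              paste0("s", 1:4)))
  expect_equal(apply(log2_transform(r), 2, rank), apply(r, 2, rank))
})

test_that("count transform matches the median-of-ratios oracle", {
  counts <- cbind(s1 = c(10, 20, 40, 5), s2 = c(20, 40, 80, 10),
                  s3 = c(10, 25, 35, 5))
  rownames(counts) <- paste0("g", 1:4)
  # hand oracle: geometric-mean reference, median ratio per sample
  ref <- exp(rowMeans(log(counts)))
  sf_oracle <- apply(counts, 2, function(col) median(col / ref))
  expect_equal(size_factors(counts), sf_oracle, tolerance = 1e-12)

  # identical columns: all size factors 1
  same <- cbind(s1 = c(4, 8, 2), s2 = c(4, 8, 2))
  rownames(same) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(same)), c(1, 1))

  # doubled column: size factor 2 and transformed values equal the original
  dbl <- cbind(s1 = c(4, 8, 2), s2 = c(8, 16, 4))
  rownames(dbl) <- paste0("g", 1:3)
  sf <- size_factors(dbl)
  expect_equal(unname(sf), c(sqrt(0.5), sqrt(2)), tolerance = 1e-12)
  tr <- transform_counts(dbl)
  expect_equal(tr[, 1], tr[, 2], tolerance = 1e-12)

  # all-zero rows excluded from the reference with a warning
  z <- rbind(dbl, g4 = c(0, 0))
  expect_warning(size_factors(z), "zero counts")

  # independent cross-check against the established implementation
  expect_equal(unname(size_factors(counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-8)
})

test_that("target building averages per-sample quantile functions", {
  one <- cbind(s1 = sort(rnorm(40)))
  rownames(one) <- paste0("g", 1:40)
  t1 <- build_target(one, L = 40)
  expect_equal(t1$quantiles,
               unname(quantile(one[, 1], probs = (1:40 - 0.5) / 40,
                               type = 5)), tolerance = 1e-12)
  two_same <- cbind(one, s2 = one[, 1])
  expect_equal(build_target(two_same, L = 40)$quantiles, t1$quantiles)

  set.seed(3)
  a <- rnorm(30); b <- rexp(30)
  m <- cbind(s1 = a, s2 = b); rownames(m) <- paste0("g", 1:30)
  t2 <- build_target(m, L = 15)
  probs <- (1:15 - 0.5) / 15
  oracle <- (quantile(a, probs, type = 5, names = FALSE) +
               quantile(b, probs, type = 5, names = FALSE)) / 2
  expect_equal(t2$quantiles, oracle, tolerance = 1e-12)
  expect_false(is.unsorted(t2$quantiles))
})

test_that("normalization to a target preserves ranks and matches hand
           interpolation", {
  # sample equal to the target quantiles is unchanged
  set.seed(6)
  v <- sort(rnorm(25))
  m <- cbind(s1 = v); rownames(m) <- paste0("g", 1:25)
  target <- build_target(m, L = 25)
  expect_equal(unname(normalize_to_target(m, target)[, 1]), v,
               tolerance = 1e-9)

  # n = 3 sample against a linear target spanning [0, 10]
  L <- 101
  lin <- structure(list(probabilities = (1:L - 0.5) / L,
                        quantiles = seq(0, 10, length.out = L),
                        n_samples = 1L), class = "TargetDistribution")
  s <- cbind(s1 = c(5, 1, 3)); rownames(s) <- paste0("g", 1:3)
  got <- normalize_to_target(s, lin)[, 1]
  oracle <- approx(lin$probabilities, lin$quantiles,
                   xout = c(5 / 6, 1 / 6, 3 / 6), rule = 2)$y
  expect_equal(unname(got), oracle, tolerance = 1e-12)

  # rank preservation and KS-distance reduction on 50 random samples
  ks <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 1)))
  }
  set.seed(7)
  tgt_src <- matrix(rnorm(200 * 4, 8, 1), 200, 4,
                    dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  target2 <- build_target(tgt_src, L = 200)
  for (i in 1:50) {
    x <- rnorm(60, sample(c(4, 8, 12), 1), runif(1, 0.5, 2))
    xm <- cbind(s = x); rownames(xm) <- paste0("g", 1:60)
    y <- normalize_to_target(xm, target2)[, 1]
    expect_identical(unname(rank(y, ties.method = "average")),
                     rank(x, ties.method = "average"))
    expect_lte(ks(y, target2$quantiles), ks(x, target2$quantiles))
  }
})

test_that("gene intersection keeps shared symbols and counts drops", {
  m1 <- matrix(1, 4, 2, dimnames = list(c("A", "B", "C", "D"),
                                        c("s1", "s2")))
  m2 <- matrix(2, 3, 2, dimnames = list(c("B", "C", "E"), c("s3", "s4")))
  m3 <- matrix(3, 3, 1, dimnames = list(c("C", "B", "F"), "s5"))
  merged <- intersect_genes(list(m1, m2, m3))
  expect_equal(rownames(merged), c("B", "C"))
  expect_equal(ncol(merged), 5)
  expect_equal(unname(attr(merged, "dropped")), c(2, 1, 1))

  expect_equal(nrow(intersect_genes(list(m1, m1))), 4)
  m4 <- matrix(1, 2, 1, dimnames = list(c("X", "Y"), "s6"))
  expect_error(intersect_genes(list(m1, m4)), "empty gene intersection")
})
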