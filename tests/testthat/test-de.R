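test_that("log fold change matches closed forms and is antisymmetric", {
  expect_equal(logFoldChange(3, 3), 0)
  expect_equal(logFoldChange(3, 1), 1)
  expect_equal(logFoldChange(8.06, 0), log2(9.06))  # finite despite zero mean
  expect_equal(logFoldChange(8.06, 0), 3.18, tolerance = 0.01)
  expect_equal(logFoldChange(c(1, 5), c(5, 1)), -logFoldChange(c(5, 1), c(1, 5)))
  expect_error(logFoldChange(-1, 2), "non-negative")
  expect_error(logFoldChange(1, 2, pseudocount = 0))
})

test_that("NB exact test reduces to the conditional binomial at phi = 0", {
  # 10 vs 0, unit size factors: two-sided binomial of 10/10 at p = 0.5
  expect_equal(nbExactTest(10, 0), 2 * (0.5)^10, tolerance = 1e-12)
  expect_equal(nbExactTest(10, 0),
               binom.test(10, 10, 0.5)$p.value, tolerance = 1e-12)
  # general phi = 0 case agrees with binom.test conditioned on the total
  expect_equal(nbExactTest(c(4, 3), c(1, 0)),
               binom.test(7, 8, 0.5)$p.value, tolerance = 1e-12)
  # identical groups: p = 1
  expect_equal(nbExactTest(c(5, 5), c(5, 5), phi = 0.1), 1)
  expect_equal(nbExactTest(0, 0), 1)
  # p always in (0, 1]
  set.seed(1)
  ps <- replicate(50, nbExactTest(rpois(3, 8), rpois(4, 8), phi = 0.2))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("dispersion estimator recovers planted moments", {
  set.seed(10)
  n <- 3000
  # Poisson gene: phi -> 0 (raw estimator, no shrinkage target distortion)
  pois <- matrix(rpois(n, 8), 1, n, dimnames = list("p", NULL))
  colnames(pois) <- paste0("s", 1:n)
  ph <- estimateDispersion(pois, shrink = 0)
  # 3 SE of the MoM phi at mu 8, n 3000 is well under 0.05
  expect_lt(ph[["p"]], 0.05)

  # planted phi = 0.5
  nb <- matrix(rnbinom(n, mu = 8, size = 2), 1, n, dimnames = list("g", NULL))
  colnames(nb) <- paste0("s", 1:n)
  ph2 <- estimateDispersion(nb, shrink = 0)
  expect_equal(ph2[["g"]], 0.5, tolerance = 0.15)

  # constant gene: phi = 0 exactly
  cst <- matrix(4, 1, 10, dimnames = list("c", paste0("s", 1:10)))
  expect_equal(unname(estimateDispersion(cst, shrink = 0)), 0)

  # shrinkage pulls toward the across-gene mean
  two <- rbind(pois, nb)
  raw <- estimateDispersion(two, shrink = 0)
  full <- estimateDispersion(two, shrink = 1)
  expect_equal(unname(full), rep(mean(raw), 2), tolerance = 1e-12)
})

test_that("comparison means and LFCs equal brute-force recomputation", {
  set.seed(2)
  m <- matrix(rpois(30, 6), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("b", 1:6)))
  s <- tiny_sample(m, sample_id = "s")
  spec <- comparisonSpec(
    data.frame(sample_id = "s", barcode = paste0("b", 1:3)),
    data.frame(sample_id = "s", barcode = paste0("b", 4:6)), "half vs half")
  de <- runComparison(spec, list(s = s))

  # independent recomputation from raw counts
  tot <- colSums(m)
  sf <- tot / mean(tot)
  nrm <- sweep(m, 2, sf, "/")
  mean_a <- rowMeans(nrm[, 1:3]); mean_b <- rowMeans(nrm[, 4:6])
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  idx <- match(rownames(de), names(mean_a))
  expect_equal(de$mean_A, unname(mean_a[idx]), tolerance = 1e-12)
  expect_equal(de$mean_B, unname(mean_b[idx]), tolerance = 1e-12)
  expect_equal(de$lfc, unname(lfc[idx]), tolerance = 1e-12)
  expect_equal(S4Vectors::metadata(de)$n_a, 3)

  # swapped clusters: lfc negated, p unchanged
  de_sw <- runComparison(comparisonSpec(
    data.frame(sample_id = "s", barcode = paste0("b", 4:6)),
    data.frame(sample_id = "s", barcode = paste0("b", 1:3)), "swap"),
    list(s = s))
  idx2 <- match(rownames(de), rownames(de_sw))
  expect_equal(de_sw$lfc[idx2], -de$lfc, tolerance = 1e-12)
  expect_equal(de_sw$p[idx2], de$p, tolerance = 1e-12)
})

test_that("cluster specs enforce disjointness and filtering", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("b1", "b2", "b3")))
  s <- tiny_sample(m, sample_id = "s", in_tissue = c(TRUE, TRUE, FALSE))
  expect_error(comparisonSpec(
    data.frame(sample_id = "s", barcode = c("b1", "b2")),
    data.frame(sample_id = "s", barcode = c("b2", "b3"))), "disjoint")
  # b3 is not in tissue: cluster containing it is rejected
  spec <- comparisonSpec(data.frame(sample_id = "s", barcode = "b1"),
                         data.frame(sample_id = "s", barcode = "b3"))
  expect_error(runComparison(spec, list(s = s)), "filtered")
})

test_that("null simulations are calibrated and p-values near-uniform", {
  set.seed(42)
  ng <- 500; n1 <- 50; n2 <- 50
  cts <- matrix(rnbinom(ng * (n1 + n2), mu = 5, size = 10), ng)
  dimnames(cts) <- list(paste0("g", seq_len(ng)), paste0("s", seq_len(n1 + n2)))
  grp <- rep(c("A", "B"), c(n1, n2))
  nm <- sizeFactorNormalize(cts)
  sf <- nm$size_factors
  ph <- estimateDispersion(cts, sf, groups = grp)
  p <- vapply(seq_len(ng), function(g) {
    nbExactTest(cts[g, grp == "A"], cts[g, grp == "B"],
                sf[grp == "A"], sf[grp == "B"], ph[g])
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.01)
  expect_lte(mean(p < 0.05), 0.10)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("planted effects are recovered and power grows with amplitude", {
  ps <- planted_sample(seed = 11, amplitude = 7, sigma = 200)
  gt <- S4Vectors::metadata(ps$sample)$ground_truth
  d <- gt$distance
  near <- names(d)[d < 300]; far <- names(d)[d > 800]
  expect_gte(length(near), 20)
  spec <- comparisonSpec(data.frame(sample_id = "planted", barcode = near),
                         data.frame(sample_id = "planted", barcode = far),
                         "near vs far")
  de <- runComparison(spec, list(planted = ps$sample))
  # expected LFC from the ground-truth kernel (library effects cancel in
  # expectation through the size factors)
  mu_a <- 5 * mean(gt$factor["Target", near])
  mu_b <- 5 * mean(gt$factor["Target", far])
  expected <- log2((mu_a + 1) / (mu_b + 1))
  expect_lt(abs(de["Target", "lfc"] - expected), 0.3)
  expect_true(de["Target", "significant"])
  expect_gt(de["Target", "lfc"], 0)
  # >= 95% of null genes non-significant
  nulls <- de[rownames(de) != "Target", ]
  expect_gte(mean(!nulls$significant), 0.95)

  # power: |lfc| monotone in planted amplitude
  lfcs <- vapply(c(1, 3, 7), function(a) {
    pa <- planted_sample(seed = 17, amplitude = a, sigma = 200)
    gta <- S4Vectors::metadata(pa$sample)$ground_truth
    da <- gta$distance
    sp <- comparisonSpec(
      data.frame(sample_id = "planted", barcode = names(da)[da < 300]),
      data.frame(sample_id = "planted", barcode = names(da)[da > 800]), "a")
    runComparison(sp, list(planted = pa$sample))["Target", "lfc"]
  }, numeric(1))
  expect_true(all(diff(lfcs) > 0))
})

test_that("zero-in-both genes and low-count flags behave as documented", {
  m <- rbind(zz = c(0, 0, 0, 0), lo = c(1, 0, 0, 0), hi = c(9, 9, 1, 1))
  colnames(m) <- paste0("b", 1:4)
  s <- tiny_sample(m, sample_id = "s")
  spec <- comparisonSpec(data.frame(sample_id = "s", barcode = c("b1", "b2")),
                         data.frame(sample_id = "s", barcode = c("b3", "b4")))
  de <- runComparison(spec, list(s = s))
  expect_equal(de["zz", "lfc"], 0)
  expect_equal(de["zz", "p"], 1)
  expect_false(de["zz", "significant"])
  expect_true(de["lo", "low_count"])
  expect_false(de["hi", "low_count"])
  # low-count exclusion drops flagged genes
  de2 <- runComparison(comparisonSpec(
    data.frame(sample_id = "s", barcode = c("b1", "b2")),
    data.frame(sample_id = "s", barcode = c("b3", "b4")),
    low_count_included = FALSE), list(s = s))
  expect_false(any(de2$low_count))
  # welch cross-check runs and agrees on the obvious gene's direction
  de3 <- runComparison(spec, list(s = s), test = "welch")
  expect_equal(de3["hi", "lfc"], de["hi", "lfc"])
})
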