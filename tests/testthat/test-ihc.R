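test_that("a blank channel yields zero nuclei", {
  blank <- matrix(0.2, 120, 120)
  ns <- segmentNuclei(blank, px_per_um = 1)
  expect_equal(nrow(ns@table), 0)
})

test_that("planted non-overlapping nuclei are counted exactly", {
  # 100 blobs on a 10x10 grid, 40 um apart, no noise
  centers <- expand.grid(x = seq(30, 390, 40), y = seq(30, 390, 40))
  img <- render_test_blobs(420, 420, centers$x, centers$y, sd_px = 2.5)
  img <- pmin(img, 1)
  ns <- segmentNuclei(img, px_per_um = 1, min_area = 5, max_area = 400)
  expect_equal(nrow(ns@table), 100)
  m <- match_centroids(ns@table, data.frame(x_um = centers$x, y_um = centers$y),
                       tol_um = 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  # rotation tolerance: +/- 1 count under a 90 degree rotation
  rot <- t(img[nrow(img):1, ])
  ns_rot <- segmentNuclei(rot, px_per_um = 1, min_area = 5, max_area = 400)
  expect_lte(abs(nrow(ns_rot@table) - 100), 1)
})

test_that("segmentation keeps recall and precision >= 0.95 under noise", {
  res <- vapply(1:10, function(sd) {
    cfg <- syntheticImageConfig(px_per_um = 1, width_um = 400, height_um = 400,
                                nuclei_density = 500, neuron_depletion_amp = 0,
                                noise_sigma = 0.2, seed = sd)
    im <- simulateSectionImage(cfg, c(200, 200))
    ns <- segmentNuclei(im$image[, , 1], px_per_um = 1)
    m <- match_centroids(ns@table, im$ground_truth$nuclei, tol_um = 5)
    c(m$recall, m$precision)
  }, numeric(2))
  expect_gte(min(res[1, ]), 0.95)
  expect_gte(min(res[2, ]), 0.95)
})

test_that("NeuN classification separates planted bright and dark nuclei", {
  centers <- expand.grid(x = seq(30, 370, 40), y = seq(30, 370, 40))  # 81
  nuc <- pmin(render_test_blobs(400, 400, centers$x, centers$y, 2.5), 1)
  ns <- segmentNuclei(nuc, px_per_um = 1, min_area = 5)
  expect_equal(nrow(ns@table), nrow(centers))

  # all bright / all dark NeuN channels
  all_on <- classifyNeun(ns, matrix(0.9, 400, 400), threshold = 0.5)
  expect_true(all(all_on@table$neun_positive))
  all_off <- classifyNeun(ns, matrix(0.05, 400, 400), threshold = 0.5)
  expect_false(any(all_off@table$neun_positive))

  # 60/40 split with wide separation: confusion-free via Otsu
  bright <- seq_len(nrow(centers)) <= 49
  neun <- pmin(render_test_blobs(400, 400, centers$x[bright],
                                 centers$y[bright], 2.5), 1) +
    0.02 * pmin(render_test_blobs(400, 400, centers$x[!bright],
                                  centers$y[!bright], 2.5), 1)
  cls <- classifyNeun(ns, neun)
  # match back to planted labels by position
  planted <- rep(FALSE, nrow(centers))
  planted[bright] <- TRUE
  d2 <- outer(cls@table$x_um, centers$x, "-")^2 +
    outer(cls@table$y_um, centers$y, "-")^2
  truth <- planted[apply(d2, 1, which.min)]
  expect_identical(cls@table$neun_positive, truth)
})

test_that("neuronal density arithmetic is exact on a known mask", {
  # 10 NeuN+ nuclei over a 100 x 100 px tissue mask at 1 px/um = 0.01 mm^2
  lab <- matrix(0L, 150, 150)
  tab <- data.frame(x_um = seq(5, 95, 10), y_um = seq(5, 95, 10),
                    area_um2 = 20, neun_mean = 1, neun_positive = TRUE)
  ns <- methods::new("NucleiSet", table = tab, labels = lab, pxPerUm = 1)
  mask <- matrix(FALSE, 150, 150)
  mask[1:100, 1:100] <- TRUE
  prof <- neuronalDensityProfile(ns, manualSite(0, 0), bin_width = 200,
                                 max_radius = 200, tissue_mask = mask)
  expect_equal(prof@statistic[1], 10 / 0.01)  # 1000 nuclei/mm^2
  expect_equal(prof@units, "nuclei/mm^2")
})

test_that("uniform nuclei give a flat density profile within Poisson error", {
  cfg <- syntheticImageConfig(px_per_um = 0.5, width_um = 1200,
                              height_um = 1200, nuclei_density = 800,
                              neuron_fraction = 1, neuron_depletion_amp = 0,
                              noise_sigma = 0, seed = 9)
  im <- simulateSectionImage(cfg, c(600, 600))
  truth <- im$ground_truth$nuclei
  lab <- matrix(0L, 600, 600)
  ns <- methods::new("NucleiSet",
                     table = data.frame(x_um = truth$x_um, y_um = truth$y_um,
                                        area_um2 = 20, neun_mean = 1,
                                        neun_positive = truth$neun_positive),
                     labels = lab, pxPerUm = 0.5)
  prof <- neuronalDensityProfile(ns, manualSite(600, 600), bin_width = 100,
                                 max_radius = 500)
  area_mm2 <- prof@n / prof@statistic
  lam <- 800
  for (b in seq_along(prof@n)) {
    expect_lt(abs(prof@n[b] - lam * area_mm2[b]),
              3 * sqrt(lam * area_mm2[b]) + 1)
  }
})

test_that("planted central depletion shows lowest density at the tract", {
  cfg <- syntheticImageConfig(px_per_um = 0.5, width_um = 1200,
                              height_um = 1200, nuclei_density = 1200,
                              neuron_fraction = 1, neuron_depletion_amp = 0.9,
                              neuron_depletion_sigma = 250, noise_sigma = 0,
                              seed = 12)
  im <- simulateSectionImage(cfg, c(600, 600))
  truth <- im$ground_truth$nuclei
  ns <- methods::new("NucleiSet",
                     table = data.frame(x_um = truth$x_um, y_um = truth$y_um,
                                        area_um2 = 20, neun_mean = 1,
                                        neun_positive = TRUE),
                     labels = matrix(0L, 600, 600), pxPerUm = 0.5)
  prof <- neuronalDensityProfile(ns, manualSite(600, 600), bin_width = 100,
                                 max_radius = 500)
  expect_equal(which.min(prof@statistic), 1)
  expect_gt(prof@statistic[5], prof@statistic[1])
})

test_that("GFAP normalization is exact for constant and planted fields", {
  # constant image: every bin exactly 1
  const <- matrix(0.4, 200, 200)
  prof <- gfapIntensityProfile(const, manualSite(100, 100), px_per_um = 1,
                               bin_width = 10, max_radius = 100)
  expect_true(all(abs(prof@statistic - 1) < 1e-12))

  # pixel-count-weighted mean over all tissue bins is 1 by construction
  set.seed(5)
  noisy <- matrix(runif(200 * 200, 0.2, 0.8), 200, 200)
  p2 <- gfapIntensityProfile(noisy, manualSite(100, 100), px_per_um = 1,
                             bin_width = 25, max_radius = Inf)
  w_mean <- sum(p2@statistic * p2@n, na.rm = TRUE) / sum(p2@n)
  expect_equal(w_mean, 1, tolerance = 1e-12)

  # planted exponential decay, no noise: within 2% of the analytic profile
  cfg <- syntheticImageConfig(px_per_um = 1, width_um = 600, height_um = 600,
                              nuclei_density = 0, gfap_baseline = 0.2,
                              gfap_amp = 0.5, gfap_decay = 150,
                              noise_sigma = 0, seed = 2)
  im <- simulateSectionImage(cfg, c(300, 300))
  p3 <- gfapIntensityProfile(im$image[, , 3], manualSite(300, 300),
                             px_per_um = 1, bin_width = 10, max_radius = 250)
  norm <- mean(im$image[, , 3])
  mids <- (p3@binEdges[-1] + p3@binEdges[-length(p3@binEdges)]) / 2
  analytic <- (0.2 + 0.5 * exp(-mids / 150)) / norm
  expect_true(all(abs(p3@statistic / analytic - 1) < 0.02))

  expect_error(gfapIntensityProfile(const, manualSite(0, 0), 1,
                                    tissue_mask = matrix(FALSE, 200, 200)),
               "empty")
})

test_that("gene and protein radial profiles agree on shared kernels", {
  # Gfap counts (Gaussian sigma 300) and GFAP intensity (exponential decay)
  # both decay monotonically from the tract: Spearman rho > 0.8
  cfg <- syntheticConfig(25, 25, genes = rbind(
    geneSpec("Gfap", 5, 0.1, "induced", amplitude = 4, decay_sigma = 300),
    do.call(rbind, lapply(1:15, function(i) {
      geneSpec(sprintf("Bg%02d", i), 5, 0.1)
    }))), libsize_sigma = 0, seed = 31)
  s <- simulateSample(cfg, "conc")
  site <- manualSite(cfg$implant_xy[1], cfg$implant_xy[2])
  gene_prof <- radialGeneProfile(s, "Gfap", site, 100, 1000)

  icfg <- syntheticImageConfig(px_per_um = 0.25, width_um = 2400,
                               height_um = 2100, nuclei_density = 0,
                               gfap_baseline = 0.2, gfap_amp = 0.4,
                               gfap_decay = 300, noise_sigma = 0.01, seed = 31)
  im <- simulateSectionImage(icfg, c(site@x, site@y))
  prot_prof <- gfapIntensityProfile(im$image[, , 3], site, px_per_um = 0.25,
                                    bin_width = 100, max_radius = 1000)
  ok <- !is.na(gene_prof@statistic) & !is.na(prot_prof@statistic)
  rho <- cor(gene_prof@statistic[ok], prot_prof@statistic[ok],
             method = "spearman")
  expect_gt(rho, 0.8)
})
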