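test_that("a point mass of marker counts localizes to that spot", {
  cts <- matrix(0, 2, 9, dimnames = list(c("Ccl3", "H"), paste0("b", 1:9)))
  cts["Ccl3", 5] <- 50
  cts["H", ] <- 1
  grid <- expand.grid(array_col = 0:2, array_row = 0:2)
  spots <- data.frame(barcode = paste0("b", 1:9),
                      array_row = grid$array_row, array_col = grid$array_col,
                      x_um = grid$array_col * 100, y_um = grid$array_row * 100,
                      in_tissue = TRUE)
  s <- SpatialStimSample(cts, spots, sample_id = "pm")
  site <- localizeImplant(s, markers = "Ccl3", prior_xy = c(100, 100),
                          mass_threshold = 1)
  expect_equal(site@method, "marker_centroid")
  expect_equal(c(site@x, site@y), c(100, 100))
  expect_error(localizeImplant(s, markers = "Nope", prior_xy = c(0, 0)),
               "absent")
})

test_that("zero marker signal falls back to the stereotaxic prior", {
  cfg <- syntheticConfig(10, 10, genes = rbind(
    geneSpec("Ccl3", 0), geneSpec("Ccl4", 0), geneSpec("Gfap", 0),
    geneSpec("H", 5)), seed = 1)
  s <- simulateSample(cfg, "s0")
  site <- suppressWarnings(localizeImplant(s, prior_xy = c(450, 390)))
  expect_equal(site@method, "prior_only")
  expect_equal(c(site@x, site@y), c(450, 390))
})

test_that("planted implants are recovered within one spot pitch", {
  hits <- vapply(1:20, function(sd) {
    ms <- marker_sample(seed = sd)
    site <- localizeImplant(ms$sample,
                            prior_xy = ms$cfg$implant_xy + c(150, -120),
                            seed = sd)
    err <- sqrt(sum((c(site@x, site@y) - ms$cfg$implant_xy)^2))
    site@method == "marker_centroid" && err < 100
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("weighted-centroid localization is translation-equivariant", {
  ms <- marker_sample(seed = 3)
  s <- ms$sample
  delta <- c(370, -240)
  sp <- spotPositions(s)
  sp$x_um <- sp$x_um + delta[1]
  sp$y_um <- sp$y_um + delta[2]
  s2 <- SpatialStimSample(spotCounts(s), sp, sample_id = "shifted")
  site1 <- localizeImplant(s, prior_xy = ms$cfg$implant_xy + c(100, 80),
                           seed = 5)
  site2 <- localizeImplant(s2, prior_xy = ms$cfg$implant_xy + c(100, 80) + delta,
                           seed = 5)
  expect_equal(c(site2@x, site2@y), c(site1@x, site1@y) + delta,
               tolerance = 1e-9)
})

test_that("distance binning is half-open and left-closed", {
  # one spot at exactly d = 250 with bin width 100 lands in [200, 300)
  cts <- matrix(c(4, 4), 1, 2, dimnames = list("g", c("near", "far")))
  spots <- data.frame(barcode = c("near", "far"), array_row = 0L,
                      array_col = 0:1, x_um = c(0, 250), y_um = 0,
                      in_tissue = TRUE)
  s <- SpatialStimSample(cts, spots)
  prof <- radialGeneProfile(s, "g", manualSite(0, 0), bin_width = 100,
                            max_radius = 500)
  expect_equal(prof@n, c(1, 0, 1, 0, 0))
  expect_equal(prof@binEdges, seq(0, 500, 100))
  # empty bins are NA, not zero
  expect_true(is.na(prof@statistic[2]))
  # boundary: a spot at exactly an edge goes to the upper bin
  spots$x_um[2] <- 200
  s2 <- SpatialStimSample(cts, spots)
  prof2 <- radialGeneProfile(s2, "g", manualSite(0, 0), 100, 500)
  expect_equal(prof2@n, c(1, 0, 1, 0, 0))
})

test_that("profile mass is conserved and tables round-trip", {
  ps <- planted_sample(seed = 8, n_null = 3)
  s <- ps$sample
  site <- manualSite(ps$cfg$implant_xy[1], ps$cfg$implant_xy[2])
  prof <- radialGeneProfile(s, "Target", site, 100, 1200)
  sp <- spotPositions(s)
  d <- sqrt((sp$x_um - site@x)^2 + (sp$y_um - site@y)^2)
  expect_equal(sum(prof@n), sum(d < 1200))

  tab <- profileToTable(prof)
  expect_equal(nrow(tab), length(prof@binEdges) - 1)
  expect_equal(tab$statistic, prof@statistic)
  expect_equal(tab$bin, seq_along(prof@statistic) - 1L)
  # merged multi-profile table: row count is the sum of bins
  tab2 <- profileToTable(list(a = prof, b = prof))
  expect_equal(nrow(tab2), 2 * nrow(tab))
  # empty list gives a header-only table
  expect_equal(nrow(profileToTable(list())), 0)
})

test_that("null genes give flat radial profiles", {
  ps <- planted_sample(seed = 14, n_null = 20, libsize_sigma = 0)
  s <- ps$sample
  site <- manualSite(ps$cfg$implant_xy[1], ps$cfg$implant_xy[2])
  prof <- radialGeneProfile(s, "Null01", site, 200, 1200)
  st <- prof@statistic
  # per-bin SEs from the generator's NB variance (mu 5, phi 0.1); flat
  # means the extreme bins are compatible with each other
  mu <- 5
  se <- sqrt((mu + 0.1 * mu^2) / prof@n)
  hi <- which.max(st); lo <- which.min(st)
  expect_lt(max(st) - min(st), 3 * sqrt(se[hi]^2 + se[lo]^2))
})

test_that("a Gfap-like kernel peaks at the tract and plateaus by ~700 um", {
  # 20-gene null background keeps the marker's own induction from moving
  # the per-spot totals (as in a transcriptome-wide panel)
  cfg <- syntheticConfig(35, 35, genes = rbind(
    geneSpec("Gfap", 5, 0.1, "induced", amplitude = 4, decay_sigma = 300),
    do.call(rbind, lapply(1:20, function(i) {
      geneSpec(sprintf("Bg%02d", i), 5, 0.1)
    }))), libsize_sigma = 0, seed = 6)
  s <- simulateSample(cfg, "gfap")
  site <- manualSite(cfg$implant_xy[1], cfg$implant_xy[2])
  # 150 um bins: the first bin holds the tract spot and its six neighbours,
  # so the peak estimate is not decided by a single noisy draw
  prof <- radialGeneProfile(s, "Gfap", site, 150, 1500)
  st <- prof@statistic
  expect_equal(which.max(st), 1)  # largest peak close to the tract
  # plateau: bins beyond 750 um vary little and sit near baseline
  tail_bins <- st[6:length(st)]
  expect_lt(max(tail_bins) - min(tail_bins), 0.25 * (st[1] - mean(tail_bins)))
  # steady decrease towards the plateau
  expect_true(all(diff(st[1:4]) < 0))
})

test_that("monotone kernels yield decreasing profiles across seeds", {
  res <- vapply(1:20, function(sd) {
    cfg <- syntheticConfig(25, 25, genes = rbind(
      geneSpec("G", 5, 0.1, "induced", amplitude = 6, decay_sigma = 300),
      do.call(rbind, lapply(1:15, function(i) {
        geneSpec(sprintf("Bg%02d", i), 5, 0.1)
      }))),
      libsize_sigma = 0, seed = sd)
    s <- simulateSample(cfg, "m")
    prof <- radialGeneProfile(s, "G",
                              manualSite(cfg$implant_xy[1], cfg$implant_xy[2]),
                              150, 1200)
    ok <- !is.na(prof@statistic)
    mids <- (prof@binEdges[-1] + prof@binEdges[-length(prof@binEdges)]) / 2
    ct <- suppressWarnings(cor.test(mids[ok], prof@statistic[ok],
                                    method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }, c(rho = 0, p = 0))
  expect_true(all(res["rho", ] < 0))
  expect_true(all(res["p", ] < 0.05))
})

test_that("a site outside the tissue warns rather than errors", {
  m <- matrix(1:4, 1, 4, dimnames = list("g", paste0("b", 1:4)))
  s <- tiny_sample(m)
  expect_warning(radialGeneProfile(s, "g", manualSite(-500, -500), 100, 1000),
                 "outside")
})
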