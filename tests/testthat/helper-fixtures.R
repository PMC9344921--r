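# Fixture builders shared across test files. All fixtures are generated in
# code; none are stored on disk.

# a tiny sample from an explicit count matrix laid on a row of spots
tiny_sample <- function(counts, pitch = 100, sample_id = "tiny",
                        in_tissue = TRUE, condition = "craniotomy") {
  n <- ncol(counts)
  spots <- data.frame(
    barcode = colnames(counts), array_row = 0L, array_col = seq_len(n) - 1L,
    x_um = (seq_len(n) - 1) * pitch, y_um = 0,
    in_tissue = rep_len(in_tissue, n)
  )
  SpatialStimSample(counts, spots, sample_id = sample_id,
                    condition = condition, timepoint = "acute")
}

# synthetic sample with one planted induced gene among nulls; the null
# background is wide enough that the target's own induction contributes
# little to the per-spot totals, as in a transcriptome-wide panel
planted_sample <- function(seed, amplitude = 7, sigma = 200, n_null = 60,
                           nrow_grid = 25, baseline = 5, libsize_sigma = 0.2) {
  cfg <- syntheticConfig(
    nrow_grid, nrow_grid,
    genes = rbind(
      geneSpec("Target", baseline, 0.1, "induced", amplitude = amplitude,
               decay_sigma = sigma),
      do.call(rbind, lapply(seq_len(n_null), function(i) {
        geneSpec(sprintf("Null%02d", i), baseline, 0.1)
      }))),
    libsize_sigma = libsize_sigma, seed = seed)
  list(cfg = cfg, sample = simulateSample(cfg, "planted"))
}

# marker-bearing sample at full capture-area geometry, for localization
marker_sample <- function(seed, amplitude = 7, sigma = 200) {
  cfg <- syntheticConfig(65, 65, genes = rbind(
    geneSpec("Ccl3", 2, 0.2, "induced", amplitude = amplitude, decay_sigma = sigma),
    geneSpec("Ccl4", 2, 0.2, "induced", amplitude = amplitude, decay_sigma = sigma),
    geneSpec("Gfap", 5, 0.2, "induced", amplitude = amplitude, decay_sigma = sigma),
    do.call(rbind, lapply(1:10, function(i) geneSpec(sprintf("N%02d", i), 5, 0.1)))),
    seed = seed)
  list(cfg = cfg, sample = simulateSample(cfg, "marked"))
}

# independent blob renderer (test-side oracle, separate from the package's)
render_test_blobs <- function(h, w, cx_px, cy_px, sd_px, peak = 1) {
  # pixel (r, c) centre sits at (c - 1, r - 1) in pixel units, matching the
  # package's 0-based image coordinate convention
  img <- matrix(0, h, w)
  xs <- seq_len(w) - 1; ys <- seq_len(h) - 1
  for (k in seq_along(cx_px)) {
    gx <- exp(-((xs - cx_px[k])^2) / (2 * sd_px^2))
    gy <- exp(-((ys - cy_px[k])^2) / (2 * sd_px^2))
    img <- img + peak * outer(gy, gx)
  }
  img
}

# match detected centroids to planted truth within tol_um
match_centroids <- function(detected, truth, tol_um = 5) {
  if (!nrow(detected) || !nrow(truth)) {
    return(list(recall = 0, precision = 0))
  }
  d2 <- outer(detected$x_um, truth$x_um, "-")^2 +
    outer(detected$y_um, truth$y_um, "-")^2
  list(recall = mean(apply(d2, 2, min) < tol_um^2),
       precision = mean(apply(d2, 1, min) < tol_um^2))
}
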