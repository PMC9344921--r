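#' Specify one simulated gene
#'
#' Defines the baseline expression, negative-binomial dispersion and radial
#' spatial effect of one gene in the synthetic generator. The spatial factor
#' multiplying the baseline mean at distance `d` from the implant is
#' Gaussian-kernel shaped:
#' induced genes have `f(d) = 1 + A * exp(-d^2 / (2 sigma^2)) >= 1`,
#' depleted genes `f(d) = 1 - A * exp(-d^2 / (2 sigma^2))` (requiring
#' `0 <= A <= 1`), and null genes `f == 1`.
#'
#' @param name gene symbol.
#' @param baseline_mu mean counts per unit library size far from the implant.
#' @param dispersion negative-binomial dispersion `phi >= 0`
#'   (variance `mu + phi mu^2`); 0 means Poisson.
#' @param effect one of `"null"`, `"induced"`, `"depleted"`.
#' @param amplitude effect amplitude `A >= 0` (for depleted, at most 1).
#' @param decay_sigma Gaussian kernel width in micrometres. The default of
#'   300 um produces profiles that decay to near-baseline by roughly 700 um,
#'   the plateau distance reported for reactive-astrocyte (Gfap) expression
#'   around stimulated microwires.
#' @return a one-row `data.frame` usable in [syntheticConfig()].
#' @export
geneSpec <- function(name, baseline_mu, dispersion = 0.1,
                     effect = c("null", "induced", "depleted"),
                     amplitude = 0, decay_sigma = 300) {
  effect <- match.arg(effect)
  stopifnot(is.character(name), length(name) == 1,
            baseline_mu >= 0, dispersion >= 0, amplitude >= 0,
            decay_sigma > 0)
  if (effect == "depleted" && amplitude > 1) {
    stop("depleted amplitude must be in [0, 1]")
  }
  data.frame(name = name, baseline_mu = baseline_mu,
             dispersion = dispersion, effect = effect,
             amplitude = amplitude, decay_sigma = decay_sigma,
             stringsAsFactors = FALSE)
}

#' Configuration for a synthetic Visium-like capture area
#'
#' Geometry defaults follow the Visium platform (55 um spot diameter, 100 um
#' center-to-center pitch on a hexagonal lattice); a 65 x 65 grid at that
#' pitch spans about 6.45 x 5.54 mm, filling a 6.5 x 6.5 mm capture area.
#' Library sizes are log-normal across spots; `depth_total`, when given,
#' rescales expected totals to emulate samples sequenced to different depths.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param spot_pitch center-to-center spot distance, um; must exceed
#'   `spot_diameter`.
#' @param spot_diameter spot diameter, um.
#' @param implant_xy numeric length-2, implant (electrode tract) position in
#'   um; defaults to the grid centre.
#' @param genes `data.frame` of [geneSpec()] rows.
#' @param libsize_mu,libsize_sigma log-scale mean and SD of per-spot library
#'   size factors (`libsize_sigma = 0` gives identical library sizes).
#' @param depth_total optional expected total mapped reads for the sample;
#'   `NULL` leaves baseline means as given.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return a validated `list` of class `"syntheticConfig"`.
#' @examples
#' cfg <- syntheticConfig(10, 10, genes = rbind(
#'   geneSpec("Gfap", 5, 0.1, "induced", amplitude = 7, decay_sigma = 200),
#'   geneSpec("Actb", 20, 0.05)))
#' @export
syntheticConfig <- function(n_rows = 65, n_cols = 65, spot_pitch = 100,
                            spot_diameter = 55, implant_xy = NULL,
                            genes = defaultGenePanel(),
                            libsize_mu = 0, libsize_sigma = 0.35,
                            depth_total = NULL, seed = 1L) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be >= 1")
  stopifnot(spot_pitch > spot_diameter, spot_diameter > 0,
            libsize_sigma >= 0, is.data.frame(genes), nrow(genes) >= 1)
  if (is.null(implant_xy)) {
    implant_xy <- c((n_cols - 1) * spot_pitch / 2,
                    (n_rows - 1) * spot_pitch * sqrt(3) / 2 / 2)
  }
  stopifnot(length(implant_xy) == 2, all(is.finite(implant_xy)))
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    spot_pitch = spot_pitch, spot_diameter = spot_diameter,
    implant_xy = as.numeric(implant_xy), genes = genes,
    libsize_mu = libsize_mu, libsize_sigma = libsize_sigma,
    depth_total = depth_total, seed = as.integer(seed)
  ), class = "syntheticConfig")
}

#' Default synthetic gene panel
#'
#' A small panel emulating the expression structure around a stimulated
#' implant: radially induced inflammatory and gliosis genes (Ccl3, Ccl4,
#' Gfap, Cxcl13, C3), a locally depleted neuron marker (Rbfox3, encoding
#' NeuN), and null housekeeping-like genes. Amplitudes are loosely calibrated
#' to the magnitude class of reported log2 fold changes (Ccl3 around 3,
#' Cxcl13 much larger, Gfap between one and two) with a 300 um decay scale.
#'
#' @param n_null number of additional null genes.
#' @return `data.frame` of gene specifications.
#' @export
defaultGenePanel <- function(n_null = 40) {
  panel <- rbind(
    geneSpec("Ccl3",   2.0, 0.2, "induced", amplitude = 8,  decay_sigma = 300),
    geneSpec("Ccl4",   2.0, 0.2, "induced", amplitude = 8,  decay_sigma = 300),
    geneSpec("Gfap",   5.0, 0.2, "induced", amplitude = 4,  decay_sigma = 300),
    geneSpec("Cxcl13", 0.5, 0.3, "induced", amplitude = 40, decay_sigma = 300),
    geneSpec("C3",     1.0, 0.2, "induced", amplitude = 10, decay_sigma = 300),
    geneSpec("Rbfox3", 2.0, 0.2, "depleted", amplitude = 0.8, decay_sigma = 300)
  )
  if (n_null > 0) {
    nulls <- do.call(rbind, lapply(seq_len(n_null), function(i) {
      geneSpec(sprintf("Null%03d", i), baseline_mu = 2^((i %% 7) - 2),
               dispersion = 0.1)
    }))
    panel <- rbind(panel, nulls)
  }
  panel
}

#' Lay out spots on a hexagonal Visium-style lattice
#'
#' Spots sit on a hexagonal lattice: within an array row, centres are
#' `spot_pitch` apart in x; odd array rows are offset by half a pitch;
#' consecutive rows are `spot_pitch * sqrt(3) / 2` apart in y. Array indices
#' are 0-based and the physical origin is the top-left spot of row 0. All
#' spots start `in_tissue = TRUE` and `artifact = FALSE`.
#'
#' @param cfg a [syntheticConfig()].
#' @return `data.frame` of spots: `barcode`, `array_row`, `array_col`,
#'   `x_um`, `y_um`, `in_tissue`, `artifact`. Barcodes are unique.
#' @examples
#' grid <- makeSpotGrid(syntheticConfig(2, 2, genes = geneSpec("A", 1)))
#' grid$x_um  # row 1 offset by half a pitch
#' @export
makeSpotGrid <- function(cfg) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  rows <- rep(seq_len(cfg$n_rows) - 1L, each = cfg$n_cols)
  cols <- rep(seq_len(cfg$n_cols) - 1L, times = cfg$n_rows)
  x <- cols * cfg$spot_pitch + (rows %% 2L) * cfg$spot_pitch / 2
  y <- rows * cfg$spot_pitch * sqrt(3) / 2
  data.frame(
    barcode = sprintf("SPOT-%03d-%03d", rows, cols),
    array_row = rows, array_col = cols,
    x_um = x, y_um = y, in_tissue = TRUE, artifact = FALSE,
    stringsAsFactors = FALSE
  )
}

.spatial_factor <- function(gene, d) {
  k <- exp(-d^2 / (2 * gene$decay_sigma^2))
  switch(gene$effect,
    null = rep(1, length(d)),
    induced = 1 + gene$amplitude * k,
    depleted = 1 - gene$amplitude * k
  )
}

#' Simulate spot-level counts with known ground truth
#'
#' Counts are negative-binomial: `count[g, i] ~ NB(mean = baseline_mu_g *
#' L_i * f_g(d_i), dispersion = phi_g)` where `L_i` is a log-normal library
#' size, `d_i` the Euclidean distance from spot `i` to the implant, and
#' `f_g` the gene's radial effect kernel ([geneSpec()]). With `phi = 0` the
#' Poisson limit is used. The same config and seed give bit-identical output.
#'
#' @param cfg a [syntheticConfig()].
#' @param spots spot table from [makeSpotGrid()] (or any table with
#'   `barcode`, `x_um`, `y_um`).
#' @return list with `counts` (sparse integer gene x spot matrix) and
#'   `ground_truth` (list: `libsize` per spot, `factor` gene x spot matrix of
#'   `f_g(d_i)`, `distance` per spot, `implant_xy`, `genes`).
#' @export
simulateCounts <- function(cfg, spots) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  set.seed(cfg$seed)
  g <- cfg$genes
  n_spot <- nrow(spots)
  d <- sqrt((spots$x_um - cfg$implant_xy[1])^2 +
            (spots$y_um - cfg$implant_xy[2])^2)
  L <- if (cfg$libsize_sigma > 0) {
    stats::rlnorm(n_spot, cfg$libsize_mu, cfg$libsize_sigma)
  } else {
    rep(exp(cfg$libsize_mu), n_spot)
  }
  fmat <- t(vapply(seq_len(nrow(g)), function(j) .spatial_factor(g[j, ], d),
                   numeric(n_spot)))
  mu <- g$baseline_mu * fmat * rep(L, each = nrow(g))
  if (!is.null(cfg$depth_total)) {
    expected <- sum(mu)
    if (expected > 0) mu <- mu * cfg$depth_total / expected
  }
  counts <- matrix(0L, nrow(g), n_spot,
                   dimnames = list(g$name, spots$barcode))
  for (j in seq_len(nrow(g))) {
    counts[j, ] <- if (g$dispersion[j] > 0) {
      stats::rnbinom(n_spot, mu = mu[j, ], size = 1 / g$dispersion[j])
    } else {
      stats::rpois(n_spot, mu[j, ])
    }
  }
  dimnames(fmat) <- dimnames(counts)
  list(
    counts = methods::as(counts, "CsparseMatrix"),
    ground_truth = list(libsize = stats::setNames(L, spots$barcode),
                        factor = fmat, distance = stats::setNames(d, spots$barcode),
                        implant_xy = cfg$implant_xy, genes = g)
  )
}

#' Simulate a complete synthetic sample
#'
#' Convenience wrapper: builds the spot grid, simulates counts, and wraps
#' them in a [SpatialStimSample-class]. The ground truth is stored in
#' `metadata(x)$ground_truth` so downstream tests can read it instead of
#' re-deriving it. The mapped-read total is set to the matrix grand total,
#' the convention used for synthetic data throughout the package.
#'
#' @param cfg a [syntheticConfig()].
#' @param sample_id,condition,timepoint sample labels.
#' @return a [SpatialStimSample-class] with ground truth in its metadata.
#' @export
simulateSample <- function(cfg, sample_id = "synthetic",
                           condition = "mwa_stim", timepoint = "chronic") {
  spots <- makeSpotGrid(cfg)
  sim <- simulateCounts(cfg, spots)
  s <- SpatialStimSample(sim$counts, spots, sample_id = sample_id,
                         condition = condition, timepoint = timepoint,
                         mapped_reads = sum(sim$counts))
  metadata(s)$ground_truth <- sim$ground_truth
  s
}

#' Configuration for a synthetic IHC section image
#'
#' Parameters of the three-channel (nuclei / NeuN / GFAP) fluorescence image
#' generator. Intensities are kept in `[0, 1]`; on disk they are 16-bit.
#'
#' @param px_per_um pixels per micrometre (> 0).
#' @param width_um,height_um image extent in micrometres.
#' @param nuclei_density baseline nuclei density, nuclei per mm^2.
#' @param neuron_fraction fraction of nuclei that are NeuN-positive far from
#'   the implant.
#' @param neuron_depletion_amp,neuron_depletion_sigma radial neuron-loss
#'   kernel: NeuN+ density is multiplied by
#'   `1 - amp * exp(-d^2 / (2 sigma^2))`.
#' @param gfap_baseline,gfap_amp,gfap_decay GFAP intensity field
#'   `baseline + amp * exp(-d / decay)` (exponential radial decay).
#' @param nucleus_radius_um rendered nucleus blob radius.
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param max_pixels safety cap on total pixels per channel.
#' @param seed integer seed.
#' @return a validated list of class `"syntheticImageConfig"`.
#' @export
syntheticImageConfig <- function(px_per_um = 0.5, width_um = 2000,
                                 height_um = 2000, nuclei_density = 1500,
                                 neuron_fraction = 0.6,
                                 neuron_depletion_amp = 0.8,
                                 neuron_depletion_sigma = 300,
                                 gfap_baseline = 0.1, gfap_amp = 0.4,
                                 gfap_decay = 300, nucleus_radius_um = 4,
                                 noise_sigma = 0.01, max_pixels = 4e7,
                                 seed = 1L) {
  stopifnot(px_per_um > 0, width_um > 0, height_um > 0,
            nuclei_density >= 0, neuron_fraction >= 0, neuron_fraction <= 1,
            neuron_depletion_amp >= 0, neuron_depletion_amp <= 1,
            neuron_depletion_sigma > 0, gfap_decay > 0, noise_sigma >= 0)
  structure(list(
    px_per_um = px_per_um, width_um = width_um, height_um = height_um,
    nuclei_density = nuclei_density, neuron_fraction = neuron_fraction,
    neuron_depletion_amp = neuron_depletion_amp,
    neuron_depletion_sigma = neuron_depletion_sigma,
    gfap_baseline = gfap_baseline, gfap_amp = gfap_amp,
    gfap_decay = gfap_decay, nucleus_radius_um = nucleus_radius_um,
    noise_sigma = noise_sigma, max_pixels = max_pixels,
    seed = as.integer(seed)
  ), class = "syntheticImageConfig")
}

.render_blobs <- function(img, cx_px, cy_px, radius_px, peak = 1) {
  # add a Gaussian blob (sd = radius/2) at each centre; img is rows=y, cols=x
  if (!length(cx_px)) return(img)
  r <- ceiling(3 * radius_px)
  off <- seq(-r, r)
  kern <- exp(-(outer(off^2, off^2, "+")) / (2 * (radius_px / 2)^2)) * peak
  h <- nrow(img); w <- ncol(img)
  for (k in seq_along(cx_px)) {
    rows <- round(cy_px[k]) + off
    cols <- round(cx_px[k]) + off
    ok_r <- rows >= 1 & rows <= h
    ok_c <- cols >= 1 & cols <= w
    img[rows[ok_r], cols[ok_c]] <- img[rows[ok_r], cols[ok_c]] +
      kern[ok_r, ok_c, drop = FALSE]
  }
  img
}

#' Simulate a three-channel IHC section image with ground truth
#'
#' Channel 1 (nuclei): Gaussian blobs at Poisson-sampled centroids whose
#' local density is the baseline for non-neuronal nuclei, and the baseline
#' times `1 - depletion kernel` for NeuN+ nuclei. Channel 2 (NeuN): blobs at
#' the NeuN+ centroids only. Channel 3 (GFAP): a radially decaying intensity
#' field `baseline + amp * exp(-d / decay)` plus Gaussian noise. All
#' intensities are clipped to `[0, 1]`. Ground-truth centroids and NeuN
#' labels are returned alongside the image.
#'
#' @param cfg a [syntheticImageConfig()].
#' @param implant_xy implant position in micrometres (image frame, origin at
#'   the top-left pixel centre).
#' @return list with `image` (array `h x w x 3`, channels nuclei/NeuN/GFAP)
#'   and `ground_truth` (`data.frame` of nucleus `x_um`, `y_um`,
#'   `neun_positive`; plus `implant_xy`).
#' @export
simulateSectionImage <- function(cfg, implant_xy) {
  stopifnot(inherits(cfg, "syntheticImageConfig"), length(implant_xy) == 2)
  w <- round(cfg$width_um * cfg$px_per_um)
  h <- round(cfg$height_um * cfg$px_per_um)
  if (as.numeric(w) * h > cfg$max_pixels) {
    stop("requested image exceeds the configured pixel safety cap")
  }
  set.seed(cfg$seed)
  area_mm2 <- cfg$width_um * cfg$height_um / 1e6
  # non-neuronal nuclei: homogeneous Poisson
  n_other <- stats::rpois(1, cfg$nuclei_density * (1 - cfg$neuron_fraction) * area_mm2)
  ox <- stats::runif(n_other, 0, cfg$width_um)
  oy <- stats::runif(n_other, 0, cfg$height_um)
  # neurons: inhomogeneous Poisson by thinning with the depletion kernel
  n_neu0 <- stats::rpois(1, cfg$nuclei_density * cfg$neuron_fraction * area_mm2)
  nx <- stats::runif(n_neu0, 0, cfg$width_um)
  ny <- stats::runif(n_neu0, 0, cfg$height_um)
  dn <- sqrt((nx - implant_xy[1])^2 + (ny - implant_xy[2])^2)
  keep <- stats::runif(n_neu0) >=
    cfg$neuron_depletion_amp * exp(-dn^2 / (2 * cfg$neuron_depletion_sigma^2))
  nx <- nx[keep]; ny <- ny[keep]
  truth <- data.frame(
    x_um = c(nx, ox), y_um = c(ny, oy),
    neun_positive = c(rep(TRUE, length(nx)), rep(FALSE, length(ox)))
  )
  r_px <- cfg$nucleus_radius_um * cfg$px_per_um
  nuc <- matrix(0, h, w)
  nuc <- .render_blobs(nuc, truth$x_um * cfg$px_per_um,
                       truth$y_um * cfg$px_per_um, r_px)
  neun <- matrix(0, h, w)
  neun <- .render_blobs(neun, nx * cfg$px_per_um, ny * cfg$px_per_um, r_px)
  # GFAP field over pixel centres (pixel (r, c) centre at ((c-1)/s, (r-1)/s) um)
  px_x <- (seq_len(w) - 1) / cfg$px_per_um
  px_y <- (seq_len(h) - 1) / cfg$px_per_um
  dpix <- sqrt(outer((px_y - implant_xy[2])^2, (px_x - implant_xy[1])^2, "+"))
  gfap <- cfg$gfap_baseline + cfg$gfap_amp * exp(-dpix / cfg$gfap_decay)
  if (cfg$noise_sigma > 0) {
    nuc  <- nuc  + stats::rnorm(length(nuc),  0, cfg$noise_sigma)
    neun <- neun + stats::rnorm(length(neun), 0, cfg$noise_sigma)
    gfap <- gfap + stats::rnorm(length(gfap), 0, cfg$noise_sigma)
  }
  img <- array(0, dim = c(h, w, 3),
               dimnames = list(NULL, NULL, c("nuclei", "neun", "gfap")))
  img[, , 1] <- pmin(pmax(nuc, 0), 1)
  img[, , 2] <- pmin(pmax(neun, 0), 1)
  img[, , 3] <- pmin(pmax(gfap, 0), 1)
  list(image = img,
       ground_truth = list(nuclei = truth, implant_xy = as.numeric(implant_xy)))
}
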