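#' Segment nuclei from a fluorescence channel
#'
#' Standard deterministic pipeline: Gaussian smoothing, Otsu threshold,
#' connected components, area filter, centroids. Image pixels are indexed
#' with pixel `(row, col)` centred at `((col-1)/px_per_um, (row-1)/px_per_um)`
#' micrometres, matching the synthetic generator and TIFF reader. A blank
#' (constant) channel yields an empty set, not an error.
#'
#' @param channel numeric matrix (`h x w`) with intensities in `[0, 1]`.
#' @param px_per_um pixels per micrometre.
#' @param min_area,max_area nucleus area bounds in square micrometres.
#' @param smoothing_sigma Gaussian smoothing SD in micrometres.
#' @return a [NucleiSet-class].
#' @export
segmentNuclei <- function(channel, px_per_um, min_area = 10, max_area = 400,
                          smoothing_sigma = 1) {
  stopifnot(is.matrix(channel), px_per_um > 0)
  empty <- function() methods::new(
    "NucleiSet",
    table = data.frame(x_um = numeric(0), y_um = numeric(0),
                       area_um2 = numeric(0)),
    labels = matrix(0L, nrow(channel), ncol(channel)), pxPerUm = px_per_um)
  if (diff(range(channel)) < 1e-6) return(empty())
  # EBImage images are x-major: transpose so dim 1 is x (columns of channel)
  img <- EBImage::Image(t(channel))
  sigma_px <- smoothing_sigma * px_per_um
  if (sigma_px > 0) img <- EBImage::gblur(img, sigma = sigma_px)
  th <- EBImage::otsu(img, range = c(0, 1))
  mask <- img > th
  lab <- EBImage::bwlabel(mask)
  lab_m <- t(EBImage::imageData(lab))  # back to row = y, col = x
  if (max(lab_m) == 0) return(empty())
  areas_px <- tabulate(lab_m[lab_m > 0], nbins = max(lab_m))
  areas_um2 <- areas_px / px_per_um^2
  keep <- which(areas_um2 >= min_area & areas_um2 <= max_area)
  if (!length(keep)) return(empty())
  # centroids of kept components (pixel-centre coordinates -> um)
  idx <- which(lab_m %in% keep)
  labs <- lab_m[idx]
  rr <- (idx - 1) %% nrow(lab_m) + 1
  cc <- (idx - 1) %/% nrow(lab_m) + 1
  cx <- tapply((cc - 1) / px_per_um, labs, mean)
  cy <- tapply((rr - 1) / px_per_um, labs, mean)
  old <- as.integer(names(cx))
  relabel <- matrix(0L, nrow(lab_m), ncol(lab_m))
  map <- integer(max(lab_m))
  map[old] <- seq_along(old)
  relabel[lab_m > 0] <- map[lab_m[lab_m > 0]]
  methods::new("NucleiSet",
    table = data.frame(x_um = as.numeric(cx), y_um = as.numeric(cy),
                       area_um2 = areas_um2[old]),
    labels = relabel, pxPerUm = px_per_um)
}

#' Classify nuclei as NeuN-positive
#'
#' Computes the mean NeuN intensity within each nucleus mask and applies a
#' single global per-section threshold: Otsu over the per-nucleus means by
#' default, or a fixed numeric cutoff.
#'
#' @param nuclei a [NucleiSet-class] from [segmentNuclei()].
#' @param neun_channel numeric matrix (`h x w`), same frame as the
#'   segmentation channel.
#' @param threshold `"otsu"` or a numeric intensity cutoff.
#' @return the [NucleiSet-class] with `neun_mean` and `neun_positive`
#'   columns filled in.
#' @export
classifyNeun <- function(nuclei, neun_channel, threshold = "otsu") {
  tab <- nuclei@table
  if (!nrow(tab)) {
    tab$neun_mean <- numeric(0)
    tab$neun_positive <- logical(0)
    nuclei@table <- tab
    return(nuclei)
  }
  lab <- nuclei@labels
  stopifnot(identical(dim(lab), dim(neun_channel)))
  means <- tapply(neun_channel[lab > 0], lab[lab > 0], mean)
  mvec <- rep(NA_real_, nrow(tab))
  mvec[as.integer(names(means))] <- as.numeric(means)
  if (identical(threshold, "otsu")) {
    threshold <- if (diff(range(mvec)) < 1e-6) Inf else
      EBImage::otsu(EBImage::Image(matrix(mvec, 1)), range = range(mvec))
  }
  tab$neun_mean <- mvec
  tab$neun_positive <- mvec > threshold
  nuclei@table <- tab
  nuclei
}

# pixel-grid distances from the site, in um; returns matrix h x w
.pixel_distances <- function(h, w, px_per_um, site) {
  px_x <- (seq_len(w) - 1) / px_per_um
  px_y <- (seq_len(h) - 1) / px_per_um
  sqrt(outer((px_y - site@y)^2, (px_x - site@x)^2, "+"))
}

#' Radial NeuN+ nuclei density profile
#'
#' Density per annulus = number of NeuN+ centroids in the annulus divided by
#' the annulus area, in nuclei per mm^2. The area is computed on the pixel
#' grid intersected with the tissue mask (not the analytic ring area), so
#' annuli clipped by the section edge are handled correctly. Zero-area bins
#' are reported as missing.
#'
#' @param nuclei a classified [NucleiSet-class].
#' @param site an [ImplantSite-class].
#' @param bin_width bin width in um; 100 um is the conventional bin size for
#'   neuronal density quantification.
#' @param max_radius outermost bin edge, um.
#' @param tissue_mask optional logical matrix (`h x w`) of tissue pixels;
#'   default: the whole frame.
#' @return a [RadialProfile-class] with units `nuclei/mm^2`.
#' @export
neuronalDensityProfile <- function(nuclei, site, bin_width = 100,
                                   max_radius = 1000, tissue_mask = NULL) {
  tab <- nuclei@table
  if (is.null(tab$neun_positive)) {
    stop("nuclei must be classified with classifyNeun() first")
  }
  h <- nrow(nuclei@labels); w <- ncol(nuclei@labels)
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, h, w)
  stopifnot(identical(dim(tissue_mask), c(h, w)))
  nb <- ceiling(max_radius / bin_width)
  edges <- seq(0, nb * bin_width, by = bin_width)
  dpix <- .pixel_distances(h, w, nuclei@pxPerUm, site)
  pix_bin <- .bin_index(dpix[tissue_mask], bin_width, edges[nb + 1])
  area_mm2 <- tabulate(pix_bin + 1L, nbins = nb) / nuclei@pxPerUm^2 / 1e6
  pos <- tab[tab$neun_positive %in% TRUE, ]
  dnuc <- sqrt((pos$x_um - site@x)^2 + (pos$y_um - site@y)^2)
  nuc_bin <- .bin_index(dnuc, bin_width, edges[nb + 1])
  n <- tabulate(nuc_bin + 1L, nbins = nb)
  stat <- ifelse(area_mm2 > 0, n / area_mm2, NA_real_)
  methods::new("RadialProfile", binEdges = edges, statistic = stat,
               n = as.numeric(n), center = site, label = "NeuN+ density",
               units = "nuclei/mm^2")
}

#' Radial within-section normalized GFAP intensity profile
#'
#' Per-annulus mean pixel intensity over tissue pixels, divided by the mean
#' intensity over all tissue pixels of the section (dimensionless; a
#' constant image gives 1 in every bin). The normalizer uses tissue pixels
#' only, so background outside the section does not dilute it. The
#' pixel-count-weighted mean of the profile over all bins covering the
#' tissue equals 1 by construction.
#'
#' @param channel numeric matrix (`h x w`) of GFAP intensities.
#' @param site an [ImplantSite-class].
#' @param px_per_um pixels per micrometre.
#' @param tissue_mask logical matrix of tissue pixels (default whole frame);
#'   must contain at least one pixel.
#' @param bin_width bin width in um; 10 um is the conventional bin size for
#'   GFAP intensity quantification.
#' @param max_radius outermost bin edge, um (`Inf` to cover the frame).
#' @return a [RadialProfile-class] with dimensionless units.
#' @export
gfapIntensityProfile <- function(channel, site, px_per_um,
                                 tissue_mask = NULL, bin_width = 10,
                                 max_radius = 1000) {
  h <- nrow(channel); w <- ncol(channel)
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, h, w)
  stopifnot(identical(dim(tissue_mask), c(h, w)))
  if (!any(tissue_mask)) stop("tissue mask is empty")
  norm <- mean(channel[tissue_mask])
  if (norm <= 0) stop("whole-section mean intensity must be > 0")
  dpix <- .pixel_distances(h, w, px_per_um, site)
  vals <- channel[tissue_mask] / norm
  d <- dpix[tissue_mask]
  if (!is.finite(max_radius)) max_radius <- max(d) + bin_width
  .make_profile(vals, d, bin_width, max_radius, site,
                label = "GFAP intensity", units = "fraction of section mean")
}
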