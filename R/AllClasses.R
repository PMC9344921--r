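#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SpatialStimSample: one Visium capture area with sample metadata
#'
#' Container for a single spatial transcriptomics capture area in the
#' electrode-implant experiments: a gene-by-spot count matrix (assay
#' `"counts"`), the spot geometry (array indices, physical coordinates in
#' micrometres, tissue and artifact flags, stored in `colData`), an optional
#' registered multi-channel section image, and sample-level metadata
#' (condition, timepoint, confidently-mapped read total).
#'
#' Coordinate convention, used everywhere in the package: array indices are
#' 0-based; physical coordinates are micrometres with the origin at the
#' capture-area top-left; `x_um` grows with `array_col`, `y_um` with
#' `array_row`. Physical coordinates are derived from pixel coordinates times
#' the micrometres-per-pixel scale factor, so distances work the same way on
#' real slides and synthetic ones.
#'
#' @slot image either `NULL` or a numeric array `h x w x channels` with
#'   intensities in `[0, 1]` (written to disk as 16-bit TIFF).
#' @slot mappedReads single number, the confidently-mapped read total used by
#'   depth equalization; always at least the matrix grand total.
#'
#' @seealso [SpatialStimSample()] for the constructor,
#'   [readSample()]/[writeSample()] for on-disk IO.
#' @export
setClass("SpatialStimSample",
  contains = "SummarizedExperiment",
  slots = c(image = "ANY", mappedReads = "numeric")
)

.validate_sample <- function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("array_row", "array_col", "x_um", "y_um", "in_tissue", "artifact")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bc <- colnames(object)
  if (is.null(bc) || anyDuplicated(bc)) {
    msg <- c(msg, "spot barcodes (colnames) must be present and unique")
  }
  if (all(c("x_um", "y_um") %in% colnames(cd)) &&
      (!all(is.finite(cd$x_um)) || !all(is.finite(cd$y_um)))) {
    msg <- c(msg, "spot coordinates must be finite")
  }
  if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    cts <- SummarizedExperiment::assay(object, "counts")
    v <- if (inherits(cts, "sparseMatrix")) cts@x else as.vector(cts)
    if (length(v) && (any(v < 0) || any(v != round(v)))) {
      msg <- c(msg, "counts must be non-negative integers")
    }
    if (length(object@mappedReads) != 1 || object@mappedReads < sum(cts)) {
      msg <- c(msg, "mappedReads must be a single value >= sum(counts)")
    }
  } else {
    msg <- c(msg, "assay 'counts' is required")
  }
  if (!is.null(object@image) && !(is.array(object@image) && length(dim(object@image)) == 3)) {
    msg <- c(msg, "image must be NULL or an h x w x channels array")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SpatialStimSample", .validate_sample)

#' Construct a SpatialStimSample
#'
#' @param counts gene-by-spot matrix of non-negative integer counts (dense or
#'   sparse); rownames are gene ids, colnames are spot barcodes.
#' @param spots `data.frame` of spot geometry with columns `barcode`,
#'   `array_row`, `array_col`, `x_um`, `y_um`, `in_tissue` and optionally
#'   `artifact` (defaults to `FALSE`). Order must cover the barcodes of
#'   `counts` (matched by barcode).
#' @param gene_symbols optional character vector of gene symbols parallel to
#'   `rownames(counts)`; defaults to the ids themselves.
#' @param sample_id,condition,timepoint sample-level labels; `condition` is
#'   free text such as `"craniotomy"`, `"acute_stim"`, `"mwa_stim"`,
#'   `"mwa_nostim"`, `"hdcf_stim"`; `timepoint` typically `"acute"` or
#'   `"chronic"`.
#' @param mapped_reads confidently-mapped read total; defaults to the matrix
#'   grand total (the convention used for synthetic data, where every read is
#'   a count).
#' @param microns_per_pixel scale factor relating full-resolution image pixels
#'   to micrometres.
#' @param spot_diameter_um physical spot diameter.
#' @param image optional `h x w x channels` numeric array in `[0, 1]`.
#' @return a [SpatialStimSample-class] object.
#' @examples
#' cts <- matrix(rpois(6, 3), 2, 3,
#'   dimnames = list(c("Gfap", "Ccl3"), c("b1", "b2", "b3")))
#' spots <- data.frame(barcode = c("b1", "b2", "b3"), array_row = 0L,
#'   array_col = 0:2, x_um = c(0, 100, 200), y_um = 0,
#'   in_tissue = TRUE)
#' s <- SpatialStimSample(cts, spots, sample_id = "demo",
#'   condition = "craniotomy", timepoint = "acute")
#' s
#' @export
SpatialStimSample <- function(counts, spots, gene_symbols = NULL,
                              sample_id = "sample", condition = NA_character_,
                              timepoint = NA_character_,
                              mapped_reads = sum(counts),
                              microns_per_pixel = 1,
                              spot_diameter_um = 55,
                              image = NULL) {
  counts <- methods::as(counts, "CsparseMatrix")
  spots <- as.data.frame(spots)
  if (is.null(spots$artifact)) spots$artifact <- FALSE
  if (anyDuplicated(spots$barcode)) {
    stop(errorCondition("duplicate spot barcodes in spot table",
                        class = c("stimspace_duplicate_barcode", "error", "condition")))
  }
  idx <- match(colnames(counts), spots$barcode)
  if (anyNA(idx)) {
    stop(errorCondition("count matrix barcodes missing from spot table",
                        class = c("stimspace_dim_mismatch", "error", "condition")))
  }
  spots <- spots[idx, , drop = FALSE]
  cd <- S4Vectors::DataFrame(
    array_row = as.integer(spots$array_row),
    array_col = as.integer(spots$array_col),
    x_um = as.numeric(spots$x_um), y_um = as.numeric(spots$y_um),
    in_tissue = as.logical(spots$in_tissue),
    artifact = as.logical(spots$artifact),
    row.names = spots$barcode
  )
  if (is.null(gene_symbols)) gene_symbols <- rownames(counts)
  rd <- S4Vectors::DataFrame(
    gene_id = rownames(counts), symbol = gene_symbols,
    type = rep("Gene Expression", nrow(counts)),
    row.names = rownames(counts)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd,
    metadata = list(sample_id = sample_id, condition = condition,
                    timepoint = timepoint,
                    microns_per_pixel = microns_per_pixel,
                    spot_diameter_um = spot_diameter_um)
  )
  methods::new("SpatialStimSample", se,
               image = image, mappedReads = as.numeric(mapped_reads))
}

#' Implant-site estimate for one capture area
#'
#' @slot x,y micrometre coordinates of the estimated electrode tract.
#' @slot method how the site was obtained: `"marker_centroid"` (weighted
#'   centroid of marker-gene expression), `"prior_only"` (marker mass below
#'   threshold; the stereotaxic prior is returned), or `"manual"`.
#' @slot markerMass summed normalized marker counts used as centroid weights.
#' @slot priorXY the stereotaxic expectation (e.g. 3.5 mm lateral of midline
#'   mapped into section coordinates).
#' @slot searchRadius micrometre radius around the prior searched for marker
#'   signal.
#' @export
setClass("ImplantSite", slots = c(
  x = "numeric", y = "numeric", method = "character",
  markerMass = "numeric", priorXY = "numeric", searchRadius = "numeric"
))

setValidity("ImplantSite", function(object) {
  if (length(object@x) != 1 || length(object@y) != 1 ||
      !is.finite(object@x) || !is.finite(object@y)) {
    return("x and y must be single finite values")
  }
  if (!object@method %in% c("marker_centroid", "prior_only", "manual")) {
    return("method must be marker_centroid, prior_only or manual")
  }
  TRUE
})

#' Radial distance-binned profile around an implant site
#'
#' Half-open annular bins `[a, b)` of distance from the implant site, each
#' carrying one statistic (mean normalized counts, nuclei density, or
#' normalized intensity) and the number of contributing units. Bins with no
#' contributing spots/pixels hold `NA`, never zero.
#'
#' @slot binEdges strictly increasing vector of bin edges in micrometres
#'   (length = number of bins + 1).
#' @slot statistic per-bin value; `NA` for empty bins.
#' @slot n per-bin number of contributing spots (or nuclei, or pixels).
#' @slot center the [ImplantSite-class] the distances are measured from.
#' @slot label what the statistic is (e.g. the gene symbol or channel name).
#' @slot units unit string for `statistic`.
#' @export
setClass("RadialProfile", slots = c(
  binEdges = "numeric", statistic = "numeric", n = "numeric",
  center = "ImplantSite", label = "character", units = "character"
))

setValidity("RadialProfile", function(object) {
  if (length(object@binEdges) < 2 || any(diff(object@binEdges) <= 0)) {
    return("binEdges must be strictly increasing, length >= 2")
  }
  nb <- length(object@binEdges) - 1
  if (length(object@statistic) != nb || length(object@n) != nb) {
    return("statistic and n must have one entry per bin")
  }
  TRUE
})

#' Differential-expression result table
#'
#' A `DataFrame` subclass with one row per gene and columns `gene_id`,
#' `symbol`, `mean_A`, `mean_B` (average normalized counts per cluster),
#' `lfc` (log2 fold change A over B, pseudocount applied), `p` (two-sided
#' negative-binomial exact test), `q` (Benjamini-Hochberg), `significant`
#' (raw `p < alpha` and `|lfc| > lfc_threshold`) and `low_count` (mean raw
#' reads per spot below one). Comparison-level information (label, cluster
#' sizes, thresholds, pseudocount) lives in `metadata()`.
#'
#' @seealso [runComparison()]
#' @export
setClass("DEResult", contains = "DFrame")

#' Segmented nuclei from a fluorescence section image
#'
#' @slot table `data.frame` with one row per nucleus: centroid `x_um`,
#'   `y_um`, `area_um2`, and after [classifyNeun()] the per-nucleus mean NeuN
#'   intensity `neun_mean` and logical `neun_positive`.
#' @slot labels integer label matrix (`h x w`) from connected components; 0 is
#'   background, values index rows of `table`.
#' @slot pxPerUm pixels per micrometre of the source image.
#' @export
setClass("NucleiSet", slots = c(
  table = "data.frame", labels = "matrix", pxPerUm = "numeric"
))

#' Stimulation protocol description
#'
#' A biphasic current-controlled pulse train. Amplitude, per-phase width and
#' frequency must be strictly positive.
#'
#' @slot amplitude current amplitude in microamperes.
#' @slot pulseWidth per-phase pulse width in microseconds.
#' @slot interphaseGap interphase gap in microseconds.
#' @slot frequency pulse rate in hertz.
#' @slot waveform waveform label, e.g. `"cathodic_first_biphasic"`.
#' @slot duration stimulation duration in seconds (`NA` if open-ended).
#' @export
setClass("StimProtocol", slots = c(
  amplitude = "numeric", pulseWidth = "numeric", interphaseGap = "numeric",
  frequency = "numeric", waveform = "character", duration = "numeric"
))

setValidity("StimProtocol", function(object) {
  if (object@amplitude <= 0) return("amplitude must be > 0")
  if (object@pulseWidth <= 0) return("pulse width must be > 0")
  if (object@frequency <= 0) return("frequency must be > 0")
  if (object@interphaseGap < 0) return("interphase gap must be >= 0")
  TRUE
})

#' Electrode geometry with derived geometric surface area
#'
#' Geometric (not electrochemically effective) area, matching how charge
#' density limits are stated for microelectrodes. Supported kinds:
#' `"disk"` (area pi r^2), `"cylinder_tip"` (lateral area pi d L plus the
#' end disk), `"cone_tip"` (lateral area pi r * slant length), and
#' `"explicit_area"`.
#'
#' @slot kind geometry kind.
#' @slot diameter electrode diameter in micrometres (`NA` for explicit area).
#' @slot exposedLength exposed/deinsulated length in micrometres.
#' @slot area derived geometric area in square micrometres.
#' @export
setClass("ElectrodeGeometry", slots = c(
  kind = "character", diameter = "numeric", exposedLength = "numeric",
  area = "numeric"
))

setValidity("ElectrodeGeometry", function(object) {
  if (!is.finite(object@area) || object@area <= 0) return("derived area must be > 0")
  TRUE
})

#' Stimulation safety report
#'
#' Derived charge per phase, charge density over the electrode's geometric
#' area, the Shannon parameter k, and rule-of-thumb classifications.
#'
#' @slot chargePerPhase nanocoulombs per phase.
#' @slot chargeDensity millicoulombs per square centimetre.
#' @slot shannonK dimensionless Shannon k = log10(density in uC/cm^2) +
#'   log10(charge in uC).
#' @slot aboveShannon logical, k strictly above the configured k limit.
#' @slot aboveCogan4nC logical, charge per phase strictly above 4 nC.
#' @slot kLimit the k limit used for classification.
#' @export
setClass("SafetyReport", slots = c(
  chargePerPhase = "numeric", chargeDensity = "numeric", shannonK = "numeric",
  aboveShannon = "logical", aboveCogan4nC = "logical", kLimit = "numeric"
))
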