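#' Accessors for SpatialStimSample objects
#'
#' `spotPositions()` returns the spot geometry as a `data.frame` (barcode,
#' array indices, micrometre coordinates, tissue and artifact flags);
#' `spotCounts()` the sparse count matrix; `sectionImage()` the registered
#' multi-channel image or `NULL`; `mappedReads()` the confidently-mapped read
#' total; `sampleId()`, `sampleCondition()`, `timePoint()` and
#' `micronsPerPixel()` the sample-level metadata.
#'
#' @param x a [SpatialStimSample-class].
#' @param value replacement value.
#' @param ... unused.
#' @return see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("spotPositions", "SpatialStimSample", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(
    barcode = rownames(cd),
    array_row = cd$array_row, array_col = cd$array_col,
    x_um = cd$x_um, y_um = cd$y_um,
    in_tissue = cd$in_tissue, artifact = cd$artifact,
    row.names = NULL
  )
})

#' @rdname accessors
#' @export
setMethod("spotCounts", "SpatialStimSample", function(x) {
  SummarizedExperiment::assay(x, "counts")
})

#' @rdname accessors
#' @export
setMethod("sectionImage", "SpatialStimSample", function(x) x@image)

#' @rdname accessors
#' @export
setMethod("sectionImage<-", "SpatialStimSample", function(x, value) {
  x@image <- value
  methods::validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("mappedReads", "SpatialStimSample", function(x) x@mappedReads)

#' @rdname accessors
#' @export
setMethod("mappedReads<-", "SpatialStimSample", function(x, value) {
  x@mappedReads <- as.numeric(value)
  methods::validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("sampleId", "SpatialStimSample", function(x) metadata(x)$sample_id)

#' @rdname accessors
#' @export
setMethod("sampleCondition", "SpatialStimSample", function(x) metadata(x)$condition)

#' @rdname accessors
#' @export
setMethod("timePoint", "SpatialStimSample", function(x) metadata(x)$timepoint)

#' @rdname accessors
#' @export
setMethod("micronsPerPixel", "SpatialStimSample", function(x) {
  metadata(x)$microns_per_pixel
})

#' @export
setMethod("show", "SpatialStimSample", function(object) {
  cat("SpatialStimSample:", sampleId(object), "\n")
  cat("  ", nrow(object), "genes x", ncol(object), "spots;",
      sum(SummarizedExperiment::colData(object)$in_tissue), "in tissue,",
      sum(SummarizedExperiment::colData(object)$artifact), "under artifacts\n")
  cat("  condition:", sampleCondition(object),
      " timepoint:", timePoint(object), "\n")
  cat("  mapped reads:", format(mappedReads(object), big.mark = ","),
      " image:", if (is.null(object@image)) "none" else
        paste(dim(object@image), collapse = " x "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "ImplantSite", function(object) {
  cat(sprintf("ImplantSite (%.1f, %.1f) um, method=%s, marker mass=%.3g\n",
              object@x, object@y, object@method, object@markerMass))
  invisible(NULL)
})

#' @export
setMethod("show", "RadialProfile", function(object) {
  nb <- length(object@binEdges) - 1
  cat(sprintf("RadialProfile '%s': %d bins of [%g, %g) um, units: %s\n",
              object@label, nb, object@binEdges[1],
              object@binEdges[2], object@units))
  invisible(NULL)
})

#' @export
setMethod("show", "SafetyReport", function(object) {
  cat(sprintf(
    "SafetyReport: Q = %g nC/phase, D = %g mC/cm^2, Shannon k = %.3f\n",
    object@chargePerPhase, object@chargeDensity, object@shannonK))
  cat(sprintf("  above 4 nC rule: %s;  above Shannon k = %g: %s\n",
              object@aboveCogan4nC, object@kLimit, object@aboveShannon))
  invisible(NULL)
})

#' Convert a RadialProfile (or list of them) to a tidy table
#'
#' Lossless serialization of radial profiles: one row per bin with the bin
#' edges, midpoint, statistic, number of contributing units, profile label
#' and units. A list of profiles is row-bound; the row count equals the total
#' number of bins.
#'
#' @param x a [RadialProfile-class] or a list of them.
#' @param ... unused.
#' @return a `data.frame` with columns `label`, `bin`, `bin_lo_um`,
#'   `bin_hi_um`, `bin_mid_um`, `statistic`, `n`, `units`.
#' @export
#' @name profileToTable
setMethod("profileToTable", "RadialProfile", function(x, ...) {
  nb <- length(x@binEdges) - 1
  data.frame(
    label = rep(x@label, nb), bin = seq_len(nb) - 1L,
    bin_lo_um = x@binEdges[-(nb + 1)], bin_hi_um = x@binEdges[-1],
    bin_mid_um = (x@binEdges[-(nb + 1)] + x@binEdges[-1]) / 2,
    statistic = x@statistic, n = x@n, units = rep(x@units, nb),
    row.names = NULL
  )
})

#' @rdname profileToTable
#' @export
setMethod("profileToTable", "list", function(x, ...) {
  if (!length(x)) {
    return(data.frame(label = character(0), bin = integer(0),
                      bin_lo_um = numeric(0), bin_hi_um = numeric(0),
                      bin_mid_um = numeric(0), statistic = numeric(0),
                      n = numeric(0), units = character(0)))
  }
  out <- do.call(rbind, lapply(seq_along(x), function(i) {
    tab <- profileToTable(x[[i]])
    if (!is.null(names(x))) tab$label <- paste(names(x)[i], tab$label)
    tab
  }))
  rownames(out) <- NULL
  out
})

#' @rdname profileToTable
#' @export
setMethod("as.data.frame", "RadialProfile", function(x, ...) profileToTable(x))
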