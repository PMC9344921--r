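#' Depth-equalizing aggregation across samples
#'
#' Mirrors the aggregation step of multi-sample spatial analyses: sequencing
#' depth differs between capture areas, so deeper samples are down-sampled
#' to the depth of the shallowest one before any cross-sample comparison.
#' The thinning rate for sample `s` is `r_s = min(mapped) / mapped_s`; each
#' count is replaced by an independent `Binomial(count, r_s)` draw. The
#' shallowest sample (`r = 1`) is returned unchanged, bit-exact. Working at
#' the UMI-count level (rather than raw reads) is the count-level analogue
#' of read subsampling.
#'
#' Zero counts stay zero and no count ever increases; expected
#' post-aggregation totals are equal across samples.
#'
#' @param samples list of [SpatialStimSample-class] (>= 2), each with a
#'   positive mapped-read total.
#' @param seed integer seed for the binomial draws.
#' @return list of samples with thinned counts; each thinned sample's
#'   mapped-read total is set to `floor(mapped_s * r_s)` (= the reference
#'   total).
#' @examples
#' # totals [1000, 500] give rates [0.5, 1]; the shallow sample passes through
#' @export
aggregateSamples <- function(samples, seed = 1L) {
  stopifnot(length(samples) >= 2)
  mapped <- vapply(samples, mappedReads, numeric(1))
  if (any(mapped <= 0)) stop("every sample needs mapped_reads_total > 0")
  rates <- min(mapped) / mapped
  set.seed(seed)
  out <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    x <- samples[[s]]
    if (rates[s] < 1) {
      cts <- spotCounts(x)
      cts@x <- as.numeric(stats::rbinom(length(cts@x), size = as.integer(cts@x),
                                        prob = rates[s]))
      cts <- Matrix::drop0(cts)
      SummarizedExperiment::assay(x, "counts") <- cts
      # reference depth; the binomial draw can overshoot it by a few counts
      mappedReads(x) <- max(floor(mapped[s] * rates[s]), sum(cts))
    }
    out[[s]] <- x
  }
  names(out) <- names(samples)
  out
}

#' Aggregation plan: per-sample thinning rates
#'
#' @param samples list of [SpatialStimSample-class].
#' @return `data.frame` with `sample_id`, `mapped_reads`, `rate`
#'   (`min(mapped)/mapped`, so the shallowest sample has rate 1).
#' @export
aggregationPlan <- function(samples) {
  mapped <- vapply(samples, mappedReads, numeric(1))
  if (any(mapped <= 0)) stop("every sample needs mapped_reads_total > 0")
  data.frame(
    sample_id = vapply(samples, sampleId, character(1)),
    mapped_reads = mapped, rate = min(mapped) / mapped
  )
}

#' Spot inclusion filter
#'
#' `filterSpots()` returns the logical inclusion vector — a spot is included
#' exactly when it has tissue over it and is not under a cryosectioning
#' artifact (roll, fold or bubble). `includedSpots()` returns the barcodes.
#' Both are deterministic and idempotent.
#'
#' @param x a [SpatialStimSample-class].
#' @param ... unused.
#' @return `filterSpots()`: named logical vector over spots;
#'   `includedSpots()`: character vector of included barcodes.
#' @name filterSpots
NULL

#' @rdname filterSpots
#' @export
setMethod("filterSpots", "SpatialStimSample", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(cd$in_tissue & !cd$artifact, rownames(cd))
})

#' @rdname filterSpots
#' @export
setMethod("includedSpots", "SpatialStimSample", function(x, ...) {
  names(which(filterSpots(x)))
})

#' Per-spot size factors and normalized counts
#'
#' The size factor of spot `i` is its total count divided by the average
#' total over all spots entering the comparison:
#' `sf_i = T_i / mean(T_j)`; normalized counts are `n[g, i] = c[g, i] /
#' sf_i`. By construction `mean(sf) = 1` over the spots used. Size factors
#' are therefore comparison-specific: they are recomputed over exactly the
#' spots of each comparison, never globally.
#'
#' Spots with zero total have no defined size factor; they are dropped with
#' a warning rather than given `sf = 0`.
#'
#' @param counts gene x spot count matrix (dense or sparse).
#' @param spots optional character vector of spot barcodes (columns) to use;
#'   default all columns.
#' @return list with `normalized` (gene x spot matrix over the retained
#'   spots), `size_factors` (named, mean exactly 1), and `dropped`
#'   (barcodes excluded for zero totals).
#' @examples
#' m <- matrix(c(90, 10, 250, 50), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' sizeFactorNormalize(m)$size_factors  # totals 100, 300 -> 0.5, 1.5
#' @export
sizeFactorNormalize <- function(counts, spots = NULL) {
  if (!is.null(spots)) counts <- counts[, spots, drop = FALSE]
  tot <- Matrix::colSums(counts)
  nz <- tot > 0
  if (!any(nz)) stop("all spot totals are zero; size factors undefined")
  if (any(!nz)) {
    warning(sum(!nz), " spot(s) with zero total excluded from normalization")
  }
  counts <- counts[, nz, drop = FALSE]
  tot <- tot[nz]
  sf <- tot / mean(tot)
  normalized <- sweep_cols_sparse(counts, 1 / sf)
  list(normalized = normalized, size_factors = sf,
       dropped = names(nz)[!nz])
}

# column-scale a (possibly sparse) matrix without densifying
sweep_cols_sparse <- function(m, scale) {
  if (inherits(m, "CsparseMatrix")) {
    m@x <- m@x * rep.int(scale, diff(m@p))
    m
  } else {
    sweep(m, 2, scale, "*")
  }
}
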