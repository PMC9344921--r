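#' Read a GMT gene-set collection
#'
#' Thin wrapper over `fgsea::gmtPathways()`: one set per line, tab-separated
#' `name`, `description`, genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (gene symbols).
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis of a DE gene list
#'
#' Fixed-threshold over-representation analysis: for each set, the
#' upper-tail hypergeometric probability of drawing at least the observed
#' overlap `x` when `n` genes are sampled without replacement from a
#' universe of `N` genes containing `K` set members:
#' `p = sum_{k >= x} C(K, k) C(N - K, n - k) / C(N, n)`.
#' The universe should be the genes measured in the comparison that produced
#' the DE list, not the whole annotation. This is the scriptable equivalent
#' of threshold-based GO enrichment tools; ranked-list
#' (minimum-hypergeometric) algorithms are deliberately not implemented.
#'
#' DE genes outside the universe are dropped (count reported in the
#' `dropped_de_genes` attribute); set genes are intersected with the
#' universe; sets empty after intersection are removed.
#'
#' @param de_genes character vector of significant DE gene symbols.
#' @param collection named list of gene sets (see [readGMT()]).
#' @param universe character vector of background genes.
#' @param alpha BH-adjusted significance level for the `enriched` flag.
#' @return `data.frame` with one row per set: `set_name`, `x` (overlap),
#'   `K` (set size in universe), `n` (DE list size in universe), `N`
#'   (universe size), `p`, `q` (BH), `enriched`, `genes_in_overlap`;
#'   sorted by p.
#' @examples
#' hypergeomEnrich(letters[1:5], list(s = letters[1:5]), letters[1:10])
#' # overlap 5 of 5 from a 10-gene universe: p = 1/choose(10, 5)
#' @export
hypergeomEnrich <- function(de_genes, collection, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  n_drop <- sum(!de_genes %in% universe)
  de <- unique(de_genes[de_genes %in% universe])
  if (!length(de)) stop("empty DE list after intersecting with universe")
  sets <- lapply(collection, function(g) unique(g[g %in% universe]))
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  N <- length(universe)
  n <- length(de)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    ov <- intersect(de, sets[[nm]])
    x <- length(ov)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, x = x, K = K, n = n, N = N, p = min(p, 1),
               genes_in_overlap = paste(ov, collapse = ";"))
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, "BH")
  res$enriched <- res$q < alpha
  res <- res[order(res$p), c("set_name", "x", "K", "n", "N", "p", "q",
                             "enriched", "genes_in_overlap")]
  rownames(res) <- NULL
  attr(res, "dropped_de_genes") <- n_drop
  res
}

#' Per-spot mean expression of a gene module
#'
#' Mean normalized counts over the present genes of a set, per spot — used
#' to map the spatial footprint of an enriched process (e.g. a cell-cycle
#' module) and feed [radialGeneProfile()].
#'
#' @param x a [SpatialStimSample-class].
#' @param gene_set character vector of gene ids; at least one must be
#'   present in the sample.
#' @return named numeric vector over included spots (spots dropped by
#'   normalization get `NA`).
#' @export
moduleMeanExpression <- function(x, gene_set) {
  present <- intersect(gene_set, rownames(x))
  if (!length(present)) stop("no genes of the set are present in the sample")
  inc <- includedSpots(x)
  nm <- sizeFactorNormalize(spotCounts(x), inc)
  v <- Matrix::colMeans(nm$normalized[present, , drop = FALSE])
  out <- stats::setNames(rep(NA_real_, length(inc)), inc)
  out[names(v)] <- v
  out
}
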