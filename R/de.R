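#' Log2 fold change between cluster means
#'
#' `lfc = log2((mean_A + c) / (mean_B + c))` with pseudocount `c > 0`
#' (default 1 normalized count). The pseudocount keeps the LFC finite for
#' genes expressed in only one cluster — e.g. an inflammatory chemokine
#' absent from a craniotomy control still gets a finite, large LFC.
#' Antisymmetric under swapping the clusters.
#'
#' @param mean_a,mean_b average normalized counts per cluster (vectors
#'   allowed); must be non-negative.
#' @param pseudocount positive pseudocount.
#' @return log2 fold change(s).
#' @examples
#' logFoldChange(3, 1)      # 1
#' logFoldChange(8.06, 0)   # ~3.18, finite despite a zero mean
#' @export
logFoldChange <- function(mean_a, mean_b, pseudocount = 1) {
  if (any(mean_a < 0) || any(mean_b < 0)) stop("means must be non-negative")
  stopifnot(pseudocount > 0)
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Method-of-moments dispersion with shrinkage
#'
#' Per-gene negative-binomial dispersion estimated on normalized counts by
#' the method of moments, `phi_g = max(0, (s2_g - mu_g) / mu_g^2)`, then
#' shrunk toward the across-gene mean dispersion:
#' `phi_shrunk = (1 - w) * phi_g + w * mean(phi)`. When `groups` is given,
#' moments are taken within each group (residuals about the group mean) and
#' pooled, so a true expression difference between clusters does not inflate
#' the dispersion.
#'
#' @param counts gene x spot raw count matrix.
#' @param size_factors per-spot size factors (defaults to all 1).
#' @param groups optional factor/vector over spots; moments pooled within
#'   groups.
#' @param shrink shrinkage weight `w` in `[0, 1]` toward the common value.
#' @return named numeric vector of dispersions (`>= 0`).
#' @export
estimateDispersion <- function(counts, size_factors = NULL, groups = NULL,
                               shrink = 0.5) {
  stopifnot(shrink >= 0, shrink <= 1)
  if (ncol(counts) < 2) stop("need at least 2 spots to estimate dispersion")
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  norm <- sweep_cols_sparse(counts, 1 / size_factors)
  norm <- as.matrix(norm)
  if (is.null(groups)) groups <- rep(1L, ncol(counts))
  groups <- as.factor(groups)
  mu_all <- rowMeans(norm)
  ss <- rep(0, nrow(norm))
  df <- 0
  for (g in levels(groups)) {
    cols <- groups == g
    if (sum(cols) < 2) next
    sub <- norm[, cols, drop = FALSE]
    mu_g <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu_g)^2)
    df <- df + sum(cols) - 1
  }
  if (df == 0) stop("no group has >= 2 spots")
  s2 <- ss / df
  raw <- ifelse(mu_all > 0, pmax(0, (s2 - mu_all) / mu_all^2), 0)
  shrunk <- (1 - shrink) * raw + shrink * mean(raw)
  stats::setNames(pmax(shrunk, 0), rownames(counts))
}

#' Two-sided negative-binomial exact test for two spot clusters
#'
#' Conditional exact test on the cluster count sums. With per-spot size
#' factors `s_i`, the sum of cluster `g` is modelled as negative binomial
#' with mean `q * S_g` (where `S_g = sum(s_i)` and `q` is the common
#' per-unit-size expression fitted from the pooled data) and effective
#' dispersion `phi * sum(s_i^2) / S_g^2` — the dispersion of a sum of
#' independent NB counts. Conditioning on the total, the two-sided p-value
#' sums the probabilities of all splits at most as likely as the observed
#' one. With `phi = 0` and equal size factors this reduces to the
#' conditional binomial (two-sample Poisson) exact test.
#'
#' @param counts_a,counts_b raw counts of one gene over the spots of
#'   clusters A and B.
#' @param sf_a,sf_b matching size factors (default 1).
#' @param phi negative-binomial dispersion (`>= 0`; 0 = Poisson).
#' @return two-sided p-value in `(0, 1]`.
#' @examples
#' nbExactTest(10, 0)  # = 2 * (1/2)^10 ~ 0.00195, the binomial answer
#' @export
nbExactTest <- function(counts_a, counts_b, sf_a = NULL, sf_b = NULL,
                        phi = 0) {
  stopifnot(phi >= 0, length(counts_a) >= 1, length(counts_b) >= 1)
  if (is.null(sf_a)) sf_a <- rep(1, length(counts_a))
  if (is.null(sf_b)) sf_b <- rep(1, length(counts_b))
  ka <- sum(counts_a); kb <- sum(counts_b)
  ks <- ka + kb
  if (ks == 0) return(1)
  sa <- sum(sf_a); sb <- sum(sf_b)
  q <- ks / (sa + sb)
  mu_a <- q * sa; mu_b <- q * sb
  a <- 0:ks
  if (phi > 0) {
    size_a <- sa^2 / (phi * sum(sf_a^2))
    size_b <- sb^2 / (phi * sum(sf_b^2))
    logw <- stats::dnbinom(a, mu = mu_a, size = size_a, log = TRUE) +
      stats::dnbinom(ks - a, mu = mu_b, size = size_b, log = TRUE)
  } else {
    logw <- stats::dpois(a, mu_a, log = TRUE) +
      stats::dpois(ks - a, mu_b, log = TRUE)
  }
  m <- max(logw)
  w <- exp(logw - m)
  obs <- w[ka + 1]
  p <- sum(w[w <= obs * (1 + 1e-8)]) / sum(w)
  min(max(p, .Machine$double.xmin), 1)
}

#' Specify a cluster-vs-cluster comparison
#'
#' A cluster is a set of `(sample_id, barcode)` pairs. Clusters must be
#' disjoint and non-empty, and every member must pass the spot filter
#' ([filterSpots()]) of its sample.
#'
#' @param cluster_a,cluster_b `data.frame`s with columns `sample_id` and
#'   `barcode`.
#' @param label human-readable label, e.g. `"acute_stim vs craniotomy"`.
#' @param low_count_included keep genes averaging under one read per spot
#'   (flagged `low_count` in the result). Implant effects are spatially
#'   confined, so such genes are retained by default.
#' @return list of class `"comparisonSpec"`.
#' @export
comparisonSpec <- function(cluster_a, cluster_b, label = "A vs B",
                           low_count_included = TRUE) {
  stopifnot(nrow(cluster_a) >= 1, nrow(cluster_b) >= 1,
            all(c("sample_id", "barcode") %in% colnames(cluster_a)),
            all(c("sample_id", "barcode") %in% colnames(cluster_b)))
  key_a <- paste(cluster_a$sample_id, cluster_a$barcode)
  key_b <- paste(cluster_b$sample_id, cluster_b$barcode)
  if (length(intersect(key_a, key_b))) {
    stop("clusters must be disjoint")
  }
  structure(list(cluster_a = cluster_a, cluster_b = cluster_b,
                 label = label, low_count_included = low_count_included),
            class = "comparisonSpec")
}

#' Whole-section cluster helper
#'
#' Builds the `(sample_id, barcode)` table of all included spots of the
#' given samples — the whole-tissue-section clusters used when no localized
#' marker signal is available to subset spots.
#'
#' @param samples list of [SpatialStimSample-class].
#' @return `data.frame` with `sample_id`, `barcode`.
#' @export
wholeSectionCluster <- function(samples) {
  if (inherits(samples, "SpatialStimSample")) samples <- list(samples)
  do.call(rbind, lapply(samples, function(s) {
    bc <- includedSpots(s)
    if (!length(bc)) return(NULL)
    data.frame(sample_id = sampleId(s), barcode = bc)
  }))
}

#' Run a cluster-vs-cluster differential expression comparison
#'
#' The full DE chain on (already depth-aggregated) samples: size factors are
#' computed over exactly the spots of this comparison; per-cluster average
#' normalized counts give the log2 fold change (pseudocount applied); the
#' per-gene p-value comes from the negative-binomial exact test with
#' moment-based, shrunk dispersions ([estimateDispersion()]); significance
#' uses the raw-p-and-LFC rule `p < alpha` and `|lfc| > lfc_threshold`
#' (defaults 0.05 and 0.6). Benjamini-Hochberg q-values are reported
#' alongside but do not enter the significance flag. Genes with zero counts
#' in both clusters get `lfc = 0`, `p = 1` and are never called significant.
#' Genes averaging under one raw read per spot are flagged `low_count` (and
#' dropped when `low_count_included` is `FALSE`).
#'
#' @param spec a [comparisonSpec()].
#' @param samples named list of [SpatialStimSample-class] (names or
#'   `sampleId`s must cover the spec's `sample_id`s); all samples must share
#'   the same gene list.
#' @param pseudocount LFC pseudocount (normalized counts).
#' @param alpha raw p-value threshold for the significance flag.
#' @param lfc_threshold minimum `|lfc|` for the significance flag.
#' @param shrink dispersion shrinkage weight, see [estimateDispersion()].
#' @param test `"nb_exact"` (default) or `"welch"`, a Welch t-test on
#'   log1p-normalized counts offered as a cross-check.
#' @return a [DEResult-class] sorted by p-value.
#' @export
runComparison <- function(spec, samples, pseudocount = 1, alpha = 0.05,
                          lfc_threshold = 0.6, shrink = 0.5,
                          test = c("nb_exact", "welch")) {
  stopifnot(inherits(spec, "comparisonSpec"))
  test <- match.arg(test)
  if (inherits(samples, "SpatialStimSample")) samples <- list(samples)
  ids <- vapply(samples, sampleId, character(1))
  if (is.null(names(samples))) names(samples) <- ids

  pull <- function(cluster) {
    parts <- lapply(split(cluster, cluster$sample_id), function(cl) {
      sid <- cl$sample_id[1]
      s <- samples[[sid]] %||% samples[[match(sid, ids)]]
      if (is.null(s)) stop("sample not provided: ", sid)
      ok <- filterSpots(s)[cl$barcode]
      if (anyNA(ok) || !all(ok)) {
        stop("cluster contains unknown or filtered-out spots in sample ", sid)
      }
      cts <- spotCounts(s)[, cl$barcode, drop = FALSE]
      colnames(cts) <- paste(sid, cl$barcode)
      cts
    })
    genes <- rownames(parts[[1]])
    for (p in parts) {
      if (!identical(rownames(p), genes)) {
        stop("samples must share an identical gene list")
      }
    }
    do.call(cbind, parts)
  }
  cts_a <- pull(spec$cluster_a)
  cts_b <- pull(spec$cluster_b)
  if (ncol(cts_a) == 0 || ncol(cts_b) == 0) {
    stop("empty cluster after filtering")
  }
  all_cts <- cbind(cts_a, cts_b)
  grp <- rep(c("A", "B"), c(ncol(cts_a), ncol(cts_b)))

  nm <- sizeFactorNormalize(all_cts)
  keep <- colnames(nm$normalized)
  grp <- grp[match(keep, colnames(all_cts))]
  norm <- as.matrix(nm$normalized)
  raw <- as.matrix(all_cts[, keep, drop = FALSE])
  sf <- nm$size_factors

  mean_a <- rowMeans(norm[, grp == "A", drop = FALSE])
  mean_b <- rowMeans(norm[, grp == "B", drop = FALSE])
  lfc <- logFoldChange(mean_a, mean_b, pseudocount)
  both_zero <- rowSums(raw) == 0
  lfc[both_zero] <- 0

  phi <- estimateDispersion(raw, sf, groups = grp, shrink = shrink)
  p <- numeric(nrow(raw))
  if (test == "nb_exact") {
    ia <- grp == "A"; ib <- grp == "B"
    for (g in seq_len(nrow(raw))) {
      p[g] <- nbExactTest(raw[g, ia], raw[g, ib], sf[ia], sf[ib], phi[g])
    }
  } else {
    la <- log1p(norm[, grp == "A", drop = FALSE])
    lb <- log1p(norm[, grp == "B", drop = FALSE])
    for (g in seq_len(nrow(raw))) {
      p[g] <- if (stats::sd(la[g, ]) == 0 && stats::sd(lb[g, ]) == 0) 1 else
        stats::t.test(la[g, ], lb[g, ])$p.value
    }
  }
  p[both_zero] <- 1
  q <- stats::p.adjust(p, "BH")
  low_count <- rowMeans(raw) < 1
  significant <- p < alpha & abs(lfc) > lfc_threshold & !both_zero

  res <- S4Vectors::DataFrame(
    gene_id = rownames(raw), symbol = rownames(raw),
    mean_A = unname(mean_a), mean_B = unname(mean_b), lfc = unname(lfc),
    p = p, q = q, significant = unname(significant),
    low_count = unname(low_count),
    row.names = rownames(raw)
  )
  if (!spec$low_count_included) res <- res[!res$low_count, ]
  res <- res[order(res$p, -abs(res$lfc)), ]
  res <- methods::new("DEResult", res)
  metadata(res) <- list(label = spec$label, n_a = sum(grp == "A"),
                        n_b = sum(grp == "B"), alpha = alpha,
                        lfc_threshold = lfc_threshold,
                        pseudocount = pseudocount, test = test,
                        dropped_spots = nm$dropped)
  res
}
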