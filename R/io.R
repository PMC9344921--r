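#' Write a sample in the SpaceRanger-style on-disk dialect
#'
#' Emits, under `dir_path`: `matrix.mtx` (MatrixMarket integer, genes x
#' spots), `features.tsv` (id, symbol, type; no header), `barcodes.tsv`,
#' `tissue_positions.csv` (header `barcode,in_tissue,array_row,array_col,
#' pxl_row,pxl_col`; pixel coordinates are micrometres divided by the scale
#' factor, full precision), `scalefactors_json.json` (key/value; carries
#' `microns_per_pixel`, `spot_diameter_um`, and — since the dialect has no
#' other metadata file — the sample id, condition, timepoint and mapped-read
#' total), optionally `image.tiff` (16-bit multi-channel) and
#' `artifacts.csv` (artifact polygons, if stored in
#' `metadata(x)$artifact_polygons`).
#'
#' @param x a [SpatialStimSample-class].
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @seealso [readSample()]; a write/read round trip reproduces all fields
#'   used downstream, counts bit-exactly.
#' @export
writeSample <- function(x, dir_path) {
  if (!dir.exists(dir_path) &&
      !dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", dir_path)
  }
  cts <- spotCounts(x)
  # MatrixMarket *integer* coordinate, which Matrix::writeMM cannot emit;
  # entries in column-major order so repeated writes are byte-identical
  tm <- methods::as(methods::as(cts, "CsparseMatrix"), "TsparseMatrix")
  con <- file(file.path(dir_path, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(cts), ncol(cts), length(tm@x))), con)
  if (length(tm@x)) {
    writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
  }
  close(con)
  rd <- SummarizedExperiment::rowData(x)
  utils::write.table(
    data.frame(rd$gene_id, rd$symbol, rd$type),
    file.path(dir_path, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  writeLines(colnames(x), file.path(dir_path, "barcodes.tsv"))
  sp <- spotPositions(x)
  upp <- micronsPerPixel(x)
  pos <- data.frame(
    barcode = sp$barcode, in_tissue = as.integer(sp$in_tissue),
    array_row = sp$array_row, array_col = sp$array_col,
    pxl_row = sp$y_um / upp, pxl_col = sp$x_um / upp
  )
  utils::write.csv(pos, file.path(dir_path, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  sf <- list(
    microns_per_pixel = upp,
    spot_diameter_um = metadata(x)$spot_diameter_um,
    sample_id = sampleId(x), condition = sampleCondition(x),
    timepoint = timePoint(x), mapped_reads_total = mappedReads(x)
  )
  jsonlite::write_json(sf, file.path(dir_path, "scalefactors_json.json"),
                       auto_unbox = TRUE, digits = NA)
  polys <- metadata(x)$artifact_polygons
  if (!is.null(polys)) {
    utils::write.csv(polys, file.path(dir_path, "artifacts.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  img <- sectionImage(x)
  if (!is.null(img)) {
    tiff::writeTIFF(img, file.path(dir_path, "image.tiff"),
                    bits.per.sample = 16L)
  }
  invisible(dir_path)
}

.require_file <- function(dir_path, name) {
  p <- file.path(dir_path, name)
  if (!file.exists(p)) {
    stop(errorCondition(paste0("required file missing: ", p),
                        class = c("stimspace_missing_file", "error", "condition")))
  }
  p
}

#' Read a SpaceRanger-style sample directory
#'
#' Reads the dialect written by [writeSample()] (and by the synthetic data
#' generator): `matrix.mtx`, `features.tsv`, `barcodes.tsv`,
#' `tissue_positions.csv`, `scalefactors_json.json`, plus `image.tiff` and
#' `artifacts.csv` if present. Pixel coordinates are converted to
#' micrometres with the scale factor. If an artifact polygon sidecar is
#' present, spots whose centre falls inside any polygon are flagged
#' `artifact = TRUE` (see [markArtifacts()]).
#'
#' Validation failures raise distinct classed errors:
#' `stimspace_missing_file`, `stimspace_dim_mismatch`,
#' `stimspace_duplicate_barcode`, `stimspace_negative_count`.
#'
#' @param dir_path directory containing the files above.
#' @return a [SpatialStimSample-class].
#' @export
readSample <- function(dir_path) {
  mtx_p <- .require_file(dir_path, "matrix.mtx")
  feat_p <- .require_file(dir_path, "features.tsv")
  bc_p <- .require_file(dir_path, "barcodes.tsv")
  pos_p <- .require_file(dir_path, "tissue_positions.csv")
  sf_p <- .require_file(dir_path, "scalefactors_json.json")

  m <- Matrix::readMM(mtx_p)
  if (length(m@x) && any(m@x < 0)) {
    tm <- methods::as(m, "TsparseMatrix")
    neg <- which(tm@x < 0)[1]
    stop(errorCondition(
      sprintf("negative count at matrix cell (gene %d, spot %d)",
              tm@i[neg] + 1L, tm@j[neg] + 1L),
      class = c("stimspace_negative_count", "error", "condition")))
  }
  feats <- if (file.size(feat_p) == 0) {
    data.frame(V1 = character(0), V2 = character(0), V3 = character(0))
  } else {
    utils::read.table(feat_p, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "")
  }
  barcodes <- readLines(bc_p)
  if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m)) {
    stop(errorCondition(
      sprintf("matrix is %d x %d but features/barcodes have %d / %d entries",
              nrow(m), ncol(m), nrow(feats), length(barcodes)),
      class = c("stimspace_dim_mismatch", "error", "condition")))
  }
  if (anyDuplicated(barcodes)) {
    stop(errorCondition("duplicate barcodes in barcodes.tsv",
                        class = c("stimspace_duplicate_barcode", "error", "condition")))
  }
  pos <- utils::read.csv(pos_p)
  if (!setequal(pos$barcode, barcodes)) {
    stop(errorCondition("tissue_positions barcodes do not match barcodes.tsv",
                        class = c("stimspace_dim_mismatch", "error", "condition")))
  }
  sf <- jsonlite::read_json(sf_p, simplifyVector = TRUE)
  upp <- sf$microns_per_pixel
  spots <- data.frame(
    barcode = pos$barcode, array_row = pos$array_row,
    array_col = pos$array_col,
    x_um = pos$pxl_col * upp, y_um = pos$pxl_row * upp,
    in_tissue = pos$in_tissue == 1, artifact = FALSE
  )
  counts <- methods::as(m, "CsparseMatrix")
  dimnames(counts) <- list(feats[[1]], barcodes)
  img_p <- file.path(dir_path, "image.tiff")
  img <- NULL
  if (file.exists(img_p)) {
    raw <- tiff::readTIFF(img_p, all = FALSE)
    img <- if (length(dim(raw)) == 2) array(raw, c(dim(raw), 1)) else raw
  }
  s <- SpatialStimSample(
    counts, spots, gene_symbols = feats[[2]],
    sample_id = sf$sample_id %||% basename(dir_path),
    condition = sf$condition %||% NA_character_,
    timepoint = sf$timepoint %||% NA_character_,
    mapped_reads = sf$mapped_reads_total %||% sum(counts),
    microns_per_pixel = upp,
    spot_diameter_um = sf$spot_diameter_um %||% 55,
    image = img
  )
  art_p <- file.path(dir_path, "artifacts.csv")
  if (file.exists(art_p)) {
    polys <- utils::read.csv(art_p)
    s <- markArtifacts(s, polys)
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag spots under cryosectioning artifacts from polygon outlines
#'
#' Sections can carry rolls, folds and bubbles from cryosectioning; spots
#' under such regions must be excluded from every comparison. Regions are
#' supplied as polygons in a tidy vertex table (the scriptable equivalent of
#' manual GUI curation): columns `polygon_id`, `vertex_index`, `x_um`,
#' `y_um`. A spot whose centre falls inside (or on the border of) any
#' polygon gets `artifact = TRUE`; all other flags are cleared, so the
#' operation is idempotent. The polygons are stored in the sample metadata
#' and serialized to `artifacts.csv` by [writeSample()].
#'
#' @param x a [SpatialStimSample-class].
#' @param polygons polygon vertex `data.frame` as described, or `NULL` to
#'   clear all flags.
#' @return the updated sample.
#' @export
markArtifacts <- function(x, polygons) {
  cd <- SummarizedExperiment::colData(x)
  art <- rep(FALSE, ncol(x))
  if (!is.null(polygons) && nrow(polygons)) {
    for (pid in unique(polygons$polygon_id)) {
      v <- polygons[polygons$polygon_id == pid, ]
      v <- v[order(v$vertex_index), ]
      inside <- pracma::inpolygon(cd$x_um, cd$y_um, v$x_um, v$y_um,
                                  boundary = TRUE)
      art <- art | inside
    }
  }
  cd$artifact <- art
  SummarizedExperiment::colData(x) <- cd
  metadata(x)$artifact_polygons <- polygons
  x
}
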