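#' Run the end-to-end analysis pipeline from a YAML config
#'
#' Drives the full chain — simulate (optional), read, filter, aggregate,
#' localize, differential expression, radial profiles, enrichment
#' (optional), stimulation safety check (optional) — writing one
#' subdirectory of outputs per stage under `out_dir`, plus a
#' `provenance.json` recording the config hash (md5 of the YAML), package
#' version and all derived seeds. Given the same config and seed the run is
#' deterministic. Completed stages are skipped on rerun when their output
#' and stage manifest already exist for the same config hash.
#'
#' Config schema (YAML, `schema: 1`): top-level keys `seed`, `samples` (list
#' of `id`, `condition`, `timepoint` and either `path` to a SpaceRanger-style
#' directory or `simulate: {n_rows, n_cols, implant_x, implant_y, depth_total}`),
#' `comparisons` (list of `label`, `cluster_a`, `cluster_b`, each a list of
#' sample ids; whole sections are used), `markers`, `prior` (`x`, `y`),
#' `profiles` (list of `gene`, `bin_width`, `max_radius`), optional `gmt`
#' path, optional `protocols` CSV path. All paths are validated before any
#' compute.
#'
#' The single global seed is split into per-stage seeds as
#' `stage_seed = seed * 1000 + stage_index` (simulate = 1, aggregate = 2,
#' localize = 3), so each stage is independently reproducible.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory.
#' @return invisibly, a list with the loaded samples, DE tables, profiles
#'   and paths of all written artifacts.
#' @export
runPipeline <- function(config, out_dir) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  stage_seed <- function(i) seed * 1000L + i

  # -- validation before any compute
  for (s in config$samples) {
    if (!is.null(s$path) && !dir.exists(s$path)) {
      stop("sample path does not exist: ", s$path)
    }
  }
  if (!is.null(config$gmt) && !file.exists(config$gmt)) {
    stop("gmt file does not exist: ", config$gmt)
  }
  if (!is.null(config$protocols) && !file.exists(config$protocols)) {
    stop("protocols file does not exist: ", config$protocols)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_hash <- if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path)) else {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, tmp)
    h <- unname(tools::md5sum(tmp)); unlink(tmp); h
  }
  manifest_p <- function(stage) file.path(out_dir, paste0(".", stage, ".done"))
  stage_done <- function(stage) {
    file.exists(manifest_p(stage)) &&
      identical(readLines(manifest_p(stage))[1], cfg_hash)
  }
  mark_done <- function(stage) writeLines(cfg_hash, manifest_p(stage))

  # -- simulate / read
  samples <- list()
  sim_dir <- file.path(out_dir, "samples")
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    if (!is.null(s$path)) {
      samples[[s$id]] <- readSample(s$path)
    } else {
      sim <- s$simulate %||% list()
      cfg <- syntheticConfig(
        n_rows = sim$n_rows %||% 30, n_cols = sim$n_cols %||% 30,
        implant_xy = if (!is.null(sim$implant_x))
          c(sim$implant_x, sim$implant_y) else NULL,
        genes = defaultGenePanel(),
        depth_total = sim$depth_total,
        seed = stage_seed(1L) + i
      )
      smp <- simulateSample(cfg, sample_id = s$id,
                            condition = s$condition %||% NA_character_,
                            timepoint = s$timepoint %||% NA_character_)
      if (!stage_done("simulate")) {
        writeSample(smp, file.path(sim_dir, s$id))
      }
      samples[[s$id]] <- smp
    }
  }
  if (!stage_done("simulate")) mark_done("simulate")

  # -- aggregate (depth equalization)
  if (length(samples) >= 2) {
    samples <- aggregateSamples(samples, seed = stage_seed(2L))
  }
  plan <- aggregationPlan(samples)
  utils::write.table(plan, file.path(out_dir, "aggregation_plan.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # -- localize
  sites <- list()
  if (!is.null(config$prior)) {
    for (id in names(samples)) {
      sites[[id]] <- localizeImplant(
        samples[[id]], markers = unlist(config$markers %||%
                                          c("Ccl3", "Ccl4", "Gfap")),
        prior_xy = c(config$prior$x, config$prior$y),
        seed = stage_seed(3L)
      )
    }
    site_tab <- do.call(rbind, lapply(names(sites), function(id) {
      s <- sites[[id]]
      data.frame(sample_id = id, x_um = s@x, y_um = s@y, method = s@method,
                 marker_mass = s@markerMass)
    }))
    utils::write.table(site_tab, file.path(out_dir, "implant_sites.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # -- differential expression
  de_tables <- list()
  for (cmp in config$comparisons %||% list()) {
    spec <- comparisonSpec(
      wholeSectionCluster(samples[unlist(cmp$cluster_a)]),
      wholeSectionCluster(samples[unlist(cmp$cluster_b)]),
      label = cmp$label %||% "A vs B"
    )
    de <- runComparison(spec, samples,
                        alpha = config$alpha %||% 0.05,
                        lfc_threshold = config$lfc_threshold %||% 0.6)
    de_tables[[spec$label]] <- de
    fn <- file.path(out_dir, paste0(
      "de_", gsub("[^A-Za-z0-9]+", "_", spec$label), ".tsv"))
    utils::write.table(as.data.frame(de), fn, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  # -- radial profiles
  profiles <- list()
  for (pr in config$profiles %||% list()) {
    for (id in names(sites)) {
      prof <- radialGeneProfile(samples[[id]], pr$gene, sites[[id]],
                                bin_width = pr$bin_width %||% 100,
                                max_radius = pr$max_radius %||% 2000)
      profiles[[paste(id, pr$gene)]] <- prof
    }
  }
  if (length(profiles)) {
    utils::write.table(profileToTable(profiles),
                       file.path(out_dir, "radial_profiles.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  # -- enrichment
  enrich_tables <- list()
  if (!is.null(config$gmt) && length(de_tables)) {
    sets <- readGMT(config$gmt)
    for (lab in names(de_tables)) {
      de <- de_tables[[lab]]
      sig <- de$gene_id[de$significant]
      if (!length(sig)) next
      enr <- hypergeomEnrich(sig, sets, universe = de$gene_id)
      enrich_tables[[lab]] <- enr
      fn <- file.path(out_dir, paste0(
        "enrichment_", gsub("[^A-Za-z0-9]+", "_", lab), ".tsv"))
      utils::write.table(enr, fn, sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  # -- stimulation safety
  if (!is.null(config$protocols)) {
    prot <- utils::read.csv(config$protocols)
    st <- safetyTable(prot, k_limit = config$k_limit %||% 1.85)
    utils::write.table(st, file.path(out_dir, "safety.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  prov <- list(config_hash = cfg_hash, seed = seed,
               stage_seeds = list(simulate = stage_seed(1L),
                                  aggregate = stage_seed(2L),
                                  localize = stage_seed(3L)),
               package_version = as.character(utils::packageVersion("stimspace")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(list(samples = samples, sites = sites, de = de_tables,
                 profiles = profiles, enrichment = enrich_tables,
                 out_dir = out_dir))
}
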