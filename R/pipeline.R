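#' Run the full gene-body epigenomics pipeline
#'
#' Orchestrates the stages in dependency order: gene models and region
#' derivation, HELP angle merging and region medians, region FPKM for every
#' fragment set, expression clustering and categorization, accumulation and
#' fold-enrichment calls, the metaplot and the cross-modality statistics.
#' Intermediate tables are written under `out_dir` and a JSON manifest
#' records the configuration hash, seeds, per-stage outputs and the gene
#' universe size after each filter.
#'
#' The configuration is a list (or YAML path) with either
#' `synthetic: TRUE` (plus optional `seed` and [synthetic_config()]
#' overrides under `synthetic_args`) or explicit input paths: `annotation`
#' (+ `annotation_format`), `help_sites` (named list of per-sample TSVs),
#' `expression`, `fragments` (named list of BED/BAM paths, gene-body ChIP
#' and 5hmC libraries alike). Optional knobs: `flank`, `conf_cutoff`, `k`,
#' `seed`, `n_restarts`, `specificity_margin`, `accumulation_threshold`,
#' `polii_high_threshold`, `polii_factor`.
#'
#' @param config List or YAML path.
#' @param out_dir Output directory (default `tempfile("gbepi_run")`).
#' @return List of class `run_manifest` (also written as
#'   `manifest.json`): `config_hash`, `seed`, `stages` (named output
#'   paths), `universe` (named sizes after each filter), `results` (the
#'   in-memory stage outputs).
#' @export
run_pipeline <- function(config, out_dir = tempfile("gbepi_run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!isTRUE(config$synthetic)) {
    for (need in c("annotation", "help_sites", "expression")) {
      if (is.null(config[[need]])) {
        stop("config error: missing required field '", need, "'")
      }
      paths <- unlist(config[[need]])
      if (need != "expression" || is.character(paths)) {
        missing <- paths[!file.exists(paths)]
        if (length(missing)) {
          stop("config error: input does not exist: ",
               paste(missing, collapse = ", "))
        }
      }
    }
  }
  cfgv <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  seed <- cfgv("seed", 1L)
  flank <- cfgv("flank", 2000L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c(); universe <- c()
  log_stage <- function(name, path) {
    message("[gbepi] stage ", name, " -> ", path)
    stages[[name]] <<- path
  }

  ## stage 1: gene models and regions
  if (isTRUE(config$synthetic)) {
    scfg <- do.call(synthetic_config,
                    c(list(seed = seed), config$synthetic_args))
    ds <- generate_dataset(scfg)
    genes <- ds$genes
    help_tables <- ds$help
    expr <- ds$expr
    sample_info <- ds$expr_samples
    frag_sets <- c(ds$fragments$hmc, ds$fragments$chip)
  } else {
    genes <- load_gene_models(config$annotation,
                              cfgv("annotation_format", "refFlat"))
    help_tables <- lapply(config$help_sites, read_help_sites)
    expr <- read_expression_tsv(config$expression)
    sample_info <- as.data.frame(config$expression_samples)
    frag_sets <- lapply(config$fragments, load_fragments,
                        read_mode = cfgv("read_mode", "single_extended"))
    ds <- NULL
  }
  universe["transcripts"] <- nrow(genes)
  genes <- dedup_by_symbol(genes)
  universe["symbols"] <- nrow(genes)
  regions <- derive_regions(genes, flank = flank)
  universe["with_gene_body"] <- sum(!regions$body_empty)
  p <- file.path(out_dir, "regions.bed")
  write_regions_bed(regions, p); log_stage("regions", p)

  ## stage 2: methylation
  merged <- merge_analysed_sites(help_tables,
                                 conf_cutoff = cfgv("conf_cutoff", 3))
  universe["analysed_hpaii_sites"] <- nrow(merged)
  meth <- region_median_angle(merged, regions,
                              min_sites = cfgv("min_sites", 1L))
  p <- file.path(out_dir, "methylation.tsv")
  write_methylation_tsv(meth, p); log_stage("methylation", p)

  ## stage 3: region quantification
  quants <- lapply(frag_sets, region_fpkm, regions = regions)
  gb_mat <- quant_matrix(quants, region = "gene_body")
  p <- file.path(out_dir, "gene_body_fpkm.tsv")
  write_quant_tsv(gb_mat, p); log_stage("gene_body_fpkm", p)

  ## stage 4: expression clustering
  expr_std <- relative_profiles(expr)
  universe["clustered_genes"] <- nrow(expr_std)
  km <- kmeans_expression(expr_std, k = cfgv("k", 12L), seed = seed,
                          n_restarts = cfgv("n_restarts", 50L))
  cats <- categorize_clusters(km, expr, sample_info,
                              specificity_margin = cfgv("specificity_margin",
                                                        0.75))
  p <- file.path(out_dir, "clusters.tsv")
  write_clusters_tsv(cats, p); log_stage("clusters", p)

  ## stage 5: enrichment calls
  polii_factor <- cfgv("polii_factor", grep("PolII", names(quants),
                                            value = TRUE)[1])
  calls <- list()
  for (fac in names(quants)) {
    calls[[fac]] <- call_accumulated(
      quants[[fac]], factor_id = fac, sample = fac,
      threshold = cfgv("accumulation_threshold", 1.0))
  }
  folds <- if (!is.na(polii_factor)) {
    fold_enrichment(calls[[polii_factor]], cats$assignment)
  } else NULL
  if (!is.null(folds)) {
    p <- file.path(out_dir, "fold_enrichment.tsv")
    utils::write.table(folds, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    log_stage("fold_enrichment", p)
  }

  ## stage 6: stats
  ks <- length_ks_matrix(genes, cats$assignment)
  p <- file.path(out_dir, "length_ks.tsv")
  utils::write.table(ks, p, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("length_ks", p)

  manifest <- list(config_hash = rlang::hash(config), seed = seed,
                   stages = as.list(stages), universe = as.list(universe))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- list(genes = genes, regions = regions, meth = meth,
                           quants = quants, km = km, categories = cats,
                           calls = calls, folds = folds, ks = ks,
                           dataset = ds)
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("gbepi run", x$config_hash, "(seed", x$seed, ")\n")
  cat("universe:", paste(names(x$universe), unlist(x$universe),
                         sep = "=", collapse = ", "), "\n")
  cat("stages:", paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}
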