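#' Assemble a pipeline configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param counts named list of per-species count TSV paths (`parent1`,
#'   `parent2`, `hybrid` labels as in `species_labels`); ignored when
#'   `simulation` is given.
#' @param metadata sample metadata TSV path.
#' @param ortholog_pairs pairwise ortholog TSV path.
#' @param transcripts optional named list of per-species transcript-table
#'   TSV paths; when present the unigene-selection stage runs and restricts
#'   each species' counts to its unigene clusters.
#' @param simulation optional [sim_config()]; when present the pipeline
#'   simulates its own inputs (written under `out_dir/simulated`) and then
#'   analyses them like any other input set.
#' @param species_labels names of the two parents and the hybrid as used in
#'   the metadata's `species` column.
#' @param fpkm_cutoff,padj_cutoff,log2fc_cutoff analysis thresholds.
#' @param seed integer seed for any stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            counts = NULL, metadata = NULL,
                            ortholog_pairs = NULL, transcripts = NULL,
                            simulation = NULL,
                            species_labels = c(parent1 = "parent1",
                                               parent2 = "parent2",
                                               hybrid = "hybrid"),
                            fpkm_cutoff = 2, padj_cutoff = 0.001,
                            log2fc_cutoff = 1, seed = 1L) {
  cfg <- list(out_dir = out_dir, counts = counts, metadata = metadata,
              ortholog_pairs = ortholog_pairs, transcripts = transcripts,
              simulation = simulation, species_labels = species_labels,
              fpkm_cutoff = fpkm_cutoff, padj_cutoff = padj_cutoff,
              log2fc_cutoff = log2fc_cutoff, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  if (any(c(fpkm_cutoff, padj_cutoff, log2fc_cutoff) <= 0))
    stop("thresholds must be positive")
  if (anyDuplicated(species_labels))
    stop("species labels must be distinct")
  if (is.null(simulation) &&
      (is.null(counts) || is.null(metadata) || is.null(ortholog_pairs)))
    stop("either a simulation block or counts + metadata + ortholog_pairs ",
         "paths are required")
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(sim_config, y$simulation)
  if (!is.null(y$species_labels)) y$species_labels <- unlist(y$species_labels)
  do.call(pipeline_config, y)
}

.log_stage <- function(...) message("[hybridmode] ", format(Sys.time(), "%H:%M:%S"),
                                    " ", ...)

#' Run the full trio analysis pipeline
#'
#' Stages, in order: (optional) simulate inputs; (optional) unigene
#' selection from transcript tables; ortholog-group construction and
#' count assignment with singleton zero-fill; per-tissue normalization and
#' dispersion estimation; four differential-expression comparisons per
#' tissue (parent2 vs parent1, hybrid vs each parent, hybrid vs the MPV
#' fixed null); inheritance classification; summary tables. Every table is
#' written as TSV under `out_dir`, along with a JSON manifest recording the
#' package version, seed, configuration hash and output checksums; reruns
#' with an identical configuration and seed are byte-identical.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @return invisibly, a list with the in-memory results (`groups`, `venn`,
#'   `de`, `classification`, `tables`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config or a YAML path")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  if (!is.null(config$simulation)) {
    .log_stage("simulate: ", config$simulation$n_genes, " genes")
    sim <- simulate_trio(config$simulation)
    paths <- write_simulation(sim, file.path(config$out_dir, "simulated"))
    config$counts <- as.list(paths[paste0("counts_", names(sim$counts))])
    names(config$counts) <- names(sim$counts)
    config$metadata <- paths[["metadata"]]
    config$ortholog_pairs <- paths[["ortholog_pairs"]]
  }

  sl <- config$species_labels
  counts <- lapply(config$counts, read_counts)
  names(counts) <- names(config$counts)
  meta <- read_metadata(config$metadata)
  pairs <- read_ortholog_pairs(config$ortholog_pairs)

  unigene_summaries <- NULL
  if (!is.null(config$transcripts)) {
    .log_stage("select: unigene selection on ", length(config$transcripts),
               " transcript tables")
    selected <- lapply(config$transcripts, function(p)
      select_unigenes(read_transcript_table(p), fpkm_cutoff = config$fpkm_cutoff))
    unigene_summaries <- do.call(rbind, Map(function(sp, u)
      cbind(species = sp, assembly_summary(u)), names(selected), selected))
    for (sp in names(selected)) {
      if (sp %in% names(counts)) {
        keep <- rownames(counts[[sp]]) %in% selected[[sp]]$cluster_id
        counts[[sp]] <- counts[[sp]][keep, , drop = FALSE]
      }
    }
  }

  .log_stage("groups: building ortholog groups")
  unigene_sets <- lapply(counts, rownames)
  groups <- build_groups(pairs, unigene_sets)
  venn <- venn_counts(groups)
  gm <- counts_to_groups(groups, counts)

  .log_stage("dge + classify: ", length(unique(meta$tissue)), " tissue(s)")
  ana <- analyze_trio(gm, meta, species_labels = sl,
                      padj_cutoff = config$padj_cutoff,
                      lfc_cutoff = config$log2fc_cutoff)
  classification <- ana$classification
  de_all <- ana$de_all

  .log_stage("report: summary tables")
  parent_de <- de_all[de_all$comparison ==
                        paste0(sl[["parent2"]], "_vs_", sl[["parent1"]]), ]
  tables <- list(
    venn = data.frame(region = names(venn), n = as.integer(venn)),
    hybrid_specific_pct = hybrid_specific_fraction(
      setNames(venn, sub(paste0("^", sl[["hybrid"]], "_only$"), "hybrid_only",
                         names(venn)))),
    deg_summary = deg_summary(parent_de),
    inheritance = if (!is.null(classification$calls) &&
                      nrow(classification$calls) > 0)
      inheritance_table(classification) else NULL,
    unigene_summaries = unigene_summaries)

  out <- list(groups = groups, venn = venn, de = de_all,
              classification = classification, tables = tables)
  out$manifest <- .write_outputs(out, config)
  invisible(out)
}

.write_outputs <- function(out, config) {
  od <- config$out_dir
  files <- c()
  wt <- function(df, name) {
    p <- file.path(od, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- p
  }
  wt(out$groups, "ortholog_groups.tsv")
  wt(out$tables$venn, "venn_regions.tsv")
  wt(out$de, "de_results.tsv")
  if (!is.null(out$classification$calls) && nrow(out$classification$calls) > 0) {
    wt(out$classification$calls, "inheritance_calls.tsv")
    wt(out$classification$overall, "inheritance_overall.tsv")
  }
  if (!is.null(out$tables$inheritance)) wt(out$tables$inheritance,
                                           "inheritance_table.tsv")
  wt(out$tables$deg_summary, "deg_summary.tsv")
  if (!is.null(out$tables$unigene_summaries))
    wt(out$tables$unigene_summaries, "unigene_summaries.tsv")

  cfg_path <- file.path(od, "config_used.yaml")
  cfg_serial <- config
  cfg_serial$simulation <- if (!is.null(config$simulation))
    unclass(config$simulation)
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (!is.null(names(x))) as.list(x)   # keep names as YAML map keys
    else x
  }
  yaml::write_yaml(yamlify(unclass(cfg_serial)), cfg_path)
  manifest <- list(
    package = "hybridmode",
    version = as.character(utils::packageVersion("hybridmode")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(files, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
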