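#' Simulation configuration for a parent/parent/hybrid count trio
#'
#' Bundles and validates every knob of the trio simulator. Counts are drawn
#' from a negative binomial with mean/dispersion parameterization
#' `Var = mu + alpha * mu^2` (alpha = 0 degenerates to Poisson). Group means
#' encode the gene's true inheritance mode; the mid-parent value (MPV) is
#' defined on the linear expected-count scale, `(mu1 + mu2) / 2`, because the
#' trait under study is expression abundance itself.
#'
#' @param n_genes number of simulated genes (ortholog groups).
#' @param replicates_per_tissue biological replicates per species per tissue.
#' @param tissues character vector of tissue labels.
#' @param mode_proportions named numeric summing to 1 over
#'   `conserved, F1a, F1b_P1, F1b_P2, F1c, F1d_over, F1d_under`:
#'   the fraction of genes whose hybrid mean is additive (= MPV), equal to one
#'   parent, strictly intermediate but off-MPV, or transgressive
#'   (above/below the parental range). `conserved` genes have equal means in
#'   all three species.
#' @param singleton_fraction_per_species fraction of genes, per species, that
#'   are species-specific: expressed only in that species and structurally
#'   zero in the other two.
#' @param base_log2_mean_range range (log2 expected counts) from which the
#'   reference parental mean is drawn. The default `c(5, 10)` (32-1024
#'   expected counts) reflects genes surviving an FPKM > 2 retention filter
#'   at typical bulk sequencing depths.
#' @param parental_log2fc_min minimum |log2 fold change| between the two
#'   parents for non-conserved genes; must be >= 1 so that simulated effects
#'   sit above the |log2FC| > 1 detection threshold. True fold changes are
#'   drawn uniformly from `[parental_log2fc_min, parental_log2fc_min + 2]`.
#' @param dispersion per-gene NB dispersion alpha (scalar recycled, or vector
#'   of length `n_genes`); one shared value per gene across species and
#'   tissues.
#' @param size_factor_range range of per-sample library-size factors
#'   (uniform draw).
#' @param transgressive_margin_log2 log2 distance (> 0) that transgressive
#'   (F1d) hybrid means lie outside the parental range; incomplete-dominant
#'   (F1c) means are at least this far from the MPV in log2.
#' @param seed integer seed; identical configs give byte-identical output.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       replicates_per_tissue = 2,
                       tissues = c("leaf", "corolla"),
                       mode_proportions = c(conserved = 0.70, F1a = 0.01,
                                            F1b_P1 = 0.13, F1b_P2 = 0.11,
                                            F1c = 0.02, F1d_over = 0.02,
                                            F1d_under = 0.01),
                       singleton_fraction_per_species = 0.2,
                       base_log2_mean_range = c(5, 10),
                       parental_log2fc_min = 2,
                       dispersion = 0.05,
                       size_factor_range = c(0.7, 1.4),
                       transgressive_margin_log2 = 1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              replicates_per_tissue = as.integer(replicates_per_tissue),
              tissues = as.character(tissues),
              mode_proportions = unlist(mode_proportions),
              singleton_fraction_per_species = singleton_fraction_per_species,
              base_log2_mean_range = base_log2_mean_range,
              parental_log2fc_min = parental_log2fc_min,
              dispersion = dispersion,
              size_factor_range = size_factor_range,
              transgressive_margin_log2 = transgressive_margin_log2,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

.sim_modes <- c("conserved", "F1a", "F1b_P1", "F1b_P2",
                "F1c", "F1d_over", "F1d_under")

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("n_genes must be a positive integer")
  if (cfg$replicates_per_tissue < 1L)
    stop("replicates_per_tissue must be a positive integer")
  if (length(cfg$tissues) < 1L) stop("at least one tissue label is required")
  mp <- cfg$mode_proportions
  if (is.null(names(mp)) || !all(names(mp) %in% .sim_modes))
    stop("mode_proportions must be named with subset of: ",
         paste(.sim_modes, collapse = ", "))
  if (any(mp < 0)) stop("mode_proportions must be non-negative")
  if (abs(sum(mp) - 1) > 1e-9)
    stop("mode_proportions must sum to 1 (got ", sum(mp), ")")
  n_modes <- sum(mp > 0)
  if (cfg$n_genes < n_modes)
    stop("n_genes (", cfg$n_genes, ") is smaller than the number of active modes")
  sf <- cfg$singleton_fraction_per_species
  if (sf < 0 || sf >= 1/3)
    stop("singleton_fraction_per_species must lie in [0, 1/3)")
  if (cfg$parental_log2fc_min < 1)
    stop("parental_log2fc_min must be >= 1")
  if (any(cfg$dispersion < 0)) stop("dispersion must be >= 0")
  if (!length(cfg$dispersion) %in% c(1L, cfg$n_genes))
    stop("dispersion must be a scalar or of length n_genes")
  if (cfg$transgressive_margin_log2 <= 0)
    stop("transgressive_margin_log2 must be > 0")
  if (any(cfg$size_factor_range <= 0) || diff(cfg$size_factor_range) < 0)
    stop("size_factor_range must be a positive, non-decreasing interval")
  if (diff(cfg$base_log2_mean_range) < 0)
    stop("base_log2_mean_range must be non-decreasing")
  # F1c means must fit strictly between the low parent and MPV / 2^margin:
  # requires 2^lfc_min > 2^(margin + 1) - 1.
  if (!is.na(mp["F1c"]) && mp["F1c"] > 0 &&
      2^cfg$parental_log2fc_min <= 2^(cfg$transgressive_margin_log2 + 1) - 1)
    stop("with F1c genes present, parental_log2fc_min must satisfy ",
         "2^lfc_min > 2^(margin+1) - 1 so an intermediate mean can sit ",
         "at least `transgressive_margin_log2` below the MPV")
  invisible(cfg)
}

# NB draw with Var = mu + alpha mu^2; alpha = 0 is the Poisson limit.
rnb_counts <- function(n, mu, alpha) {
  out <- integer(n)
  pois <- alpha == 0 | mu == 0
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                                        size = 1 / alpha[!pois])
  out
}

#' Simulate a parent/parent/hybrid count trio with known inheritance modes
#'
#' Draws one negative-binomial count matrix per species (genes x
#' tissue-replicate samples) plus a ground-truth table. Per gene and tissue a
#' reference parental mean is drawn on log2 scale; non-conserved genes get a
#' parental fold change of at least `parental_log2fc_min` (random direction),
#' and the hybrid mean is set by the gene's mode: the exact linear MPV (F1a),
#' one parental mean (F1b), a value strictly between the parents at least
#' `transgressive_margin_log2` below the MPV in log2 (F1c; the region above
#' the MPV is never wide enough, see the methods vignette), or a value at
#' least the margin outside the parental range (F1d). Species-specific
#' singleton genes have structural zeros in the two absent species.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (named list of integer matrices for
#'   `parent1`, `parent2`, `hybrid`), `metadata` (one row per sample across
#'   all species: sample, species, tissue, replicate), `truth` (per gene and
#'   tissue: true mode, the three group means, dispersion, singleton species),
#'   `size_factors`, and the `config`.
#' @export
simulate_trio <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  species <- c("parent1", "parent2", "hybrid")
  genes <- sprintf("g%05d", seq_len(n))
  alpha <- rep_len(config$dispersion, n)

  # mode assignment: deterministic counts per mode (largest remainder), then
  # shuffled; guarantees every active mode is represented.
  mp <- config$mode_proportions[config$mode_proportions > 0]
  n_mode <- floor(mp * n)
  rem <- n - sum(n_mode)
  if (rem > 0) {
    frac <- mp * n - floor(mp * n)
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_mode[top] <- n_mode[top] + 1L
  }
  n_mode[n_mode == 0] <- 1L
  while (sum(n_mode) > n) n_mode[which.max(n_mode)] <- n_mode[which.max(n_mode)] - 1L
  mode <- sample(rep(names(n_mode), n_mode))

  # singleton assignment, overriding the mode
  singleton <- rep(NA_character_, n)
  n_single <- floor(config$singleton_fraction_per_species * n)
  if (n_single > 0) {
    picked <- sample(n, 3 * n_single)
    singleton[picked] <- rep(species, each = n_single)
    mode[picked] <- "singleton"
  }

  reps <- config$replicates_per_tissue
  n_samp <- length(config$tissues) * reps
  meta <- do.call(rbind, lapply(species, function(sp) {
    data.frame(sample = paste(sp, rep(config$tissues, each = reps),
                              rep(seq_len(reps), length(config$tissues)),
                              sep = "_"),
               species = sp,
               tissue = rep(config$tissues, each = reps),
               replicate = rep(seq_len(reps), length(config$tissues)),
               stringsAsFactors = FALSE)
  }))
  sf <- setNames(runif(nrow(meta), config$size_factor_range[1],
                       config$size_factor_range[2]), meta$sample)

  lfc_min <- config$parental_log2fc_min
  marg <- config$transgressive_margin_log2

  truth <- vector("list", length(config$tissues))
  mats <- lapply(species, function(sp)
    matrix(0L, n, n_samp, dimnames = list(genes, meta$sample[meta$species == sp])))
  names(mats) <- species

  for (ti in seq_along(config$tissues)) {
    tissue <- config$tissues[ti]
    base <- 2^runif(n, config$base_log2_mean_range[1],
                    config$base_log2_mean_range[2])
    lfc <- runif(n, lfc_min, lfc_min + 2) * sample(c(-1, 1), n, replace = TRUE)
    mu1 <- base
    mu2 <- base * 2^lfc
    mu1[mode == "conserved"] <- base[mode == "conserved"]
    mu2[mode == "conserved"] <- base[mode == "conserved"]
    mpv <- (mu1 + mu2) / 2
    hi <- pmax(mu1, mu2); lo <- pmin(mu1, mu2)

    muh <- mpv                                   # F1a: exact linear MPV
    muh[mode == "conserved"] <- base[mode == "conserved"]
    muh[mode == "F1b_P1"] <- mu1[mode == "F1b_P1"]
    muh[mode == "F1b_P2"] <- mu2[mode == "F1b_P2"]
    i <- mode == "F1c"
    if (any(i)) {
      # strictly between the parents, >= margin below the MPV in log2
      room <- log2(mpv[i]) - log2(lo[i]) - marg   # > 0 by config validation
      d <- runif(sum(i), marg, marg + room / 2)
      muh[i] <- mpv[i] / 2^d
    }
    i <- mode == "F1d_over"
    if (any(i)) muh[i] <- hi[i] * 2^(marg + runif(sum(i), 0, 1))
    i <- mode == "F1d_under"
    if (any(i)) muh[i] <- lo[i] / 2^(marg + runif(sum(i), 0, 1))

    # structural zeros for singleton genes in the two absent species
    mu_sp <- list(parent1 = mu1, parent2 = mu2, hybrid = muh)
    for (sp in species) {
      absent <- !is.na(singleton) & singleton != sp
      mu_sp[[sp]][absent] <- 0
      present_single <- !is.na(singleton) & singleton == sp
      mu_sp[[sp]][present_single] <- base[present_single]
    }

    for (sp in species) {
      cols <- meta$sample[meta$species == sp & meta$tissue == tissue]
      for (cn in cols) {
        mats[[sp]][, cn] <- rnb_counts(n, sf[cn] * mu_sp[[sp]], alpha)
      }
    }
    truth[[ti]] <- data.frame(gene = genes, tissue = tissue, true_mode = mode,
                              parent1_mean = mu_sp$parent1,
                              parent2_mean = mu_sp$parent2,
                              hybrid_mean = mu_sp$hybrid,
                              dispersion = alpha,
                              singleton_species = singleton,
                              stringsAsFactors = FALSE)
  }

  list(counts = mats,
       metadata = meta,
       truth = do.call(rbind, truth),
       size_factors = sf,
       config = config)
}

#' Simulate per-species transcript tables for unigene selection
#'
#' Emits, for each species, a table of transcript clusters with 1-3 isoforms
#' each: lengths, FPKM values that straddle the retention threshold of 2
#' (including exact 2.0 boundary cases), and ortholog-presence flags
#' consistent with the trio's singleton assignments (a species' singleton
#' genes carry no ortholog evidence).
#'
#' @param config a [sim_config()].
#' @param max_isoforms maximum isoforms per cluster.
#' @return named list (`parent1`, `parent2`, `hybrid`) of data frames with
#'   columns `cluster_id`, `transcript_id`, `length_bp`, `fpkm`,
#'   `has_ortholog`.
#' @export
simulate_transcript_tables <- function(config, max_isoforms = 3L) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_genes
  species <- c("parent1", "parent2", "hybrid")
  singleton <- rep(NA_character_, n)
  n_single <- floor(config$singleton_fraction_per_species * n)
  if (n_single > 0) {
    # same RNG stream position logic is not shared with simulate_trio;
    # singleton identity here is an independent fixture property
    picked <- sample(n, 3 * n_single)
    singleton[picked] <- rep(species, each = n_single)
  }
  out <- lapply(species, function(sp) {
    present <- is.na(singleton) | singleton == sp
    idx <- which(present)
    k <- sample(max_isoforms, length(idx), replace = TRUE)
    cluster <- rep(sprintf("%s_c%05d", sp, idx), k)
    iso <- unlist(lapply(k, seq_len))
    fpkm <- round(2^runif(length(iso), -2, 6), 3)
    fpkm[sample(length(fpkm), max(1L, length(fpkm) %/% 50))] <- 2.0
    data.frame(cluster_id = cluster,
               transcript_id = paste0(cluster, "_i", iso),
               length_bp = as.integer(round(runif(length(iso), 200, 3000))),
               fpkm = fpkm,
               has_ortholog = rep(is.na(singleton[idx]), k) &
                 runif(length(iso)) < 0.6,
               stringsAsFactors = FALSE)
  })
  names(out) <- species
  out
}

#' Write a simulated trio to disk as pipeline-ready TSV inputs
#'
#' Serializes per-species count matrices (species-prefixed gene identifiers,
#' restricted to the genes actually present in that species), the sample
#' metadata, the pairwise ortholog map linking non-singleton genes across the
#' three species, the truth table and the configuration, so that the
#' simulated data can be re-analysed through [run_pipeline()] exactly as
#' field data would be.
#'
#' @param sim result of [simulate_trio()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  species <- names(sim$counts)
  truth1 <- sim$truth[sim$truth$tissue == sim$truth$tissue[1], ]
  singleton <- setNames(truth1$singleton_species, truth1$gene)
  paths <- c()
  for (sp in species) {
    present <- is.na(singleton) | singleton == sp
    m <- sim$counts[[sp]][present, , drop = FALSE]
    rownames(m) <- paste0(sp, ".", rownames(m))
    p <- file.path(dir, paste0("counts_", sp, ".tsv"))
    write_tsv_matrix(m, p, id_col = "gene_id")
    paths[paste0("counts_", sp)] <- p
  }
  p <- file.path(dir, "metadata.tsv")
  utils::write.table(sim$metadata, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["metadata"] <- p

  shared <- truth1$gene[is.na(singleton)]
  pairs <- rbind(
    data.frame(species_a = "parent1", gene_a = paste0("parent1.", shared),
               species_b = "parent2", gene_b = paste0("parent2.", shared)),
    data.frame(species_a = "parent1", gene_a = paste0("parent1.", shared),
               species_b = "hybrid", gene_b = paste0("hybrid.", shared)))
  p <- file.path(dir, "ortholog_pairs.tsv")
  utils::write.table(pairs, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["ortholog_pairs"] <- p

  p <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth"] <- p

  p <- file.path(dir, "sim_config.yaml")
  yaml::write_yaml(unclass(sim$config), p)
  paths["config"] <- p
  invisible(paths)
}
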