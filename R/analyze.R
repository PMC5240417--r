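#' Differential expression and inheritance classification for a count trio
#'
#' Core analysis on a group-level count matrix spanning all three species'
#' samples: per tissue, estimates size factors and dispersions, runs the
#' four comparisons (parent2 vs parent1, hybrid vs each parent, hybrid vs
#' the fixed MPV null with delta-method parental uncertainty), and
#' classifies parent-vs-parent DEGs into inheritance modes.
#'
#' @param counts matrix, groups/genes x samples (all species).
#' @param metadata data frame with `sample`, `species`, `tissue` covering
#'   the columns of `counts`.
#' @param species_labels named character vector mapping `parent1`,
#'   `parent2`, `hybrid` to the metadata's species values.
#' @param padj_cutoff,lfc_cutoff DEG thresholds (defaults 0.001 and 1).
#' @param priority tissue priority for overall deduplication.
#' @return list: `de_by_tissue` (per-tissue lists of [test_de()] results),
#'   `de_all` (bound rows with a `tissue` column), `classification`
#'   (from [classify_all()]).
#' @export
analyze_trio <- function(counts, metadata,
                         species_labels = c(parent1 = "parent1",
                                            parent2 = "parent2",
                                            hybrid = "hybrid"),
                         padj_cutoff = 0.001, lfc_cutoff = 1,
                         priority = c("corolla", "leaf")) {
  miss <- setdiff(metadata$sample, colnames(counts))
  if (length(miss))
    stop("metadata sample(s) absent from the count matrix: ",
         paste(head(miss, 3), collapse = ", "))
  sl <- species_labels
  tissues <- unique(metadata$tissue)
  de_by_tissue <- list()
  de_rows <- list()
  for (tt in tissues) {
    cols <- metadata$sample[metadata$tissue == tt]
    sub <- counts[, cols, drop = FALSE]
    norm <- normalize_counts(sub)
    spp <- metadata$species[match(cols, metadata$sample)]
    alpha <- estimate_dispersion(norm, split(seq_along(cols), spp))
    cp1 <- cols[spp == sl[["parent1"]]]
    cp2 <- cols[spp == sl[["parent2"]]]
    ch <- cols[spp == sl[["hybrid"]]]
    de <- list(
      p2_vs_p1 = test_de(norm, alpha, cp1, cp2,
                         comparison = paste0(sl[["parent2"]], "_vs_", sl[["parent1"]]),
                         padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff),
      h_vs_p1 = test_de(norm, alpha, cp1, ch,
                        comparison = paste0(sl[["hybrid"]], "_vs_", sl[["parent1"]]),
                        padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff),
      h_vs_p2 = test_de(norm, alpha, cp2, ch,
                        comparison = paste0(sl[["hybrid"]], "_vs_", sl[["parent2"]]),
                        padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff))
    m1 <- rowMeans(norm$normalized[, cp1, drop = FALSE])
    m2 <- rowMeans(norm$normalized[, cp2, drop = FALSE])
    v1 <- vapply(seq_len(nrow(sub)), function(i)
      .mean_var(m1[i], norm$size_factors[cp1], alpha[i]), 0)
    v2 <- vapply(seq_len(nrow(sub)), function(i)
      .mean_var(m2[i], norm$size_factors[cp2], alpha[i]), 0)
    de$h_vs_mpv <- test_de(norm, alpha, NULL, ch,
                           comparison = paste0(sl[["hybrid"]], "_vs_MPV"),
                           null_mean = (m1 + m2) / 2,
                           null_mean_var = (v1 + v2) / 4,
                           padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff)
    de_by_tissue[[tt]] <- de
    for (nm in names(de))
      de_rows[[paste(tt, nm)]] <- cbind(tissue = tt, de[[nm]])
  }
  de_all <- do.call(rbind, de_rows)
  rownames(de_all) <- NULL
  list(de_by_tissue = de_by_tissue,
       de_all = de_all,
       classification = classify_all(de_by_tissue, padj_cutoff = padj_cutoff,
                                     priority = priority))
}

#' Classification-recovery metrics against a simulation truth table
#'
#' Compares inheritance calls with the simulator's ground truth over the
#' genes that entered the classification workflow (true parent-vs-parent
#' DEGs actually detected: classification can only act on its entry set).
#' Recall of a mode = correctly called / entered genes of that true mode;
#' precision = correctly called / all calls of that mode.
#'
#' @param calls per-tissue call rows from [classify_all()] (the `calls`
#'   element).
#' @param truth truth table from [simulate_trio()] (per gene and tissue).
#' @return list: `confusion` (true mode x called category table), `recall`
#'   and `precision` per mode, `mean_recall` over modes present in truth,
#'   and `f1d_precision` pooled over the two transgressive calls.
#' @export
recovery_metrics <- function(calls, truth) {
  modes <- c("F1a", "F1b_P1", "F1b_P2", "F1c", "F1d_over", "F1d_under")
  key <- function(g, t) paste(g, t)
  tm <- setNames(truth$true_mode, key(truth$gene, truth$tissue))
  truemode <- tm[key(calls$group_id, calls$tissue)]
  keep <- truemode %in% modes
  cl <- calls$category[keep]
  trm <- factor(truemode[keep], levels = modes)
  cld <- factor(cl, levels = c(modes, "ambiguous"))
  confusion <- table(true = trm, called = cld)
  recall <- vapply(modes, function(m) {
    n <- sum(trm == m)
    if (n == 0) NA_real_ else sum(trm == m & cl == m) / n
  }, 0)
  precision <- vapply(modes, function(m) {
    n <- sum(cl == m)
    if (n == 0) NA_real_ else sum(trm == m & cl == m) / n
  }, 0)
  f1d_called <- cl %in% c("F1d_over", "F1d_under")
  f1d_ok <- f1d_called & cl == as.character(trm)
  list(confusion = confusion,
       recall = recall,
       precision = precision,
       mean_recall = mean(recall, na.rm = TRUE),
       f1d_precision = if (any(f1d_called)) sum(f1d_ok) / sum(f1d_called)
                       else NA_real_)
}
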