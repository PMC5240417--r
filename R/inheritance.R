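#' Classify parent-vs-parent DEGs into inheritance modes
#'
#' Implements the decision workflow for expression inheritance in an F1
#' hybrid. Entry set: genes differentially expressed between the two parents
#' (the dual-test DEG rule). For each such gene the hybrid is compared
#' against parent 1, parent 2 and the mid-parent value (MPV), and the three
#' outcomes (`sig_up`/`sig_down`/`ns`) decide the category, evaluated in
#' this order:
#'
#' 1. significantly above both parents -> `F1d_over`; below both ->
#'    `F1d_under` (transgressive calls take precedence: a gene outside the
#'    parental range must never be labelled dominant);
#' 2. not distinguishable from exactly one parent, significant against the
#'    other -> complete dominance toward the indistinguishable parent
#'    (`F1b_P1` / `F1b_P2`);
#' 3. significant against both parents in opposite directions (strictly
#'    between them) -> `F1a` (additive) if the hybrid is indistinguishable
#'    from the MPV, otherwise `F1c` (incomplete dominance);
#' 4. indistinguishable from both parents -> `ambiguous` (the design lacks
#'    resolution for this gene; excluded from summary denominators).
#'
#' @param deg_ids ids of the parent-vs-parent DEGs (the entry set).
#' @param res_h_p1,res_h_p2 [test_de()] results for hybrid vs parent1 and
#'   hybrid vs parent2 (hybrid is group B; all genes, superset of
#'   `deg_ids`).
#' @param res_h_mpv [test_de()] result for hybrid vs the fixed MPV null.
#' @param tissue tissue label attached to the calls.
#' @param padj_cutoff significance cutoff for the companion comparisons
#'   (dual-test, no fold-change gate; see [de_outcome()]).
#' @return data frame, one row per entry gene: `group_id`, `tissue`,
#'   `category`, the three outcomes, and the normalized hybrid/parent/MPV
#'   means.
#' @export
classify <- function(deg_ids, res_h_p1, res_h_p2, res_h_mpv,
                     tissue = NA_character_, padj_cutoff = 0.001) {
  for (r in list(res_h_p1, res_h_p2, res_h_mpv)) {
    if (!all(deg_ids %in% r$group_id))
      stop("companion comparison is missing result rows for some DEGs")
  }
  if (length(deg_ids) == 0) {
    return(data.frame(group_id = character(), tissue = character(),
                      category = character(), hybrid_vs_p1 = character(),
                      hybrid_vs_p2 = character(), hybrid_vs_mpv = character(),
                      hybrid_mean = numeric(), parent1_mean = numeric(),
                      parent2_mean = numeric(), mpv = numeric(),
                      stringsAsFactors = FALSE))
  }
  i1 <- match(deg_ids, res_h_p1$group_id)
  i2 <- match(deg_ids, res_h_p2$group_id)
  im <- match(deg_ids, res_h_mpv$group_id)
  o1 <- de_outcome(res_h_p1, padj_cutoff)[i1]
  o2 <- de_outcome(res_h_p2, padj_cutoff)[i2]
  om <- de_outcome(res_h_mpv, padj_cutoff)[im]

  category <- rep("ambiguous", length(deg_ids))
  category[o1 == "sig_up" & o2 == "sig_up"] <- "F1d_over"
  category[o1 == "sig_down" & o2 == "sig_down"] <- "F1d_under"
  category[o1 == "ns" & o2 != "ns"] <- "F1b_P1"
  category[o2 == "ns" & o1 != "ns"] <- "F1b_P2"
  between <- (o1 == "sig_up" & o2 == "sig_down") |
             (o1 == "sig_down" & o2 == "sig_up")
  category[between & om == "ns"] <- "F1a"
  category[between & om != "ns"] <- "F1c"

  data.frame(group_id = deg_ids,
             tissue = tissue,
             category = category,
             hybrid_vs_p1 = o1,
             hybrid_vs_p2 = o2,
             hybrid_vs_mpv = om,
             hybrid_mean = res_h_p1$base_mean_b[i1],
             parent1_mean = res_h_p1$base_mean_a[i1],
             parent2_mean = res_h_p2$base_mean_a[i2],
             mpv = res_h_mpv$base_mean_a[im],
             stringsAsFactors = FALSE)
}

#' Classify DEGs across tissues and build a deduplicated overall set
#'
#' Runs [classify()] per tissue and adds an `Overall` set: the union of the
#' per-tissue calls deduplicated by group id. A group classified in several
#' tissues with conflicting categories is counted once under the first
#' tissue in `priority` (the flower being the phenotype of interest,
#' corollas take precedence by default) and flagged in `conflict`.
#'
#' @param de_by_tissue named list (one element per tissue), each holding
#'   `p2_vs_p1`, `h_vs_p1`, `h_vs_p2`, `h_vs_mpv` [test_de()] results.
#' @param padj_cutoff companion-comparison significance cutoff.
#' @param priority tissue order for overall deduplication.
#' @return list: `calls` (per-tissue rows), `overall` (deduplicated, with a
#'   `conflict` flag).
#' @export
classify_all <- function(de_by_tissue, padj_cutoff = 0.001,
                         priority = c("corolla", "leaf")) {
  need <- c("p2_vs_p1", "h_vs_p1", "h_vs_p2", "h_vs_mpv")
  calls <- lapply(names(de_by_tissue), function(tt) {
    de <- de_by_tissue[[tt]]
    miss <- setdiff(need, names(de))
    if (length(miss))
      stop("tissue '", tt, "' is missing comparison(s): ",
           paste(miss, collapse = ", "))
    entry <- de$p2_vs_p1$group_id[de$p2_vs_p1$is_deg]
    classify(entry, de$h_vs_p1, de$h_vs_p2, de$h_vs_mpv,
             tissue = tt, padj_cutoff = padj_cutoff)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls) || nrow(calls) == 0)
    return(list(calls = calls, overall = calls))

  tissues <- unique(calls$tissue)
  ord <- c(intersect(priority, tissues), setdiff(tissues, priority))
  dd <- calls[order(match(calls$tissue, ord)), , drop = FALSE]
  n_cat <- tapply(dd$category, dd$group_id, function(x) length(unique(x)))
  dd <- dd[!duplicated(dd$group_id), , drop = FALSE]
  dd$conflict <- as.vector(n_cat[dd$group_id] > 1)
  rownames(dd) <- NULL
  list(calls = calls, overall = dd)
}
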