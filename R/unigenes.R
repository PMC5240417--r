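#' Select representative unigenes from a transcript cluster table
#'
#' Applies the two retention rules used for de novo assemblies: a transcript
#' is kept iff its FPKM is strictly greater than `fpkm_cutoff` OR it has
#' ortholog evidence in another species. One representative then survives per
#' cluster: in clusters with ortholog-flagged retained transcripts, the
#' longest ortholog-flagged transcript; otherwise the longest retained
#' transcript (alternative splicing collapses to the longest isoform). Ties
#' on length break to the lexicographically smallest transcript_id, so the
#' selection is deterministic. Clusters with no retained transcript are
#' dropped.
#'
#' @param records data frame with columns `cluster_id`, `transcript_id`,
#'   `length_bp`, `fpkm`, `has_ortholog` (one species per call).
#' @param fpkm_cutoff strict FPKM threshold (default 2: FPKM exactly 2 is
#'   excluded).
#' @return data frame (one row per surviving cluster): `cluster_id`,
#'   `transcript_id`, `length_bp`, `fpkm`, `has_ortholog`.
#' @export
select_unigenes <- function(records, fpkm_cutoff = 2) {
  need <- c("cluster_id", "transcript_id", "length_bp", "fpkm", "has_ortholog")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) stop("records must be non-empty")
  if (anyDuplicated(records$transcript_id))
    stop("duplicate transcript_id in records: ",
         records$transcript_id[duplicated(records$transcript_id)][1])
  if (any(records$length_bp < 1)) stop("length_bp must be >= 1")
  if (any(records$fpkm < 0)) stop("fpkm must be >= 0")

  kept <- records[records$fpkm > fpkm_cutoff | records$has_ortholog, ,
                  drop = FALSE]
  if (nrow(kept) == 0)
    return(kept[, need])
  pick <- function(d) {
    cand <- if (any(d$has_ortholog)) d[d$has_ortholog, , drop = FALSE] else d
    cand <- cand[order(-cand$length_bp, cand$transcript_id), , drop = FALSE]
    cand[1, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(kept, kept$cluster_id), pick))
  out <- out[order(out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, need]
}

#' Compute the N50 of a set of contig lengths
#'
#' The N50 is the length L such that contigs of length >= L account for at
#' least half of the total assembly length (cumulative sum over the lengths
#' sorted in descending order).
#'
#' @param lengths positive integer vector.
#' @return a single length (same units as input).
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) stop("lengths must be non-empty")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' Summarize an assembled unigene set
#'
#' @param unigenes result of [select_unigenes()].
#' @param sequences optional named character vector of unigene sequences
#'   (names = transcript_id); GC content is reported only when given.
#' @return one-row data frame: number of unigenes, total and mean length,
#'   N50, and GC percentage (NA without sequences).
#' @export
assembly_summary <- function(unigenes, sequences = NULL) {
  if (nrow(unigenes) == 0) stop("unigene set is empty")
  gc <- NA_real_
  if (!is.null(sequences)) {
    s <- toupper(paste(sequences[unigenes$transcript_id], collapse = ""))
    bases <- strsplit(s, "")[[1]]
    gc <- 100 * sum(bases %in% c("G", "C")) / sum(bases %in% c("A", "C", "G", "T"))
  }
  data.frame(n_unigenes = nrow(unigenes),
             total_length_bp = sum(as.numeric(unigenes$length_bp)),
             mean_length_bp = mean(unigenes$length_bp),
             n50_bp = compute_n50(unigenes$length_bp),
             gc_percent = gc)
}
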