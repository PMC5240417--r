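#' Read a gene-level count matrix from TSV
#'
#' First column is the gene identifier; remaining columns are samples.
#'
#' @param path TSV file path.
#' @return integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata (sample, species, tissue, replicate) from TSV
#' @param path TSV file path.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "species", "tissue", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a transcript table (cluster, transcript, length, FPKM, ortholog flag)
#' @param path TSV with columns cluster_id, transcript_id, length_bp, fpkm,
#'   has_ortholog.
#' @return data frame of transcript records.
#' @export
read_transcript_table <- function(path) {
  if (!file.exists(path)) stop("transcript table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cluster_id", "transcript_id", "length_bp", "fpkm", "has_ortholog")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("transcript table is missing column(s): ", paste(miss, collapse = ", "))
  df$has_ortholog <- as.logical(df$has_ortholog)
  df
}

#' Build a transcript table from a FASTA file plus an FPKM table
#'
#' Transcript lengths (and sequences, for GC content) come from the FASTA;
#' FPKM values from a two-column TSV (`transcript_id`, `fpkm`). Cluster
#' membership is parsed from Trinity-style identifiers (`<cluster>_i<k>`
#' suffix) unless a `cluster_map` is supplied.
#'
#' @param fasta path to an uncompressed FASTA of transcripts.
#' @param fpkm_path two-column TSV keyed by transcript_id.
#' @param cluster_map optional data frame (transcript_id, cluster_id).
#' @param ortholog_ids optional character vector of transcript_ids with
#'   ortholog evidence.
#' @return list: `records` (transcript table) and `sequences`
#'   (named character vector).
#' @export
read_transcripts_fasta <- function(fasta, fpkm_path, cluster_map = NULL,
                                   ortholog_ids = character()) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required to read FASTA input")
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- ids
  fp <- utils::read.delim(fpkm_path, stringsAsFactors = FALSE)
  fpkm <- setNames(as.numeric(fp[[2]]), fp[[1]])
  if (is.null(cluster_map)) {
    cl <- sub("_i\\d+$", "", ids)
  } else {
    cl <- cluster_map$cluster_id[match(ids, cluster_map$transcript_id)]
  }
  rec <- data.frame(cluster_id = cl, transcript_id = ids,
                    length_bp = Biostrings::width(seqs),
                    fpkm = unname(fpkm[ids]),
                    has_ortholog = ids %in% ortholog_ids,
                    stringsAsFactors = FALSE)
  if (anyNA(rec$fpkm))
    stop("FPKM value missing for ",
         sum(is.na(rec$fpkm)), " transcript(s)")
  list(records = rec, sequences = setNames(as.character(seqs), ids))
}

#' Read a pairwise ortholog map (species_a, gene_a, species_b, gene_b)
#' @param path 4-column TSV.
#' @return data frame of ortholog pairs.
#' @export
read_ortholog_pairs <- function(path) {
  if (!file.exists(path)) stop("ortholog pair file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_a", "gene_a", "species_b", "gene_b")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ortholog pair table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$species_a == df$species_b))
    stop("ortholog pairs must link two different species")
  df
}
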