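#' Build three-species ortholog groups from pairwise ortholog links
#'
#' Groups are the connected components of the pairwise ortholog graph over
#' the unigenes of the (up to three) species. Each group receives a universal
#' identifier and holds at most one gene per species: if a component contains
#' several genes of one species (many-to-many orthology), the
#' lexicographically first gene of that species is kept in the group and the
#' others are demoted to singleton groups, because downstream count
#' assignment needs exactly one expression value per species per group.
#' Unigenes untouched by any pair become singleton groups.
#'
#' @param pairs data frame of ortholog pairs (`species_a`, `gene_a`,
#'   `species_b`, `gene_b`); every gene must be present in `unigenes`.
#' @param unigenes named list (one element per species) of character vectors
#'   of unigene identifiers.
#' @return data frame: `group_id` plus one column per species holding the
#'   member unigene id or NA.
#' @export
build_groups <- function(pairs, unigenes) {
  species <- names(unigenes)
  if (is.null(species) || any(species == ""))
    stop("unigenes must be a named list (one element per species)")
  if (nrow(pairs) > 0) {
    bad <- !(pairs$species_a %in% species) | !(pairs$species_b %in% species)
    if (any(bad)) stop("ortholog pair references unknown species")
    for (i in seq_len(nrow(pairs))) {
      if (!(pairs$gene_a[i] %in% unigenes[[pairs$species_a[i]]]))
        stop("ortholog pair references unknown unigene: ", pairs$gene_a[i])
      if (!(pairs$gene_b[i] %in% unigenes[[pairs$species_b[i]]]))
        stop("ortholog pair references unknown unigene: ", pairs$gene_b[i])
    }
  }
  node <- function(sp, g) paste0(sp, "\r", g)
  all_nodes <- unlist(lapply(species, function(sp) node(sp, unigenes[[sp]])))
  memb <- if (nrow(pairs) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = node(pairs$species_a, pairs$gene_a),
                 to = node(pairs$species_b, pairs$gene_b)),
      directed = FALSE,
      vertices = data.frame(name = all_nodes))
    igraph::components(g)$membership[all_nodes]
  } else {
    setNames(seq_along(all_nodes), all_nodes)
  }

  parts <- strsplit(names(memb), "\r", fixed = TRUE)
  node_sp <- vapply(parts, `[`, "", 1L)
  node_gene <- vapply(parts, `[`, "", 2L)

  rows <- list()
  for (comp in split(seq_along(memb), memb)) {
    sp <- node_sp[comp]
    gene <- node_gene[comp]
    row <- setNames(rep(NA_character_, length(species)), species)
    for (s in unique(sp)) {
      genes_s <- sort(gene[sp == s])
      row[s] <- genes_s[1]
      for (extra in genes_s[-1]) {            # demote to singleton groups
        r2 <- setNames(rep(NA_character_, length(species)), species)
        r2[s] <- extra
        rows[[length(rows) + 1L]] <- r2
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  # deterministic group order/ids independent of graph internals
  tab <- tab[do.call(order, c(as.list(tab), list(na.last = TRUE))), ,
             drop = FALSE]
  tab <- cbind(group_id = sprintf("OG%06d", seq_len(nrow(tab))), tab)
  rownames(tab) <- NULL
  tab
}

#' Assemble a group-level count matrix across the three species
#'
#' Each group's row concatenates the member gene's counts from every
#' species' matrix; for species absent from the group (singletons in the
#' other species), all that species' sample columns are set to 0 — the
#' structural-zero convention for species-specific genes.
#'
#' @param groups group table from [build_groups()].
#' @param counts named list of per-species count matrices (names matching
#'   the group table's species columns; rownames = unigene ids).
#' @return integer matrix, groups x (all species' samples).
#' @export
counts_to_groups <- function(groups, counts) {
  species <- setdiff(names(groups), "group_id")
  miss <- setdiff(species, names(counts))
  if (length(miss))
    stop("no count matrix supplied for species: ", paste(miss, collapse = ", "))
  out <- NULL
  for (sp in species) {
    m <- counts[[sp]]
    member <- groups[[sp]]
    known <- is.na(member) | member %in% rownames(m)
    if (!all(known))
      stop("group member without counts in ", sp, ": ",
           member[!known][1])
    block <- matrix(0L, nrow(groups), ncol(m),
                    dimnames = list(groups$group_id, colnames(m)))
    hit <- !is.na(member)
    block[hit, ] <- m[member[hit], , drop = FALSE]
    out <- if (is.null(out)) block else cbind(out, block)
  }
  out
}

#' Tally the seven Venn regions of a three-species group table
#'
#' @param groups group table from [build_groups()].
#' @return named integer vector: one count per species-unique region, per
#'   pairwise-only overlap, the triple overlap, and `union` (= number of
#'   groups).
#' @export
venn_counts <- function(groups) {
  species <- setdiff(names(groups), "group_id")
  if (length(species) != 3)
    stop("venn_counts expects exactly three species columns")
  pres <- !is.na(as.matrix(groups[, species]))
  pat <- apply(pres, 1, function(x) paste(species[x], collapse = "+"))
  lab <- c(paste0(species, "_only"),
           paste(species[1], species[2], sep = "+"),
           paste(species[1], species[3], sep = "+"),
           paste(species[2], species[3], sep = "+"),
           "all_three")
  key <- c(species,
           paste(species[1], species[2], sep = "+"),
           paste(species[1], species[3], sep = "+"),
           paste(species[2], species[3], sep = "+"),
           paste(species, collapse = "+"))
  out <- setNames(integer(length(lab)), lab)
  tabs <- table(pat)
  for (i in seq_along(key))
    out[lab[i]] <- if (key[i] %in% names(tabs)) tabs[[key[i]]] else 0L
  c(out, union = nrow(groups))
}
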