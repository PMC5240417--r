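# Independent brute-force oracles. Each re-derives an expected result from
# first principles, deliberately sharing no code with the implementation.

# Literal re-application of the unigene retention rules, record by record.
oracle_select_unigenes <- function(records, fpkm_cutoff = 2) {
  survivors <- list()
  for (cl in unique(records$cluster_id)) {
    d <- records[records$cluster_id == cl, , drop = FALSE]
    keep <- logical(nrow(d))
    for (i in seq_len(nrow(d)))
      keep[i] <- (d$fpkm[i] > fpkm_cutoff) || d$has_ortholog[i]
    d <- d[keep, , drop = FALSE]
    if (nrow(d) == 0) next
    pool <- if (any(d$has_ortholog)) d[d$has_ortholog, , drop = FALSE] else d
    best <- pool[1, ]
    for (i in seq_len(nrow(pool))) {
      if (pool$length_bp[i] > best$length_bp ||
          (pool$length_bp[i] == best$length_bp &&
           pool$transcript_id[i] < best$transcript_id))
        best <- pool[i, ]
    }
    survivors[[cl]] <- best
  }
  out <- do.call(rbind, survivors)
  out[order(out$cluster_id), , drop = FALSE]
}

oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (L in s) {
    acc <- acc + L
    if (acc >= half) return(L)
  }
}

# Exhaustive BFS over the pairwise ortholog graph; returns a canonical
# signature (sorted members per component, components sorted).
oracle_components <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[[start]]) next
    queue <- start
    comp <- character()
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (seen[[v]]) next
      seen[[v]] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, adj[[v]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, `[`, "", 1L))]
}

# Hand-computed BH step-up: p(i) * m / i on the sorted values, then a
# cumulative minimum from the largest rank down.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided binomial conditional test (Poisson limit): given the total S,
# group A's sum is Binomial(S, SA / (SA + SB)); sum probabilities of splits
# as or less likely than the observed one.
oracle_binom_conditional <- function(ka, kb, sfa_sum, sfb_sum) {
  S <- ka + kb
  if (S == 0) return(1)
  pr <- dbinom(0:S, S, sfa_sum / (sfa_sum + sfb_sum))
  pobs <- pr[ka + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Exhaustive NB-convolution conditional test: builds each group's sum
# distribution by convolving the per-sample NB pmfs numerically (grid
# 0..S), then enumerates every split of the observed total.
oracle_nb_exact <- function(counts_a, counts_b, sf_a, sf_b, alpha) {
  S <- sum(counts_a) + sum(counts_b)
  if (S == 0) return(1)
  q <- S / (sum(sf_a) + sum(sf_b))
  grid <- 0:S
  pmf_one <- function(sf) {
    if (alpha == 0) dpois(grid, q * sf) else
      dnbinom(grid, mu = q * sf, size = 1 / alpha)
  }
  conv_group <- function(sf) {
    acc <- pmf_one(sf[1])
    for (j in seq_along(sf)[-1]) {
      nxt <- pmf_one(sf[j])
      out <- numeric(S + 1)
      for (s in grid)   # truncated convolution on 0..S
        out[s + 1] <- sum(acc[1:(s + 1)] * nxt[(s + 1):1])
      acc <- out
    }
    acc
  }
  pa <- conv_group(sf_a)
  pb <- conv_group(sf_b)
  joint <- pa * rev(pb)   # P(A = k) * P(B = S - k)
  pobs <- joint[sum(counts_a) + 1]
  min(1, sum(joint[joint <= pobs * (1 + 1e-7)]) / sum(joint))
}

# Direct median-of-ratios re-computation per its definition.
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  m <- counts[keep, , drop = FALSE]
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  sf <- apply(m, 2, function(col) median(col / geo))
  sf / prod(sf)^(1 / length(sf))
}

# Random transcript-cluster fixture spanning the retention boundary.
random_transcript_records <- function(n_clusters, seed) {
  set.seed(seed)
  k <- sample(1:4, n_clusters, replace = TRUE)
  cl <- rep(sprintf("c%04d", seq_len(n_clusters)), k)
  n <- length(cl)
  data.frame(cluster_id = cl,
             transcript_id = sprintf("t%05d", sample(n)),
             length_bp = sample(200:3000, n, replace = TRUE),
             fpkm = round(sample(c(runif(n, 0, 4), rep(2, n %/% 10)))[1:n], 3),
             has_ortholog = runif(n) < 0.3,
             stringsAsFactors = FALSE)
}

# Equal-share config used by the simulation-recovery checks.
recovery_config <- function(n_genes, replicates, seed,
                            dispersion = 0.05, lfc_min = 2, margin = 1) {
  sim_config(n_genes = n_genes, replicates_per_tissue = replicates,
             tissues = "leaf",
             mode_proportions = c(conserved = 0.10, F1a = 0.15, F1b_P1 = 0.15,
                                  F1b_P2 = 0.15, F1c = 0.15, F1d_over = 0.15,
                                  F1d_under = 0.15),
             singleton_fraction_per_species = 0,
             dispersion = dispersion, parental_log2fc_min = lfc_min,
             transgressive_margin_log2 = margin, seed = seed)
}

# Minimal test_de-shaped frame for driving classify() directly.
fake_de <- function(ids, padj, lfc, wald_only = FALSE) {
  data.frame(group_id = ids, comparison = "x",
             base_mean_a = 10, base_mean_b = 10 * 2^lfc,
             log2fc = lfc,
             p_exact = if (wald_only) NA_real_ else padj,
             p_wald = padj,
             padj_exact = if (wald_only) NA_real_ else padj,
             padj_wald = padj,
             is_deg = padj < 0.001 & abs(lfc) > 1,
             direction = ifelse(padj >= 0.001, "none",
                                ifelse(lfc > 0, "higher", "lower")),
             stringsAsFactors = FALSE)
}
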