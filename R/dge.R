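#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of the ratio of
#' that sample's count to the gene's geometric mean across samples, using
#' only genes with nonzero counts in every sample; factors are then rescaled
#' to have geometric mean 1.
#'
#' @param counts integer matrix, genes x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene has nonzero counts in all samples; supply a ",
         "pseudo-reference or filter samples")
  m <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  sf <- apply(m, 2, function(col) median(col / geo))
  sf / exp(mean(log(sf)))
}

#' Attach size factors to a count matrix
#'
#' @param counts integer matrix, genes x samples.
#' @param size_factors optional; estimated with [estimate_size_factors()]
#'   when missing.
#' @return a `normalized_counts` list: `counts`, `size_factors`, and the
#'   normalized matrix `normalized` (counts / size factor).
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (any(size_factors <= 0)) stop("size factors must be strictly positive")
  if (length(size_factors) != ncol(counts))
    stop("need one size factor per sample")
  names(size_factors) <- colnames(counts)
  structure(list(counts = counts,
                 size_factors = size_factors,
                 normalized = sweep(counts, 2, size_factors, "/")),
            class = "normalized_counts")
}

#' Method-of-moments NB dispersion with shrinkage
#'
#' Per gene, each design group with >= 2 replicates contributes a moment
#' estimate `(s^2 - mu) / mu^2` of the dispersion alpha (parameterization
#' `Var = mu + alpha mu^2`) computed on normalized counts; the per-gene
#' estimate pools groups weighted by their degrees of freedom and is floored
#' at 0. Gene-wise estimates at few replicates are noisy, so each is shrunk
#' toward the 10%-trimmed mean of all finite gene-wise estimates with weight
#' `1 / (mean replicates per group)` — the shrinkage vanishes as replication
#' grows.
#'
#' @param norm a [normalize_counts()] object.
#' @param groups list of sample index/name vectors, one per design group.
#' @return numeric vector of per-gene dispersions (>= 0).
#' @export
estimate_dispersion <- function(norm, groups) {
  if (!inherits(norm, "normalized_counts"))
    stop("norm must come from normalize_counts()")
  sizes <- lengths(groups)
  if (sum(sizes) < 2 || max(sizes) < 2)
    stop("dispersion estimation needs >= 2 replicates in some group")
  y <- norm$normalized
  raw_num <- rep(0, nrow(y))
  raw_den <- rep(0, nrow(y))
  for (g in groups) {
    if (length(g) < 2) next
    yg <- y[, g, drop = FALSE]
    mu <- rowMeans(yg)
    s2 <- apply(yg, 1, var)
    a <- (s2 - mu) / mu^2
    ok <- is.finite(a)
    w <- length(g) - 1
    raw_num[ok] <- raw_num[ok] + w * a[ok]
    raw_den[ok] <- raw_den[ok] + w
  }
  alpha_raw <- ifelse(raw_den > 0, pmax(0, raw_num / pmax(raw_den, 1)), NA_real_)
  fin <- is.finite(alpha_raw)
  prior <- if (any(fin)) mean(alpha_raw[fin], trim = 0.1) else 0
  w_shrink <- 1 / mean(sizes[sizes >= 2])
  alpha <- (1 - w_shrink) * alpha_raw + w_shrink * prior
  alpha[!fin] <- prior
  pmax(alpha, 0)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical BH: sort the m p-values ascending, multiply the i-th by m/i,
#' enforce monotonicity by a cumulative minimum from the largest down, and
#' cap at 1; the result is returned in the input order. NAs propagate.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv, decreasing = TRUE)
    adj <- pmin(1, cummin(m / (m:1) * pv[o]))
    out[ok] <- adj[order(o)]
  }
  out
}

# Moment-matched NB law for a group's count sum: mean q*sum(sf), and the
# size parameter reproducing Var = sum_j (q sf_j + alpha (q sf_j)^2).
.sum_nb_params <- function(q, sf, alpha) {
  mu <- q * sum(sf)
  list(mu = mu,
       size = if (alpha > 0) sum(sf)^2 / (alpha * sum(sf^2)) else Inf)
}

#' Exact conditional NB test for one gene
#'
#' Tests equality of the per-unit-size-factor mean between two groups by
#' conditioning on the total count. Under the null the two group sums are
#' independent (moment-matched) negative binomials with common rate; the
#' two-sided p-value sums, over the lattice of splits of the observed total,
#' the joint probabilities no larger than that of the observed split,
#' normalized by the total lattice probability. With `alpha = 0` the sums
#' are Poisson and the conditional law is exactly binomial. Totals above
#' `max_total` switch to a normal approximation of the conditional law
#' (documented cutoff, default 10000).
#'
#' @param counts_a,counts_b raw counts of the gene in each group.
#' @param sf_a,sf_b size factors of the corresponding samples.
#' @param alpha NB dispersion (>= 0).
#' @param max_total largest total enumerated exactly.
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(counts_a, counts_b, sf_a, sf_b, alpha,
                          max_total = 10000) {
  if (any(c(counts_a, counts_b) < 0)) stop("counts must be non-negative")
  if (alpha < 0) stop("dispersion must be >= 0")
  ka <- sum(counts_a); kb <- sum(counts_b)
  S <- ka + kb
  if (S == 0) return(1)
  q <- S / (sum(sf_a) + sum(sf_b))
  pa <- .sum_nb_params(q, sf_a, alpha)
  pb <- .sum_nb_params(q, sf_b, alpha)
  if (S <= max_total) {
    k <- 0:S
    la <- if (is.finite(pa$size)) dnbinom(k, mu = pa$mu, size = pa$size, log = TRUE)
          else dpois(k, pa$mu, log = TRUE)
    lb <- if (is.finite(pb$size)) dnbinom(S - k, mu = pb$mu, size = pb$size, log = TRUE)
          else dpois(S - k, pb$mu, log = TRUE)
    lp <- la + lb
    lp <- lp - max(lp)
    pr <- exp(lp)
    pobs <- pr[ka + 1]
    min(1, sum(pr[pr <= pobs * (1 + 1e-7)]) / sum(pr))
  } else {
    va <- pa$mu + if (is.finite(pa$size)) pa$mu^2 / pa$size else 0
    vb <- pb$mu + if (is.finite(pb$size)) pb$mu^2 / pb$size else 0
    # conditional variance of the split given the total
    v <- va * vb / (va + vb)
    z <- (ka - pa$mu) / sqrt(v)
    min(1, 2 * pnorm(-abs(z)))
  }
}

# Variance of a group's normalized-count mean under NB sampling:
# Var(mean_j K_j / sf_j) = (1/n^2) sum_j (mu / sf_j + alpha mu^2).
.mean_var <- function(mu, sf, alpha) {
  (sum(mu / sf) + length(sf) * alpha * mu^2) / length(sf)^2
}

#' Two-group NB differential expression with dual-test consensus
#'
#' For every gene, computes the log2 fold change of group B over group A on
#' normalized means (pseudo-count 0.5 keeps structural-zero singleton groups
#' finite), an exact conditional NB p-value ([nb_exact_test()]) and a Wald
#' p-value on the log-mean difference with delta-method variances from NB
#' moments. Both p-value columns are BH-adjusted across genes, and a gene is
#' flagged `is_deg` only when **both** adjusted p-values fall below
#' `padj_cutoff` and |log2FC| exceeds `lfc_cutoff` — the dual-test consensus
#' rule.
#'
#' When `null_mean` is supplied (testing the hybrid against the fixed
#' mid-parent value), the null for group B is that per-gene mean, only the
#' Wald form applies (`p_exact` is NA), and `null_mean_var` (e.g. parental
#' estimation uncertainty, delta method) is added to the Wald variance;
#' `cols_a` may then be NULL.
#'
#' @param norm a [normalize_counts()] object covering both groups' samples.
#' @param alpha per-gene NB dispersion (scalar recycled).
#' @param cols_a,cols_b column names/indices of the two groups (A is the
#'   baseline).
#' @param comparison label stored in the result.
#' @param null_mean optional per-gene null mean for group B (fixed-null
#'   Wald test).
#' @param null_mean_var optional per-gene variance of `null_mean`.
#' @param padj_cutoff,lfc_cutoff DEG thresholds (defaults 0.001 and 1).
#' @param pseudo_count pseudo-count on normalized means for the fold change.
#' @param max_total exact-test enumeration cutoff, see [nb_exact_test()].
#' @return data frame, one row per gene: `group_id`, `comparison`,
#'   `base_mean_a`, `base_mean_b`, `log2fc`, `p_exact`, `p_wald`,
#'   `padj_exact`, `padj_wald`, `is_deg`, `direction` (of B relative to A).
#' @export
test_de <- function(norm, alpha, cols_a, cols_b, comparison = "B_vs_A",
                    null_mean = NULL, null_mean_var = NULL,
                    padj_cutoff = 0.001, lfc_cutoff = 1,
                    pseudo_count = 0.5, max_total = 10000) {
  if (!inherits(norm, "normalized_counts"))
    stop("norm must come from normalize_counts()")
  if (any(alpha < 0)) stop("dispersion must be >= 0")
  if (any(norm$counts < 0)) stop("counts must be non-negative")
  ng <- nrow(norm$counts)
  alpha <- rep_len(alpha, ng)
  yb <- norm$normalized[, cols_b, drop = FALSE]
  sfb <- norm$size_factors[cols_b]
  mb <- rowMeans(yb)
  vb <- vapply(seq_len(ng), function(i) .mean_var(mb[i], sfb, alpha[i]), 0)

  fixed_null <- !is.null(null_mean)
  if (fixed_null) {
    ma <- rep_len(null_mean, ng)
    va <- if (is.null(null_mean_var)) rep(0, ng) else rep_len(null_mean_var, ng)
    p_exact <- rep(NA_real_, ng)
  } else {
    ya <- norm$normalized[, cols_a, drop = FALSE]
    sfa <- norm$size_factors[cols_a]
    ma <- rowMeans(ya)
    va <- vapply(seq_len(ng), function(i) .mean_var(ma[i], sfa, alpha[i]), 0)
    ca <- norm$counts[, cols_a, drop = FALSE]
    cb <- norm$counts[, cols_b, drop = FALSE]
    p_exact <- vapply(seq_len(ng), function(i)
      nb_exact_test(ca[i, ], cb[i, ], sfa, sfb, alpha[i],
                    max_total = max_total), 0)
  }

  log2fc <- log2((mb + pseudo_count) / (ma + pseudo_count))
  # delta method on log scale; pseudo-count stabilizes zero means
  vl <- va / (ma + pseudo_count)^2 + vb / (mb + pseudo_count)^2
  z <- ifelse(vl > 0, (log(mb + pseudo_count) - log(ma + pseudo_count)) / sqrt(vl), 0)
  p_wald <- pmin(1, 2 * pnorm(-abs(z)))

  padj_exact <- adjust_bh(p_exact)
  padj_wald <- adjust_bh(p_wald)
  sig <- if (fixed_null) padj_wald < padj_cutoff
         else padj_exact < padj_cutoff & padj_wald < padj_cutoff
  is_deg <- sig & abs(log2fc) > lfc_cutoff
  direction <- ifelse(!sig, "none", ifelse(log2fc > 0, "higher", "lower"))

  data.frame(group_id = rownames(norm$counts),
             comparison = comparison,
             base_mean_a = ma, base_mean_b = mb,
             log2fc = log2fc,
             p_exact = p_exact, p_wald = p_wald,
             padj_exact = padj_exact, padj_wald = padj_wald,
             is_deg = is_deg, direction = direction,
             stringsAsFactors = FALSE)
}

#' Outcome of a companion comparison for inheritance classification
#'
#' Reduces a [test_de()] row to `sig_up` / `sig_down` / `ns` using the
#' dual-test adjusted-p rule (both `padj` below the cutoff; Wald alone for
#' fixed-null results) — deliberately **without** the |log2FC| gate, so that
#' "equals parent" / "equals MPV" judgments are not masked by fold-change
#' thresholds. Set `use_lfc_gate = TRUE` to restore the gate.
#'
#' @param res a [test_de()] result.
#' @param padj_cutoff adjusted-p threshold.
#' @param use_lfc_gate also require |log2FC| > `lfc_cutoff` for significance.
#' @param lfc_cutoff threshold used when `use_lfc_gate` is TRUE.
#' @return character vector in `sig_up`, `sig_down`, `ns`.
#' @export
de_outcome <- function(res, padj_cutoff = 0.001, use_lfc_gate = FALSE,
                       lfc_cutoff = 1) {
  sig <- ifelse(is.na(res$padj_exact), res$padj_wald < padj_cutoff,
                res$padj_exact < padj_cutoff & res$padj_wald < padj_cutoff)
  if (use_lfc_gate) sig <- sig & abs(res$log2fc) > lfc_cutoff
  ifelse(!sig, "ns", ifelse(res$log2fc > 0, "sig_up", "sig_down"))
}

#' Summarize DEG counts by direction per tissue plus a deduplicated overall row
#'
#' For each tissue, counts DEGs with the hybrid/second condition higher vs
#' lower, with percentages of the tissue's DEG total. The `Overall` row is
#' the union of the tissue DEG sets deduplicated by group id; a group called
#' in both tissues with conflicting directions is counted under the tissue
#' listed first in `priority`.
#'
#' @param results data frame binding [test_de()] rows with a `tissue` column.
#' @param priority tissue order used to resolve direction conflicts in the
#'   overall row.
#' @return data frame: tissue, n_higher, n_lower, pct_higher, pct_lower
#'   (2-decimal, round half away from zero; `NA` when a row has no DEGs).
#' @export
deg_summary <- function(results, priority = c("corolla", "leaf")) {
  if (!"tissue" %in% names(results))
    stop("results must carry a 'tissue' column")
  degs <- results[results$is_deg, , drop = FALSE]
  tissues <- unique(results$tissue)
  row_for <- function(label, d) {
    hi <- sum(d$direction == "higher"); lo <- sum(d$direction == "lower")
    tot <- hi + lo
    data.frame(tissue = label, n_higher = hi, n_lower = lo,
               pct_higher = if (tot > 0) percent(hi, tot) else NA_real_,
               pct_lower = if (tot > 0) percent(lo, tot) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(tissues, function(tt)
    row_for(tt, degs[degs$tissue == tt, , drop = FALSE])))
  ord <- c(intersect(priority, tissues), setdiff(tissues, priority))
  dd <- degs[order(match(degs$tissue, ord)), , drop = FALSE]
  dd <- dd[!duplicated(dd$group_id), , drop = FALSE]
  rbind(out, row_for("Overall", dd))
}
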