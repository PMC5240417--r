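#' Percentage with a fixed rounding contract
#'
#' `100 * count / denominator`, rounded to 2 decimals with ties going half
#' away from zero (so 0.125% prints as 0.13, not banker's 0.12). This is the
#' single rounding rule used by every summary table in the package.
#'
#' @param count non-negative numerator.
#' @param denominator positive denominator.
#' @param digits decimal places (default 2).
#' @return numeric percentage.
#' @export
percent <- function(count, denominator, digits = 2) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  round_half_away(100 * count / denominator, digits)
}

round_half_away <- function(x, digits = 2) {
  s <- 10^digits
  # nudge compensates for binary representation of exact .xx5 halves
  sign(x) * floor(abs(x) * s + 0.5 + sqrt(.Machine$double.eps)) / s
}

#' Inheritance-mode summary table
#'
#' Tabulates classification calls per tissue plus the deduplicated overall
#' row into the four-mode shape: additive (F1a), complete dominance toward
#' each parent (F1b), incomplete dominance (F1c) and transgressive over-
#' and under-dominance (F1d). `ambiguous` calls are excluded from the counts
#' and from the percentage denominator, which is the row's classified total.
#' All-zero rows are suppressed.
#'
#' @param calls result of [classify_all()] (or a compatible data frame of
#'   calls when `overall` is NULL).
#' @return data frame: tissue, n_total, one count and one percentage column
#'   per category.
#' @export
inheritance_table <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) {
    per_tissue <- calls$calls
    overall <- calls$overall
  } else {
    per_tissue <- calls
    overall <- NULL
  }
  cats <- c("F1a", "F1b_P1", "F1b_P2", "F1c", "F1d_over", "F1d_under")
  row_for <- function(label, d) {
    d <- d[d$category != "ambiguous", , drop = FALSE]
    n <- vapply(cats, function(cc) sum(d$category == cc), 0L)
    tot <- sum(n)
    if (tot == 0) return(NULL)
    out <- data.frame(tissue = label, n_total = tot, stringsAsFactors = FALSE)
    for (cc in cats) {
      out[[paste0("n_", cc)]] <- n[[cc]]
      out[[paste0("pct_", cc)]] <- percent(n[[cc]], tot)
    }
    out
  }
  rows <- lapply(unique(per_tissue$tissue), function(tt)
    row_for(tt, per_tissue[per_tissue$tissue == tt, , drop = FALSE]))
  if (!is.null(overall) && nrow(overall) > 0)
    rows <- c(rows, list(row_for("Overall", overall)))
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no classified (non-ambiguous) calls to tabulate")
  rownames(out) <- NULL
  out
}

#' Hybrid-specific unigene fraction from Venn region counts
#'
#' Share of ortholog groups found only in the hybrid, as a percentage of
#' the union of groups across the three assemblies.
#'
#' @param venn result of [venn_counts()] (expects a `hybrid_only` region and
#'   `union`).
#' @return percentage via [percent()].
#' @export
hybrid_specific_fraction <- function(venn) {
  if (!all(c("hybrid_only", "union") %in% names(venn)))
    stop("venn must contain 'hybrid_only' and 'union' counts")
  percent(venn[["hybrid_only"]], venn[["union"]])
}

#' Render a summary data frame as aligned plain text
#'
#' @param df any summary table from this package.
#' @return character vector of lines (also printed invisibly usable via
#'   `writeLines`).
#' @export
format_table <- function(df) {
  utils::capture.output(print(df, row.names = FALSE))
}
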