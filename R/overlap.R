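# Cross-study concordance: top-fraction overlap of two result sets, exact
# binomial sign tests on shared effect directions, and 2x2 Fisher
# enrichment of one gene set against another over a common universe.

#' Overlap of the top fraction of two association result sets
#'
#' Within each result set, genes are ranked by their best (minimum) p-value
#' across transcripts; the top `frac` of genes from each set are
#' intersected. The sign of the effect of the best transcript per gene is
#' carried along for downstream sign testing.
#'
#' @param results_a,results_b `data.frame`s with columns `gene_id`, `p`,
#'   `effect`.
#' @param frac Fraction of genes taken from the top of each ranking
#'   (default 0.05).
#' @return `data.frame` of overlapping genes with `sign_a`, `sign_b` and a
#'   `shared` flag. Empty when the intersection is empty.
#' @export
top_fraction_overlap <- function(results_a, results_b, frac = 0.05) {
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  top_genes <- function(res) {
    res <- res[!is.na(res$gene_id) & !is.na(res$p), , drop = FALSE]
    best <- do.call(rbind, lapply(split(res, res$gene_id), function(g) {
      g[which.min(g$p), c("gene_id", "p", "effect")]
    }))
    best <- best[order(best$p), , drop = FALSE]
    utils::head(best, ceiling(frac * nrow(best)))
  }
  ta <- top_genes(results_a)
  tb <- top_genes(results_b)
  shared <- intersect(ta$gene_id, tb$gene_id)
  if (!length(shared)) {
    return(data.frame(gene_id = character(), sign_a = numeric(),
                      sign_b = numeric(), shared = logical()))
  }
  sa <- sign(ta$effect[match(shared, ta$gene_id)])
  sb <- sign(tb$effect[match(shared, tb$gene_id)])
  data.frame(gene_id = shared, sign_a = sa, sign_b = sb,
             shared = sa == sb, row.names = NULL)
}

#' Exact one-sided binomial sign test
#'
#' Tests whether the number of overlapping genes sharing effect direction
#' exceeds the 50% expected under independence: upper-tail exact binomial
#' `p = P(X >= k | n, 1/2)`.
#'
#' @param n Number of overlapping genes (>= 1).
#' @param k Number sharing direction (0 <= k <= n).
#' @return List with `n`, `k`, `p`.
#' @export
sign_test <- function(n, k) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  p <- stats::pbinom(k - 1, size = n, prob = 0.5, lower.tail = FALSE)
  list(n = as.integer(n), k = as.integer(k), p = p)
}

#' 2x2 gene-set enrichment with Fisher's exact test
#'
#' Cross-classifies a gene universe by membership in a query set and a
#' target set: `a = |query & target|`, `b = |query \ target|`,
#' `c = |target \ query|`, `d` the rest. The enrichment odds ratio is
#' `ad / bc` (flagged infinite when `bc = 0`) and the p-value comes from the
#' two-sided Fisher exact test (minimum-likelihood method).
#'
#' @param query,target Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all eligible gene ids (non-empty).
#' @return List with `counts` (a, b, c, d), `odds_ratio`, `or_infinite`,
#'   `p`.
#' @export
gene_set_enrichment_2x2 <- function(query, target, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  target <- intersect(unique(target), universe)
  a <- length(intersect(query, target))
  b <- length(setdiff(query, target))
  c <- length(setdiff(target, query))
  d <- length(universe) - a - b - c
  or_inf <- (b * c) == 0 && (a * d) > 0
  or <- if (or_inf) Inf else if (a * d == 0 && b * c == 0) NA_real_ else
    (a * d) / (b * c)
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
  list(counts = c(a = a, b = b, c = c, d = d),
       odds_ratio = or, or_infinite = or_inf, p = p)
}
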