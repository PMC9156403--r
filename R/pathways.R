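# Marker-level circular-permutation gene-set enrichment. The null rotates
# the ordered top-marker indicator around the genome circle, preserving the
# local correlation structure among neighbouring markers and accounting for
# gene size (genes with more markers are more often hit in rotations too).
# Cramer's V on the gene-level 2x2 table (top gene x pathway membership) is
# the enrichment statistic; family-wise error control reuses the same
# rotations through the Westfall-Young max-statistic distribution.

#' Map markers to genes with an upstream promoter flank
#'
#' Gene intervals are extended by `upstream_flank` on the strand-aware
#' upstream side (before `start` on `+`, after `end` on `-`); a marker maps
#' to every gene whose extended interval contains its position, so one
#' marker may map to several overlapping genes and markers mapping nowhere
#' keep their place in the genomic order (they still occupy circle
#' positions).
#'
#' @param markers `data.frame` with columns `marker_id`, `chrom`, `pos`
#'   (0-based positions).
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open; strand `+` or `-`).
#' @param upstream_flank Bases added upstream (default 10 kb, i.e.
#'   promoters).
#' @return A `marker_gene_map`: markers in genomic order (chrom, pos), a
#'   marker-to-gene multimap, and the gene universe.
#' @export
map_markers_to_genes <- function(markers, genes, upstream_flank = 10000) {
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  }
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  ext_start <- ifelse(genes$strand == "+", genes$start - upstream_flank,
                      genes$start)
  ext_end <- ifelse(genes$strand == "+", genes$end,
                    genes$end + upstream_flank)
  gr_genes <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(ext_start, 0) + 1, end = ext_end))
  gr_mark <- GenomicRanges::GRanges(
    seqnames = markers$chrom,
    ranges = IRanges::IRanges(start = markers$pos + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(gr_mark, gr_genes)
  map <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits),
                      levels = seq_len(nrow(markers))))
  names(map) <- markers$marker_id
  structure(list(markers = markers,
                 marker_to_genes = lapply(map, unique),
                 gene_universe = unique(genes$gene_id)),
            class = "marker_gene_map")
}

#' Cramer's V for a 2x2 contingency table
#'
#' Closed form `|ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d))`, identical to
#' `sqrt(chi-squared / n)` for a 2x2 table; returns 0 when any margin is 0.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return V in \[0, 1\].
#' @export
cramers_v_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (sum(a, b, c, d) < 1) stop("need at least one observation")
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  abs(a * d - b * c) / sqrt(denom)
}

# Vectorised V over pathways: a = top-in-pathway counts, K = pathway sizes,
# T = number of top genes, G = universe size.
cramers_v_vec <- function(a, K, T, G) {
  b <- T - a; c <- K - a; d <- G - T - K + a
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  v <- abs(a * d - b * c) / sqrt(denom)
  v[denom == 0] <- 0
  v
}

#' Circular-permutation pathway enrichment
#'
#' Builds the binary top-marker vector in genomic order from the TWAS
#' results for one context (default top rule: q-value below `q_threshold`);
#' a gene is "top" iff at least one of its markers is top, each gene counted
#' once. For each pathway with at least `min_genes` genes in the universe,
#' the observed Cramer's V on the 2x2 table (top gene x pathway membership)
#' is compared to its distribution under `n_perm` random rotations of the
#' top-marker vector around the genome-wide circle (chromosomes concatenated
#' in sorted order; `per_chromosome = TRUE` rotates each chromosome
#' independently instead). The permutation p-value is the proportion of
#' rotations with V at least the observed value (ties count), floored at
#' `1/n_perm`; the FWER-adjusted p-value uses the max-V distribution across
#' tested pathways per rotation (Westfall-Young single-step), or Bonferroni
#' when `fwer_method = "bonferroni"`.
#'
#' @param twas_results `data.frame` of association results for one context
#'   with columns `transcript_id` (the marker id) and `q` (or `p`).
#' @param map A `marker_gene_map` from [map_markers_to_genes()]; every
#'   marker in `twas_results` must appear in it.
#' @param pathways A [pathway_db()].
#' @param q_threshold Top rule: marker is "top" iff q < this (default 0.1).
#' @param n_perm Number of rotations (default 10000).
#' @param min_genes Minimum pathway genes in the universe (default 3).
#' @param fwer_method `"westfall-young"` or `"bonferroni"`.
#' @param per_chromosome Rotate per chromosome instead of genome-wide.
#' @param alpha FWER significance level (default 0.05).
#' @param seed Integer seed for the rotation offsets.
#' @return `data.frame` per tested pathway: `pathway`, `n_genes`,
#'   `n_overlap`, `V`, `p`, `p_adj`, `significant`, plus `overlap_genes` as
#'   a list column and `cluster` (`NA` until [cluster_pathways()]).
#' @export
circular_permutation_enrichment <- function(twas_results, map, pathways,
                                            q_threshold = 0.1,
                                            n_perm = 10000, min_genes = 3,
                                            fwer_method = c("westfall-young",
                                                            "bonferroni"),
                                            per_chromosome = FALSE,
                                            alpha = 0.05, seed = 1L) {
  fwer_method <- match.arg(fwer_method)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value grid")
  mk <- map$markers$marker_id
  miss <- setdiff(twas_results$transcript_id, mk)
  if (length(miss)) {
    stop("markers missing from marker-gene map: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  qv <- twas_results$q[match(mk, twas_results$transcript_id)]
  top <- as.numeric(!is.na(qv) & qv < q_threshold)
  L <- length(top)

  universe <- map$gene_universe
  G <- length(universe)
  # sparse gene x marker incidence
  pairs <- data.frame(
    marker = rep(seq_len(L), lengths(map$marker_to_genes)),
    gene = match(unlist(map$marker_to_genes, use.names = FALSE), universe))
  M <- Matrix::sparseMatrix(i = pairs$gene, j = pairs$marker, x = 1,
                            dims = c(G, L))

  sets <- lapply(pathways$sets, function(g) intersect(g, universe))
  keep <- lengths(sets) >= min_genes
  skipped <- names(sets)[!keep & lengths(sets) == 0]
  if (length(skipped)) {
    warning("pathways with no genes in universe skipped: ",
            paste(utils::head(skipped, 3), collapse = ", "))
  }
  sets <- sets[keep]
  if (!length(sets)) {
    stop("no pathway has >= ", min_genes, " genes in the universe")
  }
  Pmat <- Matrix::sparseMatrix(
    i = match(unlist(sets, use.names = FALSE), universe),
    j = rep(seq_along(sets), lengths(sets)), x = 1,
    dims = c(G, length(sets)))
  K <- Matrix::colSums(Pmat)

  gene_top_counts <- function(tvec) {
    gt <- as.numeric(M %*% tvec > 0)
    a <- as.numeric(Matrix::crossprod(Pmat, gt))
    list(gt = gt, a = a, T = sum(gt))
  }
  obs <- gene_top_counts(top)
  V_obs <- cramers_v_vec(obs$a, K, obs$T, G)

  set.seed(seed)
  chrom_f <- factor(map$markers$chrom)
  ge <- matrix(0, nrow = n_perm, ncol = length(sets))   # counts V_perm >= V_obs
  maxV <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    if (per_chromosome) {
      rot <- top
      for (ch in levels(chrom_f)) {
        i <- which(chrom_f == ch)
        o <- sample.int(length(i), 1) - 1L
        rot[i] <- top[i][((seq_along(i) - 1L + o) %% length(i)) + 1L]
      }
    } else {
      o <- sample.int(L, 1) - 1L
      rot <- top[((seq_len(L) - 1L + o) %% L) + 1L]
    }
    pb <- gene_top_counts(rot)
    Vb <- cramers_v_vec(pb$a, K, pb$T, G)
    ge[b, ] <- Vb >= V_obs
    maxV[b] <- max(Vb)
  }
  p <- pmax(colMeans(ge), 1 / n_perm)
  p_adj <- if (fwer_method == "westfall-young") {
    pmax(vapply(V_obs, function(v) mean(maxV >= v), numeric(1)), 1 / n_perm)
  } else {
    pmin(1, p * length(sets))
  }
  p_adj <- pmax(p_adj, p)
  overlap <- lapply(seq_along(sets), function(j) {
    universe[as.logical(Pmat[, j]) & obs$gt > 0]
  })
  data.frame(pathway = names(sets), n_genes = as.integer(K),
             n_overlap = lengths(overlap), V = V_obs, p = p, p_adj = p_adj,
             significant = p_adj <= alpha,
             overlap_genes = I(overlap), cluster = NA_integer_,
             row.names = NULL)
}

#' Cluster enriched pathways by gene-set similarity
#'
#' Builds a graph with the significant pathways as nodes and edges weighted
#' by the Jaccard index of their gene sets when it reaches
#' `similarity_threshold`, then applies Louvain community detection.
#' Singleton pathways become singleton clusters.
#'
#' @param results Enrichment results (rows to cluster, typically the
#'   significant ones) from [circular_permutation_enrichment()].
#' @param pathways A [pathway_db()] with the gene sets.
#' @param similarity_threshold Minimum Jaccard index for an edge
#'   (default 0.25).
#' @param seed Integer seed for the (stochastic) Louvain refinement.
#' @return The `results` data.frame with the `cluster` column filled.
#' @export
cluster_pathways <- function(results, pathways, similarity_threshold = 0.25,
                             seed = 1L) {
  if (nrow(results) < 1) stop("need at least one pathway to cluster")
  ids <- results$pathway
  sets <- pathways$sets[ids]
  n <- length(ids)
  edges <- NULL
  w <- numeric()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        jac <- length(intersect(sets[[i]], sets[[j]])) /
          length(union(sets[[i]], sets[[j]]))
        if (jac >= similarity_threshold) {
          edges <- rbind(edges, c(i, j))
          w <- c(w, jac)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))
    igraph::E(g)$weight <- w
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(g)
  results$cluster <- igraph::membership(cl)
  results
}
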