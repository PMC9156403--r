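# Regulation (deQTL / meQTL / hormone) scan: does a marker act on case
# status through a differentially expressed transcript? The indirect effect
# is the average causal mediation effect (ACME) under a linear mediator
# model and a logistic outcome model, with quasi-Bayesian Monte Carlo
# inference: parameter vectors are drawn from each model's asymptotic normal
# sampling distribution and the ACME is recomputed per draw by averaging
# simulated potential outcomes over the observed sample. The null is
# H0: a x b = 0. The causal asymmetry is honoured: markers are never
# regressed on the mediator or the outcome.

#' Mediation scan specification
#'
#' @param marker_type `"snp"`, `"cpg"` or `"hormone"`.
#' @param cis_window Bases around the gene body within which a snp/cpg
#'   marker is a cis candidate (default 10 kb; ignored for hormones).
#' @param preselect_alpha Nominal case-status association threshold for
#'   candidate markers (default 0.05).
#' @param sims_schedule Monte Carlo draw counts, strictly increasing by a
#'   factor of 10 (default 1e3 to 1e6); when a p-value comes out exactly 0
#'   the test is rerun at the next schedule entry.
#' @param treat,control Marker values contrasted in the potential-outcome
#'   averages (default 1 and 0 copies for SNP dosage).
#' @param q_threshold Significance threshold on the q-value (default 0.1).
#' @param seed Integer seed.
#' @return A `mediation_spec` list.
#' @export
mediation_spec <- function(marker_type = c("snp", "cpg", "hormone"),
                           cis_window = 10000, preselect_alpha = 0.05,
                           sims_schedule = c(1e3, 1e4, 1e5, 1e6),
                           treat = 1, control = 0,
                           q_threshold = 0.1, seed = 1L) {
  marker_type <- match.arg(marker_type)
  if (preselect_alpha <= 0 || preselect_alpha >= 1) {
    stop("preselect_alpha must lie in (0, 1)")
  }
  if (length(sims_schedule) < 1 ||
      (length(sims_schedule) > 1 &&
       any(abs(diff(log10(sims_schedule)) - 1) > 1e-9))) {
    stop("sims_schedule must increase by factors of 10")
  }
  structure(list(marker_type = marker_type, cis_window = cis_window,
                 preselect_alpha = preselect_alpha,
                 sims_schedule = as.integer(sims_schedule),
                 treat = treat, control = control,
                 q_threshold = q_threshold, seed = as.integer(seed)),
            class = "mediation_spec")
}

#' Pre-select candidate (marker, gene) pairs
#'
#' Keeps markers with a nominal case-status association (OLS of the marker
#' value on case status, p below `preselect_alpha`). For snp/cpg markers a
#' candidate pair additionally requires the marker position to fall within
#' the gene body extended by the cis window on both sides (strand-agnostic);
#' hormones pass on the association criterion alone and pair with every
#' gene.
#'
#' @param marker_values Numeric matrix, markers x samples (rows named by
#'   marker id, columns by sample id).
#' @param marker_coords `data.frame` with `marker_id`, `chrom`, `pos`
#'   (0-based), or `NULL` for hormones.
#' @param pheno A [sample_table()].
#' @param genes `data.frame` of genes to pair with: `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param spec A [mediation_spec()].
#' @return `data.frame` of candidate pairs: `marker_id`, `gene_id`,
#'   `assoc_p`.
#' @export
preselect_markers <- function(marker_values, marker_coords = NULL, pheno,
                              genes, spec = mediation_spec()) {
  marker_values <- as.matrix(marker_values)
  idx <- match(colnames(marker_values), pheno$sample_id)
  if (anyNA(idx)) stop("marker samples missing from phenotype table")
  case <- as.numeric(pheno$case_status[idx])
  X <- cbind(`(Intercept)` = 1, case_status = case)
  fit <- fit_many_ols(X, marker_values)
  assoc_p <- fit$p[2, ]
  keep <- which(!is.na(assoc_p) & assoc_p < spec$preselect_alpha)
  if (!length(keep)) {
    return(data.frame(marker_id = character(), gene_id = character(),
                      assoc_p = numeric()))
  }
  ids <- rownames(marker_values)[keep]
  if (spec$marker_type == "hormone") {
    out <- expand.grid(marker_id = ids, gene_id = genes$gene_id,
                       stringsAsFactors = FALSE)
  } else {
    if (is.null(marker_coords)) {
      stop("marker coordinates required for snp/cpg markers")
    }
    co <- marker_coords[match(ids, marker_coords$marker_id), ]
    if (anyNA(co$marker_id)) stop("coordinates missing for some markers")
    gr_g <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = pmax(genes$start - spec$cis_window, 0) + 1,
                                end = genes$end + spec$cis_window))
    gr_m <- GenomicRanges::GRanges(
      seqnames = co$chrom,
      ranges = IRanges::IRanges(start = co$pos + 1, width = 1))
    hits <- GenomicRanges::findOverlaps(gr_m, gr_g)
    out <- data.frame(marker_id = ids[S4Vectors::queryHits(hits)],
                      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)])
  }
  out$assoc_p <- assoc_p[match(out$marker_id, rownames(marker_values))]
  rownames(out) <- NULL
  out
}

#' Quasi-Bayesian causal mediation test
#'
#' Fits the mediator model (linear: mediator ~ marker) and the outcome model
#' (logistic: outcome ~ mediator + marker), then draws parameter vectors
#' from each model's asymptotic normal sampling distribution. Per draw, the
#' ACME is the difference in average predicted outcome probability when the
#' mediator is set to its simulated potential value under the treat versus
#' control marker level (mediator prediction error included), averaged over
#' the observed sample and over the two treatment arms. The point estimate
#' is the mean of the draws; `p = 2 min(frac <= 0, frac >= 0)` (capped at
#' 1). When a tail fraction is exactly 0 the draw count escalates through
#' `spec$sims_schedule` (10-fold steps) until the p-value is resolvable or
#' the schedule is exhausted.
#'
#' @param marker Numeric vector of marker values (covariates already
#'   regressed out for snp/cpg/hormone data).
#' @param mediator Numeric vector of residualised transcript abundance.
#' @param outcome Binary case status (0/1), never residualised.
#' @param spec A [mediation_spec()].
#' @param seed Integer seed for the Monte Carlo draws.
#' @return One-row `data.frame`: `a`, `b`, `c_prime`, `acme`, `p`,
#'   `n_sims`, `converged`.
#' @export
mediation_test <- function(marker, mediator, outcome,
                           spec = mediation_spec(), seed = spec$seed) {
  if (stats::sd(mediator) == 0) stop("constant mediator")
  n <- length(marker)
  med_fit <- stats::lm(mediator ~ marker)
  a <- unname(stats::coef(med_fit)[2])
  sigma_m <- summary(med_fit)$sigma
  out_fit <- suppressWarnings(
    stats::glm(outcome ~ mediator + marker, family = stats::binomial()))
  bcoef <- stats::coef(out_fit)
  non_converged <- !out_fit$converged || any(abs(bcoef) > 15)
  if (non_converged) {
    return(data.frame(a = a, b = NA_real_, c_prime = NA_real_,
                      acme = NA_real_, p = NA_real_, n_sims = 0L,
                      converged = FALSE))
  }
  Va <- stats::vcov(med_fit)
  Vb <- stats::vcov(out_fit)
  ca <- stats::coef(med_fit)

  set.seed(seed)
  for (K in spec$sims_schedule) {
    draws <- acme_draws(K, ca, Va, sigma_m, bcoef, Vb,
                        spec$treat, spec$control)
    lo <- mean(draws <= 0)
    hi <- mean(draws >= 0)
    p <- min(1, 2 * min(lo, hi))
    if (p > 0) break
  }
  data.frame(a = a, b = unname(bcoef["mediator"]),
             c_prime = unname(bcoef["marker"]),
             acme = mean(draws), p = p, n_sims = K, converged = TRUE)
}

# Chunked quasi-Bayesian ACME draws (rows = draws). With covariates already
# residualised out of marker and mediator, the average of potential outcomes
# over the observed sample reduces to a one-dimensional Gaussian integral
# over the mediator prediction error; it is evaluated by deterministic
# quantile quadrature (equal-weight normal quantile nodes), which replaces
# the per-sample error simulation with a lower-variance approximation of the
# same quantity.
acme_draws <- function(K, coef_med, vcov_med, sigma_m, coef_out, vcov_out,
                       treat, control, nodes = 101L, chunk = 20000L) {
  z <- sigma_m * stats::qnorm((seq_len(nodes) - 0.5) / nodes)
  out <- numeric(K)
  done <- 0L
  while (done < K) {
    k <- min(chunk, K - done)
    A <- MASS::mvrnorm(k, coef_med, vcov_med)        # k x 2: (a0, a1)
    B <- MASS::mvrnorm(k, coef_out, vcov_out)        # k x 3: (b0, b_med, b_mark)
    if (k == 1) { A <- matrix(A, nrow = 1); B <- matrix(B, nrow = 1) }
    Z <- matrix(z, k, nodes, byrow = TRUE)
    L1 <- B[, 1] + B[, 2] * (A[, 1] + A[, 2] * treat + Z)    # k x nodes
    L0 <- B[, 1] + B[, 2] * (A[, 1] + A[, 2] * control + Z)
    bx <- B[, 3]
    acme_t <- rowMeans(stats::plogis(L1 + bx * treat) -
                         stats::plogis(L0 + bx * treat))
    acme_c <- rowMeans(stats::plogis(L1 + bx * control) -
                         stats::plogis(L0 + bx * control))
    out[(done + 1):(done + k)] <- (acme_t + acme_c) / 2
    done <- done + k
  }
  out
}

#' Run a full regulation (mediation) scan
#'
#' Pre-selects candidate (marker, gene) pairs, expands each pair to all
#' annotated transcripts of the gene with expression data, residualises
#' markers and transcript abundance on the covariates (case status is never
#' residualised), runs [mediation_test()] per (marker, transcript) pair, and
#' attaches Benjamini-Hochberg q-values over all tests in the scan.
#'
#' @param marker_values Numeric matrix, markers x samples.
#' @param marker_coords `data.frame` (`marker_id`, `chrom`, `pos`) or `NULL`
#'   for hormones.
#' @param expr An [expression_matrix()] (bulk abundance; the mediator for a
#'   transcript is its covariate-residualised bulk abundance).
#' @param pheno A [sample_table()].
#' @param de_genes Character vector of gene ids with a differentially
#'   expressed transcript; all annotated transcripts of these genes are
#'   tested.
#' @param covariates Covariate column names regressed out of markers and
#'   mediators before testing.
#' @param spec A [mediation_spec()].
#' @return `data.frame` per tested pair: `marker_id`, `transcript_id`,
#'   `gene_id`, `a`, `b`, `c_prime`, `acme`, `p`, `n_sims`, `q`,
#'   `significant`.
#' @export
run_regulation_scan <- function(marker_values, marker_coords = NULL, expr,
                                pheno, de_genes, covariates = character(),
                                spec = mediation_spec()) {
  ann <- expr$annotation
  genes <- unique(ann[!is.na(ann$gene_id) & ann$gene_id %in% de_genes,
                      c("gene_id", "chrom", "start", "end")])
  genes <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end))
  }))
  if (is.null(genes) || nrow(genes) == 0) {
    stop("no annotated genes among de_genes")
  }
  cand <- preselect_markers(marker_values, marker_coords, pheno, genes, spec)
  if (nrow(cand) == 0) {
    message("run_regulation_scan: no candidate markers pass pre-selection")
    return(data.frame())
  }
  idx <- match(colnames(marker_values), pheno$sample_id)
  ph <- pheno[idx, , drop = FALSE]
  samples <- colnames(marker_values)
  mk_res <- residualize_rows(marker_values, ph, covariates)
  ex <- expr$abundance[, samples, drop = FALSE]
  ex_res <- residualize_rows(ex, ph, covariates)
  outcome <- as.numeric(ph$case_status)

  tx_by_gene <- split(ann$transcript_id, ann$gene_id)
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(cand))) {
    txs <- intersect(tx_by_gene[[cand$gene_id[i]]], rownames(ex_res))
    for (tx in txs) {
      k <- k + 1L
      r <- mediation_test(mk_res[cand$marker_id[i], ], ex_res[tx, ], outcome,
                          spec, seed = spec$seed + k)
      rows[[k]] <- cbind(data.frame(marker_id = cand$marker_id[i],
                                    transcript_id = tx,
                                    gene_id = cand$gene_id[i]), r)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_qvalues(out$p)
  out$significant <- !is.na(out$q) & out$q < spec$q_threshold
  message(sprintf("run_regulation_scan: %d pairs tested, %d significant at q < %g",
                  nrow(out), sum(out$significant), spec$q_threshold))
  rownames(out) <- NULL
  out
}

# Regress covariates out of each row of a matrix (intercept included).
residualize_rows <- function(mat, pheno, covariates) {
  if (!length(covariates)) {
    return(mat - rowMeans(mat))
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(pheno)[, covariates, drop = FALSE]))
  t(stats::lm.fit(X, t(mat))$residuals)
}
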