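# Bulk and cell-type-specific TWAS. The cell-type model is the no-intercept
# proportion-interaction regression
#   Y_bulk = sum_c m_c P_c + sum_c m_c^case (case x P_c) + covariates + E,
# identifiable without a constant because the proportions sum to one. The
# interaction coefficient m_c^case is the case-control difference in the
# cell-type-c mean and is tested against zero with a t test on residual
# degrees of freedom. All transcripts share one design, so coefficients for
# the whole matrix come from a single QR decomposition.

#' TWAS model specification
#'
#' @param context `"bulk"` or `"celltype"`.
#' @param covariates Covariate column names in the sample table, entered as
#'   plain additive columns.
#' @param include_proportions_in_bulk Adjust the bulk model for cell
#'   proportions (one proportion column dropped against the intercept).
#' @param fdr_threshold Significance threshold on the q-value (default 0.1).
#' @param qvalue_method `"BH"` (default) or `"storey"`.
#' @return A `twas_spec` list.
#' @export
twas_spec <- function(context = c("celltype", "bulk"),
                      covariates = character(),
                      include_proportions_in_bulk = TRUE,
                      fdr_threshold = 0.1,
                      qvalue_method = c("BH", "storey")) {
  context <- match.arg(context)
  qvalue_method <- match.arg(qvalue_method)
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must lie in (0, 1)")
  }
  structure(list(context = context, covariates = covariates,
                 include_proportions_in_bulk = include_proportions_in_bulk,
                 fdr_threshold = fdr_threshold,
                 qvalue_method = qvalue_method),
            class = "twas_spec")
}

# Fit one design to every transcript at once; returns per-coefficient
# effect/SE/t/p matrices (coefficients x transcripts).
fit_many_ols <- function(X, Y) {
  n <- ncol(Y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]],
               collapse = ", "))
  }
  B <- qr.coef(qrX, t(Y))                       # p x nt
  res <- t(Y) - X %*% B
  df <- n - ncol(X)
  if (df <= 0) stop("not enough samples for the model (df <= 0)")
  sigma2 <- colSums(res^2) / df
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
  SE <- sqrt(outer(XtXinv_diag, sigma2))
  Tm <- B / SE
  P <- 2 * stats::pt(abs(Tm), df, lower.tail = FALSE)
  list(beta = B, se = SE, t = Tm, p = P, df = df)
}

#' Bulk whole-tissue TWAS
#'
#' Per transcript, OLS of abundance on case status, covariates and
#' (optionally) the cell proportions, with one proportion column dropped to
#' avoid collinearity with the intercept. Reports the case coefficient with
#' a two-sided t-test p-value and per-context q-values.
#'
#' @param expr An [expression_matrix()].
#' @param pheno A [sample_table()].
#' @param P A [cell_proportions()] or `NULL` to omit proportion adjustment.
#' @param spec A [twas_spec()].
#' @return `data.frame` with columns `transcript_id`, `gene_id`, `context`,
#'   `effect`, `se`, `t`, `p`, `q`.
#' @export
fit_bulk_twas <- function(expr, pheno, P = NULL, spec = twas_spec("bulk")) {
  idx <- match(colnames(expr$abundance), pheno$sample_id)
  if (anyNA(idx)) stop("expression samples missing from phenotype table")
  ph <- pheno[idx, , drop = FALSE]
  X <- build_design(ph, spec$covariates, intercept = TRUE)
  if (!is.null(P) && isTRUE(spec$include_proportions_in_bulk)) {
    Pm <- P$P[match(colnames(expr$abundance), rownames(P$P)), , drop = FALSE]
    if (anyNA(Pm)) stop("expression samples missing from proportions")
    X <- cbind(X, Pm[, -1, drop = FALSE])
  }
  fit <- fit_many_ols(X, expr$abundance)
  i <- which(colnames(X) == "case_status")
  p <- fit$p[i, ]
  data.frame(transcript_id = rownames(expr$abundance),
             gene_id = expr$annotation$gene_id,
             context = "bulk",
             effect = fit$beta[i, ], se = fit$se[i, ], t = fit$t[i, ],
             p = p, q = fdr_qvalues(p, method = spec$qvalue_method),
             row.names = NULL)
}

#' Cell-type-specific TWAS (no-intercept interaction model)
#'
#' Per transcript, OLS with no intercept of bulk abundance on the cell
#' proportions, the case-by-proportion interactions, and covariates. For
#' each cell type `c` the interaction coefficient estimates the case-control
#' difference of the cell-type-c mean; its two-sided t-test p-value tests
#' the null of equal means. q-values are computed within each cell type
#' separately. With a single cell type and P identically 1 the model
#' collapses exactly to the standard two-group comparison.
#'
#' @inheritParams fit_bulk_twas
#' @return `data.frame` with one row per transcript x cell type, columns
#'   `transcript_id`, `gene_id`, `context` (the cell type), `effect`, `se`,
#'   `t`, `p`, `q`. Interactions with near-zero variance (a cell type absent
#'   in all cases) are flagged untestable with `p = NA`.
#' @export
fit_celltype_twas <- function(expr, pheno, P, spec = twas_spec("celltype")) {
  idx <- match(colnames(expr$abundance), pheno$sample_id)
  if (anyNA(idx)) stop("expression samples missing from phenotype table")
  ph <- pheno[idx, , drop = FALSE]
  Pm <- P$P[match(colnames(expr$abundance), rownames(P$P)), , drop = FALSE]
  if (anyNA(Pm)) stop("expression samples missing from proportions")
  if (any(abs(rowSums(Pm) - 1) > 1e-6)) {
    stop("validation error: proportions must sum to 1 per sample")
  }
  nc <- ncol(Pm)
  n <- nrow(Pm)
  if (n <= 2 * nc + length(spec$covariates)) {
    stop("need n_samples > 2 * n_celltypes + n_covariates")
  }
  case <- as.numeric(ph$case_status)
  Xint <- Pm * case
  colnames(Xint) <- paste0("case:", colnames(Pm))
  X <- cbind(Pm, Xint)
  for (cv in spec$covariates) X <- cbind(X, stats::setNames(ph[[cv]], NULL))
  colnames(X) <- c(colnames(Pm), colnames(Xint), spec$covariates)
  untestable <- apply(Xint, 2, stats::sd) < 1e-10
  if (any(untestable)) {
    # drop degenerate interactions from the fit; they are reported as NA
    X <- X[, !(colnames(X) %in% colnames(Xint)[untestable]), drop = FALSE]
  }
  fit <- fit_many_ols(X, expr$abundance)
  nt <- nrow(expr$abundance)
  res <- vector("list", nc)
  for (c in seq_len(nc)) {
    ct <- colnames(Pm)[c]
    nm <- paste0("case:", ct)
    if (untestable[c]) {
      res[[c]] <- data.frame(transcript_id = rownames(expr$abundance),
                             gene_id = expr$annotation$gene_id,
                             context = ct, effect = NA_real_, se = NA_real_,
                             t = NA_real_, p = NA_real_, q = NA_real_,
                             row.names = NULL)
      next
    }
    i <- which(colnames(X) == nm)
    p <- fit$p[i, ]
    res[[c]] <- data.frame(transcript_id = rownames(expr$abundance),
                           gene_id = expr$annotation$gene_id,
                           context = ct,
                           effect = fit$beta[i, ], se = fit$se[i, ],
                           t = fit$t[i, ], p = p,
                           q = fdr_qvalues(p, method = spec$qvalue_method),
                           row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor lambda
#'
#' `lambda = median(qchisq(p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)`;
#' values near 1 indicate calibrated tests.
#'
#' @param pvalues Numeric vector of p-values in (0, 1\]; at least 100 finite
#'   values required.
#' @return Scalar lambda.
#' @export
compute_lambda <- function(pvalues) {
  p <- pvalues[is.finite(pvalues) & pvalues > 0 & pvalues <= 1]
  if (length(p) < 100) stop("need >= 100 finite p-values in (0, 1]")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' False-discovery-rate q-values
#'
#' Benjamini-Hochberg step-up q-values (monotone enforced) by default;
#' `method = "storey"` rescales them by a pi0 estimate from the smoother
#' method (natural cubic spline of pi0(lambda) evaluated at lambda = 0.9).
#' `NA` p-values propagate `NA` and do not count toward the number of tests.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param method `"BH"` or `"storey"`.
#' @return q-values, same length and order as the input.
#' @export
fdr_qvalues <- function(pvalues, method = c("BH", "storey")) {
  method <- match.arg(method)
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(pvalues))
  if (m == 0) return(q)
  o <- order(p, decreasing = TRUE)
  qo <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  qi <- numeric(m)
  qi[o] <- qo
  if (method == "storey") {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lam, pi0_l, df = 3)
    pi0 <- min(1, max(stats::predict(fit, x = 0.9)$y, 1 / m))
    qi <- pmin(1, qi * pi0)
  }
  q[ok] <- qi
  q
}

#' Permutation calibration of TWAS test statistics
#'
#' Shuffles case-control labels (covariates and proportions stay attached to
#' their samples), reruns the chosen TWAS, and summarises each permutation
#' by its genomic-inflation lambda. Average lambdas near 1 indicate no
#' test-statistic inflation under the empirical null.
#'
#' @inheritParams fit_bulk_twas
#' @param n_perm Number of label permutations.
#' @param seed Integer seed (recorded in the output).
#' @return List with `lambdas` (matrix, permutations x contexts),
#'   `mean_lambda`, and `seed`.
#' @export
permutation_calibration <- function(expr, pheno, P, spec = twas_spec("celltype"),
                                    n_perm = 10, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  contexts <- if (spec$context == "bulk") "bulk" else P$celltypes
  lambdas <- matrix(NA_real_, nrow = n_perm, ncol = length(contexts),
                    dimnames = list(NULL, contexts))
  for (b in seq_len(n_perm)) {
    ph <- pheno
    ph$case_status <- sample(ph$case_status)
    res <- if (spec$context == "bulk") {
      fit_bulk_twas(expr, ph, P, spec)
    } else {
      fit_celltype_twas(expr, ph, P, spec)
    }
    for (ctx in contexts) {
      lambdas[b, ctx] <- compute_lambda(res$p[res$context == ctx])
    }
  }
  list(lambdas = lambdas, mean_lambda = mean(lambdas), seed = seed)
}
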