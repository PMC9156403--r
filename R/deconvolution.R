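# Reference-based cell-type deconvolution of bulk methylation, plus
# case-control comparison and validation of estimated proportions.

#' Estimate cell-type proportions from bulk methylation
#'
#' Per sample, solves the constrained least-squares problem
#' min || m - R w ||^2 subject to w >= 0, sum(w) = 1, where R is the
#' reference panel restricted to CpGs shared with the bulk data. The default
#' estimator is non-negative least squares followed by renormalisation onto
#' the simplex; `method = "sum1"` instead enforces the sum-to-one constraint
#' inside the solve by augmenting the system with a heavily weighted
#' unit-sum row (a standard weighted formulation of equality-constrained
#' NNLS) — on well-conditioned references the two agree to numerical
#' precision.
#'
#' @param meth A [methylation_matrix()] of bulk betas.
#' @param ref A [reference_panel()].
#' @param method `"nnls"` (default) or `"sum1"`.
#' @return A [cell_proportions()] for all samples.
#' @export
estimate_proportions <- function(meth, ref, method = c("nnls", "sum1")) {
  method <- match.arg(method)
  shared <- intersect(rownames(meth$betas), rownames(ref$means))
  k <- ncol(ref$means)
  if (length(shared) < k) {
    stop("insufficient reference: only ", length(shared),
         " CpGs shared between methylation data and reference panel (need >= ",
         k, ")")
  }
  R <- ref$means[shared, , drop = FALSE]
  B <- meth$betas[shared, , drop = FALSE]
  if (method == "sum1") {
    lambda <- 1e3 * max(abs(R))
    R_aug <- rbind(R, lambda)
    P <- t(apply(B, 2, function(m) {
      w <- pracma::lsqnonneg(R_aug, c(m, lambda))$x
      w / sum(w)
    }))
  } else {
    P <- t(apply(B, 2, function(m) {
      w <- pracma::lsqnonneg(R, m)$x
      if (sum(w) == 0) w <- rep(1 / k, k) else w <- w / sum(w)
      w
    }))
  }
  dimnames(P) <- list(colnames(B), colnames(R))
  cell_proportions(P)
}

#' Compare cell proportions between cases and controls
#'
#' Per cell type, ordinary least squares of the proportion on case status
#' plus covariates. A positive coefficient means the proportion is higher in
#' cases.
#'
#' @param P A [cell_proportions()].
#' @param pheno A [sample_table()] aligned with `P` (matched by sample id).
#' @param covariates Character vector of covariate column names in `pheno`.
#' @return `data.frame` with one row per cell type: `celltype`, `beta`,
#'   `se`, `p`, and a `degenerate` flag for constant proportion columns.
#' @export
compare_proportions <- function(P, pheno, covariates = character()) {
  idx <- match(rownames(P$P), pheno$sample_id)
  if (anyNA(idx)) stop("samples in proportions not found in phenotype table")
  ph <- pheno[idx, , drop = FALSE]
  X <- build_design(ph, covariates, intercept = TRUE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]],
               collapse = ", "))
  }
  out <- lapply(colnames(P$P), function(ct) {
    y <- P$P[, ct]
    if (stats::sd(y) == 0) {
      return(data.frame(celltype = ct, beta = 0, se = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    }
    fit <- stats::lm.fit(X, y)
    stats_i <- ols_coef_stats(fit, X)
    i <- which(colnames(X) == "case_status")
    data.frame(celltype = ct, beta = stats_i$beta[i], se = stats_i$se[i],
               p = stats_i$p[i], degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Validate estimated proportions against truth or cell counts
#'
#' @param P_est A [cell_proportions()].
#' @param P_ref A [cell_proportions()] of ground truth, or a samples x
#'   cell-types matrix of (relative) cell counts with matching row/column
#'   names.
#' @return `data.frame` per cell type with Pearson and Spearman correlations.
#' @export
validate_proportions <- function(P_est, P_ref) {
  ref_mat <- if (inherits(P_ref, "cell_proportions")) P_ref$P else as.matrix(P_ref)
  shared <- intersect(rownames(P_est$P), rownames(ref_mat))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  cts <- intersect(colnames(P_est$P), colnames(ref_mat))
  out <- lapply(cts, function(ct) {
    x <- P_est$P[shared, ct]; y <- ref_mat[shared, ct]
    data.frame(celltype = ct,
               pearson = stats::cor(x, y),
               spearman = stats::cor(x, y, method = "spearman"))
  })
  do.call(rbind, out)
}

# Design matrix helpers shared with the TWAS module.
build_design <- function(pheno, covariates, intercept = TRUE) {
  miss <- setdiff(covariates, names(pheno))
  if (length(miss)) stop("covariates not in phenotype table: ",
                         paste(miss, collapse = ", "))
  X <- cbind(case_status = as.numeric(pheno$case_status))
  for (cv in covariates) X <- cbind(X, stats::setNames(pheno[[cv]], NULL))
  colnames(X) <- c("case_status", covariates)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

ols_coef_stats <- function(fit, X) {
  df <- length(fit$residuals) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df
  piv <- fit$qr$pivot
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- rep(NA_real_, ncol(X))
  se[piv[seq_len(fit$rank)]] <- sqrt(diag(XtXinv)[seq_len(fit$rank)] * sigma2)
  beta <- fit$coefficients
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = beta, se = se, t = tval, p = p, df = df)
}
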