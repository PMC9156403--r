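# Lightweight S3 containers with strict validation. Matrices are features x
# samples throughout; annotation rows align with matrix rows by position.

#' Construct an expression matrix with per-transcript annotation
#'
#' Container for transcript-level abundance (TPM-like, non-negative) together
#' with genomic coordinates, gene assignment and biotype per transcript.
#' Coordinates are stored 0-based half-open.
#'
#' @param abundance Numeric matrix, transcripts x samples; finite and >= 0.
#'   Row names are transcript ids, column names are sample ids.
#' @param annotation `data.frame` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`; one row per transcript in
#'   the same order as `abundance`. `gene_id` may be `NA` (unannotated).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(abundance, annotation) {
  abundance <- as.matrix(abundance)
  if (!is.numeric(abundance)) {
    stop("abundance must be numeric")
  }
  if (is.null(rownames(abundance))) {
    stop("abundance must carry transcript ids as row names")
  }
  if (anyDuplicated(rownames(abundance))) {
    stop("duplicate transcript ids in abundance")
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundance must be finite and non-negative")
  }
  need <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand",
            "biotype")
  missing_cols <- setdiff(need, names(annotation))
  if (length(missing_cols)) {
    stop("annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(annotation) != nrow(abundance) ||
      !identical(as.character(annotation$transcript_id), rownames(abundance))) {
    stop("annotation rows must match abundance rows (same transcript order)")
  }
  structure(list(abundance = abundance,
                 annotation = as.data.frame(annotation)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

#' Construct a sample phenotype/covariate table
#'
#' @param df `data.frame` with columns `sample_id` and `case_status`
#'   (binary 0 control / 1 case, no missing values); any further numeric
#'   columns are covariates or hormone measurements.
#' @return A `sample_table` (validated `data.frame`).
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("sample_id", "case_status") %in% names(df))) {
    stop("sample table needs 'sample_id' and 'case_status' columns")
  }
  if (anyNA(df$case_status) || !all(df$case_status %in% c(0, 1))) {
    stop("case_status must be 0/1 with no missing values")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Construct a CpG methylation beta matrix
#'
#' @param betas Numeric matrix, CpGs x samples, values in \[0, 1\].
#' @param coords `data.frame` with columns `cpg_id`, `chrom`, `pos`
#'   aligned with `betas` rows.
#' @return A `methylation_matrix`.
#' @export
methylation_matrix <- function(betas, coords) {
  betas <- as.matrix(betas)
  if (anyNA(betas) || any(betas < 0) || any(betas > 1)) {
    stop("methylation betas must lie in [0, 1]")
  }
  if (is.null(rownames(betas)) || anyDuplicated(rownames(betas))) {
    stop("betas must carry unique CpG ids as row names")
  }
  if (!all(c("cpg_id", "chrom", "pos") %in% names(coords)) ||
      nrow(coords) != nrow(betas) ||
      !identical(as.character(coords$cpg_id), rownames(betas))) {
    stop("coords must align with betas rows (cpg_id, chrom, pos)")
  }
  structure(list(betas = betas, coords = as.data.frame(coords)),
            class = "methylation_matrix")
}

#' Construct a genotype dosage matrix
#'
#' @param dosages Numeric matrix, SNPs x samples, allele dosages in \[0, 2\].
#' @param coords `data.frame` with columns `snp_id`, `chrom`, `pos` aligned
#'   with `dosages` rows.
#' @return A `genotype_matrix` carrying per-SNP minor-allele frequency.
#' @export
genotype_matrix <- function(dosages, coords) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages) || any(dosages < 0) || any(dosages > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  if (is.null(rownames(dosages)) || anyDuplicated(rownames(dosages))) {
    stop("dosages must carry unique SNP ids as row names")
  }
  if (!all(c("snp_id", "chrom", "pos") %in% names(coords)) ||
      nrow(coords) != nrow(dosages) ||
      !identical(as.character(coords$snp_id), rownames(dosages))) {
    stop("coords must align with dosages rows (snp_id, chrom, pos)")
  }
  af <- rowMeans(dosages) / 2
  maf <- pmin(af, 1 - af)
  structure(list(dosages = dosages, coords = as.data.frame(coords),
                 maf = maf),
            class = "genotype_matrix")
}

#' Construct a cell-type methylation reference panel
#'
#' Per-cell-type mean beta profiles used to estimate mixture proportions from
#' bulk methylation.
#'
#' @param means Numeric matrix, CpGs x cell types, values in \[0, 1\]; row
#'   names are CpG ids, column names are unique cell-type labels (>= 2).
#' @return A `reference_panel`.
#' @export
reference_panel <- function(means) {
  means <- as.matrix(means)
  if (ncol(means) < 2) stop("reference panel needs >= 2 cell types")
  if (is.null(colnames(means)) || anyDuplicated(colnames(means))) {
    stop("cell-type labels must be unique column names")
  }
  if (is.null(rownames(means)) || anyDuplicated(rownames(means))) {
    stop("reference CpG ids must be unique row names")
  }
  if (anyNA(means) || any(means < 0) || any(means > 1)) {
    stop("reference betas must lie in [0, 1]")
  }
  structure(list(means = means), class = "reference_panel")
}

#' Construct a cell-proportion matrix
#'
#' @param P Numeric matrix, samples x cell types; entries >= 0 and each row
#'   summing to 1 within 1e-8. Row names are sample ids, column names
#'   cell-type labels.
#' @return A `cell_proportions` object.
#' @export
cell_proportions <- function(P) {
  P <- as.matrix(P)
  if (any(P < -1e-12)) stop("cell proportions must be non-negative")
  P[P < 0] <- 0
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("cell-proportion rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  if (is.null(colnames(P))) stop("cell-type labels required as column names")
  structure(list(P = P, celltypes = colnames(P)), class = "cell_proportions")
}

#' @export
print.cell_proportions <- function(x, ...) {
  cat(sprintf("cell_proportions: %d samples x %d cell types (%s)\n",
              nrow(x$P), ncol(x$P), paste(x$celltypes, collapse = ", ")))
  invisible(x)
}

#' Construct a pathway database
#'
#' @param sets Named list mapping pathway id to a character vector of gene
#'   ids; sets must be non-empty, ids unique. Duplicate genes within a set
#'   are collapsed.
#' @param source Label for provenance (e.g. the GMT file name).
#' @return A `pathway_db`.
#' @export
pathway_db <- function(sets, source = "unknown") {
  if (length(sets) && anyDuplicated(names(sets))) {
    stop("duplicate pathway ids")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("empty gene set in pathway database")
  structure(list(sets = sets, source = source), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d gene sets (source: %s)\n",
              length(x$sets), x$source))
  invisible(x)
}
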