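# Readers/writers for the plain-text formats the pipeline touches, plus the
# transcript-level quality-control filter applied before association testing.
# Coordinates are 1-based inclusive on disk and 0-based half-open in memory.

read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("malformed matrix file (need id column + samples): ",
                         path)
  ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(dt[-1], is.numeric, logical(1)))[1]
    stop("parse error in ", path, ": non-numeric cell in column '",
         names(dt)[bad + 1], "'")
  }
  rownames(mat) <- ids
  mat
}

#' Read a transcript expression matrix and its annotation
#'
#' @param path TSV with transcript ids in column 1 and one column per sample.
#' @param annotation_path BED-like TSV with columns `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`, `gene_id`, `biotype` (coordinates 1-based
#'   inclusive; converted to 0-based half-open on ingest). Empty or "NA"
#'   gene ids are treated as unannotated.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, annotation_path) {
  mat <- read_feature_matrix(path)
  ann <- data.table::fread(annotation_path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("transcript_id", "chrom", "start", "end", "strand", "gene_id",
            "biotype")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  ann <- ann[match(rownames(mat), ann$transcript_id), ]
  if (anyNA(ann$transcript_id)) {
    stop("annotation missing transcripts present in the expression matrix")
  }
  ann$gene_id[!is.na(ann$gene_id) & ann$gene_id == ""] <- NA
  ann$start <- ann$start - 1L  # to 0-based half-open
  message(sprintf("read_expression: %d transcripts x %d samples",
                  nrow(mat), ncol(mat)))
  expression_matrix(mat, ann[, c("transcript_id", "gene_id", "chrom", "start",
                                 "end", "strand", "biotype")])
}

#' Read a methylation beta matrix with CpG coordinates
#'
#' @param path TSV with CpG ids in column 1, one column per sample; betas
#'   must lie in \[0, 1\].
#' @param coords_path TSV with columns `cpg_id`, `chrom`, `pos` (1-based).
#' @return A [methylation_matrix()].
#' @export
read_methylation <- function(path, coords_path) {
  mat <- read_feature_matrix(path)
  if (any(mat < 0 | mat > 1, na.rm = TRUE)) {
    bad <- which(mat < 0 | mat > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("validation error: beta outside [0,1] at row %d column %d",
                 bad[1], bad[2]))
  }
  co <- data.table::fread(coords_path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  co <- co[match(rownames(mat), co$cpg_id), ]
  if (anyNA(co$cpg_id)) stop("coordinates missing for some CpGs")
  co$pos <- co$pos - 1L
  message(sprintf("read_methylation: %d CpGs x %d samples",
                  nrow(mat), ncol(mat)))
  methylation_matrix(mat, co[, c("cpg_id", "chrom", "pos")])
}

#' Read genotype dosages from TSV (or a minimal VCF)
#'
#' The dosage TSV (SNP ids in column 1, samples in the header, values in
#' \[0,2\]) is the primary format. Files ending in `.vcf`/`.vcf.gz` are read
#' through the vcfR package instead: GT fields become allele counts and
#' missing genotypes are imputed to the per-SNP sample mean (logged).
#'
#' @param path Dosage TSV or VCF file.
#' @param coords_path TSV with columns `snp_id`, `chrom`, `pos` (1-based);
#'   ignored for VCF input, which carries its own coordinates.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, coords_path = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    return(read_genotypes_vcf(path))
  }
  mat <- read_feature_matrix(path)
  if (is.null(coords_path)) stop("coords_path required for dosage TSV input")
  co <- data.table::fread(coords_path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  co <- co[match(rownames(mat), co$snp_id), ]
  if (anyNA(co$snp_id)) stop("coordinates missing for some SNPs")
  co$pos <- co$pos - 1L
  message(sprintf("read_genotypes: %d SNPs x %d samples",
                  nrow(mat), ncol(mat)))
  genotype_matrix(mat, co[, c("snp_id", "chrom", "pos")])
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt))
  dimnames(dos) <- dimnames(gt)
  n_missing <- sum(is.na(dos))
  if (n_missing > 0) {
    message(sprintf("read_genotypes: imputing %d missing GT calls to SNP means",
                    n_missing))
    for (i in which(rowSums(is.na(dos)) > 0)) {
      dos[i, is.na(dos[i, ])] <- mean(dos[i, ], na.rm = TRUE)
    }
  }
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[is.na(ids) | ids == ".", "CHROM"],
                                         ":", fix[is.na(ids) | ids == ".", "POS"])
  rownames(dos) <- ids
  genotype_matrix(dos, data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                                  pos = as.integer(fix[, "POS"]) - 1L))
}

#' Read the sample phenotype/covariate table
#'
#' @param path TSV with columns `sample_id`, `case_status` and any number of
#'   numeric covariate/hormone columns.
#' @return A [sample_table()].
#' @export
read_phenotypes <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  message(sprintf("read_phenotypes: %d samples, %d columns", nrow(df), ncol(df)))
  sample_table(df)
}

#' Read a cell-type methylation reference panel
#'
#' @param path TSV with CpG ids in column 1 and one column per cell type.
#' @return A [reference_panel()].
#' @export
read_reference_panel <- function(path) {
  reference_panel(read_feature_matrix(path))
}

#' Read gene sets from a GMT file
#'
#' Broad dialect: one pathway per line, tab-separated fields
#' `pathway<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are collapsed to one.
#'
#' @param path GMT file.
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(pathway_db(list(), source = basename(path)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop("parse error in GMT line ", short[1], ": fewer than 3 fields")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  pathway_db(sets, source = basename(path))
}

#' Transcript quality-control filter
#'
#' Removes transcripts that are (in this order) depletion targets for
#' library preparation (rRNA biotype; globin genes), unannotated (missing
#' gene id), present in fewer than `min_presence_frac` of samples (presence
#' means abundance > 0; strict `<`), of mean TPM below `tpm_low` (low
#' expression outlier) or above `tpm_high` (high expression outlier). Rules
#' are applied sequentially; a transcript is attributed to the first rule
#' that removes it.
#'
#' @param expr An [expression_matrix()].
#' @param depletion_biotypes Biotypes treated as depletion targets.
#' @param depletion_genes Gene ids treated as depletion targets.
#' @param min_presence_frac Presence-fraction threshold (strict `<`).
#' @param tpm_low,tpm_high Mean-TPM bounds (strict `<` / `>`).
#' @return List with `expression` (filtered matrix) and `report`, a
#'   `data.frame` of transcripts removed per rule; rule counts sum to
#'   input minus output.
#' @export
transcript_qc_filter <- function(expr,
                                 depletion_biotypes = "rRNA",
                                 depletion_genes = c("HBA1", "HBA2", "HBB",
                                                     "HBD"),
                                 min_presence_frac = 0.01,
                                 tpm_low = 1, tpm_high = 20000) {
  ab <- expr$abundance
  ann <- expr$annotation
  keep <- rep(TRUE, nrow(ab))
  report <- data.frame(rule = c("depletion_target", "unannotated",
                                "low_presence", "low_mean_tpm",
                                "high_mean_tpm"),
                       removed = 0L)
  drop_rule <- function(flag, rule) {
    flag <- flag & keep
    report$removed[report$rule == rule] <<- sum(flag)
    keep <<- keep & !flag
  }
  depl <- ann$biotype %in% depletion_biotypes |
    (!is.na(ann$gene_id) & ann$gene_id %in% depletion_genes)
  drop_rule(depl, "depletion_target")
  drop_rule(is.na(ann$gene_id), "unannotated")
  presence <- rowMeans(ab > 0)
  drop_rule(presence < min_presence_frac, "low_presence")
  mean_tpm <- rowMeans(ab)
  drop_rule(mean_tpm < tpm_low, "low_mean_tpm")
  drop_rule(mean_tpm > tpm_high, "high_mean_tpm")
  if (!any(keep)) warning("all transcripts removed by QC")
  message(sprintf("transcript_qc_filter: %d in, %d out (%s)",
                  nrow(ab), sum(keep),
                  paste(sprintf("%s=%d", report$rule, report$removed),
                        collapse = ", ")))
  out <- expression_matrix(ab[keep, , drop = FALSE],
                           ann[keep, , drop = FALSE])
  list(expression = out, report = report)
}
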