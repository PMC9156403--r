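# Small fixture builders shared across test files. Everything is generated
# in code; no data files.

# tiny expression matrix with controllable annotation
make_expr <- function(abundance, gene_id = NULL, biotype = "protein_coding",
                      chrom = "chr1", strand = "+") {
  nt <- nrow(abundance)
  if (is.null(gene_id)) gene_id <- sprintf("G%03d", seq_len(nt))
  start <- seq(0, by = 10000, length.out = nt)
  expression_matrix(abundance,
                    data.frame(transcript_id = rownames(abundance),
                               gene_id = gene_id,
                               chrom = rep_len(chrom, nt),
                               start = start, end = start + 2000,
                               strand = rep_len(strand, nt),
                               biotype = rep_len(biotype, nt)))
}

make_pheno <- function(n, n_cases = floor(n / 2)) {
  sample_table(data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                          case_status = as.integer(seq_len(n) <= n_cases),
                          age = seq(20, 40, length.out = n)))
}

unit_props <- function(n, celltypes = "ALL") {
  P <- matrix(1, n, length(celltypes),
              dimnames = list(sprintf("S%04d", seq_len(n)), celltypes))
  cell_proportions(P / rowSums(P))
}

# marker/gene scaffold where marker i sits inside gene i (1:1), evenly
# spaced so markers are exchangeable under rotation
iid_marker_map <- function(n, spacing = 10000) {
  markers <- data.frame(marker_id = sprintf("M%04d", seq_len(n)),
                        chrom = "chr1",
                        pos = seq(500, by = spacing, length.out = n))
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n)), chrom = "chr1",
                      start = seq(0, by = spacing, length.out = n),
                      end = seq(0, by = spacing, length.out = n) + 2000,
                      strand = "+")
  map_markers_to_genes(markers, genes, upstream_flank = 0)
}

# brute-force upper-tail sign-test p by enumerating all 2^n sign vectors
sign_test_enum <- function(n, k) {
  counts <- vapply(0:(2^n - 1), function(x) {
    sum(bitwAnd(x, bitwShiftL(1, 0:(n - 1))) > 0)
  }, numeric(1))
  mean(counts >= k)
}

# hand Benjamini-Hochberg oracle (direct step-up definition)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(sapply(i:m, function(j) p[o[j]] * m / j))
  }
  pmin(q, 1)
}

# regulation-scan fixture: three planted SNP -> transcript -> case paths
# among 60 SNPs and 25 candidate genes; returns recovered/false pair counts
scan_one_seed <- function(s, planted_b = 0.9) {
  planted <- data.frame(snp = c(5, 12, 20), transcript = c(5, 12, 20))
  eq <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(snp = planted$snp[i], transcript = planted$transcript[i],
               celltype = 1:6, slope = 0.6)
  }))
  med <- data.frame(snp = planted$snp, transcript = planted$transcript,
                    b = planted_b, c_prime = 0.2)
  cfg <- simulation_config(n_samples = 500, n_cases = 250,
                           n_transcripts = 50, n_snps = 60,
                           eqtl_map = eq,
                           mediation_map = if (planted_b > 0) med else NULL,
                           seed = s)
  ds <- simulate_cohort(cfg)
  de <- sprintf("G%05d", 1:25)
  co <- ds$genotypes$coords
  scan <- suppressMessages(run_regulation_scan(
    ds$genotypes$dosages,
    data.frame(marker_id = co$snp_id, chrom = co$chrom, pos = co$pos),
    ds$expression, ds$phenotypes, de, covariates = "age",
    mediation_spec("snp", sims_schedule = c(1e3, 1e4), seed = s)))
  truth_pairs <- paste0(sprintf("SNP%05d", planted$snp), "_",
                        sprintf("TX%05d", planted$transcript))
  if (!nrow(scan)) return(c(rec = 0, fp = 0))
  sig <- scan[scan$significant, ]
  if (!nrow(sig)) return(c(rec = 0, fp = 0))
  pairs <- paste0(sig$marker_id, "_", sig$transcript_id)
  c(rec = sum(truth_pairs %in% pairs), fp = sum(!pairs %in% truth_pairs))
}
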