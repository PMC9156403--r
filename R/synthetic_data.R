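# Synthetic multi-omics cohort generator. Ground truth (cell-type case
# effects, eQTLs, mediation paths, reference-panel mixtures) is known by
# construction so every downstream stage can be validated end to end.

default_celltypes <- c("CD8T", "CD4T", "B", "Mono", "Gran", "NK")

#' Configuration for a synthetic multi-omics cohort
#'
#' Defines the generative model: Dirichlet cell-type proportions (optionally
#' shifted for cases), per-cell-type Gaussian transcript abundance on a
#' log2(TPM+1)-like scale, bulk expression as the proportion-weighted mixture
#' plus noise, cis-SNPs with per-cell-type eQTL slopes, mediation paths from
#' SNP through transcript to case status, bulk methylation as a mixture of a
#' cell-type reference panel, and hormone levels with optional case shifts.
#'
#' @param n_samples Number of samples.
#' @param n_cases Number of cases (expected count when `mediation_map` is
#'   non-empty; exact count otherwise).
#' @param celltype_names Cell-type labels (default the six blood cell types
#'   CD8T, CD4T, B, Mono, Gran, NK).
#' @param dirichlet_alpha Positive Dirichlet concentration per cell type for
#'   control samples; controls proportion means and variances.
#' @param prop_case_shift Additive shift on the Dirichlet mean proportions
#'   for cases (applied on the mean scale, then renormalised to the simplex
#'   at the same total concentration).
#' @param n_transcripts Number of transcripts.
#' @param effect_map `data.frame(transcript, celltype, effect)`: 1-based
#'   transcript index, cell-type index, and case effect in units of the
#'   within-cell-type SD (`within_sd`).
#' @param within_sd Within-cell-type SD of transcript abundance (per-sample
#'   deviations shared across cell types).
#' @param bulk_noise_sd SD of measurement noise added to the bulk mixture.
#' @param n_snps Number of SNPs.
#' @param maf_range Interval in (0, 0.5] from which per-SNP minor allele
#'   frequencies are drawn uniformly.
#' @param eqtl_map `data.frame(snp, transcript, celltype, slope)`: additive
#'   dosage effect on the transcript's mean in the given cell type.
#' @param mediation_map `data.frame(snp, transcript, b, c_prime)`: logit
#'   slope of the transcript (mediator) on case probability and direct logit
#'   slope of the SNP.
#' @param n_cpgs Number of CpGs in the methylation data and reference panel.
#' @param ref_noise_sd SD of Gaussian noise on bulk methylation betas
#'   (clipped to \[0,1\]).
#' @param hormone_spec `data.frame(hormone, mean, sd, case_shift)`.
#' @param seed Integer seed; identical configurations (including seed)
#'   reproduce the dataset exactly.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 200,
                              n_cases = floor(n_samples / 2),
                              celltype_names = default_celltypes,
                              dirichlet_alpha = rep(1, length(celltype_names)),
                              prop_case_shift = rep(0, length(celltype_names)),
                              n_transcripts = 200,
                              effect_map = NULL,
                              within_sd = 1,
                              bulk_noise_sd = 1,
                              n_snps = 0,
                              maf_range = c(0.1, 0.5),
                              eqtl_map = NULL,
                              mediation_map = NULL,
                              n_cpgs = 150,
                              ref_noise_sd = 0.02,
                              hormone_spec = default_hormone_spec(),
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_cases = as.integer(n_cases),
              celltype_names = as.character(celltype_names),
              dirichlet_alpha = as.numeric(dirichlet_alpha),
              prop_case_shift = as.numeric(prop_case_shift),
              n_transcripts = as.integer(n_transcripts),
              effect_map = if (!is.null(effect_map)) as.data.frame(effect_map),
              within_sd = within_sd,
              bulk_noise_sd = bulk_noise_sd,
              n_snps = as.integer(n_snps), maf_range = as.numeric(maf_range),
              eqtl_map = if (!is.null(eqtl_map)) as.data.frame(eqtl_map),
              mediation_map = if (!is.null(mediation_map)) as.data.frame(mediation_map),
              n_cpgs = as.integer(n_cpgs), ref_noise_sd = ref_noise_sd,
              hormone_spec = hormone_spec, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

default_hormone_spec <- function() {
  data.frame(hormone = c("estradiol", "progesterone", "oxytocin", "BDNF"),
             mean = c(50, 10, 20, 25), sd = c(15, 4, 6, 8),
             case_shift = c(0, 0, 0, 0))
}

validate_simulation_config <- function(cfg) {
  nc <- length(cfg$celltype_names)
  if (cfg$n_samples < 2 || cfg$n_cases < 0 || cfg$n_cases > cfg$n_samples) {
    stop("configuration error in field 'n_cases': need 0 <= n_cases <= n_samples")
  }
  if (length(cfg$dirichlet_alpha) != nc) {
    stop("configuration error in field 'dirichlet_alpha': length must equal number of cell types")
  }
  if (any(cfg$dirichlet_alpha <= 0)) {
    stop("configuration error in field 'dirichlet_alpha': must be strictly positive")
  }
  if (length(cfg$prop_case_shift) != nc) {
    stop("configuration error in field 'prop_case_shift': length must equal number of cell types")
  }
  if (cfg$bulk_noise_sd < 0 || cfg$ref_noise_sd < 0 || cfg$within_sd < 0) {
    stop("configuration error: noise SDs must be non-negative")
  }
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("configuration error in field 'maf_range': need interval within (0, 0.5]")
  }
  check_map <- function(map, cols, field) {
    if (is.null(map)) return(invisible(NULL))
    if (!all(cols %in% names(map))) {
      stop("configuration error in field '", field, "': needs columns ",
           paste(cols, collapse = ", "))
    }
    if (any(map$transcript < 1 | map$transcript > cfg$n_transcripts)) {
      stop("configuration error in field '", field, "': transcript index out of range")
    }
    if ("celltype" %in% cols && any(map$celltype < 1 | map$celltype > nc)) {
      stop("configuration error in field '", field, "': celltype index out of range")
    }
    if ("snp" %in% cols && any(map$snp < 1 | map$snp > cfg$n_snps)) {
      stop("configuration error in field '", field, "': snp index out of range")
    }
    invisible(NULL)
  }
  check_map(cfg$effect_map, c("transcript", "celltype", "effect"), "effect_map")
  check_map(cfg$eqtl_map, c("snp", "transcript", "celltype", "slope"), "eqtl_map")
  check_map(cfg$mediation_map, c("snp", "transcript", "b", "c_prime"),
            "mediation_map")
  invisible(cfg)
}

rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Non-overlapping feature coordinates on two synthetic chromosomes
# (0-based half-open internally). Transcripts occupy 2 kb bodies every 10 kb;
# SNPs and CpGs are placed inside the body of a host transcript (cycled) so
# that cis relationships exist by construction.
layout_transcripts <- function(n) {
  chrom <- rep(c("chr1", "chr2"), length.out = n)
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along) - 1L
  start <- idx * 10000L
  data.frame(chrom = chrom, start = start, end = start + 2000L,
             strand = rep(c("+", "-"), length.out = n))
}

layout_markers <- function(n_markers, tx_layout, offset) {
  if (n_markers == 0) {
    return(data.frame(chrom = character(), pos = integer()))
  }
  host <- ((seq_len(n_markers) - 1L) %% nrow(tx_layout)) + 1L
  cycle <- (seq_len(n_markers) - 1L) %/% nrow(tx_layout)
  data.frame(chrom = tx_layout$chrom[host],
             pos = tx_layout$start[host] + offset + 7L * cycle,
             host_transcript = host)
}

#' Simulate a synthetic multi-omics cohort with known ground truth
#'
#' Generates, in order: genotypes, case labels (deterministic split, or drawn
#' from the mediation logistic model when `mediation_map` is non-empty),
#' cell-type proportions, per-cell-type latent expression (case effects and
#' eQTL effects applied on the cell-type means), bulk expression as the
#' proportion-weighted mixture plus Gaussian noise, bulk methylation as the
#' mixture of a cell-type reference panel, and hormone levels.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_dataset` list with elements `expression`,
#'   `celltype_expression` (ground-truth latent matrices), `methylation`,
#'   `reference_panel`, `genotypes` (or `NULL`), `proportions_true`,
#'   `phenotypes`, and `truth` (the realised effect/eQTL/mediation maps and
#'   per-cell-type means).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  nc <- length(config$celltype_names)
  nt <- config$n_transcripts
  sample_ids <- sprintf("S%04d", seq_len(n))
  tx_ids <- sprintf("TX%05d", seq_len(nt))

  # --- genotypes ---------------------------------------------------------
  genotypes <- NULL
  G <- NULL
  snp_layout <- NULL
  tx_layout <- layout_transcripts(nt)
  if (config$n_snps > 0) {
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    G <- matrix(stats::rbinom(config$n_snps * n, 2, rep(maf, times = n)),
                nrow = config$n_snps)
    rownames(G) <- sprintf("SNP%05d", seq_len(config$n_snps))
    colnames(G) <- sample_ids
    snp_layout <- layout_markers(config$n_snps, tx_layout, offset = 500L)
  }

  # Per-sample transcript deviations, independent across cell types: each
  # cell type's expression varies on its own with SD `within_sd`.
  U_list <- lapply(seq_len(nc), function(c) {
    matrix(stats::rnorm(nt * n, sd = config$within_sd), nrow = nt,
           dimnames = list(tx_ids, sample_ids))
  })
  mu <- matrix(stats::rnorm(nt * nc, mean = 5, sd = 1.5), nrow = nt,
               dimnames = list(tx_ids, config$celltype_names))
  noise <- if (config$bulk_noise_sd > 0) {
    matrix(stats::rnorm(nt * n, sd = config$bulk_noise_sd), nrow = nt)
  } else {
    matrix(0, nt, n)
  }

  med <- config$mediation_map
  mediated <- !is.null(med) && nrow(med) > 0
  if (mediated && any(config$prop_case_shift != 0)) {
    stop("configuration error: prop_case_shift cannot be combined with ",
         "mediation_map (labels must depend on the mediator, not vice versa)")
  }

  # Per-cell-type expression without case effects (eQTL effects included);
  # case effects are layered on after labels exist.
  celltype_expr <- vector("list", nc)
  names(celltype_expr) <- config$celltype_names
  for (c in seq_len(nc)) {
    Yc <- matrix(mu[, c], nrow = nt, ncol = n) + U_list[[c]]
    qm <- config$eqtl_map
    if (!is.null(qm)) {
      for (r in which(qm$celltype == c)) {
        Yc[qm$transcript[r], ] <- Yc[qm$transcript[r], ] +
          qm$slope[r] * G[qm$snp[r], ]
      }
    }
    dimnames(Yc) <- list(tx_ids, sample_ids)
    celltype_expr[[c]] <- Yc
  }
  mix_bulk <- function(P) {
    bulk <- matrix(0, nrow = nt, ncol = n, dimnames = list(tx_ids, sample_ids))
    for (c in seq_len(nc)) {
      bulk <- bulk + sweep(celltype_expr[[c]], 2, P[, c], `*`)
    }
    bulk + noise
  }

  # --- case labels and proportions --------------------------------------
  alpha <- config$dirichlet_alpha
  a0 <- sum(alpha)
  if (mediated) {
    # labels drawn from the logistic model on the OBSERVED bulk mediator
    # (proportions first, from the common alpha; measurement noise included
    # so the planted slope b applies to the mediator the scan will use)
    P <- rdirichlet_mat(n, alpha)
    dimnames(P) <- list(sample_ids, config$celltype_names)
    bulk0 <- mix_bulk(P)
    eta <- rep(stats::qlogis(max(min(config$n_cases / n, 0.99), 0.01)), n)
    for (r in seq_len(nrow(med))) {
      m_obs <- bulk0[med$transcript[r], ]
      g <- G[med$snp[r], ]
      eta <- eta + med$b[r] * (m_obs - mean(m_obs)) +
        med$c_prime[r] * (g - mean(g))
    }
    case <- stats::rbinom(n, 1, stats::plogis(eta))
  } else {
    case <- as.integer(seq_len(n) <= config$n_cases)
    mean_case <- alpha / a0 + config$prop_case_shift
    if (any(mean_case <= 0)) {
      stop("configuration error in field 'prop_case_shift': shifted means must stay positive")
    }
    alpha_case <- a0 * mean_case / sum(mean_case)
    P <- rdirichlet_mat(n, alpha)
    if (any(case == 1) && any(config$prop_case_shift != 0)) {
      P[case == 1, ] <- rdirichlet_mat(sum(case == 1), alpha_case)
    }
    dimnames(P) <- list(sample_ids, config$celltype_names)
  }

  # --- case effects on cell-type means, then the bulk mixture ------------
  em <- config$effect_map
  if (!is.null(em)) {
    for (c in seq_len(nc)) {
      for (r in which(em$celltype == c)) {
        celltype_expr[[c]][em$transcript[r], case == 1] <-
          celltype_expr[[c]][em$transcript[r], case == 1] +
          em$effect[r] * config$within_sd
      }
    }
  }
  bulk <- mix_bulk(P)
  # abundance container requires non-negativity; the Gaussian scale sits
  # around 5 so shifting the rare negative tail to zero is inconsequential
  bulk[bulk < 0] <- 0

  annotation <- data.frame(transcript_id = tx_ids,
                           gene_id = sprintf("G%05d", seq_len(nt)),
                           chrom = tx_layout$chrom, start = tx_layout$start,
                           end = tx_layout$end, strand = tx_layout$strand,
                           biotype = "protein_coding")
  expr <- expression_matrix(bulk, annotation)

  # --- methylation -------------------------------------------------------
  cpg_ids <- sprintf("cg%06d", seq_len(config$n_cpgs))
  ref <- matrix(stats::rbeta(config$n_cpgs * nc, 1.5, 1.5),
                nrow = config$n_cpgs,
                dimnames = list(cpg_ids, config$celltype_names))
  M <- ref %*% t(P)
  if (config$ref_noise_sd > 0) {
    M <- M + matrix(stats::rnorm(length(M), sd = config$ref_noise_sd),
                    nrow = nrow(M))
  }
  M <- pmin(pmax(M, 0), 1)
  cpg_layout <- layout_markers(config$n_cpgs, tx_layout, offset = 1200L)
  meth <- methylation_matrix(M, data.frame(cpg_id = cpg_ids,
                                           chrom = cpg_layout$chrom,
                                           pos = cpg_layout$pos))

  # --- phenotypes --------------------------------------------------------
  pheno <- data.frame(sample_id = sample_ids, case_status = case)
  hs <- config$hormone_spec
  for (h in seq_len(nrow(hs))) {
    pheno[[hs$hormone[h]]] <- stats::rnorm(n, hs$mean[h] +
                                             hs$case_shift[h] * case, hs$sd[h])
  }
  pheno$age <- round(stats::rnorm(n, 30, 5), 1)

  geno <- NULL
  if (!is.null(G)) {
    geno <- genotype_matrix(G, data.frame(snp_id = rownames(G),
                                          chrom = snp_layout$chrom,
                                          pos = snp_layout$pos))
  }

  structure(list(expression = expr,
                 celltype_expression = celltype_expr,
                 methylation = meth,
                 reference_panel = reference_panel(ref),
                 genotypes = geno,
                 proportions_true = cell_proportions(P),
                 phenotypes = sample_table(pheno),
                 truth = list(effect_map = config$effect_map,
                              eqtl_map = config$eqtl_map,
                              mediation_map = config$mediation_map,
                              celltype_means = mu,
                              config = config)),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits TSV matrices (feature id in column 1, sample ids in the header), a
#' BED-like annotation table with 1-based inclusive coordinates, the
#' reference panel, the phenotype table, the true proportions and a truth
#' JSON with the realised effect maps. Reading the files back reproduces the
#' matrices exactly.
#'
#' @param ds A `synthetic_dataset`.
#' @param directory Output directory (created if absent).
#' @return Named character vector of written files (the manifest), invisibly
#'   also written as `manifest.tsv`.
#' @export
write_dataset <- function(ds, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  fp <- function(name) file.path(directory, name)
  write_feature_matrix(ds$expression$abundance, "transcript_id",
                       fp("expression.tsv"))
  ann <- ds$expression$annotation
  ann_out <- data.frame(transcript_id = ann$transcript_id, chrom = ann$chrom,
                        start = ann$start + 1L, end = ann$end,
                        strand = ann$strand, gene_id = ann$gene_id,
                        biotype = ann$biotype)
  data.table::fwrite(ann_out, fp("annotation.tsv"), sep = "\t")
  write_feature_matrix(ds$methylation$betas, "cpg_id", fp("methylation.tsv"))
  co <- ds$methylation$coords
  data.table::fwrite(data.frame(cpg_id = co$cpg_id, chrom = co$chrom,
                                pos = co$pos + 1L),
                     fp("methylation_coords.tsv"), sep = "\t")
  write_feature_matrix(ds$reference_panel$means, "cpg_id",
                       fp("reference_panel.tsv"))
  data.table::fwrite(as.data.frame(ds$phenotypes), fp("phenotypes.tsv"),
                     sep = "\t")
  write_feature_matrix(t(ds$proportions_true$P), "celltype",
                       fp("proportions_true.tsv"))
  files <- c(expression = "expression.tsv", annotation = "annotation.tsv",
             methylation = "methylation.tsv",
             methylation_coords = "methylation_coords.tsv",
             reference_panel = "reference_panel.tsv",
             phenotypes = "phenotypes.tsv",
             proportions_true = "proportions_true.tsv")
  if (!is.null(ds$genotypes)) {
    write_feature_matrix(ds$genotypes$dosages, "snp_id", fp("genotypes.tsv"))
    gc <- ds$genotypes$coords
    data.table::fwrite(data.frame(snp_id = gc$snp_id, chrom = gc$chrom,
                                  pos = gc$pos + 1L),
                       fp("genotype_coords.tsv"), sep = "\t")
    files <- c(files, genotypes = "genotypes.tsv",
               genotype_coords = "genotype_coords.tsv")
  }
  truth <- ds$truth[c("effect_map", "eqtl_map", "mediation_map")]
  jsonlite::write_json(truth, fp("truth.json"), dataframe = "columns",
                       digits = NA, null = "null")
  files <- c(files, truth = "truth.json")
  manifest <- data.frame(type = names(files), file = unname(files))
  data.table::fwrite(manifest, fp("manifest.tsv"), sep = "\t")
  stats::setNames(file.path(directory, files), names(files))
}

write_feature_matrix <- function(mat, id_col, path) {
  df <- data.frame(id = rownames(mat), as.data.frame(mat, optional = TRUE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
}
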