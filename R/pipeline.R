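# End-to-end orchestration: simulate (optional) -> transcript QC ->
# deconvolution -> bulk + cell-type TWAS -> pathway enrichment -> regulation
# scan -> overlap statistics. Every output file carries a header with the
# package version, a config hash and the seed; the manifest lists files with
# checksums. Stages remain independently invokable through their functions.

#' Load and validate a pipeline configuration
#'
#' @param config A named list or the path to a YAML file. Recognised
#'   top-level entries: `simulate` (arguments to [simulation_config()]) or
#'   `inputs` (paths: `expression`, `annotation`, `methylation`,
#'   `methylation_coords`, `reference_panel`, `phenotypes`, optional
#'   `genotypes`, `genotype_coords`, `gmt`), plus `out_dir`, `covariates`,
#'   `twas` (e.g. `fdr_threshold`), `pathways` (`n_perm`, `min_genes`,
#'   `flank`, `context`), `regulation` (`cis_window`, `max_sims`), `seed`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config error: 'out_dir' is required")
  if (is.null(config$simulate)) {
    need <- c("expression", "annotation", "methylation", "methylation_coords",
              "reference_panel", "phenotypes")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) {
      stop("config error: missing input paths: ", paste(miss, collapse = ", "))
    }
    for (f in unlist(config$inputs)) {
      if (!file.exists(f)) stop("config error: input file not found: ", f)
    }
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$covariates <- as.character(config$covariates %||% character())
  structure(config, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

write_stage_tsv <- function(df, path, meta) {
  con <- file(path, "w")
  writeLines(sprintf("# decontwas %s | config %s | seed %d",
                     meta$version, meta$hash, meta$seed), con)
  close(con)
  suppressWarnings(utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  path
}

#' Read a pipeline stage output TSV (skipping the metadata header)
#'
#' @param path File written by [run_pipeline()].
#' @return `data.frame`.
#' @export
read_stage_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage in order, each stage's output feeding the
#' next. Any stage failure aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param seed Optional override of the config seed.
#' @return `data.frame` manifest of output files with MD5 checksums (also
#'   written to `manifest.tsv` in `out_dir`).
#' @export
run_pipeline <- function(config, seed = NULL) {
  config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  meta <- list(version = as.character(utils::packageVersion("decontwas")),
               hash = config_hash(config), seed = config$seed)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # --- inputs ------------------------------------------------------------
  env <- new.env()
  stage("load", function() {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% config$seed
      cfg <- do.call(simulation_config, args)
      ds <- simulate_cohort(cfg)
      env$expr <- ds$expression; env$meth <- ds$methylation
      env$ref <- ds$reference_panel; env$pheno <- ds$phenotypes
      env$geno <- ds$genotypes; env$ds <- ds
    } else {
      inp <- config$inputs
      env$expr <- read_expression(inp$expression, inp$annotation)
      env$meth <- read_methylation(inp$methylation, inp$methylation_coords)
      env$ref <- read_reference_panel(inp$reference_panel)
      env$pheno <- read_phenotypes(inp$phenotypes)
      env$geno <- if (!is.null(inp$genotypes)) {
        read_genotypes(inp$genotypes, inp$genotype_coords)
      }
    }
    env$gmt <- if (!is.null(config$inputs$gmt)) read_gmt(config$inputs$gmt)
    invisible(NULL)
  })

  stage("qc", function() {
    qc <- transcript_qc_filter(env$expr)
    env$expr <- qc$expression
    outputs["qc_report"] <<- write_stage_tsv(qc$report,
                                             file.path(out_dir, "qc_report.tsv"),
                                             meta)
  })

  stage("deconvolve", function() {
    env$P <- estimate_proportions(env$meth, env$ref)
    outputs["proportions"] <<- write_stage_tsv(
      data.frame(sample_id = rownames(env$P$P), env$P$P, check.names = FALSE),
      file.path(out_dir, "proportions.tsv"), meta)
    cmp <- compare_proportions(env$P, env$pheno, config$covariates)
    outputs["proportion_differences"] <<- write_stage_tsv(
      cmp, file.path(out_dir, "proportion_differences.tsv"), meta)
  })

  stage("twas", function() {
    fdr <- config$twas$fdr_threshold %||% 0.1
    env$bulk_res <- fit_bulk_twas(env$expr, env$pheno, env$P,
                                  twas_spec("bulk", config$covariates,
                                            fdr_threshold = fdr))
    env$ct_res <- fit_celltype_twas(env$expr, env$pheno, env$P,
                                    twas_spec("celltype", config$covariates,
                                              fdr_threshold = fdr))
    outputs["twas_bulk"] <<- write_stage_tsv(
      env$bulk_res, file.path(out_dir, "twas_bulk.tsv"), meta)
    outputs["twas_celltype"] <<- write_stage_tsv(
      env$ct_res, file.path(out_dir, "twas_celltype.tsv"), meta)
  })

  stage("pathways", function() {
    if (is.null(env$gmt)) {
      message("no GMT configured; skipping pathway enrichment")
      return(invisible(NULL))
    }
    pw_cfg <- config$pathways %||% list()
    context <- pw_cfg$context %||% "B"
    res_ctx <- env$ct_res[env$ct_res$context == context, ]
    ann <- env$expr$annotation
    markers <- data.frame(marker_id = ann$transcript_id, chrom = ann$chrom,
                          pos = ann$start)
    genes <- unique(ann[!is.na(ann$gene_id),
                        c("gene_id", "chrom", "start", "end", "strand")])
    mgmap <- map_markers_to_genes(markers, genes,
                                  upstream_flank = pw_cfg$flank %||% 10000)
    enr <- circular_permutation_enrichment(
      res_ctx, mgmap, env$gmt,
      q_threshold = config$twas$fdr_threshold %||% 0.1,
      n_perm = pw_cfg$n_perm %||% 10000,
      min_genes = pw_cfg$min_genes %||% 3, seed = config$seed + 101L)
    if (any(enr$significant)) {
      enr[enr$significant, "cluster"] <-
        cluster_pathways(enr[enr$significant, ], env$gmt,
                         seed = config$seed + 102L)$cluster
    }
    env$enrichment <- enr
    outputs["pathway_enrichment"] <<- write_stage_tsv(
      enr[, setdiff(names(enr), "overlap_genes")],
      file.path(out_dir, "pathway_enrichment.tsv"), meta)
  })

  stage("regulation", function() {
    if (is.null(env$geno)) {
      message("no genotypes configured; skipping regulation scan")
      return(invisible(NULL))
    }
    fdr <- config$twas$fdr_threshold %||% 0.1
    de <- unique(env$ct_res$gene_id[!is.na(env$ct_res$q) &
                                      env$ct_res$q < fdr])
    de <- de[!is.na(de)]
    if (!length(de)) {
      message("no differentially expressed genes; skipping regulation scan")
      return(invisible(NULL))
    }
    reg_cfg <- config$regulation %||% list()
    sched <- c(1e3, 1e4, 1e5, 1e6)
    sched <- sched[sched <= (reg_cfg$max_sims %||% 1e6)]
    co <- env$geno$coords
    scan <- run_regulation_scan(
      env$geno$dosages,
      data.frame(marker_id = co$snp_id, chrom = co$chrom, pos = co$pos),
      env$expr, env$pheno, de, config$covariates,
      mediation_spec("snp", cis_window = reg_cfg$cis_window %||% 10000,
                     sims_schedule = sched, seed = config$seed + 201L))
    if (nrow(scan)) {
      outputs["regulation"] <<- write_stage_tsv(
        scan, file.path(out_dir, "regulation.tsv"), meta)
    }
    env$regulation <- scan
  })

  stage("overlap", function() {
    # cross-context concordance: bulk vs each cell type, top 5% by gene
    rows <- lapply(unique(env$ct_res$context), function(ctx) {
      ov <- top_fraction_overlap(env$bulk_res,
                                 env$ct_res[env$ct_res$context == ctx, ],
                                 frac = config$overlap$frac %||% 0.05)
      if (!nrow(ov)) {
        return(data.frame(context = ctx, n_overlap = 0L, n_shared = 0L,
                          sign_p = NA_real_))
      }
      st <- sign_test(nrow(ov), sum(ov$shared))
      data.frame(context = ctx, n_overlap = st$n, n_shared = st$k,
                 sign_p = st$p)
    })
    outputs["overlap"] <<- write_stage_tsv(
      do.call(rbind, rows), file.path(out_dir, "overlap.tsv"), meta)
  })

  manifest <- data.frame(output = names(outputs), file = unname(outputs),
                         md5 = unname(tools::md5sum(unname(outputs))))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest
}
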