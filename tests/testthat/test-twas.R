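test_that("bulk TWAS on one transcript equals the two-sample equal-variance t-test", {
  set.seed(1)
  n <- 60
  y <- matrix(rnorm(n, mean = 10), 1,
              dimnames = list("tx1", sprintf("S%04d", 1:n)))
  expr <- make_expr(y)
  pheno <- make_pheno(n)
  res <- fit_bulk_twas(expr, pheno, P = NULL, twas_spec("bulk"))
  tt <- t.test(y[1, pheno$case_status == 1], y[1, pheno$case_status == 0],
               var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$effect, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
})

test_that("single-cell-type interaction model collapses to the two-group comparison", {
  set.seed(2)
  n <- 80
  y <- matrix(rnorm(3 * n, mean = 5), 3,
              dimnames = list(paste0("tx", 1:3), sprintf("S%04d", 1:n)))
  expr <- make_expr(y)
  pheno <- make_pheno(n)
  res_ct <- fit_celltype_twas(expr, pheno, unit_props(n), twas_spec("celltype"))
  res_bulk <- fit_bulk_twas(expr, pheno, P = NULL, twas_spec("bulk"))
  expect_equal(res_ct$p, res_bulk$p, tolerance = 1e-10)
  expect_equal(res_ct$effect, res_bulk$effect, tolerance = 1e-10)
})

test_that("lambda oracles: uniform grid, scaled chi-square, and median identity", {
  n <- 1000
  p_grid <- (seq_len(n) - 0.5) / n
  expect_equal(compute_lambda(p_grid), 1, tolerance = 1e-3)

  chi <- qchisq(p_grid, df = 1, lower.tail = FALSE)
  p_scaled <- pchisq(2 * chi, df = 1, lower.tail = FALSE)
  expect_equal(compute_lambda(p_scaled), 2, tolerance = 1e-2)

  expect_equal(compute_lambda(rep(0.5, 150)), 1, tolerance = 1e-12)
  expect_error(compute_lambda(runif(50)), "100")
})

test_that("BH q-values match the hand oracle and p.adjust", {
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_qvalues(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  p <- runif(200)^2
  expect_equal(fdr_qvalues(p), bh_oracle(p), tolerance = 1e-12)
  expect_equal(fdr_qvalues(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  # NA propagation: NAs stay NA and do not count toward m
  pna <- c(0.01, NA, 0.04)
  expect_equal(fdr_qvalues(pna), c(0.02, NA, 0.04))
  # monotone in p
  o <- order(p)
  expect_true(all(diff(fdr_qvalues(p)[o]) >= -1e-15))
})

test_that("Storey q-values are BH rescaled by pi0 <= 1", {
  set.seed(4)
  p <- c(runif(900), rbeta(100, 0.2, 5))
  q_bh <- fdr_qvalues(p)
  q_st <- fdr_qvalues(p, method = "storey")
  expect_true(all(q_st <= q_bh + 1e-12))
  expect_true(all(q_st >= 0 & q_st <= 1))
})

test_that("a planted cell-type effect is localised with power and specificity", {
  hits <- sapply(1:20, function(s) {
    cfg <- simulation_config(
      n_samples = 600, n_cases = 300, n_transcripts = 100,
      effect_map = data.frame(transcript = 1, celltype = 3, effect = 3),
      seed = s)
    ds <- simulate_cohort(cfg)
    res <- fit_celltype_twas(ds$expression, ds$phenotypes,
                             ds$proportions_true)
    other <- res[!(res$context == "B" & res$transcript_id == "TX00001"), ]
    c(hit = res$q[res$context == "B" & res$transcript_id == "TX00001"] < 0.1,
      fp_frac = mean(other$q < 0.1, na.rm = TRUE))
  })
  expect_gte(mean(hits["hit", ]), 0.9)
  expect_lte(mean(hits["fp_frac", ]), 0.01)
})

test_that("interaction estimates are unbiased for the planted difference", {
  est <- sapply(1:30, function(s) {
    cfg <- simulation_config(
      n_samples = 600, n_cases = 300, n_transcripts = 10,
      effect_map = data.frame(transcript = 2, celltype = 2, effect = 2),
      seed = 400 + s)
    ds <- simulate_cohort(cfg)
    res <- fit_celltype_twas(ds$expression, ds$phenotypes,
                             ds$proportions_true)
    res$effect[res$context == "CD4T" & res$transcript_id == "TX00002"]
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 2), 2 * mc_se + 1e-8)
})

test_that("null per-cell-type p-values are uniform and FDR calls are controlled", {
  cfg <- simulation_config(n_samples = 400, n_cases = 200,
                           n_transcripts = 2000, seed = 23)
  ds <- simulate_cohort(cfg)
  res <- fit_celltype_twas(ds$expression, ds$phenotypes, ds$proportions_true)
  for (ctx in unique(res$context)) {
    expect_gt(ks.test(res$p[res$context == ctx], "punif")$p.value, 0.01)
  }
  expect_lte(mean(res$q < 0.1, na.rm = TRUE), 0.1)
  res_b <- fit_bulk_twas(ds$expression, ds$phenotypes, ds$proportions_true)
  expect_gt(compute_lambda(res_b$p), 0.9)
  expect_lt(compute_lambda(res_b$p), 1.1)
})

test_that("an additive case effect across all cell types is found by the bulk TWAS", {
  hits <- sapply(1:10, function(s) {
    cfg <- simulation_config(
      n_samples = 400, n_cases = 200, n_transcripts = 100,
      effect_map = data.frame(transcript = 1, celltype = 1:6, effect = 1),
      seed = 600 + s)
    ds <- simulate_cohort(cfg)
    res <- fit_bulk_twas(ds$expression, ds$phenotypes, ds$proportions_true)
    res$q[res$transcript_id == "TX00001"] < 0.1
  })
  expect_gte(mean(hits), 0.9)
})

test_that("a cell type absent from all cases is flagged untestable", {
  n <- 60
  set.seed(6)
  P <- matrix(rgamma(n * 3, 1), n)
  P <- P / rowSums(P)
  pheno <- make_pheno(n)
  P[pheno$case_status == 1, 3] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(pheno$sample_id, c("a", "b", "c"))
  y <- matrix(rnorm(2 * n, 5), 2, dimnames = list(c("t1", "t2"),
                                                  pheno$sample_id))
  res <- fit_celltype_twas(make_expr(y), pheno, cell_proportions(P))
  expect_true(all(is.na(res$p[res$context == "c"])))
  expect_true(all(!is.na(res$p[res$context != "c"])))
})

test_that("permutation calibration is deterministic and label-count preserving", {
  cfg <- simulation_config(n_samples = 150, n_cases = 60, n_transcripts = 300,
                           seed = 12)
  ds <- simulate_cohort(cfg)
  pc1 <- permutation_calibration(ds$expression, ds$phenotypes,
                                 ds$proportions_true, n_perm = 2, seed = 5)
  pc2 <- permutation_calibration(ds$expression, ds$phenotypes,
                                 ds$proportions_true, n_perm = 2, seed = 5)
  expect_identical(pc1$lambdas, pc2$lambdas)
  # a permutation is a reshuffle: rerunning the real-label TWAS afterwards
  # must still see the original case count
  expect_equal(sum(ds$phenotypes$case_status), 60)
})

test_that("rank-deficient designs raise an error naming collinear columns", {
  n <- 40
  pheno <- make_pheno(n)
  pheno$dup <- pheno$age
  y <- matrix(rnorm(n, 5), 1, dimnames = list("t", pheno$sample_id))
  expect_error(fit_bulk_twas(make_expr(y), pheno, NULL,
                             twas_spec("bulk", covariates = c("age", "dup"))),
               "collinear")
})
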