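test_that("configuration invariants are enforced with informative errors", {
  expect_error(simulation_config(dirichlet_alpha = rep(0, 6)),
               "dirichlet_alpha")
  expect_error(simulation_config(n_samples = 10, n_cases = 11), "n_cases")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(n_transcripts = 5,
                                 effect_map = data.frame(transcript = 9,
                                                         celltype = 1,
                                                         effect = 1)),
               "effect_map")
  expect_error(simulation_config(n_snps = 2, n_transcripts = 5,
                                 eqtl_map = data.frame(snp = 3, transcript = 1,
                                                       celltype = 1,
                                                       slope = 1)),
               "eqtl_map")
})

test_that("identical configurations reproduce the dataset exactly", {
  cfg <- simulation_config(n_samples = 40, n_transcripts = 30, n_snps = 10,
                           seed = 11)
  ds1 <- simulate_cohort(cfg)
  ds2 <- simulate_cohort(cfg)
  expect_identical(ds1$expression$abundance, ds2$expression$abundance)
  expect_identical(ds1$methylation$betas, ds2$methylation$betas)
  expect_identical(ds1$genotypes$dosages, ds2$genotypes$dosages)
  expect_identical(ds1$proportions_true$P, ds2$proportions_true$P)
  expect_identical(ds1$phenotypes$case_status, ds2$phenotypes$case_status)
})

test_that("noiseless bulk equals the proportion-weighted mixture", {
  cfg <- simulation_config(n_samples = 30, n_transcripts = 20,
                           bulk_noise_sd = 0, seed = 2)
  ds <- simulate_cohort(cfg)
  mix <- Reduce(`+`, lapply(seq_along(ds$celltype_expression), function(c) {
    sweep(ds$celltype_expression[[c]], 2, ds$proportions_true$P[, c], `*`)
  }))
  expect_equal(ds$expression$abundance, pmax(mix, 0), tolerance = 1e-12)
})

test_that("with zero noise, no-intercept regression on true proportions recovers cell-type means", {
  cfg <- simulation_config(n_samples = 50, n_transcripts = 10,
                           bulk_noise_sd = 0, within_sd = 0, seed = 3)
  ds <- simulate_cohort(cfg)
  P <- ds$proportions_true$P
  for (t in c(1, 5, 10)) {
    fit <- lm(ds$expression$abundance[t, ] ~ 0 + P)
    expect_equal(unname(coef(fit)), unname(ds$truth$celltype_means[t, ]),
                 tolerance = 1e-8)
  }
})

test_that("null configuration yields uniform case-control t-test p-values", {
  cfg <- simulation_config(n_samples = 200, n_cases = 100,
                           n_transcripts = 1000, seed = 19)
  ds <- simulate_cohort(cfg)
  case <- ds$phenotypes$case_status == 1
  pv <- apply(ds$expression$abundance, 1, function(y) {
    t.test(y[case], y[!case], var.equal = TRUE)$p.value
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("methylation betas stay in [0,1] and proportions on the simplex", {
  ds <- simulate_cohort(simulation_config(n_samples = 50, seed = 5))
  expect_true(all(ds$methylation$betas >= 0 & ds$methylation$betas <= 1))
  expect_true(all(abs(rowSums(ds$proportions_true$P) - 1) < 1e-8))
})

test_that("mediation ground truth induces positive dosage-case correlation", {
  eq <- data.frame(snp = 1, transcript = 1, celltype = 1:6, slope = 0.8)
  med <- data.frame(snp = 1, transcript = 1, b = 1.2, c_prime = 0.3)
  cfg <- simulation_config(n_samples = 1500, n_transcripts = 10, n_snps = 3,
                           eqtl_map = eq, mediation_map = med, seed = 8)
  ds <- simulate_cohort(cfg)
  expect_gt(cor(ds$genotypes$dosages[1, ], ds$phenotypes$case_status), 0.05)
})

test_that("proportion case shifts cannot be combined with mediation labels", {
  expect_error(
    simulate_cohort(simulation_config(
      n_samples = 50, n_snps = 2, n_transcripts = 10,
      prop_case_shift = c(0.05, -0.05, 0, 0, 0, 0),
      mediation_map = data.frame(snp = 1, transcript = 1, b = 1,
                                 c_prime = 0))),
    "prop_case_shift")
})

test_that("write_dataset round-trips matrices exactly and lists one file per data type", {
  ds <- simulate_cohort(simulation_config(n_samples = 25, n_transcripts = 15,
                                          n_snps = 5, n_cpgs = 20, seed = 4))
  td <- withr::local_tempdir()
  manifest <- write_dataset(ds, td)
  expect_true(all(c("expression", "annotation", "methylation",
                    "reference_panel", "phenotypes", "genotypes", "truth")
                  %in% names(manifest)))
  expect_true(all(file.exists(manifest)))
  expr2 <- suppressMessages(read_expression(manifest["expression"],
                                            manifest["annotation"]))
  expect_equal(expr2$abundance, ds$expression$abundance, tolerance = 1e-12)
  expect_equal(expr2$annotation$start, ds$expression$annotation$start)
  meth2 <- suppressMessages(read_methylation(manifest["methylation"],
                                             manifest["methylation_coords"]))
  expect_equal(meth2$betas, ds$methylation$betas, tolerance = 1e-12)
  geno2 <- suppressMessages(read_genotypes(manifest["genotypes"],
                                           manifest["genotype_coords"]))
  expect_equal(geno2$dosages, ds$genotypes$dosages, tolerance = 1e-12)
  truth <- jsonlite::read_json(manifest["truth"], simplifyVector = TRUE)
  expect_null(truth$effect_map)
  ref2 <- read_reference_panel(manifest["reference_panel"])
  expect_equal(ref2$means, ds$reference_panel$means, tolerance = 1e-12)
})

test_that("truth JSON round-trips the effect map", {
  em <- data.frame(transcript = c(1, 3), celltype = c(2, 5),
                   effect = c(1.5, -2))
  ds <- simulate_cohort(simulation_config(n_samples = 20, n_transcripts = 5,
                                          effect_map = em, seed = 6))
  td <- withr::local_tempdir()
  manifest <- write_dataset(ds, td)
  truth <- jsonlite::read_json(manifest["truth"], simplifyVector = TRUE)
  expect_equal(as.data.frame(truth$effect_map), em)
})
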