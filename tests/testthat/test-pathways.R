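test_that("marker-gene mapping honours the strand-aware upstream flank", {
  genes <- data.frame(gene_id = c("plus", "minus"),
                      chrom = c("chr1", "chr1"),
                      start = c(50000, 100000), end = c(52000, 102000),
                      strand = c("+", "-"))
  markers <- data.frame(
    marker_id = c("up5k_plus", "up15k_plus", "up5k_minus", "up15k_minus",
                  "inside_plus"),
    chrom = "chr1",
    pos = c(45000, 35000, 107000, 117000, 51000))
  map <- map_markers_to_genes(markers, genes, upstream_flank = 10000)
  g <- map$marker_to_genes
  expect_equal(g[["up5k_plus"]], "plus")
  expect_length(g[["up15k_plus"]], 0)
  expect_equal(g[["up5k_minus"]], "minus")   # downstream of end = upstream on -
  expect_length(g[["up15k_minus"]], 0)
  expect_equal(g[["inside_plus"]], "plus")
  expect_error(map_markers_to_genes(markers,
                                    transform(genes, strand = c("+", "*"))),
               "strand")
})

test_that("a marker inside two overlapping genes maps to both", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(1000, 1500), end = c(3000, 4000),
                      strand = c("+", "-"))
  markers <- data.frame(marker_id = "m", chrom = "chr1", pos = 2000)
  map <- map_markers_to_genes(markers, genes)
  expect_setequal(map$marker_to_genes[["m"]], c("gA", "gB"))
})

test_that("Cramer's V closed form matches the brute-force chi-square oracle", {
  expect_equal(cramers_v_2x2(10, 0, 0, 10), 1)
  expect_equal(cramers_v_2x2(5, 5, 5, 5), 0)
  expect_equal(cramers_v_2x2(8, 2, 4, 6), 0.40825, tolerance = 1e-5)
  expect_equal(cramers_v_2x2(7, 0, 3, 0), 0)  # zero margin
  expect_error(cramers_v_2x2(-1, 1, 1, 1), "non-negative")
  set.seed(5)
  for (i in 1:25) {
    tab <- rmultinom(1, 40, rep(0.25, 4))
    chi <- suppressWarnings(
      chisq.test(matrix(tab, 2), correct = FALSE)$statistic)
    v_oracle <- sqrt(unname(chi) / sum(tab))
    if (is.nan(v_oracle)) v_oracle <- 0
    expect_equal(cramers_v_2x2(tab[1], tab[2], tab[3], tab[4]), v_oracle,
                 tolerance = 1e-12)
  }
})

test_that("pathways below the minimum gene count are excluded", {
  map <- iid_marker_map(40)
  res <- data.frame(transcript_id = map$markers$marker_id,
                    q = c(rep(0.01, 5), rep(0.5, 35)))
  pw <- pathway_db(list(big = sprintf("G%04d", 1:10),
                        small = sprintf("G%04d", 11:12)))
  enr <- suppressWarnings(
    circular_permutation_enrichment(res, map, pw, n_perm = 200, seed = 1))
  expect_equal(enr$pathway, "big")
})

test_that("an all-null top vector gives V = 0 and p = 1 everywhere", {
  map <- iid_marker_map(30)
  res <- data.frame(transcript_id = map$markers$marker_id, q = rep(0.5, 30))
  pw <- pathway_db(list(a = sprintf("G%04d", 1:5), b = sprintf("G%04d", 10:20)))
  enr <- suppressWarnings(
    circular_permutation_enrichment(res, map, pw, n_perm = 200, seed = 1))
  expect_true(all(enr$V == 0))
  expect_true(all(enr$p == 1))
  expect_true(all(enr$p_adj >= enr$p))
})

test_that("enrichment p-values are invariant to pathway relabeling and id renaming", {
  map <- iid_marker_map(60)
  set.seed(8)
  res <- data.frame(transcript_id = map$markers$marker_id,
                    q = sample(c(rep(0.01, 10), rep(0.5, 50))))
  pw <- pathway_db(list(x = sprintf("G%04d", 1:12), y = sprintf("G%04d", 30:45)))
  e1 <- circular_permutation_enrichment(res, map, pw, n_perm = 500, seed = 3)
  pw2 <- pathway_db(list(y = sprintf("G%04d", 30:45), x = sprintf("G%04d", 1:12)))
  e2 <- circular_permutation_enrichment(res, map, pw2, n_perm = 500, seed = 3)
  expect_equal(e1$p[match(c("x", "y"), e1$pathway)],
               e2$p[match(c("x", "y"), e2$pathway)])
})

test_that("null fixture: p-values are valid (super-uniform) and FWER hits rare", {
  # V on a small 2x2 is heavily tied and ties count toward the upper tail,
  # so null permutation p-values are discrete and conservative; the
  # calibration property to check is P(p <= alpha) <= alpha, not exact
  # uniformity
  out <- sapply(1:8, function(s) {
    map <- iid_marker_map(120)
    set.seed(s)
    res <- data.frame(transcript_id = map$markers$marker_id,
                      q = sample(c(rep(0.01, 18), rep(0.5, 102))))
    pw <- lapply(1:12, function(i) {
      sprintf("G%04d", sample(120, 10))
    })
    names(pw) <- paste0("pw", 1:12)
    enr <- circular_permutation_enrichment(res, map, pathway_db(pw),
                                           n_perm = 1000, seed = 100 + s)
    c(nsig = sum(enr$significant), p = enr$p)
  })
  expect_gte(mean(out["nsig", ] == 0), 0.75)
  allp <- as.vector(out[-1, ])
  for (alpha in c(0.05, 0.1, 0.25)) {
    se3 <- 3 * sqrt(alpha * (1 - alpha) / length(allp))
    expect_lte(mean(allp <= alpha), alpha + se3)
  }
})

test_that("with exchangeable markers, rotation p matches gene-label permutation p", {
  # 1:1 marker-gene map, iid top assignment: the circular null and the
  # gene-label permutation null coincide as the circle grows (the rotation
  # null resamples from L distinct offsets, a finite-population version of
  # the label permutation)
  L <- 600; ntop <- 90; K <- 120
  map <- iid_marker_map(L)
  set.seed(21)
  top <- sample(c(rep(TRUE, ntop), rep(FALSE, L - ntop)))
  res <- data.frame(transcript_id = map$markers$marker_id,
                    q = ifelse(top, 0.01, 0.5))
  pw_genes <- sprintf("G%04d", sample(L, K))
  enr <- circular_permutation_enrichment(res, map,
                                         pathway_db(list(pw = pw_genes)),
                                         n_perm = 4000, seed = 4)
  obs_a <- sum(sprintf("G%04d", which(top)) %in% pw_genes)
  v_obs <- cramers_v_2x2(obs_a, ntop - obs_a, K - obs_a,
                         L - ntop - K + obs_a)
  B <- 4000
  set.seed(99)
  v_perm <- replicate(B, {
    lab <- sample(L, ntop)
    a <- sum(sprintf("G%04d", lab) %in% pw_genes)
    cramers_v_2x2(a, ntop - a, K - a, L - ntop - K + a)
  })
  p_label <- max(mean(v_perm >= v_obs), 1 / B)
  mc_se <- sqrt(p_label * (1 - p_label) / B) +
    sqrt(enr$p * (1 - enr$p) / B)
  expect_lt(abs(enr$p - p_label), 2 * mc_se + 1e-6)
})

test_that("pathway clustering groups by gene-set similarity", {
  pw <- pathway_db(list(a1 = sprintf("g%02d", 1:10),
                        a2 = sprintf("g%02d", 1:10),
                        b1 = sprintf("g%02d", 21:30),
                        b2 = sprintf("g%02d", c(21:28, 31:32)),
                        c1 = sprintf("g%02d", 41:50)))
  res <- data.frame(pathway = names(pw$sets))
  cl <- cluster_pathways(res, pw, similarity_threshold = 0.25, seed = 1)
  expect_equal(cl$cluster[1], cl$cluster[2])       # identical sets
  expect_equal(cl$cluster[3], cl$cluster[4])       # Jaccard 2/3
  expect_false(cl$cluster[1] == cl$cluster[3])     # disjoint
  expect_false(cl$cluster[5] %in% cl$cluster[1:4]) # singleton
  expect_length(unique(cl$cluster), 3)
})
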