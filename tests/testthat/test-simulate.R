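test_that("identical configurations give bitwise-identical simulations", {
  cfg <- sim_config(n_genes = 120, seed = 42)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(sim_config(n_genes = 120, seed = 43))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("degenerate no-effect configuration gives zero effects and Poisson-like counts", {
  cfg <- sim_config(n_genes = 400, nb_dispersion = 0, length_effect_slope = 0,
                    effect_sd = 0, shared_up_fraction = 0, pair_sd = 0,
                    baseline_log_mean = 6, baseline_log_sd = 0.3, seed = 3)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$genes$true_l2fc == 0))
  # Poisson: index of dispersion (var/mean across the 8 identical-mean
  # libraries) has expectation 1; its gene-average should sit near 1,
  # far below the phi = 0.05 NB value (1 + 0.05 * mu ~ 20 at mu = 400)
  m <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1, var)
  expect_lt(abs(mean(v / m) - 1), 0.15)
})

test_that("the length-coupled component is exactly linear in centred log10 CDS", {
  cfg <- sim_config(n_genes = 2000, length_effect_slope = 0.3, effect_sd = 0,
                    shared_up_fraction = 0, seed = 1)
  sim <- simulate_counts(cfg)
  x <- log10(sim$truth$genes$cds_length)
  fit <- lm(sim$truth$genes$true_l2fc ~ I(x - mean(x)))
  expect_equal(unname(coef(fit)), c(0, 0.3), tolerance = 1e-12)
})

test_that("the full pipeline recovers the length-effect slope (bootstrap CI)", {
  cfg <- sim_config(n_genes = 2000, length_effect_slope = 0.3, seed = 1)
  sim <- simulate_counts(cfg)
  f <- median_of_ratios(sim$counts)
  filt <- filter_low_expression(sim$counts, f)
  de <- paired_de(sim$counts, sim$design, f, filt$retained)
  x <- log10(sim$truth$genes$cds_length[match(de$gene_id,
                                              sim$truth$genes$gene_id)])
  x <- x - mean(x)
  y <- de$l2fc
  set.seed(7)
  boots <- replicate(400, {
    i <- sample.int(length(y), replace = TRUE)
    coef(lm(y[i] ~ x[i]))[2]
  })
  ci <- quantile(boots, c(0.025, 0.975))
  expect_lt(ci[1], 0.3)
  expect_gt(ci[2], 0.3)
})

test_that("sample means recover configured means for Poisson counts", {
  cfg <- sim_config(n_genes = 1000, nb_dispersion = 0,
                    length_effect_slope = 0, effect_sd = 0,
                    shared_up_fraction = 0, pair_sd = 0,
                    baseline_log_mean = 7, baseline_log_sd = 1, seed = 11)
  sim <- simulate_counts(cfg)
  # no effects, no pair factors: every library mean equals baseline_mean
  mu <- sim$truth$genes$baseline_mean
  big <- mu >= 100
  expect_gt(sum(big), 400)
  rel_err <- abs(rowMeans(sim$counts) - mu) / mu
  expect_lt(mean(rel_err[big]), 0.05)
  expect_lt(max(rel_err[big]), 0.15)
})

test_that("paired design labels are complete and consistent", {
  sim <- simulate_counts(sim_config(n_genes = 50, n_pairs = 3, seed = 2))
  expect_equal(ncol(sim$counts), 6)
  tab <- table(sim$design$pair, sim$design$condition)
  expect_true(all(tab == 1))
  expect_identical(colnames(sim$counts), sim$design$sample)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_pairs = 1), "n_pairs")
  expect_error(sim_config(nb_dispersion = -0.1), "nb_dispersion")
  expect_error(sim_config(length_log_sd = 0), "length_log_sd")
  expect_error(sim_config(shared_up_fraction = 2), "shared_up_fraction")
})

test_that("a shared genome seed shares lengths and the up-set but not effects", {
  a <- simulate_counts(sim_config(n_genes = 300, seed = 1, genome_seed = 9))
  b <- simulate_counts(sim_config(n_genes = 300, seed = 2, genome_seed = 9))
  expect_identical(a$truth$genes$cds_length, b$truth$genes$cds_length)
  expect_identical(a$truth$genes$shared_up, b$truth$genes$shared_up)
  expect_identical(a$truth$transcripts, b$truth$transcripts)
  expect_false(identical(a$truth$genes$true_l2fc, b$truth$genes$true_l2fc))
})

test_that("simulated gene sets respect size bounds and emptiness", {
  sim <- simulate_counts(sim_config(n_genes = 600, seed = 4))
  sets <- simulate_genesets(sim$truth, n_sets = 25,
                            set_size_range = c(20, 500),
                            enrich_long_fraction = 0, seed = 5)
  expect_length(sets, 25)
  expect_true(all(lengths(sets) >= 20 & lengths(sets) <= 500))
  empty <- simulate_genesets(sim$truth, n_sets = 0, seed = 5)
  expect_length(empty, 0)
  expect_error(simulate_genesets(sim$truth, 3, set_size_range = c(50, 20)),
               "lower bound")
})

test_that("length-biased sets are biased and unbiased sets are calibrated", {
  sim <- simulate_counts(sim_config(n_genes = 400, seed = 6))
  top <- sim$truth$genes$cds_length >=
    quantile(sim$truth$genes$cds_length, 0.75, type = 1)
  p_top <- mean(top)
  top_ids <- sim$truth$genes$gene_id[top]

  biased <- simulate_genesets(sim$truth, n_sets = 10,
                              set_size_range = c(20, 40),
                              enrich_long_fraction = 1, seed = 8)
  expect_true(all(attr(biased, "truth")$long_biased))
  expect_gt(mean(attr(biased, "truth")$frac_top_quartile), 0.5)

  # with no bias, membership is independent of the length quartile:
  # the chi-square test should be non-significant in >= 95 of 100 seeds
  n_ok <- 0L
  for (s in 1:100) {
    sets <- simulate_genesets(sim$truth, n_sets = 8,
                              set_size_range = c(15, 30),
                              enrich_long_fraction = 0, seed = s)
    members <- unlist(sets, use.names = FALSE)
    n_top <- sum(members %in% top_ids)
    p <- suppressWarnings(
      chisq.test(c(n_top, length(members) - n_top),
                 p = c(p_top, 1 - p_top))$p.value)
    if (p >= 0.01) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 95L)
})
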