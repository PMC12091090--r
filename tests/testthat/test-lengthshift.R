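make_annotation <- function(id, cds) {
  ann <- data.frame(gene_id = as.character(id), transcript_id = paste0(id, ".t1"),
                    cds_length = cds, tx_length = cds + 1000,
                    utr5_length = 150, utr3_length = 850,
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

test_that("an exactly log-linear fold change gives r = 1", {
  ids <- sprintf("g%03d", 1:40)
  cds <- round(seq(200, 8000, length.out = 40))
  ann <- make_annotation(ids, cds)
  sig <- signed_set(ids, 0.4 * log10(cds + 1) - 0.5)
  res <- length_correlation(sig, ann, feature = "cds")
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_equal(res$n, 40)
})

test_that("length correlation drops unannotated genes and needs three points", {
  ids <- c("a", "b", "c", "zz")
  ann <- make_annotation(c("a", "b", "c"), c(500, 1500, 3000))
  sig <- signed_set(ids, c(1, -1, 2, 1))
  res <- length_correlation(sig, ann)
  expect_equal(res$n, 3)
  expect_equal(res$n_dropped, 1)
  expect_error(length_correlation(signed_set(c("a", "b"), c(1, 1)), ann),
               "insufficient")
})

test_that("null length correlations are calibrated and positive couplings recovered", {
  p_null <- numeric(40)
  r_pos <- p_pos <- numeric(40)
  for (s in 1:40) {
    sim <- simulate_counts(sim_config(n_genes = 400, length_effect_slope = 0,
                                      effect_sd = 0.2, shared_up_fraction = 0,
                                      seed = 3000 + s))
    ann <- make_annotation(sim$truth$genes$gene_id, sim$truth$genes$cds_length)
    sig <- signed_set(sim$truth$genes$gene_id,
                      ifelse(sim$truth$genes$true_l2fc == 0, 1e-9,
                             sim$truth$genes$true_l2fc))
    p_null[s] <- length_correlation(sig, ann)$p
    sim2 <- simulate_counts(sim_config(n_genes = 400,
                                       length_effect_slope = 0.3,
                                       effect_sd = 0.2,
                                       shared_up_fraction = 0,
                                       seed = 4000 + s))
    ann2 <- make_annotation(sim2$truth$genes$gene_id,
                            sim2$truth$genes$cds_length)
    sig2 <- signed_set(sim2$truth$genes$gene_id, sim2$truth$genes$true_l2fc)
    lc <- length_correlation(sig2, ann2)
    r_pos[s] <- lc$r
    p_pos[s] <- lc$p
  }
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)
  expect_true(all(r_pos > 0))
  expect_gte(mean(p_pos < 0.01), 0.95)
})

test_that("equal fold changes give exactly zero z in every bin", {
  ids <- sprintf("g%03d", 1:40)
  cds <- rep(c(500, 1500, 3000, 6000), each = 10)
  de <- make_de(ids, l2fc = rep(0.7, 40))
  rep0 <- binned_ztest(de, make_annotation(ids, cds))
  expect_equal(rep0$bins$z, rep(0, 4))
})

test_that("a shifted bin matches the hand-computed z statistic", {
  ids <- sprintf("g%03d", 1:40)
  cds <- rep(c(500, 1500, 3000, 6000), each = 10)
  set.seed(8)
  base <- rnorm(40, 0, 0.3)
  delta <- 0.9
  l2fc <- base + delta * (cds >= 4000)
  de <- make_de(ids, l2fc = l2fc)
  rep1 <- binned_ztest(de, make_annotation(ids, cds))
  g <- l2fc[cds >= 4000]
  z_hand <- (mean(g) - mean(l2fc)) /
    sqrt(var(g) / length(g) + var(l2fc) / length(l2fc))
  expect_equal(rep1$bins$z[rep1$bins$bin == ">4 kb"], z_hand,
               tolerance = 1e-12)
  expect_gt(z_hand, 0)
  # exclusive reference variant uses the complement
  rep2 <- binned_ztest(de, make_annotation(ids, cds), reference = "rest")
  r <- l2fc[cds < 4000]
  z_rest <- (mean(g) - mean(r)) /
    sqrt(var(g) / length(g) + var(r) / length(r))
  expect_equal(rep2$bins$z[rep2$bins$bin == ">4 kb"], z_rest,
               tolerance = 1e-12)
})

test_that("bin means satisfy the weighted-sum identity and location invariance", {
  sim <- simulate_counts(sim_config(n_genes = 800, length_effect_slope = 0.3,
                                    seed = 44))
  ann <- select_most_abundant(sim$truth$transcripts)
  de <- make_de(sim$truth$genes$gene_id, l2fc = sim$truth$genes$true_l2fc)
  rep1 <- binned_ztest(de, ann)
  expect_equal(sum(rep1$bins$n), rep1$n_all)
  expect_equal(sum(rep1$bins$n * rep1$bins$mean_l2fc),
               rep1$n_all * rep1$mean_all, tolerance = 1e-9)
  shifted <- de
  shifted$l2fc <- shifted$l2fc + 5
  rep2 <- binned_ztest(shifted, ann)
  expect_equal(rep2$bins$z, rep1$bins$z, tolerance = 1e-9)
})

test_that("tiny bins are skipped with a warning", {
  ids <- sprintf("g%02d", 1:12)
  cds <- c(rep(500, 11), 6000)
  de <- make_de(ids, l2fc = rnorm(12))
  w <- capture_warnings(rep1 <- binned_ztest(de, make_annotation(ids, cds)))
  expect_match(w, "skipped", all = TRUE)
  expect_true(is.na(rep1$bins$z[rep1$bins$bin == ">4 kb"]))
})

test_that("the long set applies the CDS threshold and reports the up fraction", {
  # 421 significant long genes of which 321 positive
  ids <- sprintf("g%04d", 1:500)
  cds <- c(rep(3000, 421), rep(500, 79))
  l2fc <- c(rep(1, 321), rep(-1, 100), rep(1, 79))
  de <- make_de(ids, l2fc = l2fc, padj = rep(0.05, 500))
  ann <- make_annotation(ids, cds)
  ls <- long_set(de, ann, threshold = 2000, mode = "padj", alpha = 0.1)
  expect_equal(nrow(ls), 421)
  expect_equal(attr(ls, "n_up"), 321)
  expect_equal(round(attr(ls, "percent_up"), 2), 76.25)

  expect_equal(nrow(long_set(de, ann, threshold = 1e7)), 0)
  all_sig <- long_set(de, ann, threshold = 0)
  expect_equal(nrow(all_sig), 500)
})

test_that("positive length coupling produces the expected bin-mean ordering", {
  means <- matrix(0, nrow = 20, ncol = 4)
  for (s in 1:20) {
    sim <- simulate_counts(sim_config(n_genes = 600,
                                      length_effect_slope = 0.3,
                                      shared_up_fraction = 0,
                                      seed = 5000 + s))
    ann <- make_annotation(sim$truth$genes$gene_id,
                           sim$truth$genes$cds_length)
    de <- make_de(sim$truth$genes$gene_id,
                  l2fc = sim$truth$genes$true_l2fc)
    means[s, ] <- binned_ztest(de, ann)$bins$mean_l2fc
  }
  avg <- colMeans(means)
  expect_true(all(diff(avg) > 0))
})
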