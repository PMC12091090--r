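ranked_fixture <- function(n, seed = 1) {
  set.seed(seed)
  ranked_list(data.frame(gene_id = sprintf("g%04d", 1:n),
                         l2fc = sort(rnorm(n), decreasing = TRUE) +
                           seq(n, 1) * 1e-9))
}

test_that("ranking is by descending score with deterministic tie-breaks", {
  de <- make_de(c("b", "a", "c", "d"), l2fc = c(2, 2, -1, 3))
  r <- ranked_list(de)
  expect_equal(r$gene_id, c("d", "a", "b", "c"))
  expect_error(ranked_list(make_de(c("a", "a"), c(1, 2))), "duplicate")
})

test_that("a top-ranked single-member set attains ES = 1", {
  r <- ranked_fixture(10)
  res <- enrichment_score(r, r$gene_id[1])
  expect_equal(res$es, 1, tolerance = 1e-12)
})

test_that("single-member placements match exhaustive enumeration", {
  r <- ranked_fixture(3)
  for (pos in 1:3) {
    res <- enrichment_score(r, r$gene_id[pos])
    expect_equal(res$es, es_oracle(r$gene_id, r$gene_id[pos]),
                 tolerance = 1e-12)
  }
})

test_that("all member subsets of short lists match the brute-force oracle", {
  for (n in c(4, 7, 10)) {
    r <- ranked_fixture(n, seed = n)
    for (k in 1:(n - 1)) {
      combos <- combn(n, k)
      take <- seq_len(min(ncol(combos), 60))
      for (j in take) {
        members <- r$gene_id[combos[, j]]
        res <- enrichment_score(r, members)
        expect_equal(res$es, es_oracle(r$gene_id, members),
                     tolerance = 1e-12)
        # internal consistency: ES magnitude is the running-sum extreme
        expect_equal(abs(res$es), max(abs(res$running)), tolerance = 1e-12)
        # fast positional form agrees with the materialized profile
        expect_equal(translens:::es_from_positions(combos[, j], n), res$es,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the classic score agrees with an independent reference implementation", {
  skip_if_not_installed("fgsea")
  r <- ranked_fixture(200, seed = 9)
  stats_vec <- setNames(r$score, r$gene_id)
  set.seed(10)
  for (k in c(5, 20, 50)) {
    members <- sample(r$gene_id, k)
    ours <- enrichment_score(r, members)$es
    # gseaParam = 0 weights every gene equally: the classic statistic
    theirs <- fgsea::calcGseaStat(stats_vec,
                                  selectedStats = which(r$gene_id %in% members),
                                  gseaParam = 0)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("reversing the ranked list negates every enrichment score", {
  r <- ranked_fixture(50, seed = 4)
  rev_r <- r[nrow(r):1, ]
  class(rev_r) <- c("ranked_list", "data.frame")
  set.seed(5)
  for (k in c(3, 10, 25)) {
    members <- sample(r$gene_id, k)
    expect_equal(enrichment_score(rev_r, members)$es,
                 -enrichment_score(r, members)$es, tolerance = 1e-12)
  }
})

test_that("preranked GSEA is seeded, size-filtered, and reports exclusions", {
  r <- ranked_fixture(300, seed = 2)
  set.seed(3)
  sets <- gene_set_collection(list(
    ok1 = sample(r$gene_id, 30),
    ok2 = sample(r$gene_id, 25),
    tiny = sample(r$gene_id, 5),
    huge = r$gene_id[1:290]))
  res1 <- preranked_gsea(r, sets, min_size = 20, max_size = 100,
                         n_perm = 100, seed = 7)
  res2 <- preranked_gsea(r, sets, min_size = 20, max_size = 100,
                         n_perm = 100, seed = 7)
  expect_identical(res1, res2)
  expect_setequal(res1$set, c("ok1", "ok2"))
  expect_setequal(attr(res1, "excluded")$set, c("tiny", "huge"))
  expect_true(all(abs(res1$es) <= 1))
  expect_true(all(res1$p_nominal >= 0 & res1$p_nominal <= 1))
  expect_true(all(sign(res1$nes) == sign(res1$es)))
  expect_error(preranked_gsea(r, sets, n_perm = 0), "n_perm")
  expect_error(preranked_gsea(r, gene_set_collection(list())), "empty")
})

test_that("a set planted in the top of the list is called with positive NES", {
  r <- ranked_fixture(2000, seed = 6)
  set.seed(11)
  planted <- sample(r$gene_id[1:100], 30)  # wholly inside the top 5%
  sets <- gene_set_collection(list(planted = planted))
  res <- preranked_gsea(r, sets, min_size = 20, max_size = 500,
                        n_perm = 1000, seed = 8)
  expect_gt(res$nes, 0)
  expect_lte(res$p_nominal, 1 / 1000)
  expect_lt(res$fdr_q, 0.05)
})

test_that("random sets have approximately uniform nominal p values", {
  r <- ranked_fixture(400, seed = 12)
  p <- numeric(200)
  for (i in 1:200) {
    set.seed(20000 + i)
    members <- sample(r$gene_id, 25)
    res <- preranked_gsea(r, gene_set_collection(list(s = members)),
                          min_size = 10, max_size = 100, n_perm = 200,
                          seed = 30000 + i)
    p[i] <- res$p_nominal
  }
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("the permutation null depends only on set size", {
  r <- ranked_fixture(300, seed = 13)
  set.seed(14)
  sets <- gene_set_collection(list(a = sample(r$gene_id, 40),
                                   b = sample(r$gene_id, 40)))
  # same size, same seed: the two sets share one null, so their NES are
  # computed against identical references; their null ES distributions
  # coincide by construction and the KS statistic between two fresh
  # draws of size-40 nulls should be unremarkable
  null_a <- replicate(300, translens:::es_from_positions(sample.int(300, 40), 300))
  null_b <- replicate(300, translens:::es_from_positions(sample.int(300, 40), 300))
  expect_gt(suppressWarnings(ks.test(null_a, null_b)$p.value), 0.01)
})

test_that("term-level signed sets feed the overlap machinery", {
  r <- ranked_fixture(500, seed = 15)
  set.seed(16)
  sets <- gene_set_collection(c(
    list(top = sample(r$gene_id[1:50], 25),
         bottom = sample(r$gene_id[451:500], 25)),
    setNames(lapply(1:6, function(i) sample(r$gene_id, 25)),
             paste0("rand", 1:6))))
  res <- preranked_gsea(r, sets, min_size = 10, max_size = 100,
                        n_perm = 300, seed = 17)
  ts <- term_set(res, mode = "p_nominal", alpha = 0.05)
  expect_true("top" %in% ts$id)
  expect_true("bottom" %in% ts$id)
  expect_equal(ts$sign[ts$id == "top"], 1)
  expect_equal(ts$sign[ts$id == "bottom"], -1)
  rep_tt <- overlap_report(ts, ts, universe = res$set)
  expect_equal(rep_tt$percent_same_sign, 100)
})

test_that("over-representation matches enumeration and handles edge cases", {
  u <- sprintf("u%02d", 1:8)
  hits <- u[1:4]
  sets <- gene_set_collection(list(same = hits, disjoint = u[5:8],
                                   partial = u[3:6]))
  res <- overrepresentation(hits, sets, u)
  expect_equal(res$p[res$set == "same"], hyper_tail_oracle(8, 4, 4, 4),
               tolerance = 1e-12)
  expect_equal(res$p[res$set == "same"], 1 / choose(8, 4), tolerance = 1e-12)
  expect_equal(res$p[res$set == "disjoint"], 1)
  expect_equal(res$p[res$set == "partial"], hyper_tail_oracle(8, 4, 4, 2),
               tolerance = 1e-12)
  # hits = universe: every set fully hit with certainty
  res_all <- overrepresentation(u, sets, u)
  expect_true(all(res_all$p == 1))
  expect_error(overrepresentation(c("zz"), sets, u), "universe")
})
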