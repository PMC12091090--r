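# Small in-code fixtures shared across test files.

# minimal well-formed DE table
make_de <- function(id, l2fc, pvalue = NULL, padj = NULL,
                    base_mean = NULL, se = NULL) {
  n <- length(id)
  de <- data.frame(
    gene_id = as.character(id),
    base_mean = if (is.null(base_mean)) rep(100, n) else base_mean,
    l2fc = l2fc,
    l2fc_se = if (is.null(se)) rep(0.1, n) else se,
    pvalue = if (is.null(pvalue)) rep(0.5, n) else pvalue,
    padj = if (is.null(padj)) rep(0.5, n) else padj,
    stringsAsFactors = FALSE)
  class(de) <- c("de_table", "data.frame")
  de
}

make_set <- function(ids, scores) signed_set(ids, scores)

# enumeration oracle for the upper-tail hypergeometric overlap
# probability: P(|A \cap B| >= k) over all placements of a size-|A| set
# in a universe holding |B| marked elements
hyper_tail_oracle <- function(n_universe, n_a, n_b, k) {
  js <- max(0, n_a + n_b - n_universe):min(n_a, n_b)
  js <- js[js >= k]
  sum(choose(n_b, js) * choose(n_universe - n_b, n_a - js)) /
    choose(n_universe, n_a)
}

# naive running-sum enrichment score, written independently of the
# package implementation (explicit loop, no cumsum)
es_oracle <- function(ranked_ids, members) {
  nh <- sum(ranked_ids %in% members)
  nm <- length(ranked_ids) - nh
  # integer arithmetic on the common denominator nh * nm keeps magnitude
  # ties exact: a hit steps +nm, a miss steps -nh
  run <- 0L
  hi <- lo <- 0L
  for (g in ranked_ids) {
    run <- run + if (g %in% members) nm else -nh
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  (if (hi >= -lo) hi else lo) / (nh * nm)  # ties resolved to the positive side
}

# simulate one null dataset and return its paired DE table
null_de <- function(seed, n_genes = 300) {
  cfg <- sim_config(n_genes = n_genes, length_effect_slope = 0,
                    effect_sd = 0, shared_up_fraction = 0, seed = seed)
  sim <- simulate_counts(cfg)
  f <- median_of_ratios(sim$counts)
  filt <- filter_low_expression(sim$counts, f)
  list(sim = sim,
       de = paired_de(sim$counts, sim$design, f, filt$retained))
}

geometric_mean_test_helper <- function(x) prod(x)^(1 / length(x))
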