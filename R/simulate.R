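#' Simulation configuration for paired TRAP-like count data
#'
#' Builds and validates the configuration for [simulate_counts()]. The
#' defaults describe a typical bulk TRAP-seq comparison: four matched
#' littermate pairs, ~2,000 genes, moderate negative-binomial
#' overdispersion, log-normal baseline expression and CDS lengths, a small
#' immediate-early-gene-like shared up-set, and (optionally) a condition
#' effect coupled to CDS length.
#'
#' The per-gene true effect (log2 fold change of the perturbed over the
#' control condition) is the sum of three components:
#' \deqn{L2FC_g = \beta_{len}\,(\log_{10} CDS_g - \overline{\log_{10} CDS})
#'   + s_g\,\delta + \epsilon_g,}
#' where \eqn{s_g} indicates membership in the shared up-set,
#' \eqn{\delta} = `shared_up_l2fc`, and
#' \eqn{\epsilon_g \sim N(0, \mathrm{effect\_sd}^2)}. With
#' `length_effect_slope = 0` and `shared_up_fraction = 0` all true effects
#' are exchangeable draws centred at zero.
#'
#' @param n_pairs Number of matched sample pairs (>= 2). Each pair
#'   contributes one control and one perturbed library.
#' @param n_genes Number of simulated genes (>= 1).
#' @param nb_dispersion Negative-binomial dispersion \eqn{\phi} in the
#'   parameterization \eqn{Var = \mu + \phi \mu^2}; `0` gives Poisson
#'   counts.
#' @param baseline_log_mean,baseline_log_sd Parameters (natural-log scale)
#'   of the log-normal distribution of per-gene baseline mean counts.
#' @param length_log_mean,length_log_sd Parameters (natural-log scale) of
#'   the log-normal distribution of CDS length in bases;
#'   `length_log_sd` must be > 0.
#' @param length_effect_slope Change in true log2 fold change per unit
#'   log10(CDS length), i.e. the length coupling of the condition effect.
#'   Positive values emulate an LTP-like (long-mRNA-up) shift, negative an
#'   LTD-like shift.
#' @param shared_up_fraction Fraction of genes given a length-independent
#'   positive effect, emulating immediate-early genes induced by any
#'   stimulation.
#' @param shared_up_l2fc Log2 fold change added to shared up-set members.
#' @param effect_sd Standard deviation of the gene-level random effect
#'   component (log2 scale).
#' @param pair_sd Standard deviation (natural-log scale) of the
#'   multiplicative pair-specific size factors; both libraries of a pair
#'   share one factor, which is what makes the paired design informative.
#' @param utr_cds_coupling Coupling of log 3'UTR length to centred
#'   log10(CDS); `0` (default) simulates UTR lengths independent of CDS so
#'   that CDS-specific shifts are distinguishable from UTR shifts.
#' @param seed Integer RNG seed for the dataset-level draws (gene-level
#'   effect noise, pair factors, counts).
#' @param genome_seed Integer RNG seed for the genome-level draws (CDS/UTR
#'   lengths, transcript structure and TPM, baseline means, shared up-set
#'   membership). Defaults to `seed`. Two datasets simulated with the same
#'   `genome_seed` but different `seed`s share one genome and one
#'   immediate-early-gene up-set while their condition effects and counts
#'   are independent -- the structure of a real cross-dataset comparison.
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_counts()], [simulate_genesets()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, length_effect_slope = 0.3, seed = 1)
#' sim <- simulate_counts(cfg)
#' dim(sim$counts)
sim_config <- function(n_pairs = 4,
                       n_genes = 2000,
                       nb_dispersion = 0.05,
                       baseline_log_mean = 5.5,
                       baseline_log_sd = 1.2,
                       length_log_mean = 7.2,
                       length_log_sd = 0.9,
                       length_effect_slope = 0,
                       shared_up_fraction = 0.02,
                       shared_up_l2fc = 2,
                       effect_sd = 0.15,
                       pair_sd = 0.2,
                       utr_cds_coupling = 0,
                       seed = 1,
                       genome_seed = NULL) {
  check_scalar(n_pairs, "n_pairs", min = 2, integer = TRUE)
  check_scalar(n_genes, "n_genes", min = 1, integer = TRUE)
  check_scalar(nb_dispersion, "nb_dispersion", min = 0)
  check_scalar(baseline_log_mean, "baseline_log_mean")
  check_scalar(baseline_log_sd, "baseline_log_sd", min = 0)
  check_scalar(length_log_mean, "length_log_mean")
  check_scalar(length_log_sd, "length_log_sd")
  if (length_log_sd <= 0) abort("configuration error: 'length_log_sd' must be > 0")
  check_scalar(length_effect_slope, "length_effect_slope")
  check_scalar(shared_up_fraction, "shared_up_fraction", min = 0, max = 1)
  check_scalar(shared_up_l2fc, "shared_up_l2fc")
  check_scalar(effect_sd, "effect_sd", min = 0)
  check_scalar(pair_sd, "pair_sd", min = 0)
  check_scalar(utr_cds_coupling, "utr_cds_coupling")
  check_scalar(seed, "seed", integer = TRUE)
  if (is.null(genome_seed)) genome_seed <- seed
  check_scalar(genome_seed, "genome_seed", integer = TRUE)
  structure(
    list(n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
         nb_dispersion = nb_dispersion,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         length_log_mean = length_log_mean, length_log_sd = length_log_sd,
         length_effect_slope = length_effect_slope,
         shared_up_fraction = shared_up_fraction,
         shared_up_l2fc = shared_up_l2fc,
         effect_sd = effect_sd, pair_sd = pair_sd,
         utr_cds_coupling = utr_cds_coupling, seed = as.integer(seed),
         genome_seed = as.integer(genome_seed)),
    class = "sim_config")
}

#' Simulate a paired-design TRAP-like count matrix with known truth
#'
#' Draws negative-binomial counts for `n_genes` genes across
#' `2 * n_pairs` libraries (one control and one perturbed library per
#' pair). Perturbed-condition means equal control means scaled by
#' `2^L2FC_g`, where the true per-gene effect is built as documented in
#' [sim_config()]. Both libraries of a pair share a log-normal
#' multiplicative size factor, so a paired analysis gains power over an
#' unpaired one. A per-transcript annotation table (1--3 transcripts per
#' gene with Dirichlet-split TPM) accompanies the counts so that
#' most-abundant-transcript collapsing is exercised downstream; the most
#' abundant transcript of each gene carries the gene's true lengths.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"trap_sim"` with elements:
#' \describe{
#'   \item{counts}{integer matrix, genes x samples, with gene ids as row
#'     names and sample ids as column names.}
#'   \item{design}{data frame with columns `sample`, `pair`, `condition`
#'     (`"control"`/`"perturbed"`).}
#'   \item{truth}{list with `genes` (per-gene true log2 fold change,
#'     shared-up membership, baseline mean, true lengths, pair size
#'     factors as an attribute) and `transcripts` (per-transcript feature
#'     table with TPM, suitable for [select_most_abundant()]).}
#'   \item{config}{the configuration used.}
#' }
#' Identical configurations (including the seed) give bitwise-identical
#' output.
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_genes
  np <- config$n_pairs
  gene_id <- sprintf("gene%05d", seq_len(n))

  # genome-level draws: everything two datasets on the same genome share.
  # The genome stream is offset from the dataset stream so that the default
  # genome_seed == seed does not reuse the same random draws for lengths
  # and for gene-level effect noise.
  genome <- with_seed(config$genome_seed + 499979L, {
    # CDS lengths (bases), floored at 90 (a 30-codon minimal ORF)
    cds <- pmax(90, round(stats::rlnorm(n, config$length_log_mean,
                                        config$length_log_sd)))
    log10_cds <- log10(cds)
    n_up <- floor(config$shared_up_fraction * n)
    shared_up <- rep(FALSE, n)
    if (n_up > 0) shared_up[sample.int(n, n_up)] <- TRUE
    mu <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
    # UTR lengths; 3'UTR optionally coupled to CDS length
    utr5 <- pmax(10, round(stats::rlnorm(n, log(170), 0.7)))
    utr3 <- pmax(20, round(stats::rlnorm(
      n, log(900) + config$utr_cds_coupling * (log10_cds - mean(log10_cds)),
      0.8)))
    # 1-3 transcripts per gene; the most abundant carries the true lengths
    n_tx <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    total <- sum(n_tx)
    t_gene <- rep.int(seq_len(n), n_tx)
    t_rank <- sequence(n_tx)
    share <- stats::rgamma(total, shape = 1)  # Dirichlet(1,..,1) after split
    # force the rank-1 transcript to hold the largest share within its gene
    ord <- order(t_gene, -share)
    share <- share[ord][order(order(t_gene, t_rank))]
    share_sum <- as.numeric(tapply(share, t_gene, sum))[t_gene]
    gene_tpm <- mu / sum(mu) * 1e6  # abundance proportional to expression
    tpm <- gene_tpm[t_gene] * share / share_sum
    alt_scale <- stats::runif(total, 0.35, 0.9)
    t_cds <- ifelse(t_rank == 1L, cds[t_gene],
                    pmax(90, round(cds[t_gene] * alt_scale)))
    t_utr5 <- ifelse(t_rank == 1L, utr5[t_gene],
                     pmax(10, round(utr5[t_gene] * stats::runif(total, 0.5, 1.5))))
    t_utr3 <- ifelse(t_rank == 1L, utr3[t_gene],
                     pmax(20, round(utr3[t_gene] * stats::runif(total, 0.5, 1.5))))
    list(cds = cds, log10_cds = log10_cds, shared_up = shared_up, mu = mu,
         utr5 = utr5, utr3 = utr3,
         transcripts = data.frame(
           transcript_id = sprintf("%s.t%d", gene_id[t_gene], t_rank),
           gene_id = gene_id[t_gene],
           cds_length = t_cds,
           tx_length = t_cds + t_utr5 + t_utr3,
           utr5_length = t_utr5, utr3_length = t_utr3,
           tpm = tpm, stringsAsFactors = FALSE))
  })

  with_seed(config$seed, {
    cds <- genome$cds
    shared_up <- genome$shared_up
    mu <- genome$mu
    len_component <- config$length_effect_slope *
      (genome$log10_cds - mean(genome$log10_cds))
    noise <- if (config$effect_sd > 0) stats::rnorm(n, 0, config$effect_sd) else numeric(n)
    true_l2fc <- len_component + shared_up * config$shared_up_l2fc + noise

    pair_factor <- if (config$pair_sd > 0) {
      stats::rlnorm(np, 0, config$pair_sd)
    } else rep(1, np)

    draw <- function(m) {
      if (config$nb_dispersion > 0) {
        stats::rnbinom(length(m), mu = m, size = 1 / config$nb_dispersion)
      } else {
        stats::rpois(length(m), lambda = m)
      }
    }
    counts <- matrix(0L, nrow = n, ncol = 2L * np)
    samples <- character(2L * np)
    pair_lab <- character(2L * np)
    cond <- character(2L * np)
    for (p in seq_len(np)) {
      jc <- 2L * p - 1L
      jp <- 2L * p
      counts[, jc] <- draw(mu * pair_factor[p])
      counts[, jp] <- draw(mu * 2^true_l2fc * pair_factor[p])
      samples[c(jc, jp)] <- sprintf("pair%d_%s", p, c("control", "perturbed"))
      pair_lab[c(jc, jp)] <- sprintf("pair%d", p)
      cond[c(jc, jp)] <- c("control", "perturbed")
    }
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(gene_id, samples)
    design <- data.frame(sample = samples, pair = pair_lab, condition = cond,
                         stringsAsFactors = FALSE)

    genes <- data.frame(gene_id = gene_id, true_l2fc = true_l2fc,
                        shared_up = shared_up, baseline_mean = mu,
                        cds_length = cds,
                        tx_length = cds + genome$utr5 + genome$utr3,
                        utr5_length = genome$utr5,
                        utr3_length = genome$utr3, stringsAsFactors = FALSE)
    attr(genes, "pair_factor") <- pair_factor

    structure(list(counts = counts, design = design,
                   truth = list(genes = genes,
                                transcripts = genome$transcripts),
                   config = config),
              class = "trap_sim")
  })
}

#' @export
print.trap_sim <- function(x, ...) {
  cat(sprintf("trap_sim: %d genes x %d samples (%d pairs), phi = %g, beta_len = %g\n",
              nrow(x$counts), ncol(x$counts), x$config$n_pairs,
              x$config$nb_dispersion, x$config$length_effect_slope))
  invisible(x)
}

#' Simulate gene-set collections with controlled length bias
#'
#' Draws `n_sets` gene sets from the simulated gene universe. A stated
#' fraction of the sets is sampled preferentially from the longest-CDS
#' quartile (members of that quartile get 9x sampling weight, so biased
#' sets are ~75% long-CDS genes in expectation), so that enrichment
#' analyses and the CDS-length shift interact on synthetic data the way
#' ontology sets of long synaptic genes interact with length shifts in
#' real translatomes. The remaining sets are sampled uniformly.
#'
#' @param truth The `truth` element of a [simulate_counts()] result (or the
#'   whole `"trap_sim"` object).
#' @param n_sets Number of sets to generate (0 allowed).
#' @param set_size_range Integer pair `c(min, max)`; sizes are drawn
#'   uniformly from this range and capped at the universe size.
#' @param enrich_long_fraction Fraction of sets biased toward the
#'   longest-CDS quartile.
#' @param seed Integer RNG seed.
#' @return A [gene_set_collection()]; its `"truth"` attribute is a sidecar
#'   data frame recording, per set, its size, whether it was length-biased,
#'   and the realized fraction of members in the top CDS-length quartile.
#' @export
simulate_genesets <- function(truth, n_sets, set_size_range = c(20, 100),
                              enrich_long_fraction = 0, seed = 1) {
  if (inherits(truth, "trap_sim")) truth <- truth$truth
  genes <- truth$genes
  check_scalar(n_sets, "n_sets", min = 0, integer = TRUE)
  if (length(set_size_range) != 2L || any(!is.finite(set_size_range))) {
    abort("configuration error: 'set_size_range' must be two finite numbers")
  }
  if (set_size_range[1] > set_size_range[2]) {
    abort("configuration error: 'set_size_range' lower bound %d > upper bound %d",
          set_size_range[1], set_size_range[2])
  }
  if (set_size_range[1] < 1 || set_size_range[2] > nrow(genes)) {
    abort("configuration error: 'set_size_range' must lie within [1, n_genes]")
  }
  check_scalar(enrich_long_fraction, "enrich_long_fraction", min = 0, max = 1)

  with_seed(seed, {
    n <- nrow(genes)
    top_q <- genes$cds_length >= stats::quantile(genes$cds_length, 0.75, type = 1)
    weight_long <- ifelse(top_q, 9, 1)
    n_long <- floor(enrich_long_fraction * n_sets)
    sets <- vector("list", n_sets)
    truth_tab <- data.frame(set = character(n_sets), size = integer(n_sets),
                            long_biased = logical(n_sets),
                            frac_top_quartile = numeric(n_sets),
                            stringsAsFactors = FALSE)
    for (i in seq_len(n_sets)) {
      size <- sample(seq.int(set_size_range[1], set_size_range[2]), 1L)
      biased <- i <= n_long
      prob <- if (biased) weight_long else NULL
      members <- genes$gene_id[sample.int(n, size, prob = prob)]
      sets[[i]] <- sort(members)
      truth_tab$set[i] <- sprintf("set%03d%s", i, if (biased) "_long" else "")
      truth_tab$size[i] <- size
      truth_tab$long_biased[i] <- biased
      truth_tab$frac_top_quartile[i] <-
        mean(top_q[match(members, genes$gene_id)])
    }
    names(sets) <- truth_tab$set
    out <- gene_set_collection(sets, descriptions = ifelse(
      truth_tab$long_biased, "long-CDS-biased synthetic set",
      "unbiased synthetic set"))
    attr(out, "truth") <- truth_tab
    out
  })
}
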