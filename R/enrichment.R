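# Preranked gene-set enrichment with the classic (unweighted) statistic,
# permutation-based NES / nominal p / FDR, and hypergeometric
# over-representation. The classic statistic weights every gene equally,
# removing the magnitude bias of the ranking metric.

#' Build a ranked gene list
#'
#' Orders genes by decreasing score (log2 fold change), breaking ties by
#' ascending gene id so the order is deterministic.
#'
#' @param de A `"de_table"` data frame, or a data frame with `gene_id` and
#'   a score column.
#' @param score_col Column holding the ranking score (default `"l2fc"`).
#' @return Data frame of class `"ranked_list"` with columns `gene_id`,
#'   `score`, ordered by descending score.
#' @export
ranked_list <- function(de, score_col = "l2fc") {
  if (!all(c("gene_id", score_col) %in% names(de))) {
    abort("format error: need columns gene_id and %s", score_col)
  }
  dup <- unique(de$gene_id[duplicated(de$gene_id)])
  if (length(dup)) {
    abort("validation error: duplicate gene id(s) in ranked list: %s",
          paste(utils::head(dup, 5L), collapse = ", "))
  }
  keep <- !is.na(de[[score_col]])
  out <- data.frame(gene_id = de$gene_id[keep], score = de[[score_col]][keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

# ES from sorted hit positions without materializing the running sum.
# The running sum takes value j/nh - (pos_j - j)/nm right after the j-th
# hit and (j-1)/nh - (pos_j - j)/nm just before it; the signed maximum
# deviation from zero is attained at one of these points (ties between the
# positive and negative extreme go to the positive one).
es_from_positions <- function(pos, n_total) {
  nh <- length(pos)
  nm <- n_total - nh
  if (nh == 0L) return(NA_real_)
  if (nm == 0L) return(1)  # set covers the whole list; running sum = i/N
  pos <- sort.int(pos)
  j <- seq_len(nh)
  # integer-valued arithmetic (in doubles, exact below 2^53) on the common
  # denominator nh * nm makes magnitude ties exact; ties resolve to the
  # positive deviation
  miss_before <- (pos - j) * as.numeric(nh)
  top <- j * as.numeric(nm) - miss_before
  bottom <- (j - 1) * nm - miss_before
  hi <- max(top)
  lo <- min(bottom)
  (if (hi >= -lo) hi else lo) / (nh * nm)
}

#' Classic enrichment score with its running-sum profile
#'
#' Walks the ranked list accumulating +1/N_hit at each member of the set
#' and -1/N_miss at each non-member (the classic Kolmogorov-Smirnov-style
#' statistic with every gene weighted equally). The enrichment score is
#' the signed maximum deviation of this running sum from zero; an exact
#' magnitude tie between the positive and negative extreme resolves to
#' the positive one.
#'
#' @param ranked A [ranked_list()].
#' @param members Character vector of member gene ids.
#' @return List with `es` and `running` (the full running-sum vector,
#'   one entry per ranked gene). If no member is present in the list,
#'   `es` is `NA` with a warning (callers such as [preranked_gsea()] skip
#'   and report such sets).
#' @export
enrichment_score <- function(ranked, members) {
  n <- nrow(ranked)
  hit <- ranked$gene_id %in% members
  nh <- sum(hit)
  if (nh == 0L) {
    warn("no set member present in the ranked list; ES undefined")
    return(list(es = NA_real_, running = rep(NA_real_, n)))
  }
  nm <- n - nh
  inc <- if (nm == 0L) rep(1 / nh, n) else {
    out <- rep(-1 / nm, n)
    out[hit] <- 1 / nh
    out
  }
  running <- cumsum(inc)
  # the positional form evaluates each candidate extreme directly instead
  # of through the accumulated sum, so exact magnitude ties are resolved
  # consistently (to the positive side) without floating-point drift
  es <- es_from_positions(which(hit), n)
  list(es = es, running = running)
}

#' Preranked gene-set enrichment analysis (classic statistic)
#'
#' For every gene set (restricted to the ranked universe and filtered to
#' sizes within `[min_size, max_size]`), computes the classic enrichment
#' score and a permutation null obtained by redrawing the set's positions
#' uniformly from the ranked list (gene-label permutation with the set
#' size held fixed, the only null available for a preranked analysis).
#' Same-size sets share one null. The normalized enrichment score divides
#' ES by the mean absolute null ES of matching sign; the nominal p value
#' is the same-sign null tail fraction
#' `#{null ES at least as extreme} / #{null ES of that sign}` (0 at the
#' permutation floor). FDR q follows the standard NES-based procedure:
#' the fraction of pooled sign-matched null NES at least as extreme as the
#' observed NES, divided by the fraction of observed NES at least as
#' extreme, capped at 1 (and not clamped below the nominal p). Sets with
#' ES = 0 get NES = 0 and p = 1.
#'
#' @param ranked A [ranked_list()].
#' @param sets A [gene_set_collection()].
#' @param min_size,max_size Size bounds applied after restriction to the
#'   ranked universe (defaults 20 and 500).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed; identical inputs and seed give an
#'   identical result table.
#' @return Data frame of class `"enrichment_table"` with one row per
#'   analyzed set: `set`, `size`, `es`, `nes`, `p_nominal`, `fdr_q`,
#'   ordered by decreasing NES. Excluded sets (outside the size bounds or
#'   absent from the universe) are listed in the `"excluded"` attribute.
#' @export
preranked_gsea <- function(ranked, sets, min_size = 20, max_size = 500,
                           n_perm = 1000, seed = 1) {
  if (!length(sets)) abort("configuration error: empty gene-set collection")
  check_scalar(n_perm, "n_perm", min = 1, integer = TRUE)
  n <- nrow(ranked)
  restricted <- lapply(sets, function(m) intersect(m, ranked$gene_id))
  sizes <- lengths(restricted)
  keep <- sizes >= min_size & sizes <= max_size
  excluded <- data.frame(set = names(sets)[!keep], size = sizes[!keep],
                         stringsAsFactors = FALSE)
  restricted <- restricted[keep]
  sizes <- sizes[keep]
  if (!length(restricted)) {
    out <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_nominal = numeric(0),
                      fdr_q = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    attr(out, "excluded") <- excluded
    return(out)
  }

  es_obs <- vapply(restricted, function(m) {
    es_from_positions(which(ranked$gene_id %in% m), n)
  }, numeric(1))

  with_seed(seed, {
    # one null per distinct set size, in sorted order for determinism
    uniq_sizes <- sort(unique(sizes))
    nulls <- lapply(uniq_sizes, function(k) {
      vapply(seq_len(n_perm), function(i) {
        es_from_positions(sample.int(n, k), n)
      }, numeric(1))
    })
    names(nulls) <- as.character(uniq_sizes)
  })

  nes <- numeric(length(es_obs))
  p_nom <- numeric(length(es_obs))
  null_nes_pool <- vector("list", length(uniq_sizes))
  mean_pos <- mean_neg <- stats::setNames(numeric(length(uniq_sizes)),
                                          names(nulls))
  for (s in seq_along(uniq_sizes)) {
    nl <- nulls[[s]]
    mp <- mean(nl[nl > 0])
    mn <- mean(-nl[nl < 0])
    mean_pos[s] <- if (is.nan(mp)) NA_real_ else mp
    mean_neg[s] <- if (is.nan(mn)) NA_real_ else mn
    nn <- rep(0, length(nl))
    if (!is.na(mean_pos[s])) nn[nl > 0] <- nl[nl > 0] / mean_pos[s]
    if (!is.na(mean_neg[s])) nn[nl < 0] <- nl[nl < 0] / mean_neg[s]
    null_nes_pool[[s]] <- nn
  }
  null_nes <- unlist(null_nes_pool, use.names = FALSE)

  for (i in seq_along(es_obs)) {
    e <- es_obs[i]
    nl <- nulls[[as.character(sizes[i])]]
    if (is.na(e) || e == 0) {
      nes[i] <- 0; p_nom[i] <- 1
    } else if (e > 0) {
      same <- nl[nl > 0]
      nes[i] <- if (length(same)) e / mean(same) else NA_real_
      p_nom[i] <- if (length(same)) sum(same >= e) / length(same) else 1
    } else {
      same <- nl[nl < 0]
      nes[i] <- if (length(same)) -e / mean(same) else NA_real_
      p_nom[i] <- if (length(same)) sum(same <= e) / length(same) else 1
    }
  }

  fdr <- rep(NA_real_, length(nes))
  pos_obs <- nes[!is.na(nes) & nes > 0]
  neg_obs <- nes[!is.na(nes) & nes < 0]
  pos_null <- null_nes[null_nes > 0]
  neg_null <- null_nes[null_nes < 0]
  for (i in seq_along(nes)) {
    v <- nes[i]
    if (is.na(v)) next
    if (v == 0) { fdr[i] <- 1; next }
    if (v > 0) {
      num <- if (length(pos_null)) mean(pos_null >= v) else 0
      den <- mean(pos_obs >= v)
    } else {
      num <- if (length(neg_null)) mean(neg_null <= v) else 0
      den <- mean(neg_obs <= v)
    }
    fdr[i] <- min(1, num / den)
  }

  out <- data.frame(set = names(restricted), size = as.integer(sizes),
                    es = unname(es_obs), nes = unname(nes),
                    p_nominal = unname(p_nom), fdr_q = unname(fdr),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$nes, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "excluded") <- excluded
  attr(out, "n_perm") <- as.integer(n_perm)
  out
}

#' Signed set of enrichment terms
#'
#' Builds a [signed_set()] of gene-set terms from an enrichment table,
#' signed by NES, so that term-level overlap and concordance analyses use
#' the same machinery as transcript-level ones.
#'
#' @param enrichment An `"enrichment_table"` from [preranked_gsea()].
#' @param mode `"p_nominal"` or `"fdr_q"`.
#' @param alpha Significance threshold.
#' @return A [signed_set()] of term names scored by NES.
#' @export
term_set <- function(enrichment, mode = c("p_nominal", "fdr_q"), alpha = 0.01) {
  mode <- match.arg(mode)
  stat <- enrichment[[mode]]
  keep <- !is.na(stat) & stat < alpha & !is.na(enrichment$nes) &
    enrichment$nes != 0
  signed_set(enrichment$set[keep], enrichment$nes[keep],
             provenance = sprintf("%s < %g", mode, alpha))
}

#' Hypergeometric over-representation analysis
#'
#' For every gene set, the upper-tail hypergeometric probability of the
#' observed hit overlap given the universe, with BH adjustment across
#' sets. This is the generic over-representation test that ontology tools
#' perform.
#'
#' @param hits Character vector of hit gene ids (must lie in `universe`).
#' @param sets A [gene_set_collection()].
#' @param universe Character vector of background gene ids.
#' @return Data frame with `set`, `size` (set size within the universe),
#'   `n_hit` (overlap with hits), `p`, `q` (BH), ordered by `p`.
#' @export
overrepresentation <- function(hits, sets, universe) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    abort("validation error: hit(s) outside the universe: %s",
          paste(utils::head(outside, 5L), collapse = ", "))
  }
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, hits))
    p <- stats::phyper(k - 1, m = length(s),
                       n = length(universe) - length(s),
                       k = length(hits), lower.tail = FALSE)
    data.frame(set = nm, size = length(s), n_hit = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
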