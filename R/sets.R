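# Set algebra over signed gene (or term) sets: significance selection,
# stimulation-specific sets, the percent-overlap convention, hypergeometric
# overlap significance, and sign concordance. The same machinery serves
# transcript-level DE tables and GSEA term tables (signed by NES).

#' Construct a signed set
#'
#' A signed set records, for each member id, the direction of its change
#' (+1/-1, e.g. the sign of a log2 fold change or of a normalized
#' enrichment score) together with the score itself.
#'
#' @param id Character vector of unique member ids.
#' @param score Numeric scores; the sign of each must be nonzero.
#' @param provenance Free-text note on the source table and threshold.
#' @return Data frame of class `"signed_set"` with columns `id`, `sign`,
#'   `score` and a `"provenance"` attribute.
#' @export
signed_set <- function(id, score, provenance = "") {
  id <- as.character(id)
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    abort("validation error: duplicate member(s): %s",
          paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (length(score) != length(id)) {
    abort("validation error: id and score lengths differ")
  }
  if (any(is.na(score)) || any(score == 0)) {
    abort("validation error: scores must be nonzero and non-missing (sign undefined at 0)")
  }
  out <- data.frame(id = id, sign = sign(score), score = score,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("signed_set", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' Select the significant signed set from a DE table
#'
#' Members are the genes whose chosen statistic (`padj` or `pvalue`) is
#' below `alpha` and whose `l2fc` is nonzero, signed by the fold change.
#' Genes with `l2fc` exactly 0 (sign undefined) or a missing statistic are
#' excluded; their counts are stored in the `"n_zero_excluded"` and
#' `"n_na_excluded"` attributes. Conventional thresholds are the strict
#' `padj < 0.1` and the relaxed `pvalue < 0.01` used for cross-dataset
#' comparisons.
#'
#' @param de A `"de_table"` data frame.
#' @param mode `"padj"` or `"pvalue"`.
#' @param alpha Significance threshold in (0, 1).
#' @return A [signed_set()] scored by `l2fc`.
#' @export
significant_set <- function(de, mode = c("padj", "pvalue"), alpha = 0.1) {
  mode <- match.arg(mode)
  validate_de_table(de)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("validation error: alpha must be in (0, 1)")
  }
  stat <- de[[mode]]
  if (mode == "padj" && nrow(de) > 0 && all(is.na(stat))) {
    abort("padj is entirely missing; rerun with mode = \"pvalue\"")
  }
  na_stat <- is.na(stat)
  hit <- !na_stat & stat < alpha
  zero <- hit & de$l2fc == 0
  keep <- hit & de$l2fc != 0
  out <- signed_set(de$gene_id[keep], de$l2fc[keep],
                    provenance = sprintf("%s < %g", mode, alpha))
  attr(out, "n_zero_excluded") <- sum(zero)
  attr(out, "n_na_excluded") <- sum(na_stat)
  out
}

#' Signed set over every testable gene of a DE table
#'
#' Convenience constructor for population-wide analyses (e.g. the
#' length-shift statistics over the whole filtered translatome): all genes
#' with a nonzero fold change, signed by `l2fc`.
#'
#' @param de A `"de_table"` data frame.
#' @return A [signed_set()].
#' @export
as_signed_set <- function(de) {
  validate_de_table(de)
  keep <- !is.na(de$l2fc) & de$l2fc != 0
  signed_set(de$gene_id[keep], de$l2fc[keep], provenance = "all genes")
}

#' Stimulation-specific set
#'
#' Removes from `a` every member also present in `b`, preserving signs:
#' e.g. the "LTP-specific" population is the LTP-significant set minus
#' transcripts also significant with LTD.
#'
#' @param a,b [signed_set()] objects.
#' @return A [signed_set()] containing the members of `a` absent from `b`.
#' @export
specific_set <- function(a, b) {
  keep <- !(a$id %in% b$id)
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signed_set", "data.frame")
  attr(out, "provenance") <- sprintf("(%s) minus (%s)",
                                     attr(a, "provenance"),
                                     attr(b, "provenance"))
  out
}

#' Percent overlap between two signed sets
#'
#' The percentage is computed for the first set (the "first Venn circle"):
#' `100 * |a intersect b| / |a|`. Same-sign and opposite-sign percentages
#' are computed over the overlap. The statistic is asymmetric by design;
#' swapping the arguments changes only the denominator.
#'
#' @param a,b [signed_set()] objects; `a` supplies the denominator.
#' @return An `"overlap_report"` (see [overlap_report()]) without an
#'   overlap p value.
#' @export
percent_overlap <- function(a, b) {
  overlap_report(a, b, universe = NULL)
}

#' Hypergeometric overlap significance
#'
#' Upper-tail hypergeometric probability of observing at least the
#' realized overlap when `|a|` draws are taken without replacement from a
#' universe containing `|b|` successes:
#' `P(X >= |a intersect b|)` with `X ~ Hypergeometric(|universe|, |b|, |a|)`.
#'
#' @param a,b [signed_set()] objects (or character vectors of ids).
#' @param universe Character vector of ids; both sets must be subsets.
#'   A natural choice is the intersection of genes tested in both source
#'   tables.
#' @return One-sided p value.
#' @export
hypergeometric_overlap <- function(a, b, universe) {
  ids_a <- if (is.data.frame(a)) a$id else as.character(a)
  ids_b <- if (is.data.frame(b)) b$id else as.character(b)
  universe <- unique(as.character(universe))
  outside <- setdiff(c(ids_a, ids_b), universe)
  if (length(outside)) {
    abort("validation error: member(s) outside the universe: %s",
          paste(utils::head(outside, 5L), collapse = ", "))
  }
  k <- length(intersect(ids_a, ids_b))
  stats::phyper(k - 1, m = length(ids_b),
                n = length(universe) - length(ids_b),
                k = length(ids_a), lower.tail = FALSE)
}

#' Sign concordance over an overlap
#'
#' Over the members common to both sets, counts how many change in the
#' same direction and how many in opposite directions, with percentages of
#' the overlap.
#'
#' @param a,b [signed_set()] objects.
#' @return List with `n_overlap`, `n_same_sign`, `n_opposite_sign`,
#'   `percent_same_sign`, `percent_opposite_sign` (percentages are `NA`
#'   for an empty overlap).
#' @export
concordance <- function(a, b) {
  shared <- intersect(a$id, b$id)
  sa <- a$sign[match(shared, a$id)]
  sb <- b$sign[match(shared, b$id)]
  n_same <- sum(sa == sb)
  n_opp <- length(shared) - n_same
  pct <- function(x) if (length(shared)) 100 * x / length(shared) else NA_real_
  list(n_overlap = length(shared), n_same_sign = n_same,
       n_opposite_sign = n_opp, percent_same_sign = pct(n_same),
       percent_opposite_sign = pct(n_opp))
}

#' Full overlap report for two signed sets
#'
#' Assembles the percent-overlap convention, sign concordance, and (when a
#' universe is supplied) the hypergeometric overlap p value into one
#' record.
#'
#' @param a,b [signed_set()] objects; `a` is the "first Venn circle" whose
#'   size is the percentage denominator.
#' @param universe Optional id universe for [hypergeometric_overlap()];
#'   `NULL` skips the significance test (`p_hyper = NA`).
#' @return List of class `"overlap_report"`: `n_first`, `n_second`,
#'   `n_overlap`, `percent_overlap` (= 100 * n_overlap / n_first, `NA`
#'   with a warning when `n_first` is 0), `p_hyper`, `n_same_sign`,
#'   `n_opposite_sign`, `percent_same_sign`, `percent_opposite_sign`.
#' @export
overlap_report <- function(a, b, universe = NULL) {
  n_first <- nrow(a)
  n_second <- nrow(b)
  conc <- concordance(a, b)
  if (n_first == 0) {
    warn("first set is empty; percent overlap undefined")
    pct <- NA_real_
  } else {
    pct <- 100 * conc$n_overlap / n_first
  }
  p_hyper <- if (is.null(universe)) NA_real_ else
    hypergeometric_overlap(a, b, universe)
  structure(list(n_first = n_first, n_second = n_second,
                 n_overlap = conc$n_overlap, percent_overlap = pct,
                 p_hyper = p_hyper, n_same_sign = conc$n_same_sign,
                 n_opposite_sign = conc$n_opposite_sign,
                 percent_same_sign = conc$percent_same_sign,
                 percent_opposite_sign = conc$percent_opposite_sign),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap: %d of %d (first set) with %d (second set): %s%%\n",
              x$n_overlap, x$n_first, x$n_second,
              if (is.na(x$percent_overlap)) "NA" else
                format(round(x$percent_overlap, 2))))
  if (!is.na(x$p_hyper)) {
    cat(sprintf("  hypergeometric p = %.3g\n", x$p_hyper))
  }
  if (x$n_overlap > 0) {
    cat(sprintf("  same direction: %d (%.2f%%), opposite: %d (%.2f%%)\n",
                x$n_same_sign, x$percent_same_sign,
                x$n_opposite_sign, x$percent_opposite_sign))
  }
  invisible(x)
}
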