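# Paired differential-translation stage: median-of-ratios normalization,
# the low-expression filter, a paired log-ratio location test, and BH
# adjustment. The location test is a deliberately simple, fully specified
# stand-in for a negative-binomial Wald test: externally computed DE
# tables can always be supplied through read_de_table() when full GLM
# machinery is required.

check_design <- function(counts, design) {
  if (!all(c("sample", "pair", "condition") %in% names(design))) {
    abort("design error: design needs columns sample, pair, condition")
  }
  if (!setequal(design$sample, colnames(counts))) {
    abort("design error: design samples do not match count matrix columns")
  }
  if (!setequal(unique(design$condition), c("control", "perturbed"))) {
    abort("design error: condition must take values 'control' and 'perturbed'")
  }
  tab <- table(design$pair, design$condition)
  if (any(tab != 1L)) {
    abort("design error: every pair label must appear exactly once per condition")
  }
  if (nrow(tab) < 2L) abort("design error: at least 2 pairs required")
  invisible(design)
}

#' Median-of-ratios size factors
#'
#' Computes per-sample normalization factors by the standard
#' median-of-ratios estimator: each count is divided by the per-gene
#' geometric mean across samples (using only genes expressed in every
#' sample), and the per-sample median of these ratios is the raw factor.
#' Factors are then rescaled to have geometric mean 1, so normalized
#' counts live on a common scale whose unit is anchored to the experiment
#' as a whole.
#'
#' @param counts Non-negative count matrix (genes x samples).
#' @return Named numeric vector of positive size factors with geometric
#'   mean 1 (to numerical tolerance).
#' @export
#' @examples
#' m <- matrix(c(10, 20, 10, 20, 20, 40, 20, 40), nrow = 2)
#' f <- median_of_ratios(m)
#' abs(prod(f)^(1 / length(f)) - 1) < 1e-9
median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("normalization error: negative counts")
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable)) {
    abort(paste("normalization error: no gene has nonzero counts in every",
                "sample; consider adding a pseudocount before normalizing"))
  }
  geo <- exp(rowMeans(log(counts[usable, , drop = FALSE])))
  raw <- apply(counts[usable, , drop = FALSE], 2, function(col) {
    stats::median(col / geo)
  })
  factors <- raw / geometric_mean(raw)
  stats::setNames(factors, colnames(counts))
}

#' Low-expression filter
#'
#' Retains a gene if its normalized count (raw count divided by the sample
#' size factor) is at least `min_count` in at least `min_samples` samples;
#' this is the conventional "at least 10 normalized counts in a minimum of
#' three samples" rule used when filtering TRAP-seq count tables.
#'
#' @param counts Count matrix (genes x samples) with gene ids as row names.
#' @param factors Size factors from [median_of_ratios()].
#' @param min_count Normalized-count threshold (default 10).
#' @param min_samples Minimum number of samples meeting the threshold
#'   (default 3).
#' @return List with `retained` (character vector of gene ids) and
#'   `n_removed` (count of filtered genes).
#' @export
filter_low_expression <- function(counts, factors, min_count = 10,
                                  min_samples = 3) {
  counts <- as.matrix(counts)
  if (is.null(names(factors)) || !setequal(names(factors), colnames(counts))) {
    abort("normalization error: factors must be named for every sample")
  }
  norm <- sweep(counts, 2, factors[colnames(counts)], "/")
  keep <- rowSums(norm >= min_count) >= min_samples
  list(retained = rownames(counts)[keep], n_removed = sum(!keep))
}

#' Paired differential-translation test
#'
#' For each retained gene, forms one log2 ratio per pair,
#' \deqn{r_i = \log_2\frac{x_{perturbed,i}/f_{perturbed,i} + c}
#'                        {x_{control,i}/f_{control,i} + c},}
#' with pseudocount `c` on normalized counts, and reports the mean ratio
#' as `l2fc`, its standard error `sd(r)/sqrt(n_pairs)`, and a two-sided
#' one-sample t test of the ratios against zero. Adjusted p values are
#' Benjamini-Hochberg over the retained genes. `base_mean` is the mean
#' normalized count. No fold-change shrinkage is applied (flagged in the
#' `"shrinkage"` attribute of the result).
#'
#' @param counts Count matrix (genes x samples) with gene ids as row names.
#' @param design Data frame with columns `sample`, `pair`, `condition`
#'   (`"control"`/`"perturbed"`); every pair must appear exactly once per
#'   condition and there must be at least 2 pairs.
#' @param factors Size factors; computed by [median_of_ratios()] when
#'   `NULL`.
#' @param retained Gene ids to test; all genes when `NULL`. Typically the
#'   `retained` element of [filter_low_expression()].
#' @param pseudocount Pseudocount `c` added to normalized counts before
#'   the log ratio (default 0.5).
#' @return A `"de_table"` data frame (gene_id, base_mean, l2fc, l2fc_se,
#'   pvalue, padj), one row per retained gene, in the input gene order.
#' @export
paired_de <- function(counts, design, factors = NULL, retained = NULL,
                      pseudocount = 0.5) {
  counts <- as.matrix(counts)
  check_design(counts, design)
  if (is.null(factors)) factors <- median_of_ratios(counts)
  if (is.null(retained)) retained <- rownames(counts)
  if (!length(retained)) abort("design error: no retained genes to test")
  counts <- counts[retained, , drop = FALSE]
  norm <- sweep(counts, 2, factors[colnames(counts)], "/")

  pairs <- sort(unique(design$pair))
  ctrl_cols <- design$sample[match(paste(pairs, "control"),
                                   paste(design$pair, design$condition))]
  pert_cols <- design$sample[match(paste(pairs, "perturbed"),
                                   paste(design$pair, design$condition))]
  np <- length(pairs)
  ratios <- log2((norm[, pert_cols, drop = FALSE] + pseudocount) /
                 (norm[, ctrl_cols, drop = FALSE] + pseudocount))
  l2fc <- rowMeans(ratios)
  ss <- rowSums((ratios - l2fc)^2)
  sd_r <- sqrt(ss / (np - 1))
  se <- sd_r / sqrt(np)
  tstat <- l2fc / se               # Inf when se == 0 and l2fc != 0
  pvalue <- 2 * stats::pt(-abs(tstat), df = np - 1)
  pvalue[se == 0 & l2fc == 0] <- 1  # constant zero ratios: no evidence
  out <- data.frame(gene_id = retained, base_mean = rowMeans(norm),
                    l2fc = l2fc, l2fc_se = se, pvalue = pvalue,
                    padj = bh_adjust(pvalue), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  attr(out, "shrinkage") <- "none"
  attr(out, "pseudocount") <- pseudocount
  attr(out, "n_pairs") <- np
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement over the non-missing p values
#' (wrapping [stats::p.adjust()]); missing values are excluded from the
#' adjustment and returned missing, matching the convention of DE tools
#' that emit `NA` adjusted p values for filtered genes.
#'
#' @param pvalues Numeric vector of p values in \[0, 1\], `NA` allowed.
#' @return Adjusted p values, same length and order, `NA` where input was
#'   `NA`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) abort("validation error: p values must be numeric")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("validation error: p values outside [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}
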