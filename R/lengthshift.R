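# CDS-length translation-shift signature: correlation of fold change with
# (log) feature length, per-bin two-sample z statistics against the full
# population, and the long-transcript set.

#' Correlation of fold change with feature length
#'
#' Pearson correlation between the scores of a signed set (log2 fold
#' changes) and `log10(length + 1)` of a chosen genomic feature over the
#' annotated members. Genes lacking annotation are dropped and counted.
#' The log transform reflects the roughly log-normal distribution of CDS
#' lengths; `transform = "raw"` uses untransformed lengths.
#'
#' @param sig A [signed_set()] scored by l2fc.
#' @param annotation A `"gene_annotation"` table from
#'   [select_most_abundant()].
#' @param feature One of `"cds"`, `"tx"`, `"utr5"`, `"utr3"`.
#' @param transform `"log10"` (default) or `"raw"`.
#' @return List with `r`, `p`, `n` (genes used), `n_dropped` (members
#'   without annotation), and `feature`.
#' @export
length_correlation <- function(sig, annotation,
                               feature = c("cds", "tx", "utr5", "utr3"),
                               transform = c("log10", "raw")) {
  feature <- match.arg(feature)
  transform <- match.arg(transform)
  col <- paste0(feature, "_length")
  idx <- match(sig$id, annotation$gene_id)
  ok <- !is.na(idx)
  n_dropped <- sum(!ok)
  len <- annotation[[col]][idx[ok]]
  y <- sig$score[ok]
  if (length(y) < 3) {
    abort("insufficient data: only %d annotated significant gene(s), need >= 3",
          length(y))
  }
  x <- if (transform == "log10") log10(len + 1) else len
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(y),
       n_dropped = n_dropped, feature = feature)
}

#' Binned CDS-length z statistics
#'
#' Splits the annotated genes of a population DE table into the four CDS
#' length bins of [assign_bin()] and, for each bin, computes a two-sample
#' z statistic of the bin's mean log2 fold change against the reference
#' population with unpooled (Welch-style) variances:
#' \deqn{z = \frac{\bar{x}_{bin} - \bar{x}_{ref}}
#'   {\sqrt{s^2_{bin}/n_{bin} + s^2_{ref}/n_{ref}}}}
#' with a two-sided normal p value. `reference = "all"` (default) takes
#' the reference to be every annotated gene of the population, bin
#' included, matching the usual ">4 kb vs all" presentation; because the
#' bin then overlaps its own reference this variant is conservative.
#' `reference = "rest"` excludes the bin, which is the calibrated Welch
#' two-sample form. Bins with fewer than 2 genes are skipped with a
#' warning.
#'
#' @param population A `"de_table"` data frame (commonly either the whole
#'   filtered translatome or the relaxed-significant population).
#' @param annotation A `"gene_annotation"` table.
#' @param reference `"all"` or `"rest"`.
#' @return List of class `"length_shift_report"`: `bins` (data frame with
#'   `bin`, `n`, `mean_l2fc`, `z`, `p`), `n_all`, `mean_all`,
#'   `n_unannotated`, `reference`.
#' @export
binned_ztest <- function(population, annotation, reference = c("all", "rest")) {
  reference <- match.arg(reference)
  validate_de_table(population)
  idx <- match(population$gene_id, annotation$gene_id)
  ok <- !is.na(idx) & !is.na(population$l2fc)
  n_unannotated <- sum(is.na(idx))
  if (!any(ok)) abort("no annotated genes in the population")
  y <- population$l2fc[ok]
  bin <- assign_bin(annotation$cds_length[idx[ok]])
  n_all <- length(y)
  mean_all <- mean(y)
  var_all <- stats::var(y)

  rows <- lapply(cds_bin_labels, function(lb) {
    g <- y[bin == lb]
    nb <- length(g)
    if (nb < 2L) {
      warn("bin '%s' has %d gene(s); z test skipped", lb, nb)
      return(data.frame(bin = lb, n = nb,
                        mean_l2fc = if (nb) mean(g) else NA_real_,
                        z = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    if (reference == "all") {
      mr <- mean_all; vr <- var_all; nr <- n_all
    } else {
      r <- y[bin != lb]
      mr <- mean(r); vr <- stats::var(r); nr <- length(r)
    }
    diff <- mean(g) - mr
    z <- if (diff == 0) 0 else diff / sqrt(stats::var(g) / nb + vr / nr)
    data.frame(bin = lb, n = nb, mean_l2fc = mean(g), z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  structure(list(bins = bins, n_all = n_all, mean_all = mean_all,
                 n_unannotated = n_unannotated, reference = reference),
            class = "length_shift_report")
}

#' @export
print.length_shift_report <- function(x, ...) {
  cat(sprintf("length shift over %d annotated genes (mean l2fc %.3f, reference '%s')\n",
              x$n_all, x$mean_all, x$reference))
  print(transform(x$bins, mean_l2fc = round(mean_l2fc, 3),
                  z = round(z, 3), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Significant long-transcript set
#'
#' The significantly changed genes whose CDS length exceeds a threshold
#' (default 2,000 bases: the union of the "2-4 kb" and ">4 kb" bins),
#' signed by fold change, with the up/down breakdown that summarizes
#' whether the long translatome is predominantly up- or downregulated.
#'
#' @param population A `"de_table"` data frame.
#' @param annotation A `"gene_annotation"` table.
#' @param threshold CDS length threshold in bases (default 2000,
#'   exclusive: members satisfy `cds_length > threshold`).
#' @param mode,alpha Passed to [significant_set()].
#' @return A [signed_set()] with attributes `n_up`, `n_down`, and
#'   `percent_up` (100 * n_up / set size, `NA` for an empty set).
#' @export
long_set <- function(population, annotation, threshold = 2000,
                     mode = c("padj", "pvalue"), alpha = 0.1) {
  sig <- significant_set(population, mode = match.arg(mode), alpha = alpha)
  idx <- match(sig$id, annotation$gene_id)
  keep <- !is.na(idx) & annotation$cds_length[idx] > threshold
  out <- sig[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signed_set", "data.frame")
  attr(out, "provenance") <- sprintf("%s, cds > %g", attr(sig, "provenance"),
                                     threshold)
  attr(out, "n_up") <- sum(out$sign > 0)
  attr(out, "n_down") <- sum(out$sign < 0)
  attr(out, "percent_up") <- if (nrow(out)) 100 * sum(out$sign > 0) / nrow(out)
                             else NA_real_
  out
}
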