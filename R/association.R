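# Cross-dataset association: how one dataset's significant transcripts
# behave in another dataset. Correlation with linear and penalized-spline
# fits, and up/down group-shift tests.

#' Correlate a reference signed set with a query translatome
#'
#' Pairs the reference scores (log2 fold changes of the significant set in
#' dataset A) with the query fold changes of the same genes in dataset B,
#' and reports the Pearson correlation with a two-sided p value, the
#' ordinary least-squares line, and a penalized cubic regression spline
#' smoother (10 basis functions, smoothness by GCV) as fitted by
#' [mgcv::gam()]. Both curves are evaluated on a 100-point grid over the
#' observed reference range; the maximum absolute difference between them
#' (`linear_vs_gam_max_gap`) measures how far the relationship departs
#' from linearity.
#'
#' @param reference_sig A [signed_set()] whose `score` column holds the
#'   reference log2 fold changes.
#' @param query A `"de_table"` data frame for the query dataset.
#' @param n_grid Grid size for the curve comparison (default 100).
#' @return List of class `"association_result"`: `r`, `r2` (= r^2), `p_r`,
#'   `n`, `gam_deviance_fraction` (deviance explained by the spline fit),
#'   `linear_vs_gam_max_gap`, and `grid` (data frame of both fitted curves
#'   for plotting).
#' @export
cross_correlate <- function(reference_sig, query, n_grid = 100) {
  validate_de_table(query)
  if (anyDuplicated(query$gene_id)) {
    warn("duplicate gene ids in query; keeping first occurrence")
    query <- query[!duplicated(query$gene_id), , drop = FALSE]
  }
  idx <- match(reference_sig$id, query$gene_id)
  ok <- !is.na(idx) & !is.na(query$l2fc[idx])
  x <- reference_sig$score[ok]
  y <- query$l2fc[idx[ok]]
  n <- length(x)
  if (n < 3) abort("insufficient data: only %d shared gene(s), need >= 3", n)

  ct <- stats::cor.test(x, y, method = "pearson")
  fit_lm <- stats::lm(y ~ x)
  grid_x <- seq(min(x), max(x), length.out = n_grid)
  pred_lm <- stats::predict(fit_lm, newdata = data.frame(x = grid_x))

  k <- max(3L, min(10L, length(unique(x)) - 1L))
  gam_ok <- length(unique(x)) >= 4L
  if (gam_ok) {
    fit_gam <- mgcv::gam(y ~ s(x, bs = "cr", k = k), method = "GCV.Cp")
    pred_gam <- as.numeric(stats::predict(fit_gam,
                                          newdata = data.frame(x = grid_x)))
    dev_fraction <- 1 - sum(stats::residuals(fit_gam)^2) /
      sum((y - mean(y))^2)
  } else {
    warn("too few distinct reference values for a spline fit; using the linear fit")
    pred_gam <- pred_lm
    dev_fraction <- summary(fit_lm)$r.squared
  }

  structure(list(
    r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
    p_r = ct$p.value, n = n,
    gam_deviance_fraction = dev_fraction,
    linear_vs_gam_max_gap = max(abs(pred_gam - pred_lm)),
    grid = data.frame(x = grid_x, linear = pred_lm, gam = pred_gam)),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association: n = %d, r = %.3f, R^2 = %.3f, p = %.3g\n",
              x$n, x$r, x$r2, x$p_r))
  cat(sprintf("  spline deviance fraction = %.3f, max |linear - spline| gap = %.3g\n",
              x$gam_deviance_fraction, x$linear_vs_gam_max_gap))
  invisible(x)
}

#' Group-shift test of reference up/down sets in a query translatome
#'
#' Tests whether the query log2 fold changes of a reference-upregulated
#' and a reference-downregulated gene group are shifted. A Kruskal-Wallis
#' test compares the two groups' query distributions; post hoc, each group
#' is compared by a two-sided Wilcoxon rank-sum test against either the
#' query fold changes of all genes in neither group
#' (`reference = "rest"`, the default, which makes "no change" an
#' interpretable outcome) or a one-sample test against median zero
#' (`reference = "zero"`).
#'
#' @param reference_up,reference_down Character vectors (or
#'   [signed_set()]s) of gene ids up-/downregulated in the reference
#'   dataset.
#' @param query A `"de_table"` data frame for the query dataset.
#' @param reference `"rest"` or `"zero"` (see above).
#' @return List of class `"group_shift_result"`: `p_kw`, `p_up`, `p_down`,
#'   and per-group `n`, `median`, `iqr`.
#' @export
group_shift <- function(reference_up, reference_down, query,
                        reference = c("rest", "zero")) {
  reference <- match.arg(reference)
  validate_de_table(query)
  ids_up <- if (is.data.frame(reference_up)) reference_up$id else
    as.character(reference_up)
  ids_down <- if (is.data.frame(reference_down)) reference_down$id else
    as.character(reference_down)
  q <- query[!is.na(query$l2fc), , drop = FALSE]
  up <- q$l2fc[q$gene_id %in% ids_up]
  down <- q$l2fc[q$gene_id %in% ids_down]
  if (!length(up)) abort("empty group after intersection: up-group")
  if (!length(down)) abort("empty group after intersection: down-group")
  rest <- q$l2fc[!(q$gene_id %in% c(ids_up, ids_down))]

  p_kw <- tryCatch(stats::kruskal.test(list(up = up, down = down))$p.value,
                   error = function(e) NA_real_)
  if (is.na(p_kw)) warn("Kruskal-Wallis p undefined on degenerate groups")
  test_one <- function(g) {
    p <- tryCatch({
      if (reference == "rest") {
        if (!length(rest)) abort("empty group after intersection: rest")
        suppressWarnings(stats::wilcox.test(g, rest)$p.value)
      } else {
        suppressWarnings(stats::wilcox.test(g, mu = 0)$p.value)
      }
    }, error = function(e) NA_real_)
    if (is.na(p)) warn("Wilcoxon p undefined on a degenerate group")
    p
  }
  stats_of <- function(g) {
    list(n = length(g), median = stats::median(g), iqr = stats::IQR(g))
  }
  structure(list(p_kw = p_kw, p_up = test_one(up), p_down = test_one(down),
                 up = stats_of(up), down = stats_of(down),
                 reference = reference),
            class = "group_shift_result")
}

#' @export
print.group_shift_result <- function(x, ...) {
  cat(sprintf("group shift (vs %s): Kruskal-Wallis p = %.3g\n",
              x$reference, x$p_kw))
  cat(sprintf("  up-group   n = %d, median = %.3f, IQR = %.3f, Wilcoxon p = %.3g\n",
              x$up$n, x$up$median, x$up$iqr, x$p_up))
  cat(sprintf("  down-group n = %d, median = %.3f, IQR = %.3f, Wilcoxon p = %.3g\n",
              x$down$n, x$down$median, x$down$iqr, x$p_down))
  invisible(x)
}
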