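# Gene-level length annotation: collapse per-transcript features to one
# record per gene by abundance, and bin CDS lengths.

#' Collapse transcript features to gene-level length annotation
#'
#' For every gene, selects the transcript with the highest abundance
#' (TPM); the four length fields of that transcript become the gene's
#' annotation. This mirrors the usual "length of the most abundant
#' transcript" convention for gene-level CDS-length analyses. Ties on TPM
#' are broken by longest CDS, then by lexicographically smallest
#' transcript id; genes whose transcripts all have zero TPM follow the
#' same tie-break path and are reported in a warning.
#'
#' @param features Per-transcript feature table with the columns of
#'   [read_transcript_features()].
#' @return Data frame of class `"gene_annotation"` with one row per gene:
#'   `gene_id`, `transcript_id` (the chosen transcript), `cds_length`,
#'   `tx_length`, `utr5_length`, `utr3_length`. Row order follows the
#'   first appearance of each gene; the result is invariant to input row
#'   order up to this ordering.
#' @export
#' @examples
#' f <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g", "g"),
#'                 cds_length = c(900, 3000), tx_length = c(1500, 4000),
#'                 utr5_length = c(100, 200), utr3_length = c(500, 800),
#'                 tpm = c(10, 5))
#' select_most_abundant(f)$cds_length  # 900: t1 wins on abundance
select_most_abundant <- function(features) {
  needed <- c("transcript_id", "gene_id", "cds_length", "tx_length",
              "utr5_length", "utr3_length", "tpm")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols)) {
    abort("format error: feature table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(features$tpm))) {
    abort("validation error: every transcript needs a TPM value")
  }
  zero_tpm <- tapply(features$tpm, features$gene_id, max) == 0
  if (any(zero_tpm)) {
    warn("%d gene(s) have all-zero TPM; most-abundant choice fell back to the CDS-length/id tie-break",
         sum(zero_tpm))
  }
  ord <- order(match(features$gene_id, unique(features$gene_id)),
               -features$tpm, -features$cds_length, features$transcript_id)
  sorted <- features[ord, , drop = FALSE]
  chosen <- sorted[!duplicated(sorted$gene_id),
                   c("gene_id", "transcript_id", "cds_length", "tx_length",
                     "utr5_length", "utr3_length"), drop = FALSE]
  rownames(chosen) <- NULL
  class(chosen) <- c("gene_annotation", "data.frame")
  chosen
}

cds_bin_labels <- c("<1 kb", "1-2 kb", "2-4 kb", ">4 kb")

#' Assign CDS lengths to the standard length bins
#'
#' Bins are half-open with the lower edge inclusive:
#' \[0, 1000) is `"<1 kb"`, \[1000, 2000) is `"1-2 kb"`,
#' \[2000, 4000) is `"2-4 kb"`, and \[4000, Inf) is `">4 kb"`, so every
#' non-negative length falls in exactly one bin (a length of exactly
#' 2,000 bases is `"2-4 kb"`).
#'
#' @param cds_length Numeric vector of CDS lengths in bases (>= 0).
#' @return Factor with levels `"<1 kb"`, `"1-2 kb"`, `"2-4 kb"`,
#'   `">4 kb"`.
#' @export
#' @examples
#' assign_bin(c(500, 1999, 2000, 4000))
assign_bin <- function(cds_length) {
  if (any(is.na(cds_length)) || any(cds_length < 0)) {
    abort("validation error: CDS lengths must be non-negative and non-missing")
  }
  cut(cds_length, breaks = c(0, 1000, 2000, 4000, Inf),
      labels = cds_bin_labels, right = FALSE, include.lowest = TRUE)
}
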