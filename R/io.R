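# Readers and writers for the tabular artifacts exchanged between stages.
# All tables are plain tab-separated text with a header row, decimal point
# ".", and missing values written as "NA" (the convention of DESeq2 result
# exports and BioMart feature dumps).

de_table_fields <- c("gene_id", "base_mean", "l2fc", "l2fc_se", "pvalue", "padj")

#' Validate a differential-translation results table
#'
#' Checks the structural invariants of a DE table: required columns,
#' unique gene ids, non-negative `base_mean`, and `pvalue`/`padj` in
#' \[0, 1\] where present.
#'
#' @param de A data frame with columns `gene_id`, `base_mean`, `l2fc`,
#'   `l2fc_se`, `pvalue`, `padj`.
#' @return `de`, invisibly, with class `"de_table"` prepended.
#' @export
validate_de_table <- function(de) {
  missing_cols <- setdiff(de_table_fields, names(de))
  if (length(missing_cols)) {
    abort("format error: DE table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  dup <- unique(de$gene_id[duplicated(de$gene_id)])
  if (length(dup)) {
    abort("format error: duplicate gene id(s): %s",
          paste(utils::head(dup, 5L), collapse = ", "))
  }
  num <- c("base_mean", "l2fc", "l2fc_se", "pvalue", "padj")
  bad <- num[!vapply(de[num], is.numeric, logical(1))]
  if (length(bad)) {
    abort("format error: non-numeric column(s): %s", paste(bad, collapse = ", "))
  }
  if (any(de$base_mean < 0, na.rm = TRUE)) {
    abort("format error: negative base_mean")
  }
  for (col in c("pvalue", "padj")) {
    v <- de[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      abort("format error: %s outside [0, 1]", col)
    }
  }
  if (!inherits(de, "de_table")) class(de) <- c("de_table", class(de))
  invisible(de)
}

#' Read a differential-translation results table
#'
#' Reads a tab-separated DE table (e.g. a DESeq2 result export) and maps
#' its headers onto the canonical fields `gene_id`, `base_mean`, `l2fc`,
#' `l2fc_se`, `pvalue`, `padj`. Rows whose mapped numeric fields cannot be
#' parsed are dropped with a warning reporting their row numbers.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   to input column headers; defaults to the identity mapping.
#' @return A validated data frame of class `"de_table"`.
#' @export
#' @examples
#' de <- data.frame(gene_id = c("a", "b"), base_mean = c(10, 20),
#'                  l2fc = c(1, -1), l2fc_se = c(0.1, 0.2),
#'                  pvalue = c(0.01, 0.5), padj = c(0.05, 0.8))
#' f <- tempfile(fileext = ".tsv")
#' write_de_table(de, f)
#' identical(read_de_table(f)$gene_id, c("a", "b"))
read_de_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  map <- stats::setNames(de_table_fields, de_table_fields)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = "NA", quote = "")
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    abort("format error: mapped column(s) absent from %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(gene_id = raw[[map[["gene_id"]]]], stringsAsFactors = FALSE)
  bad_rows <- integer(0)
  for (f in setdiff(de_table_fields, "gene_id")) {
    v <- raw[[map[[f]]]]
    parsed <- suppressWarnings(as.numeric(v))
    bad_rows <- union(bad_rows, which(!is.na(v) & is.na(parsed)))
    out[[f]] <- parsed
  }
  if (length(bad_rows)) {
    warn("rejected %d row(s) with unparseable numerics (rows: %s)",
         length(bad_rows),
         paste(utils::head(sort(bad_rows), 10L), collapse = ", "))
    out <- out[-sort(bad_rows), , drop = FALSE]
    rownames(out) <- NULL
  }
  validate_de_table(out)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write a differential-translation results table
#'
#' @param de A DE table (see [validate_de_table()]).
#' @param path Output path; tab-separated with header, `NA` for missing.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  validate_de_table(de)
  utils::write.table(de[, de_table_fields], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of member gene ids.
#'   Duplicate members within a set are collapsed with a warning.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled to length of `sets`).
#' @return Named list of class `"gene_set_collection"` with a
#'   `"description"` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) && length(sets)) {
    abort("format error: gene sets must be named")
  }
  dup_names <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup_names)) {
    abort("format error: duplicate set name(s): %s",
          paste(dup_names, collapse = ", "))
  }
  n_dup <- sum(vapply(sets, function(m) sum(duplicated(m)), integer(1)))
  if (n_dup > 0) {
    warn("removed %d duplicate member(s) within sets", n_dup)
    sets <- lapply(sets, unique)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  structure(lapply(sets, as.character), class = "gene_set_collection",
            description = stats::setNames(descriptions, names(sets)))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("gene_set_collection: %d sets, sizes %s\n", length(x),
              if (length(x)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Parses the standard GMT format (one set per line: name, description,
#' then tab-separated member ids). Duplicate members within a line are
#' collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort("format error: GMT line(s) with fewer than 3 fields: line %s",
          paste(short, collapse = ", "))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  gene_set_collection(sets,
                      descriptions = vapply(fields, `[[`, character(1), 2L))
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(collection)),
                                             names(collection))
  desc[!nzchar(desc)] <- "na"
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

transcript_fields <- c("transcript_id", "gene_id", "cds_length", "tx_length",
                       "utr5_length", "utr3_length", "tpm")

#' Read a per-transcript feature table
#'
#' Reads a tab-separated table of per-transcript genomic features
#' (BioMart-style lengths plus an abundance column). Transcripts whose CDS
#' length exceeds the transcript length are structurally impossible and
#' are rejected with a warning naming them; non-numeric length or TPM
#' entries are a format error.
#'
#' @param path Path to a tab-separated file with header columns
#'   `transcript_id`, `gene_id`, `cds_length`, `tx_length`, `utr5_length`,
#'   `utr3_length`, `tpm`.
#' @return A data frame with those columns.
#' @export
read_transcript_features <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = "NA", quote = "")
  missing_cols <- setdiff(transcript_fields, names(raw))
  if (length(missing_cols)) {
    abort("format error: feature table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(transcript_id = raw$transcript_id, gene_id = raw$gene_id,
                    stringsAsFactors = FALSE)
  for (f in setdiff(transcript_fields, c("transcript_id", "gene_id"))) {
    parsed <- suppressWarnings(as.numeric(raw[[f]]))
    bad <- which(is.na(parsed))
    if (length(bad)) {
      abort("format error: non-numeric '%s' at row %s", f,
            paste(utils::head(bad, 5L), collapse = ", "))
    }
    out[[f]] <- parsed
  }
  if (any(out$cds_length < 0 | out$tx_length < 0 | out$utr5_length < 0 |
          out$utr3_length < 0 | out$tpm < 0)) {
    abort("format error: negative length or TPM")
  }
  impossible <- out$cds_length > out$tx_length
  if (any(impossible)) {
    warn("rejected %d transcript(s) with cds_length > tx_length: %s",
         sum(impossible),
         paste(utils::head(out$transcript_id[impossible], 5L), collapse = ", "))
    out <- out[!impossible, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write a per-transcript feature table
#'
#' @param features Data frame with the columns listed in
#'   [read_transcript_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_features <- function(features, path) {
  missing_cols <- setdiff(transcript_fields, names(features))
  if (length(missing_cols)) {
    abort("format error: feature table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  utils::write.table(features[, transcript_fields], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a count matrix with its design sidecar
#'
#' Counts go to a tab-separated file whose first column (`gene_id`) holds
#' the gene ids and whose remaining headers are the sample ids; the design
#' table (sample, pair, condition) goes to a sidecar file.
#'
#' @param counts Integer matrix with gene ids as row names.
#' @param design Data frame with columns `sample`, `pair`, `condition`.
#' @param counts_path,design_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(counts, design, counts_path, design_path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design[, c("sample", "pair", "condition")], design_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read a count matrix with its design sidecar
#'
#' @param counts_path,design_path Paths written by [write_counts()].
#' @return List with `counts` (integer matrix) and `design` (data frame).
#' @export
read_counts <- function(counts_path, design_path) {
  df <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1]]
  design <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                              colClasses = "character", quote = "")
  if (!setequal(design$sample, colnames(counts))) {
    abort("format error: design samples do not match count matrix columns")
  }
  list(counts = counts, design = design)
}
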