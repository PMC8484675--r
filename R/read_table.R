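#' Construct a read table
#'
#' A read table holds the per-sample sequence-read counts for every OTU in a
#' metabarcoding run, with each OTU flagged as either a spiked internal
#' standard or a fish OTU. Counts are stored as an integer matrix with samples
#' in rows and OTUs in columns.
#'
#' @param counts Non-negative integer matrix, samples x OTUs, with row and
#'   column names (sample ids and OTU ids).
#' @param standard_ids Character vector of column names that are internal
#'   standards; all other columns are treated as fish OTUs.
#' @return An object of class `read_table`: a list with elements `counts`
#'   (the matrix) and `otu_class` (named character, `"standard"` or `"fish"`).
#' @export
read_table <- function(counts, standard_ids = character()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have sample (row) and OTU (column) names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("sample and OTU ids must be unique")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  missing_std <- setdiff(standard_ids, colnames(counts))
  if (length(missing_std)) {
    stop("standard ids absent from counts: ", paste(missing_std, collapse = ", "))
  }
  storage.mode(counts) <- "double" # large totals can exceed .Machine$integer.max
  otu_class <- ifelse(colnames(counts) %in% standard_ids, "standard", "fish")
  names(otu_class) <- colnames(counts)
  structure(list(counts = counts, otu_class = otu_class), class = "read_table")
}

#' @export
print.read_table <- function(x, ...) {
  cat(sprintf(
    "<read_table> %d samples x %d OTUs (%d standards, %d fish)\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$otu_class == "standard"), sum(x$otu_class == "fish")
  ))
  invisible(x)
}

#' Extract the fish or standard submatrix of a read table
#'
#' @param rt A `read_table`.
#' @return Numeric matrix restricted to the requested OTU class.
#' @export
fish_counts <- function(rt) {
  rt$counts[, rt$otu_class == "fish", drop = FALSE]
}

#' @rdname fish_counts
#' @export
standard_counts <- function(rt) {
  rt$counts[, rt$otu_class == "standard", drop = FALSE]
}

#' Per-sample read accounting
#'
#' Splits each sample's total reads into internal-standard and fish
#' (non-standard) reads and reports the fish fraction, the figure used to
#' check how much of a run's sequencing effort went to biological signal and
#' to confirm that negative controls carry no fish reads.
#'
#' @param rt A `read_table`.
#' @return A data frame with one row per sample (`sample_id`, `total_reads`,
#'   `standard_reads`, `fish_reads`, `fish_pct`) plus an `"overall"` row
#'   pooling all samples. `fish_pct` is a percentage; it is `NA` for samples
#'   with zero total reads.
#' @export
read_accounting <- function(rt) {
  stopifnot(inherits(rt, "read_table"))
  tot <- rowSums(rt$counts)
  std <- rowSums(standard_counts(rt))
  fish <- rowSums(fish_counts(rt))
  out <- data.frame(
    sample_id = rownames(rt$counts),
    total_reads = tot,
    standard_reads = std,
    fish_reads = fish,
    fish_pct = ifelse(tot > 0, 100 * fish / tot, NA_real_),
    row.names = NULL
  )
  overall <- data.frame(
    sample_id = "overall",
    total_reads = sum(tot),
    standard_reads = sum(std),
    fish_reads = sum(fish),
    fish_pct = if (sum(tot) > 0) 100 * sum(fish) / sum(tot) else NA_real_
  )
  rbind(out, overall)
}
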