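#' Construct a variant-count table
#'
#' The central object of the artifact filter: unique target sequences by
#' amplicons, holding read counts, plus per-amplicon read totals. Totals may
#' exceed column sums when low-count variants were collapsed upstream; the
#' totals are the denominators of all per-amplicon frequencies.
#'
#' @param counts integer matrix, variants (rows) x amplicons (columns);
#'   rownames are the variant sequences
#' @param totals per-amplicon total read counts (default: column sums)
#' @return object of class \code{variant_table}
#' @export
variant_table <- function(counts, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have variant sequences as rownames", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (length(totals) != ncol(counts))
    stop("one total per amplicon required", call. = FALSE)
  if (any(colSums(counts) > totals + 1e-9))
    stop("column sums exceed amplicon totals", call. = FALSE)
  if (any(rowSums(counts) == 0))
    stop("every variant needs at least one nonzero cell", call. = FALSE)
  lens <- nchar(rownames(counts))
  structure(list(counts = counts,
                 totals = setNames(as.numeric(totals), colnames(counts)),
                 window = if (length(unique(lens)) == 1L)
                   unique(lens) else NA_integer_),
            class = "variant_table")
}

#' Tabulate a demultiplexing result into a variant table
#' @param demux a \code{\link{demultiplex}} result
#' @return a \code{\link{variant_table}}
#' @export
as_variant_table <- function(demux) {
  tab <- table(demux$assigned$sequence, demux$assigned$amplicon)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  variant_table(counts)
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$counts), "variants x", ncol(x$counts),
      "amplicons;", sum(x$totals), "reads\n")
  invisible(x)
}

#' Read a variant-count table from tab-separated text
#'
#' Variants as rows (first column = sequence), amplicons as columns. An
#' optional row named \code{TOTAL} supplies per-amplicon totals; otherwise
#' column sums are used.
#' @param path file path
#' @return a \code{\link{variant_table}}
#' @export
read_variant_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  seqs <- toupper(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- seqs
  tot_row <- which(seqs == "TOTAL")
  if (length(tot_row) == 1L) {
    totals <- m[tot_row, ]
    m <- m[-tot_row, , drop = FALSE]
    variant_table(m, totals)
  } else {
    variant_table(m)
  }
}

#' Write a variant-count table to tab-separated text
#' @param vt a \code{\link{variant_table}}
#' @param path output path
#' @export
write_variant_table <- function(vt, path) {
  d <- data.frame(sequence = c(rownames(vt$counts), "TOTAL"),
                  rbind(vt$counts, vt$totals), check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
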