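#' @importFrom stats sd setNames rnorm rbinom runif pnorm
#' @importFrom utils read.delim write.table combn head
NULL

# IUPAC degeneracy map (uppercase), including the four plain bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")

.check_iupac <- function(x, what = "primer") {
  chars <- unique(strsplit(toupper(x), "")[[1]])
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0)
    stop(sprintf("non-IUPAC character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(toupper(x))
}

#' Expand an IUPAC string into a character-class regular expression
#' @keywords internal
iupac_regex <- function(primer) {
  primer <- .check_iupac(primer)
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of DNA strings (IUPAC-aware)
#' @param x character vector of DNA sequences
#' @return character vector
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA sequences
#' @keywords internal
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
    character(1))
}

# Homopolymer runs of length >= min_len in a sequence.
# Returns data.frame(start, length, base).
homopolymer_runs <- function(seq, min_len = 3L) {
  chars <- strsplit(seq, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len
  data.frame(start = starts[keep], length = r$lengths[keep],
             base = r$values[keep], stringsAsFactors = FALSE)
}

# Hamming distance between equal-length strings (vectorised over y).
hamming <- function(x, y) {
  xs <- strsplit(x, "")[[1]]
  vapply(strsplit(y, ""), function(ys) sum(xs != ys), integer(1))
}

#' Read sequences from a FASTA or FASTQ file as a named character vector
#' @param path file path
#' @param format "fasta", "fastq" or "auto" (by extension)
#' @return named character vector of uppercase sequences
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write a named character vector of sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
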