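#' Construct a tag sheet
#'
#' A tag sheet maps the short oligonucleotide tags carried at the 5' end of
#' each fusion-primer read to the amplicon (individual x replicate PCR) they
#' identify. The tag universe is the set of all k-mers of the tag length; the
#' sheet records which of those were actually used, which is what the
#' misassignment bound is computed from.
#'
#' @param tag character vector of tag sequences (A/C/G/T, uniform length)
#' @param individual character/integer vector of individual identifiers
#' @param replicate integer vector of replicate indices (default all 1)
#' @return an object of class \code{tag_sheet}: a data.frame with columns
#'   \code{tag}, \code{individual}, \code{replicate}, \code{amplicon}, with
#'   attributes \code{tag_length} and \code{min_pairwise_distance} (reported,
#'   not enforced).
#' @export
tag_sheet <- function(tag, individual, replicate = rep(1L, length(tag))) {
  tag <- toupper(as.character(tag))
  if (length(tag) == 0L) stop("empty tag sheet", call. = FALSE)
  lens <- nchar(tag)
  if (length(unique(lens)) != 1L)
    stop("tags must have uniform length", call. = FALSE)
  if (any(grepl("[^ACGT]", tag)))
    stop("tags must use the A/C/G/T alphabet", call. = FALSE)
  if (anyDuplicated(tag))
    stop("duplicated tag sequences", call. = FALSE)
  if (length(individual) != length(tag) || length(replicate) != length(tag))
    stop("tag, individual and replicate must have equal length", call. = FALSE)
  sheet <- data.frame(tag = tag,
                      individual = as.character(individual),
                      replicate = as.integer(replicate),
                      stringsAsFactors = FALSE)
  sheet$amplicon <- paste0(sheet$individual, ".", sheet$replicate)
  if (anyDuplicated(sheet$amplicon))
    stop("each (individual, replicate) pair must map to a single tag",
         call. = FALSE)
  mind <- NA_integer_
  if (length(tag) > 1L) {
    mind <- min(vapply(seq_along(tag)[-1], function(i)
      min(hamming(tag[i], tag[seq_len(i - 1L)])), integer(1)))
  }
  structure(sheet, class = c("tag_sheet", "data.frame"),
            tag_length = unique(lens), min_pairwise_distance = mind)
}

#' Read a tag sheet from tab-separated text
#'
#' Expected columns: tag, individual, replicate (header optional when the
#' first field looks like a DNA tag).
#' @param path file path
#' @return a \code{\link{tag_sheet}}
#' @export
read_tag_sheet <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  header <- identical(tolower(first[1]), "tag")
  d <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) names(d)[1:3] <- c("tag", "individual", "replicate")
  tag_sheet(d$tag, d$individual, d$replicate)
}

#' Write a tag sheet to tab-separated text
#' @param sheet a \code{tag_sheet}
#' @param path output path
#' @export
write_tag_sheet <- function(sheet, path) {
  write.table(sheet[, c("tag", "individual", "replicate")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Locate a (possibly degenerate) primer in a read
#'
#' Finds the leftmost position at which every primer position's IUPAC base
#' set contains the read base. With \code{max_mismatch > 0}, up to that many
#' positions may fall outside their base set.
#'
#' @param read DNA string (a single read) or character vector of reads
#' @param primer IUPAC DNA string
#' @param max_mismatch allowed mismatches (default 0, exact under IUPAC
#'   expansion)
#' @return integer vector of 1-based match start positions; \code{NA} where
#'   the primer is absent
#' @export
locate_primer <- function(read, primer, max_mismatch = 0L) {
  primer <- .check_iupac(primer)
  if (nchar(primer) == 0L) stop("primer must be non-empty", call. = FALSE)
  read <- toupper(read)
  if (max_mismatch == 0L) {
    pos <- regexpr(iupac_regex(primer), read)
    pos[pos == -1L] <- NA_integer_
    return(as.integer(pos))
  }
  # mismatch-tolerant scan: per-offset set-membership count
  pl <- nchar(primer)
  pset <- IUPAC_SETS[strsplit(primer, "")[[1]]]
  vapply(read, function(r) {
    L <- nchar(r)
    if (L < pl) return(NA_integer_)
    rc <- strsplit(r, "")[[1]]
    for (off in 0:(L - pl)) {
      mm <- 0L
      for (j in seq_len(pl)) {
        if (!(rc[off + j] %in% pset[[j]])) {
          mm <- mm + 1L
          if (mm > max_mismatch) break
        }
      }
      if (mm <= max_mismatch) return(off + 1L)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Demultiplex tagged amplicon reads
#'
#' Each read is expected to carry \code{tag + forward primer + target}. The
#' primer is located (exact IUPAC match by default); the tag is read
#' immediately 5' of the primer match; the retained sequence is the first
#' \code{window} bases 3' of the primer. Reads are assigned to the amplicon
#' their tag maps to; reads with tags outside the used set are tallied as
#' unused-tag reads, the empirical basis of the misassignment bound.
#'
#' @param reads named character vector of read sequences (names = read ids)
#' @param sheet a \code{\link{tag_sheet}}
#' @param primer forward primer (IUPAC)
#' @param window length of retained target sequence (bases; default 188)
#' @param max_mismatch primer mismatches allowed (default 0)
#' @param scan_revcomp also scan the reverse complement of reads lacking a
#'   forward-orientation primer match (default TRUE)
#' @param drop_short drop reads whose post-primer segment is shorter than
#'   \code{window} (default TRUE; fixed-length windows keep per-amplicon
#'   frequencies comparable)
#' @param drop_ambiguous drop assigned reads with non-ACGT bases inside the
#'   retained window (default FALSE)
#' @return an object of class \code{demux_result}: list with elements
#'   \code{assigned} (data.frame read_id, amplicon, individual, replicate,
#'   sequence), \code{unassigned} (data.frame read_id, reason), and
#'   \code{counts} (total, complete_tag, unused_tag)
#' @export
demultiplex <- function(reads, sheet, primer, window = 188L,
                        max_mismatch = 0L, scan_revcomp = TRUE,
                        drop_short = TRUE, drop_ambiguous = FALSE) {
  if (!inherits(sheet, "tag_sheet")) stop("sheet must be a tag_sheet",
                                          call. = FALSE)
  if (nrow(sheet) == 0L) stop("empty tag sheet", call. = FALSE)
  if (window <= 0L) stop("window must be positive", call. = FALSE)
  if (length(reads) == 0L)
    stop("no reads supplied", call. = FALSE)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads <- toupper(reads)
  tlen <- attr(sheet, "tag_length")
  plen <- nchar(primer)

  pos <- locate_primer(reads, primer, max_mismatch = max_mismatch)
  if (scan_revcomp) {
    miss <- which(is.na(pos))
    if (length(miss) > 0) {
      rcpos <- locate_primer(revcomp(reads[miss]), primer,
                             max_mismatch = max_mismatch)
      hit <- !is.na(rcpos)
      if (any(hit)) {
        reads[miss[hit]] <- revcomp(reads[miss[hit]])
        pos[miss[hit]] <- rcpos[hit]
      }
    }
  }

  reason <- rep(NA_character_, length(reads))
  reason[is.na(pos)] <- "no_primer"
  ok <- !is.na(pos)
  incomplete <- ok & pos <= tlen
  reason[incomplete] <- "incomplete_tag"
  ok <- ok & !incomplete

  tag <- rep(NA_character_, length(reads))
  tag[ok] <- substr(reads[ok], pos[ok] - tlen, pos[ok] - 1L)
  target <- rep(NA_character_, length(reads))
  target[ok] <- substr(reads[ok], pos[ok] + plen,
                       pos[ok] + plen + window - 1L)

  short <- ok & nchar(target) < window
  if (drop_short) {
    reason[short] <- "short_window"
    ok <- ok & !short
  }

  used <- ok & tag %in% sheet$tag
  # complete tag = full-length tag present and full window retained
  complete <- ok
  unused <- complete & !used
  reason[unused] <- "unused_tag"

  if (drop_ambiguous) {
    amb <- used & grepl("[^ACGT]", target)
    reason[amb] <- "ambiguous_base"
    used <- used & !amb
  }

  idx <- match(tag[used], sheet$tag)
  assigned <- data.frame(read_id = names(reads)[used],
                         amplicon = sheet$amplicon[idx],
                         individual = sheet$individual[idx],
                         replicate = sheet$replicate[idx],
                         sequence = target[used],
                         stringsAsFactors = FALSE)
  unassigned <- data.frame(read_id = names(reads)[!used],
                           reason = reason[!used],
                           stringsAsFactors = FALSE)
  res <- list(assigned = assigned,
              unassigned = unassigned,
              counts = list(total = length(reads),
                            complete_tag = sum(complete),
                            unused_tag = sum(unused)),
              sheet = sheet,
              window = as.integer(window))
  class(res) <- "demux_result"
  res
}

#' @export
print.demux_result <- function(x, ...) {
  cat("demux_result:", x$counts$total, "reads;",
      nrow(x$assigned), "assigned,", nrow(x$unassigned), "unassigned (",
      x$counts$unused_tag, "with unused tags)\n")
  invisible(x)
}

#' Tag misassignment arithmetic
#'
#' Pure bookkeeping on tag-space and read tallies: the fraction of the tag
#' universe left unused, the upper bound on the read misassignment rate
#' (reads carrying unused tags over reads with complete tags), and the
#' expected number of misassigned reads per amplicon at a given coverage.
#'
#' @param tag_length tag length in bases
#' @param n_used_tags number of distinct tags actually used
#' @param n_unused_tag_reads reads observed with complete but unused tags
#' @param n_complete_tag_reads reads with complete tags (denominator)
#' @param mean_coverage mean reads per amplicon
#' @return list with \code{unused_tag_fraction_of_tag_space},
#'   \code{misassignment_rate_upper_bound},
#'   \code{expected_misassigned_reads_per_amplicon}
#' @export
misassignment_summary <- function(tag_length, n_used_tags,
                                  n_unused_tag_reads, n_complete_tag_reads,
                                  mean_coverage = NA_real_) {
  if (n_complete_tag_reads <= 0)
    stop("misassignment rate undefined for zero reads", call. = FALSE)
  space <- 4^tag_length
  rate <- n_unused_tag_reads / n_complete_tag_reads
  list(unused_tag_fraction_of_tag_space = (space - n_used_tags) / space,
       misassignment_rate_upper_bound = rate,
       expected_misassigned_reads_per_amplicon = rate * mean_coverage)
}

#' Estimate the tag misassignment rate from a demultiplexing result
#'
#' Reads whose (complete) tag matches none of the used tags must stem from
#' tag synthesis or sequencing errors. Because the unused portion of the tag
#' space is large, nearly all corrupted tags land outside the used set, so
#' the unused-tag read fraction bounds the rate at which corrupted tags land
#' \emph{on} used tags and silently misassign reads.
#'
#' @param demux a \code{\link{demultiplex}} result
#' @param mean_coverage mean reads per amplicon; default: computed from the
#'   assigned reads over the amplicons of the tag sheet
#' @return list as in \code{\link{misassignment_summary}}
#' @export
estimate_misassignment <- function(demux, mean_coverage = NULL) {
  if (is.null(mean_coverage))
    mean_coverage <- nrow(demux$assigned) / nrow(demux$sheet)
  misassignment_summary(attr(demux$sheet, "tag_length"),
                        nrow(demux$sheet),
                        demux$counts$unused_tag,
                        demux$counts$complete_tag,
                        mean_coverage)
}

#' Coverage and uniqueness summary of a demultiplexing result
#'
#' @param demux a \code{\link{demultiplex}} result
#' @return list with coverage statistics (over amplicons that received at
#'   least one read), \code{n_unique_variants}, \code{n_singletons} (unique
#'   sequences represented by exactly one read in the whole dataset) and
#'   \code{singleton_fraction} of all assigned reads
#' @export
coverage_summary <- function(demux) {
  if (nrow(demux$assigned) == 0L) stop("no assigned reads", call. = FALSE)
  cov <- table(demux$assigned$amplicon)
  tab <- table(demux$assigned$sequence)
  n_singl <- sum(tab == 1L)
  list(mean_coverage = mean(cov), sd_coverage = sd(cov),
       min_coverage = min(cov), max_coverage = max(cov),
       n_amplicons = length(cov),
       n_unique_variants = length(tab),
       n_singletons = n_singl,
       singleton_fraction = n_singl / nrow(demux$assigned))
}

#' Write per-amplicon FASTA files and a demultiplexing report
#'
#' @param demux a \code{\link{demultiplex}} result
#' @param dir output directory (created if absent)
#' @return invisibly, the directory
#' @export
write_demux <- function(demux, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (amp in unique(demux$assigned$amplicon)) {
    sub <- demux$assigned[demux$assigned$amplicon == amp, ]
    write_fasta(setNames(sub$sequence, sub$read_id),
                file.path(dir, paste0(amp, ".fasta")))
  }
  write.table(demux$unassigned, file.path(dir, "unassigned.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mis <- estimate_misassignment(demux)
  cs <- coverage_summary(demux)
  kv <- c(demux$counts, mis, cs)
  writeLines(paste(names(kv), vapply(kv, format, character(1)), sep = "\t"),
             file.path(dir, "demux_summary.tsv"))
  invisible(dir)
}
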