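#' Call the allele set of one amplicon
#'
#' Lists every accepted allele carried by at least \code{min_reads} reads in
#' the amplicon, with its read support and (optionally) cluster category.
#'
#' @param vt a \code{\link{variant_table}}
#' @param alleles character vector of accepted allele sequences (finalised
#'   by the artifact filter)
#' @param amplicon amplicon (column) identifier
#' @param min_reads minimum reads per amplicon for an allele call (default 2)
#' @param clusters optional named character vector mapping allele sequence
#'   to cluster label
#' @return data.frame of class \code{genotype}: \code{amplicon},
#'   \code{sequence}, \code{reads}, \code{cluster}
#' @export
call_alleles <- function(vt, alleles, amplicon, min_reads = 2L,
                         clusters = NULL) {
  if (!amplicon %in% colnames(vt$counts))
    stop("unknown amplicon: ", amplicon, call. = FALSE)
  alleles <- intersect(alleles, rownames(vt$counts))
  cnt <- vt$counts[alleles, amplicon]
  keep <- cnt >= min_reads
  g <- data.frame(amplicon = rep(amplicon, sum(keep)),
                  sequence = alleles[keep],
                  reads = unname(cnt[keep]),
                  cluster = if (is.null(clusters))
                              rep(NA_character_, sum(keep))
                            else unname(clusters[alleles[keep]]),
                  stringsAsFactors = FALSE)
  g <- g[order(-g$reads, g$sequence), ]
  rownames(g) <- NULL
  class(g) <- c("genotype", "data.frame")
  g
}

#' Call allele sets for every amplicon
#'
#' @inheritParams call_alleles
#' @return data.frame: one row per (amplicon, called allele)
#' @export
call_genotypes <- function(vt, alleles, min_reads = 2L, clusters = NULL) {
  do.call(rbind, lapply(colnames(vt$counts), function(a)
    call_alleles(vt, alleles, a, min_reads, clusters)))
}

#' Conservative allele count of one amplicon
#'
#' Discards every called allele that can be explained as a single-crossover
#' chimera of two more-abundant called alleles of the same amplicon, giving
#' a conservative per-individual allele count (some discarded variants may
#' be true recombinant alleles that happen to co-occur with both parents).
#' A single pass over the alleles sorted by descending abundance; the
#' explainability verdict uses the original called set throughout.
#'
#' @param genotype a \code{\link{call_alleles}} result
#' @return list with \code{count} (conservative allele count),
#'   \code{removed} (data.frame sequence, witness_a, witness_b, breakpoint)
#' @export
conservative_count <- function(genotype) {
  seqs <- genotype$sequence
  reads <- genotype$reads
  removed <- data.frame(sequence = character(0), witness_a = character(0),
                        witness_b = character(0), breakpoint = integer(0),
                        stringsAsFactors = FALSE)
  ord <- order(-reads, seqs)
  for (i in ord) {
    parents <- seqs[reads > reads[i]]
    res <- explainable_as_chimera(seqs[i], parents)
    if (isTRUE(res)) {
      w <- attr(res, "witness")
      removed <- rbind(removed, data.frame(
        sequence = seqs[i], witness_a = w$parent_a, witness_b = w$parent_b,
        breakpoint = w$breakpoint, stringsAsFactors = FALSE))
    }
  }
  list(count = length(seqs) - nrow(removed), removed = removed)
}

#' Minimum number of loci implied by a per-individual allele maximum
#'
#' Under diploidy, an individual carrying \code{max_alleles} distinct
#' alleles must possess at least \code{ceiling(max_alleles / ploidy)} loci.
#'
#' @param max_alleles maximum number of distinct alleles observed in one
#'   individual (non-negative)
#' @param ploidy chromosome copies per locus (default 2)
#' @return integer minimum locus count
#' @export
min_locus_count <- function(max_alleles, ploidy = 2L) {
  if (any(max_alleles < 0)) stop("allele count must be non-negative",
                                 call. = FALSE)
  as.integer(ceiling(max_alleles / ploidy))
}

#' Replicate concordance of allele detection
#'
#' For individuals amplified in two or more independent PCRs: an allele is
#' \emph{shared} when it has at least one read in every replicate of the
#' individual, and \emph{single-replicate} when it has at least two reads in
#' exactly one replicate and zero reads in all others. Means are reported
#' over replicated individuals, per cluster category and overall.
#'
#' @param vt a \code{\link{variant_table}}
#' @param sheet the \code{\link{tag_sheet}} (maps amplicons to individuals)
#' @param alleles accepted allele sequences
#' @param clusters optional named character vector mapping allele sequence
#'   to cluster label
#' @return data.frame with one row per category (\code{all} plus each
#'   cluster label): \code{mean_shared}, \code{mean_single_replicate},
#'   \code{n_individuals}
#' @export
replicate_concordance <- function(vt, sheet, alleles, clusters = NULL) {
  alleles <- intersect(alleles, rownames(vt$counts))
  reps <- split(sheet$amplicon, sheet$individual)
  reps <- reps[vapply(reps, length, integer(1)) >= 2L]
  reps <- lapply(reps, intersect, colnames(vt$counts))
  reps <- reps[vapply(reps, length, integer(1)) >= 2L]
  if (length(reps) == 0L) {
    warning("no individuals with >= 2 replicates")
    return(data.frame(category = character(0), mean_shared = numeric(0),
                      mean_single_replicate = numeric(0),
                      n_individuals = integer(0)))
  }
  cats <- "all"
  if (!is.null(clusters)) cats <- c(cats, unique(unname(clusters[alleles])))
  per_ind <- lapply(reps, function(amps) {
    cnt <- vt$counts[alleles, amps, drop = FALSE]
    shared <- rowSums(cnt >= 1L) == length(amps)
    single <- rowSums(cnt >= 2L) == 1L & rowSums(cnt >= 1L) == 1L
    vapply(cats, function(cat) {
      in_cat <- if (cat == "all") rep(TRUE, length(alleles))
                else unname(clusters[alleles]) == cat
      c(sum(shared & in_cat), sum(single & in_cat))
    }, numeric(2))
  })
  arr <- simplify2array(per_ind)     # 2 x categories x individuals
  data.frame(category = cats,
             mean_shared = apply(arr[1, , , drop = FALSE], 2, mean),
             mean_single_replicate = apply(arr[2, , , drop = FALSE], 2, mean),
             n_individuals = length(reps),
             row.names = NULL, stringsAsFactors = FALSE)
}
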