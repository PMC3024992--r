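#' Assess the coding integrity of a variant against a functional reference
#'
#' Globally aligns the variant to a reference of known codon phase, extracts
#' indel events, and decides whether the reading frame is preserved: the
#' frame is lost as soon as the cumulative net indel length over any
#' alignment prefix is not a multiple of 3. Translation (in the given frame)
#' is scanned for internal stop codons only up to the point of frame loss.
#' Fixed-length analysis windows cut from longer reads are handled naturally:
#' a template deletion shifts flanking sequence into the window and shows up
#' as an internal deletion plus a compensating terminal insertion, and the
#' prefix rule still reports the frameshift.
#'
#' @param variant DNA string
#' @param reference DNA string with intact reading frame over the window
#' @param frame_offset 0, 1 or 2; codon phase of the first reference base
#'   (0 = position 1 starts a codon)
#' @return list of class \code{coding_assessment}: \code{indels} (data.frame
#'   ref_pos, length; insertions positive, deletions negative),
#'   \code{net_indel}, \code{frameshift}, \code{stop_codons} (codon indices
#'   of internal stops), \code{orf_intact}
#' @export
assess_coding <- function(variant, reference, frame_offset = 0L) {
  if (!frame_offset %in% 0:2)
    stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = variant, subject = reference, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -2),
    gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap_p <- p == "-"
  gap_s <- s == "-"
  ev_pos <- integer(0); ev_len <- integer(0)
  r <- rle(ifelse(gap_p, "del", ifelse(gap_s, "ins", "m")))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ref_coord <- cumsum(!gap_s)          # reference coordinate per column
  var_coord <- cumsum(!gap_p)          # variant coordinate per column
  for (i in seq_along(r$values)) {
    if (r$values[i] == "m") next
    pos <- if (starts[i] == 1L) 1L else ref_coord[starts[i] - 1L] + 1L
    ev_pos <- c(ev_pos, pos)
    ev_len <- c(ev_len, if (r$values[i] == "ins") r$lengths[i]
                        else -r$lengths[i])
  }
  indels <- data.frame(ref_pos = ev_pos, length = ev_len)
  cum <- cumsum(ev_len)
  shift_at <- which(cum %% 3L != 0L)
  frameshift <- length(shift_at) > 0L
  # in-frame portion of the variant: up to the event that breaks the frame
  if (frameshift) {
    ev_i <- shift_at[1]
    col_i <- starts[which(r$values != "m")[ev_i]]
    inframe_len <- if (col_i == 1L) 0L else var_coord[col_i - 1L]
  } else {
    inframe_len <- nchar(variant)
  }
  stops <- integer(0)
  usable <- inframe_len - frame_offset
  if (usable >= 3L) {
    n_codon <- usable %/% 3L
    cds <- substr(variant, frame_offset + 1L, frame_offset + 3L * n_codon)
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds), if.fuzzy.codon = "X")), "")[[1]]
    stops <- which(aa == "*")
  }
  structure(list(indels = indels,
                 net_indel = if (length(ev_len)) sum(ev_len) else 0L,
                 frameshift = frameshift,
                 frame_offset = as.integer(frame_offset),
                 stop_codons = stops,
                 orf_intact = !frameshift && length(stops) == 0L),
            class = "coding_assessment")
}

#' Assign a variant to a sequence cluster
#'
#' Cluster membership follows a diagnostic base plus frameshift signatures:
#' variants carrying one of \code{cluster1_bases} at the diagnostic position
#' belong to the low-divergence pseudogene cluster I; among the remainder
#' (diagnostic G side), variants carrying the characteristic pair of 9-bp and
#' 1-bp deletions belong to pseudogene group II.A; variants with an intact
#' reading frame are putative expressed cluster II alleles; anything else is
#' unclassified.
#'
#' @param variant DNA string
#' @param assessment a \code{\link{assess_coding}} result for the variant
#' @param diagnostic_pos window position of the diagnostic base (default 1)
#' @param cluster1_bases bases diagnostic of cluster I (default C, T)
#' @param iia_deletions deletion lengths diagnostic of group II.A (default
#'   9 and 1)
#' @return list with \code{label} (one of "cluster_I", "group_IIA",
#'   "expressed_II", "unclassified") and \code{evidence}
#' @export
assign_cluster <- function(variant, assessment, diagnostic_pos = 1L,
                           cluster1_bases = c("C", "T"),
                           iia_deletions = c(9L, 1L)) {
  base <- substr(variant, diagnostic_pos, diagnostic_pos)
  dels <- -assessment$indels$length[assessment$indels$length < 0]
  has_iia <- all(iia_deletions %in% dels)
  label <- if (base %in% cluster1_bases) "cluster_I"
    else if (has_iia) "group_IIA"
    else if (assessment$orf_intact) "expressed_II"
    else "unclassified"
  list(label = label,
       evidence = list(diagnostic_base = base,
                       frameshift = assessment$frameshift,
                       deletions = dels,
                       stop_codons = assessment$stop_codons))
}

#' Majority-rule consensus of sequences (per-position modal base)
#' @param seqs character vector of equal-length sequences
#' @return consensus string
#' @export
consensus_sequence <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("consensus requires equal-length sequences", call. = FALSE)
  m <- do.call(rbind, strsplit(seqs, ""))
  paste(apply(m, 2, function(col) names(which.max(table(col)))),
        collapse = "")
}

#' Classify a set of variants into sequence clusters
#'
#' Convenience wrapper: builds (or takes) a functional reference, assesses
#' coding integrity of each variant, and assigns cluster labels. The default
#' reference is the majority-rule consensus of variants with no internal
#' stop codon in the given frame, a data-driven surrogate for a known
#' expressed allele; supply \code{reference} to override.
#'
#' @param variants character vector of variant sequences
#' @param reference functional reference sequence (default: consensus of
#'   stop-free, modal-length variants from the expressed diagnostic-base
#'   side, i.e. the variants most likely to carry an intact frame)
#' @param frame_offset codon phase of window position 1 (default 0)
#' @param diagnostic_pos,cluster1_bases diagnostic-base rule, see
#'   \code{\link{assign_cluster}}
#' @param ... passed to \code{\link{assign_cluster}}
#' @return data.frame with \code{sequence}, \code{cluster},
#'   \code{frameshift}, \code{n_stop_codons}, \code{diagnostic_base}
#' @export
classify_variants <- function(variants, reference = NULL, frame_offset = 0L,
                              diagnostic_pos = 1L,
                              cluster1_bases = c("C", "T"), ...) {
  if (length(variants) == 0L)
    return(data.frame(sequence = character(0), cluster = character(0)))
  if (is.null(reference)) {
    lens <- nchar(variants)
    modal <- as.integer(names(which.max(table(lens))))
    pool <- variants[lens == modal &
                       !substr(variants, diagnostic_pos, diagnostic_pos) %in%
                         cluster1_bases]
    if (length(pool) == 0L) pool <- variants[lens == modal]
    nostop <- pool[vapply(pool, function(v) {
      usable <- nchar(v) - frame_offset
      cds <- substr(v, frame_offset + 1L, frame_offset + 3L * (usable %/% 3L))
      !grepl("\\*", as.character(Biostrings::translate(
        Biostrings::DNAString(cds), if.fuzzy.codon = "X")))
    }, logical(1))]
    if (length(nostop) == 0L) nostop <- pool
    reference <- consensus_sequence(nostop)
  }
  rows <- lapply(variants, function(v) {
    a <- assess_coding(v, reference, frame_offset)
    cl <- assign_cluster(v, a, diagnostic_pos = diagnostic_pos,
                         cluster1_bases = cluster1_bases, ...)
    data.frame(sequence = v, cluster = cl$label,
               frameshift = a$frameshift,
               n_stop_codons = length(a$stop_codons),
               diagnostic_base = cl$evidence$diagnostic_base,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "reference") <- reference
  res
}

#' Cross-check putative alleles against cDNA-derived sequences
#'
#' cDNA variants supported by at least \code{min_clones} clones are compared
#' (exact string match) against the allele list, splitting them into
#' confirmed alleles and cDNA-only variants.
#'
#' @param alleles character vector of putative allele sequences
#' @param cdna character vector of cDNA clone sequences (one entry per
#'   clone; duplicates count as clones), trimmed to the allele window
#' @param min_clones minimum clone support (default 2)
#' @return list with \code{confirmed} (alleles also seen in cDNA),
#'   \code{cdna_only} (supported cDNA variants absent from the allele list)
#'   and \code{n_supported} cDNA variants
#' @export
match_cdna <- function(alleles, cdna, min_clones = 2L) {
  if (length(cdna) == 0L)
    return(list(confirmed = character(0), cdna_only = character(0),
                n_supported = 0L))
  if (length(alleles) > 0L &&
      !all(nchar(cdna) == nchar(alleles[1])))
    stop("cDNA sequences must be trimmed to the allele window",
         call. = FALSE)
  tab <- table(cdna)
  supported <- names(tab)[tab >= min_clones]
  list(confirmed = intersect(supported, alleles),
       cdna_only = setdiff(supported, alleles),
       n_supported = length(supported))
}

.as_dnabin <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
}

#' Tamura-Nei (TN93) distance between two sequences
#'
#' Distance under the TN93 model, which separates the two transition classes
#' (purine and pyrimidine) from transversions and uses empirical base
#' frequencies. Sites with a gap or ambiguity in either sequence are excluded
#' (pairwise deletion). Saturated pairs, for which a logarithm argument is
#' non-positive, are reported as \code{Inf}.
#'
#' @param seq1,seq2 equal-length DNA strings (gaps allowed)
#' @return non-negative distance, or \code{Inf} at saturation
#' @export
tamura_nei_distance <- function(seq1, seq2) {
  m <- tamura_nei_matrix(c(seq1, seq2))
  m[1, 2]
}

#' Tamura-Nei (TN93) distance matrix
#'
#' @param seqs character vector of equal-length sequences (gaps allowed)
#' @param pairwise_deletion drop gapped sites per pair (default TRUE);
#'   FALSE drops every site gapped in any sequence (complete deletion)
#' @return symmetric numeric matrix; saturated pairs are \code{Inf}
#' @export
tamura_nei_matrix <- function(seqs, pairwise_deletion = TRUE) {
  bin <- .as_dnabin(seqs)
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  comp <- matrix(chars %in% DNA_BASES, nrow(chars), ncol(chars))
  if (min(tcrossprod(comp)) == 0)
    stop("a sequence pair has zero comparable sites", call. = FALSE)
  d <- suppressWarnings(ape::dist.dna(bin, model = "TN93",
                                      pairwise.deletion = pairwise_deletion))
  m <- as.matrix(d)
  m[!is.finite(m)] <- Inf
  m
}

#' Neighbor joining on a distance matrix
#'
#' Canonical NJ agglomeration (Q-matrix minimisation). On additive distances
#' the generating topology and branch lengths are recovered exactly.
#'
#' @param d symmetric distance matrix with zero diagonal (matrix or
#'   \code{dist})
#' @return an unrooted \code{phylo} tree with branch lengths
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (any(is.na(m)) || any(!is.finite(m)))
    stop("distance matrix contains NA or non-finite entries", call. = FALSE)
  if (any(m < 0)) stop("negative distances", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("matrix not symmetric", call. = FALSE)
  if (any(diag(m) != 0)) stop("diagonal must be zero", call. = FALSE)
  ape::nj(m)
}

#' Neighbor-joining tree of alleles from TN93 distances, with bootstrap
#'
#' Builds the TN93 distance matrix, the NJ tree, and (optionally) bootstrap
#' support by resampling alignment columns.
#'
#' @param seqs named character vector of aligned allele sequences
#' @param bootstrap number of bootstrap replicates (0 = none; default 0)
#' @param seed RNG seed for the bootstrap resampling
#' @param pairwise_deletion see \code{\link{tamura_nei_matrix}}
#' @return a \code{phylo} tree; with bootstrap, node labels carry percent
#'   support
#' @export
build_allele_tree <- function(seqs, bootstrap = 0L, seed = NULL,
                              pairwise_deletion = TRUE) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  tree <- neighbor_joining(tamura_nei_matrix(seqs, pairwise_deletion))
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    aln <- do.call(rbind, strsplit(seqs, ""))
    rownames(aln) <- names(seqs)
    fun <- function(x) {
      s <- setNames(apply(x, 1, paste, collapse = ""), rownames(x))
      neighbor_joining(tamura_nei_matrix(s, pairwise_deletion))
    }
    bp <- ape::boot.phylo(tree, aln, fun, B = bootstrap, quiet = TRUE)
    tree$node.label <- round(100 * bp / bootstrap)
  }
  tree
}
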