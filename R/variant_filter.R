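#' Filter configuration
#'
#' Parameters of the artifact-discrimination procedure. The replication
#' criterion ("2-PCRs-3-copies-in-each") requires a variant in at least
#' \code{min_pcrs} independent PCRs with at least \code{min_copies} reads in
#' each; every amplicon, including replicates of one individual, counts as an
#' independent PCR. Chimera classification examines the
#' \code{n_check_amplicons} amplicons where the variant is most abundant and
#' is exhaustive below \code{grey_zone_upper} (the grey zone in which true
#' alleles and PCR chimeras co-occur).
#'
#' @param min_pcrs minimum number of amplicons (default 2)
#' @param min_copies minimum reads per qualifying amplicon (default 3)
#' @param n_check_amplicons amplicons examined per variant (default 3)
#' @param grey_zone_upper MPAF below which every variant is examined
#'   (default 0.015)
#' @param homopolymer_min_len minimum homopolymer run length for the
#'   sequencing-artifact flag (default 3)
#' @param full_scan examine every candidate regardless of MPAF (default
#'   FALSE)
#' @param candidate_parents_only restrict chimera parents to candidates that
#'   passed the replication criterion, rather than any observed sequence in
#'   the amplicon (default FALSE, the more conservative choice toward chimera
#'   calls)
#' @return object of class \code{filter_config}
#' @export
filter_config <- function(min_pcrs = 2L, min_copies = 3L,
                          n_check_amplicons = 3L, grey_zone_upper = 0.015,
                          homopolymer_min_len = 3L, full_scan = FALSE,
                          candidate_parents_only = FALSE) {
  stopifnot(min_pcrs >= 1, min_copies >= 1, n_check_amplicons >= 1,
            grey_zone_upper > 0, grey_zone_upper < 1,
            homopolymer_min_len >= 1)
  structure(list(min_pcrs = as.integer(min_pcrs),
                 min_copies = as.integer(min_copies),
                 n_check_amplicons = as.integer(n_check_amplicons),
                 grey_zone_upper = grey_zone_upper,
                 homopolymer_min_len = as.integer(homopolymer_min_len),
                 full_scan = isTRUE(full_scan),
                 candidate_parents_only = isTRUE(candidate_parents_only)),
            class = "filter_config")
}

#' Apply the replication ("2-PCRs-3-copies-in-each") criterion
#'
#' @param vt a \code{\link{variant_table}}
#' @param cfg a \code{\link{filter_config}}
#' @return character vector of candidate variant sequences
#' @export
apply_replication_criterion <- function(vt, cfg = filter_config()) {
  if (nrow(vt$counts) == 0L) stop("empty variant table", call. = FALSE)
  keep <- rowSums(vt$counts >= cfg$min_copies) >= cfg$min_pcrs
  rownames(vt$counts)[keep]
}

#' Maximum per-amplicon frequency (MPAF)
#'
#' A variant's highest read fraction across amplicons; the denominator of
#' each fraction is the amplicon's total read count. Amplicons with zero
#' total are excluded; a variant absent everywhere has MPAF 0.
#'
#' @param vt a \code{\link{variant_table}}
#' @param variants sequences to evaluate (default: all rows)
#' @return named numeric vector of MPAF values
#' @export
compute_mpaf <- function(vt, variants = rownames(vt$counts)) {
  miss <- setdiff(variants, rownames(vt$counts))
  ok <- vt$totals > 0
  freq <- sweep(vt$counts[intersect(variants, rownames(vt$counts)), ok,
                          drop = FALSE],
                2, vt$totals[ok], "/")
  res <- setNames(rep(0, length(variants)), variants)
  if (nrow(freq) > 0) res[rownames(freq)] <- apply(freq, 1, max)
  res
}

# Longest common prefix / suffix lengths of `variant` against each row of a
# character matrix of equal-length parent sequences.
.prefix_suffix <- function(vch, pm) {
  L <- length(vch)
  eq <- pm == matrix(vch, nrow(pm), L, byrow = TRUE)
  neq <- !eq
  has <- rowSums(neq) > 0
  pre <- rep(L, nrow(pm))
  suf <- rep(L, nrow(pm))
  if (any(has)) {
    sub <- neq[has, , drop = FALSE]
    pre[has] <- max.col(sub, ties.method = "first") - 1L
    suf[has] <- L - max.col(sub, ties.method = "last")
  }
  list(prefix = pre, suffix = suf)
}

#' Test whether a variant is explainable as a single-crossover PCR chimera
#'
#' Within one amplicon, a variant is explainable as a PCR chimera if two
#' parental sequences exist, each with strictly more reads in that amplicon
#' than the variant, such that the variant equals the prefix of one joined to
#' the suffix of the other at some internal breakpoint (and differs from both
#' parents). A PCR chimera must co-occur with both parents, so failing this
#' test in the amplicons where the variant is most abundant is evidence for a
#' true allele.
#'
#' @param variant DNA string (the tested sequence)
#' @param parent_seqs sequences present in the amplicon with strictly more
#'   reads than the variant (same length as \code{variant})
#' @return logical; when TRUE, attribute \code{witness} holds a list with
#'   \code{parent_a}, \code{parent_b} and \code{breakpoint} k such that
#'   variant = parent_a[1..k] ++ parent_b[(k+1)..L]
#' @export
explainable_as_chimera <- function(variant, parent_seqs) {
  L <- nchar(variant)
  if (length(parent_seqs) == 0L) return(FALSE)
  if (any(nchar(parent_seqs) != L))
    stop("parent sequences must match the variant length", call. = FALSE)
  parent_seqs <- setdiff(parent_seqs, variant)  # v must differ from parents
  if (length(parent_seqs) == 0L) return(FALSE)
  vch <- strsplit(variant, "")[[1]]
  pm <- do.call(rbind, strsplit(parent_seqs, ""))
  ps <- .prefix_suffix(vch, pm)
  pre <- pmin(ps$prefix, L - 1L)   # breakpoint k in [1, L-1]
  suf <- pmin(ps$suffix, L - 1L)
  i <- which.max(pre)
  j <- which.max(suf)
  if (pre[i] + suf[j] < L) return(FALSE)
  k <- max(1L, L - suf[j])
  a <- parent_seqs[i]
  b <- parent_seqs[j]
  stopifnot(identical(paste0(substr(a, 1, k), substr(b, k + 1L, L)), variant))
  structure(TRUE, witness = list(parent_a = a, parent_b = b, breakpoint = k))
}

# Amplicon cache: per amplicon, the sequences present and their counts,
# ordered by decreasing count; the character matrix is built lazily.
.amplicon_view <- function(vt, amplicon) {
  cnt <- vt$counts[, amplicon]
  present <- cnt > 0
  list(seqs = rownames(vt$counts)[present], counts = cnt[present])
}

# Parents of `variant` in one amplicon under a config: sequences with
# strictly more reads than the variant there.
.parents_in_amplicon <- function(vt, variant, amplicon, cfg,
                                 candidates = NULL) {
  av <- .amplicon_view(vt, amplicon)
  vcount <- vt$counts[variant, amplicon]
  keep <- av$counts > vcount
  if (cfg$candidate_parents_only && !is.null(candidates))
    keep <- keep & av$seqs %in% candidates
  av$seqs[keep]
}

# The n amplicons where `variant` is most abundant: raw read count
# descending, ties by amplicon frequency then amplicon identifier.
.top_amplicons <- function(vt, variant, n) {
  cnt <- vt$counts[variant, ]
  occupied <- which(cnt > 0)
  if (length(occupied) == 0L) return(character(0))
  freq <- cnt[occupied] / vt$totals[occupied]
  ids <- colnames(vt$counts)[occupied]
  ord <- order(-cnt[occupied], -freq, ids)
  ids[ord][seq_len(min(n, length(occupied)))]
}

#' Classify candidate variants as putative alleles or PCR chimeras
#'
#' Candidates are sorted by ascending MPAF. Every candidate with MPAF below
#' \code{grey_zone_upper} (all candidates when \code{full_scan}) is examined
#' in the \code{n_check_amplicons} amplicons where it is most abundant
#' (including the amplicon its MPAF comes from; all occupied amplicons when
#' it occurs in fewer). If the variant is explainable as a chimera of more
#' abundant sequences in \emph{all} examined amplicons it is classified
#' "PCR chimera", otherwise "putative allele". Chimera status does not remove
#' a sequence from the parent pool (single pass).
#'
#' @param vt a \code{\link{variant_table}}
#' @param candidates sequences that passed the replication criterion
#' @param cfg a \code{\link{filter_config}}
#' @return data.frame with columns \code{sequence}, \code{mpaf},
#'   \code{n_amplicons}, \code{checked}, \code{status},
#'   \code{witness_a}, \code{witness_b}, \code{breakpoint}
#' @export
classify_by_mpaf <- function(vt, candidates, cfg = filter_config()) {
  mpaf <- compute_mpaf(vt, candidates)
  ord <- order(mpaf, candidates)          # ascending MPAF, deterministic
  candidates <- candidates[ord]
  mpaf <- mpaf[ord]
  n <- length(candidates)
  status <- rep("putative allele", n)
  checked <- rep(FALSE, n)
  wa <- wb <- rep(NA_character_, n)
  bk <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!(cfg$full_scan || mpaf[i] < cfg$grey_zone_upper)) next
    checked[i] <- TRUE
    amps <- .top_amplicons(vt, candidates[i], cfg$n_check_amplicons)
    chim <- length(amps) > 0L
    wit <- NULL
    for (amp in amps) {
      parents <- .parents_in_amplicon(vt, candidates[i], amp, cfg, candidates)
      res <- explainable_as_chimera(candidates[i], parents)
      if (!res) { chim <- FALSE; break }
      if (is.null(wit)) wit <- attr(res, "witness")
    }
    if (chim) {
      status[i] <- "PCR chimera"
      wa[i] <- wit$parent_a
      wb[i] <- wit$parent_b
      bk[i] <- wit$breakpoint
    }
  }
  data.frame(sequence = candidates,
             mpaf = unname(mpaf),
             n_amplicons = rowSums(vt$counts[candidates, , drop = FALSE] > 0),
             checked = checked, status = status,
             witness_a = wa, witness_b = wb, breakpoint = bk,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive the MPAF threshold separating alleles from the grey zone
#'
#' The smallest putative-allele MPAF such that no variant at or above it was
#' classified as a PCR chimera (equivalently, the smallest allele MPAF
#' strictly above the largest chimera MPAF). With no chimeras, the smallest
#' allele MPAF.
#'
#' @param classification output of \code{\link{classify_by_mpaf}}
#' @return MPAF threshold (fraction), or \code{NA} when no allele lies above
#'   the largest chimera MPAF
#' @export
derive_threshold <- function(classification) {
  if (nrow(classification) == 0L)
    stop("empty classification", call. = FALSE)
  am <- classification$mpaf[classification$status == "putative allele"]
  cm <- classification$mpaf[classification$status == "PCR chimera"]
  if (length(am) == 0L) stop("no putative alleles classified", call. = FALSE)
  if (length(cm) == 0L) return(min(am))
  above <- am[am > max(cm)]
  if (length(above) == 0L) return(NA_real_)
  min(above)
}

#' Scale an MPAF threshold to another read-abundance stratum
#'
#' When a clean threshold is derivable only for one sequence class (the
#' divergent expressed alleles), thresholds for other classes are obtained by
#' scaling proportionally to their mean per-amplicon read proportions, under
#' the assumption that the PCR recombination rate is similar for all
#' variants.
#'
#' @param base_threshold threshold derived for the base class
#' @param base_read_proportion mean per-amplicon read proportion of the base
#'   class (in (0, 1])
#' @param target_read_proportion mean per-amplicon read proportion of the
#'   target class (in (0, 1])
#' @return scaled threshold, \code{base_threshold * target / base}
#' @export
scale_threshold <- function(base_threshold, base_read_proportion,
                            target_read_proportion) {
  if (base_read_proportion <= 0 || base_read_proportion > 1 ||
      target_read_proportion <= 0 || target_read_proportion > 1)
    stop("read proportions must lie in (0, 1]", call. = FALSE)
  base_threshold * target_read_proportion / base_read_proportion
}

# Single-base homopolymer edits of `seq`: one deletion of a run base and one
# duplication of a run base, for every run of length >= min_run.
.homopolymer_edits <- function(seq, min_run) {
  runs <- homopolymer_runs(seq, min_run)
  L <- nchar(seq)
  if (nrow(runs) == 0L)
    return(data.frame(del = character(0), ins = character(0)))
  del <- vapply(runs$start, function(s)
    paste0(substr(seq, 1, s - 1L), substr(seq, s + 1L, L)), character(1))
  ins <- vapply(seq_len(nrow(runs)), function(i)
    paste0(substr(seq, 1, runs$start[i]), runs$base[i],
           substr(seq, runs$start[i] + 1L, L)), character(1))
  data.frame(del = del, ins = ins, stringsAsFactors = FALSE)
}

#' Flag a variant as a homopolymer-indel sequencing artifact
#'
#' True when the variant differs from some more-abundant sequence by exactly
#' one 1-bp insertion or deletion inside a homopolymer run of length at least
#' \code{min_run} in the more abundant sequence, and by no other difference.
#' When variant and parents have the same length (fixed analysis windows cut
#' from longer reads), a template indel shifts one flanking base into or out
#' of the window, so the comparison is made on the shifted window: for a
#' deletion the variant's final base is unconstrained; for an insertion the
#' parent's final base is pushed out.
#'
#' @param variant DNA string
#' @param parent_seqs more-abundant sequences to compare against
#' @param min_run minimum homopolymer run length (default 3)
#' @return logical; when TRUE, attribute \code{witness} holds the matching
#'   parent and edit type
#' @export
flag_homopolymer_indel <- function(variant, parent_seqs, min_run = 3L) {
  Lv <- nchar(variant)
  for (parent in parent_seqs) {
    if (identical(parent, variant)) next
    Lp <- nchar(parent)
    if (abs(Lv - Lp) > 1L) next
    ed <- .homopolymer_edits(parent, min_run)
    if (nrow(ed) == 0L) next
    hit <- if (Lv == Lp - 1L) {
      variant %in% ed$del
    } else if (Lv == Lp + 1L) {
      variant %in% ed$ins
    } else {
      # fixed-window mode: compare on the shifted window
      any(substr(variant, 1, Lp - 1L) == ed$del & variant != parent) ||
        any(variant == substr(ed$ins, 1, Lp))
    }
    if (hit) {
      type <- if (Lv < Lp) "deletion"
              else if (Lv > Lp) "insertion"
              else if (any(substr(variant, 1, Lp - 1L) == ed$del))
                "deletion" else "insertion"
      return(structure(TRUE, witness = list(parent = parent, type = type)))
    }
  }
  FALSE
}

#' Run the full artifact-discrimination procedure on a variant table
#'
#' Applies the replication criterion, flags homopolymer-indel sequencing
#' artifacts among the candidates, classifies the remainder by the MPAF-
#' sorted chimera scan, and derives the MPAF threshold above which no
#' chimeras were found.
#'
#' @param vt a \code{\link{variant_table}}
#' @param cfg a \code{\link{filter_config}}
#' @return data.frame over all variants in \code{vt} with columns
#'   \code{sequence}, \code{total_reads}, \code{n_amplicons}, \code{mpaf},
#'   \code{checked}, \code{status} (one of "below-threshold",
#'   "sequencing artifact", "PCR chimera", "putative allele"),
#'   \code{witness_a}, \code{witness_b}, \code{breakpoint}; attribute
#'   \code{mpaf_threshold} carries the derived threshold
#' @export
filter_variants <- function(vt, cfg = filter_config()) {
  cand <- apply_replication_criterion(vt, cfg)
  total <- rowSums(vt$counts)
  # homopolymer artifacts among candidates, vs all more-abundant candidates
  art <- character(0)
  if (length(cand) > 1L) {
    ord <- cand[order(-total[cand])]
    for (i in seq_along(ord)[-1]) {
      if (flag_homopolymer_indel(ord[i], ord[seq_len(i - 1L)],
                                 cfg$homopolymer_min_len))
        art <- c(art, ord[i])
    }
  }
  cls <- classify_by_mpaf(vt, setdiff(cand, art), cfg)
  all_seqs <- rownames(vt$counts)
  rep_df <- data.frame(sequence = all_seqs,
                       total_reads = unname(total),
                       n_amplicons = unname(rowSums(vt$counts > 0)),
                       mpaf = unname(compute_mpaf(vt)),
                       checked = FALSE,
                       status = "below-threshold",
                       witness_a = NA_character_, witness_b = NA_character_,
                       breakpoint = NA_integer_,
                       stringsAsFactors = FALSE)
  rep_df$status[all_seqs %in% art] <- "sequencing artifact"
  m <- match(cls$sequence, all_seqs)
  rep_df$checked[m] <- cls$checked
  rep_df$status[m] <- cls$status
  rep_df$witness_a[m] <- cls$witness_a
  rep_df$witness_b[m] <- cls$witness_b
  rep_df$breakpoint[m] <- cls$breakpoint
  rep_df <- rep_df[order(-rep_df$mpaf), ]
  rownames(rep_df) <- NULL
  thr <- tryCatch(derive_threshold(cls), error = function(e) NA_real_)
  structure(rep_df, mpaf_threshold = thr)
}

#' Seeded random spot-check of variants above the grey zone
#'
#' Draws \code{n} variants with MPAF above the grey-zone bound and runs the
#' chimera examination on each, mirroring the practice of spot-checking a
#' random sample of high-frequency variants.
#'
#' @param vt a \code{\link{variant_table}}
#' @param classification output of \code{\link{classify_by_mpaf}} or
#'   \code{\link{filter_variants}}
#' @param n sample size (default 10)
#' @param cfg a \code{\link{filter_config}}
#' @param seed RNG seed for the draw
#' @return data.frame of sampled sequences with an \code{explainable} column
#' @export
spot_check_variants <- function(vt, classification, n = 10L,
                                cfg = filter_config(), seed = 1L) {
  pool <- classification$sequence[classification$mpaf >= cfg$grey_zone_upper &
                                    classification$status != "below-threshold"]
  if (length(pool) == 0L)
    return(data.frame(sequence = character(0), explainable = logical(0)))
  set.seed(seed)
  picked <- sample(pool, min(n, length(pool)))
  expl <- vapply(picked, function(v) {
    amps <- .top_amplicons(vt, v, cfg$n_check_amplicons)
    all(vapply(amps, function(a)
      isTRUE(explainable_as_chimera(v, .parents_in_amplicon(vt, v, a, cfg))),
      logical(1)))
  }, logical(1))
  data.frame(sequence = picked, explainable = unname(expl),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter bookkeeping percentages
#'
#' Retention and chimera-fraction percentages of the filtering report:
#' retained over candidate tallies and chimeras over candidates.
#'
#' @param n_retained variants retained after chimera filtering
#' @param n_candidates variants that passed the replication criterion
#' @param n_chimeras variants classified as PCR chimeras
#' @return list with \code{retention_pct} and \code{chimera_pct}
#' @export
filter_report_percentages <- function(n_retained, n_candidates,
                                      n_chimeras = NA_integer_) {
  list(retention_pct = 100 * n_retained / n_candidates,
       chimera_pct = 100 * n_chimeras / n_candidates)
}
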