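#' Run the full read-to-genotype workflow
#'
#' Demultiplexes tagged reads, tabulates variants, runs the artifact filter
#' (replication criterion, homopolymer-artifact flag, MPAF-sorted chimera
#' scan with threshold derivation), classifies the surviving putative
#' alleles into sequence clusters, scales the derived MPAF threshold to the
#' pseudogene strata by their mean per-amplicon read proportions, and calls
#' per-amplicon genotypes.
#'
#' @param reads named character vector of read sequences
#' @param sheet a \code{\link{tag_sheet}}
#' @param primer forward primer (IUPAC)
#' @param window analysis window length (default 188)
#' @param cfg a \code{\link{filter_config}}
#' @param min_reads per-amplicon read threshold for genotype calls
#'   (default 2)
#' @param reference optional functional reference for coding assessment
#' @return list with \code{demux}, \code{table}, \code{report},
#'   \code{clusters}, \code{read_proportions} (mean per-amplicon read
#'   proportion per cluster), \code{thresholds} (derived and scaled MPAF
#'   thresholds per cluster), \code{genotypes}, \code{misassignment},
#'   \code{coverage}
#' @export
mhc_pipeline <- function(reads, sheet, primer, window = 188L,
                         cfg = filter_config(), min_reads = 2L,
                         reference = NULL) {
  demux <- demultiplex(reads, sheet, primer, window = window)
  vt <- as_variant_table(demux)
  report <- filter_variants(vt, cfg)
  alleles <- report$sequence[report$status == "putative allele"]
  clusters <- classify_variants(alleles, reference = reference)
  cl_map <- setNames(clusters$cluster, clusters$sequence)

  # mean per-amplicon read proportion per cluster, over reads from alleles
  props <- NULL
  if (length(alleles) > 0L) {
    cnt <- vt$counts[alleles, , drop = FALSE]
    per_cl <- rowsum(cnt, cl_map[alleles])
    frac <- sweep(per_cl, 2, vt$totals, "/")
    props <- rowMeans(frac)
  }
  base_thr <- attr(report, "mpaf_threshold")
  thresholds <- NULL
  if (!is.null(props) && !is.na(base_thr) &&
      "expressed_II" %in% names(props)) {
    scalable <- names(props)[props > 0]
    thresholds <- vapply(scalable, function(cl)
      scale_threshold(base_thr, props[["expressed_II"]], props[[cl]]),
      numeric(1))
  }
  genotypes <- call_genotypes(vt, alleles, min_reads, cl_map)
  list(demux = demux, table = vt, report = report, clusters = clusters,
       read_proportions = props,
       thresholds = list(derived = base_thr, scaled = thresholds),
       genotypes = genotypes,
       misassignment = estimate_misassignment(demux),
       coverage = coverage_summary(demux))
}
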