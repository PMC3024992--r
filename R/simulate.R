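#' Simulation configuration
#'
#' Parameters of the amplicon read simulator. The defaults emulate the study
#' conditions of a fusion-primer 454 run over a multigene MHC class IIB
#' system: 188-bp analysis windows behind a 6-bp tag and forward primer,
#' mean coverage of several hundred reads per amplicon, a dominant
#' low-divergence pseudogene cluster (cluster I, diagnostic C/T base and a
#' 1-2 bp frameshift deletion), a divergent expressed cluster (diagnostic G,
#' intact reading frame), a second pseudogene group (II.A, 9-bp plus 1-bp
#' deletions), per-amplicon read proportions of 0.164 / 0.718 / 0.118 for
#' expressed / cluster I / II.A, PCR substitution errors, single-crossover
#' chimeras, homopolymer indels and tag corruption.
#'
#' @param window analysis window length in bases (default 188)
#' @param buffer extra template bases behind the window so deletions shift
#'   flanking sequence in (default 30)
#' @param tag_length tag length in bases (default 6)
#' @param n_individuals number of individuals (default 20)
#' @param replicate_fraction fraction of individuals amplified twice
#'   (default 1)
#' @param coverage_mean,coverage_sd per-amplicon coverage distribution
#'   (default 500, 150)
#' @param n_expressed_loci,n_cluster1_loci,n_iia_loci diploid locus counts
#'   per cluster (defaults 9, 10, 5)
#' @param pool_expressed,pool_cluster1,pool_iia allele pool sizes
#'   (defaults 30, 30, 12)
#' @param expressed_divergence target mean pairwise divergence of the
#'   expressed pool (default 0.10)
#' @param cluster_read_props per-amplicon read proportions by cluster
#'   (default c(expressed = 0.164, cluster1 = 0.718, iia = 0.118))
#' @param skew_sigma log-normal sigma of per-allele amplification skew
#'   (default 0.5)
#' @param substitution_rate PCR/sequencing substitution rate per base
#'   (default 1e-3)
#' @param chimera_fraction fraction of reads formed as single-crossover
#'   chimeras (default 0.05)
#' @param homopolymer_indel_rate per-run indel rate scale; a run of length
#'   len >= homopolymer_min_len receives an indel with probability
#'   rate * (len - 2) (default 1e-3)
#' @param homopolymer_min_len minimum run length subject to indels
#'   (default 3)
#' @param tag_corruption_rate per-base corruption rate of the tag (default
#'   5.5e-4, i.e. roughly 0.33 percent of reads carry a corrupted 6-bp tag)
#' @param min_tag_distance minimum pairwise substitution distance between
#'   used tags (default 3)
#' @param primer concrete forward primer planted in reads
#' @param primer_iupac degenerate form of the primer, for demultiplexing
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(window = 188L, buffer = 30L, tag_length = 6L,
                       n_individuals = 20L, replicate_fraction = 1,
                       coverage_mean = 500, coverage_sd = 150,
                       n_expressed_loci = 9L, n_cluster1_loci = 10L,
                       n_iia_loci = 5L,
                       pool_expressed = 30L, pool_cluster1 = 30L,
                       pool_iia = 12L,
                       expressed_divergence = 0.10,
                       cluster_read_props = c(expressed = 0.164,
                                              cluster1 = 0.718,
                                              iia = 0.118),
                       skew_sigma = 0.5,
                       substitution_rate = 1e-3,
                       chimera_fraction = 0.05,
                       homopolymer_indel_rate = 1e-3,
                       homopolymer_min_len = 3L,
                       tag_corruption_rate = 5.5e-4,
                       min_tag_distance = 3L,
                       primer = "GAGTGTCACTTCGTTAACGGCAC",
                       primer_iupac = "GAGTGTCHYTTCVTTAACGGCAC") {
  rates <- c(substitution_rate, chimera_fraction, homopolymer_indel_rate,
             tag_corruption_rate, replicate_fraction)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (any(c(n_expressed_loci, n_cluster1_loci, n_iia_loci) < 0))
    stop("locus counts must be non-negative", call. = FALSE)
  stopifnot(window > 0, buffer >= 12, tag_length > 0, n_individuals > 0,
            coverage_mean > 0, all(cluster_read_props >= 0))
  structure(list(window = as.integer(window), buffer = as.integer(buffer),
                 tag_length = as.integer(tag_length),
                 n_individuals = as.integer(n_individuals),
                 replicate_fraction = replicate_fraction,
                 coverage_mean = coverage_mean, coverage_sd = coverage_sd,
                 loci = c(expressed = as.integer(n_expressed_loci),
                          cluster1 = as.integer(n_cluster1_loci),
                          iia = as.integer(n_iia_loci)),
                 pool_sizes = c(expressed = as.integer(pool_expressed),
                                cluster1 = as.integer(pool_cluster1),
                                iia = as.integer(pool_iia)),
                 expressed_divergence = expressed_divergence,
                 cluster_read_props = cluster_read_props,
                 skew_sigma = skew_sigma,
                 substitution_rate = substitution_rate,
                 chimera_fraction = chimera_fraction,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 homopolymer_min_len = as.integer(homopolymer_min_len),
                 tag_corruption_rate = tag_corruption_rate,
                 min_tag_distance = as.integer(min_tag_distance),
                 primer = toupper(primer),
                 primer_iupac = toupper(primer_iupac)),
            class = "sim_config")
}

#' Generate a set of mutually distant tags
#'
#' @param n number of tags
#' @param tag_length tag length in bases
#' @param min_dist minimum pairwise substitution distance (default 3)
#' @return character vector of tags
#' @export
generate_tag_set <- function(n, tag_length = 6L, min_dist = 3L) {
  tags <- character(0)
  tries <- 0L
  while (length(tags) < n) {
    cand <- random_dna(1, tag_length)
    if (length(tags) == 0L || min(hamming(cand, tags)) >= min_dist)
      tags <- c(tags, cand)
    tries <- tries + 1L
    if (tries > 20000L * n)
      stop("cannot place ", n, " tags at distance >= ", min_dist,
           call. = FALSE)
  }
  tags
}

# random open-reading-frame template: a concatenation of random non-stop
# codons, truncated to `len`, with the first codon drawn from sense codons
# starting with `first_base`.
.random_orf <- function(len, first_base = "G") {
  sense <- .sense_codons()
  first_pool <- sense[startsWith(sense, first_base)]
  n_codons <- ceiling(len / 3)
  s <- paste(c(sample(first_pool, 1),
               sample(sense, n_codons - 1, replace = TRUE)), collapse = "")
  substr(s, 1, len)
}

# force stop codons (frame 0) to sense by setting their third base to C
# (TAA/TAG/TGA -> TAC/TAC/TGC, all sense).
.repair_stops <- function(seq) {
  n_codons <- nchar(seq) %/% 3L
  codons <- substring(seq, seq(1, 3 * n_codons, 3), seq(3, 3 * n_codons, 3))
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  if (any(is_stop)) {
    substr(codons[is_stop], 3, 3) <- "C"
    seq <- paste0(paste(codons, collapse = ""),
                  substr(seq, 3 * n_codons + 1, nchar(seq)))
  }
  seq
}

.mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

.delete_at <- function(seq, pos, len) {
  paste0(substr(seq, 1, pos - 1L), substr(seq, pos + len, nchar(seq)))
}

#' Generate allele pools with cluster structure
#'
#' Expressed pool: intact reading frame (no internal stop codons over the
#' window), diagnostic G at position 1, target mean pairwise divergence.
#' Cluster I pool: diagnostic C or T at position 1, a shared ancestral
#' 1-2 bp frameshift deletion mid-window, alleles within pairwise Hamming
#' distance 2. Group II.A pool: diagnostic G, shared 9-bp plus 1-bp
#' deletions, low divergence. Template regions are \code{window + buffer}
#' long so deletions shift flanking sequence into the fixed read window; the
#' canonical allele sequence is the first \code{window} bases of the region.
#'
#' @param cfg a \code{\link{sim_config}}
#' @return list with \code{regions} and \code{windows}, each a list of named
#'   character vectors per cluster, and \code{cluster} (named vector allele
#'   id -> cluster)
#' @export
generate_allele_pools <- function(cfg) {
  if (cfg$expressed_divergence <= 0 && cfg$pool_sizes["expressed"] > 1L)
    stop("degenerate expressed pool: divergence target must be positive",
         call. = FALSE)
  R <- cfg$window + cfg$buffer
  q <- cfg$expressed_divergence / 2    # per-allele mutation rate from ancestor
  regions <- list()

  for (attempt in 1:20) {
    # one master exon template keeps the three clusters homologous and
    # alignable; cluster ancestors diverge from it by substitutions before
    # their diagnostic deletions are applied
    master <- .random_orf(R, "G")
    anc_div <- 0.12
    mutate_rate <- function(seq, rate) {
      k <- rbinom(1, nchar(seq) - 1L, rate)
      if (k == 0L) seq else .mutate_positions(seq, sample(2:nchar(seq), k))
    }
    # expressed: divergent, intact ORF, G at position 1
    anc_e <- .repair_stops(mutate_rate(master, anc_div))
    expr <- vapply(seq_len(cfg$pool_sizes["expressed"]), function(i) {
      k <- rbinom(1, R - 1L, q)
      s <- .mutate_positions(anc_e, sample(2:R, k))
      .repair_stops(s)
    }, character(1))
    # cluster I: C/T at position 1, shared 1-2 bp deletion, <= 1 substitution
    # from the ancestor each (pairwise Hamming distance <= 2)
    anc_c <- mutate_rate(master, anc_div)
    substr(anc_c, 1, 1) <- sample(c("C", "T"), 1)
    anc_c <- .delete_at(anc_c, cfg$window %/% 2L, sample(1:2, 1))
    pos_c <- sample(2:cfg$window, cfg$pool_sizes["cluster1"] - 1L)
    c1 <- c(anc_c, vapply(pos_c, function(p)
      .mutate_positions(anc_c, p), character(1)))
    # group II.A: G at position 1, shared 9-bp + 1-bp deletions
    anc_a <- mutate_rate(master, anc_div)
    anc_a <- .delete_at(anc_a, cfg$window %/% 3L, 9L)
    anc_a <- .delete_at(anc_a, (2L * cfg$window) %/% 3L, 1L)
    pos_a <- sample(2:cfg$window, cfg$pool_sizes["iia"] - 1L)
    iia <- c(anc_a, vapply(pos_a, function(p)
      .mutate_positions(anc_a, p), character(1)))

    regions <- list(
      expressed = setNames(expr, sprintf("E%03d", seq_along(expr))),
      cluster1 = setNames(c1, sprintf("C%03d", seq_along(c1))),
      iia = setNames(iia, sprintf("A%03d", seq_along(iia))))
    windows <- lapply(regions, substr, 1L, cfg$window)
    if (!anyDuplicated(unlist(windows, use.names = FALSE))) break
    if (attempt == 20)
      stop("could not generate distinct allele windows", call. = FALSE)
  }
  cluster <- rep(names(regions), lengths(regions))
  names(cluster) <- unlist(lapply(regions, names), use.names = FALSE)
  list(regions = regions, windows = windows, cluster = cluster)
}

# diploid genotypes: per cluster, 2 draws per locus (with replacement, so
# homozygosity is possible); the genotype is the distinct allele set.
.simulate_genotypes <- function(cfg, pools) {
  lapply(seq_len(cfg$n_individuals), function(i) {
    ids <- unlist(lapply(names(pools$regions), function(cl) {
      n_loci <- cfg$loci[[cl]]
      if (n_loci == 0L) return(character(0))
      unique(sample(names(pools$regions[[cl]]), 2L * n_loci,
                    replace = TRUE))
    }), use.names = FALSE)
    ids
  })
}

# per-read homopolymer indel channel on a template region; returns the
# (possibly edited) region and whether an edit happened.
.hp_runs_cache <- function(region, min_len) homopolymer_runs(region, min_len)

.apply_hp_indel <- function(region, runs, rate) {
  if (nrow(runs) == 0L) return(list(seq = region, edited = FALSE))
  p <- rate * (runs$length - 2L)
  hit <- which(runif(nrow(runs)) < p)
  if (length(hit) == 0L) return(list(seq = region, edited = FALSE))
  # apply edits right-to-left so positions stay valid
  for (i in rev(hit)) {
    s <- runs$start[i]
    region <- if (runif(1) < 0.5)
      .delete_at(region, s, 1L)
    else
      paste0(substr(region, 1, s), runs$base[i],
             substr(region, s + 1L, nchar(region)))
  }
  list(seq = region, edited = TRUE)
}

#' Simulate a tagged amplicon sequencing run with ground truth
#'
#' Draws allele pools, diploid multilocus genotypes and per-amplicon
#' coverage, then emits reads of the form tag + primer + window with
#' per-allele amplification skew, single-crossover chimeras, homopolymer
#' indels, i.i.d. substitution errors and tag corruption. Every read is
#' traceable to its provenance in the returned truth tables.
#'
#' @param cfg a \code{\link{sim_config}}
#' @param seed RNG seed fixing the entire output stream
#' @return object of class \code{sim_run}: list with \code{reads} (named
#'   character vector), \code{sheet} (a \code{\link{tag_sheet}}),
#'   \code{truth} (list: \code{pools}, \code{allele_windows},
#'   \code{cluster}, \code{genotypes}, \code{read_info}) and \code{config}
#' @export
simulate_run <- function(cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sum(cfg$loci) == 0L)
    stop("no loci configured but coverage requested", call. = FALSE)
  pools <- generate_allele_pools(cfg)
  genotypes <- .simulate_genotypes(cfg, pools)
  windows <- unlist(pools$windows, use.names = FALSE)
  names(windows) <- unlist(lapply(pools$windows, names), use.names = FALSE)
  regions <- unlist(pools$regions, use.names = FALSE)
  names(regions) <- names(windows)
  runs_cache <- lapply(regions, .hp_runs_cache, cfg$homopolymer_min_len)
  skew <- setNames(exp(rnorm(length(windows), 0, cfg$skew_sigma)),
                   names(windows))

  n_dup <- round(cfg$replicate_fraction * cfg$n_individuals)
  ind <- c(rep(seq_len(cfg$n_individuals),
               times = ifelse(seq_len(cfg$n_individuals) <= n_dup, 2L, 1L)))
  repl <- unlist(lapply(seq_len(cfg$n_individuals), function(i)
    seq_len(if (i <= n_dup) 2L else 1L)))
  tags <- generate_tag_set(length(ind), cfg$tag_length, cfg$min_tag_distance)
  sheet <- tag_sheet(tags, sprintf("ind%03d", ind), repl)

  all_reads <- character(0)
  info <- vector("list", nrow(sheet))
  for (a in seq_len(nrow(sheet))) {
    amp <- sheet$amplicon[a]
    ids <- genotypes[[ind[a]]]
    cl <- pools$cluster[ids]
    w <- cfg$cluster_read_props[cl] / table(cl)[cl] * skew[ids]
    w <- as.numeric(w / sum(w))
    coverage <- max(2L, as.integer(round(rnorm(1, cfg$coverage_mean,
                                               cfg$coverage_sd))))
    can_chim <- length(ids) >= 2L
    is_chim <- can_chim & runif(coverage) < cfg$chimera_fraction
    tpl <- sample(ids, coverage, replace = TRUE, prob = w)
    tpl2 <- rep(NA_character_, coverage)
    brk <- rep(NA_integer_, coverage)
    hp <- rep(FALSE, coverage)
    win <- character(coverage)

    t_idx <- which(!is_chim)
    if (length(t_idx) > 0) {
      win[t_idx] <- windows[tpl[t_idx]]
      if (cfg$homopolymer_indel_rate > 0) {
        for (i in t_idx) {
          res <- .apply_hp_indel(regions[[tpl[i]]], runs_cache[[tpl[i]]],
                                 cfg$homopolymer_indel_rate)
          if (res$edited) {
            hp[i] <- TRUE
            win[i] <- substr(res$seq, 1, cfg$window)
          }
        }
      }
    }
    c_idx <- which(is_chim)
    for (i in c_idx) {
      b <- sample(setdiff(ids, tpl[i]), 1, prob = w[match(
        setdiff(ids, tpl[i]), ids)])
      k <- sample.int(cfg$window - 1L, 1)
      tpl2[i] <- b
      brk[i] <- k
      win[i] <- paste0(substr(windows[tpl[i]], 1, k),
                       substr(windows[b], k + 1L, cfg$window))
    }

    pre_error <- win
    # i.i.d. substitution errors within the window
    n_err <- rbinom(coverage, cfg$window, cfg$substitution_rate)
    for (i in which(n_err > 0))
      win[i] <- .mutate_positions(win[i], sample.int(cfg$window, n_err[i]))
    # tag corruption
    tag_seq <- rep(sheet$tag[a], coverage)
    n_bad <- rbinom(coverage, cfg$tag_length, cfg$tag_corruption_rate)
    for (i in which(n_bad > 0))
      tag_seq[i] <- .mutate_positions(tag_seq[i],
                                      sample.int(cfg$tag_length, n_bad[i]))
    read_id <- sprintf("%s_r%05d", amp, seq_len(coverage))
    all_reads <- c(all_reads,
                   setNames(paste0(tag_seq, cfg$primer, win), read_id))
    info[[a]] <- data.frame(
      read_id = read_id, amplicon = amp,
      individual = sheet$individual[a], replicate = sheet$replicate[a],
      type = ifelse(is_chim, "chimera", "template"),
      template = tpl, template2 = tpl2, breakpoint = brk,
      window_pre_error = pre_error,
      n_subst = n_err, hp_indel = hp,
      tag_corrupted = n_bad > 0,
      stringsAsFactors = FALSE)
  }
  structure(list(reads = all_reads, sheet = sheet,
                 truth = list(pools = pools,
                              allele_windows = windows,
                              cluster = pools$cluster,
                              genotypes = lapply(genotypes, identity),
                              read_info = do.call(rbind, info)),
                 config = cfg),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat("sim_run:", length(x$reads), "reads over", nrow(x$sheet),
      "amplicons;", length(x$truth$allele_windows), "alleles in pool\n")
  invisible(x)
}

#' Write a simulated run to disk
#'
#' Reads as FASTA, the tag sheet and the per-read truth table as
#' tab-separated text.
#' @param sim a \code{\link{simulate_run}} result
#' @param dir output directory
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reads, file.path(dir, "reads.fasta"))
  write_tag_sheet(sim$sheet, file.path(dir, "tags.tsv"))
  write.table(sim$truth$read_info, file.path(dir, "read_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(sim$truth$allele_windows, file.path(dir, "true_alleles.fasta"))
  invisible(dir)
}

#' Score pipeline outputs against simulator ground truth
#'
#' Computes allele recall and precision (overall and per cluster), chimera
#' sensitivity and false-discovery proportion, and per-amplicon genotype
#' accuracy. Recall is detectability-aware: its denominator contains only
#' true alleles whose window sequence meets the replication criterion in the
#' observed variant table (at least \code{min_copies} reads in at least
#' \code{min_pcrs} amplicons).
#'
#' @param sim a \code{\link{simulate_run}} result
#' @param vt the \code{\link{variant_table}} built from the pipeline's
#'   demultiplexing of \code{sim$reads}
#' @param report a \code{\link{filter_variants}} report on \code{vt}
#' @param cfg the \code{\link{filter_config}} used
#' @param min_reads per-amplicon read threshold for genotype calls
#'   (default 2)
#' @return list of metrics; \code{recall} and \code{precision} are named
#'   vectors with an \code{overall} entry plus one per cluster
#' @export
evaluate_against_truth <- function(sim, vt, report, cfg = filter_config(),
                                   min_reads = 2L) {
  truth <- sim$truth
  true_windows <- truth$allele_windows
  if (!all(report$sequence %in% rownames(vt$counts)))
    stop("report and variant table identifiers do not match", call. = FALSE)
  carried <- unique(unlist(lapply(truth$genotypes, function(ids)
    unname(true_windows[ids]))))
  detectable <- intersect(apply_replication_criterion(vt, cfg), carried)
  alleles <- report$sequence[report$status == "putative allele"]
  cl_of <- setNames(truth$cluster, unname(true_windows))

  cats <- c("overall", unique(unname(truth$cluster)))
  recall <- vapply(cats, function(cat) {
    denom <- if (cat == "overall") detectable
             else detectable[cl_of[detectable] == cat]
    if (length(denom) == 0L) return(NA_real_)
    mean(denom %in% alleles)
  }, numeric(1))
  # of reported putative alleles, the fraction that are true allele windows
  precision <- if (length(alleles) == 0L) NA_real_
               else mean(alleles %in% names(cl_of))

  ri <- truth$read_info
  chim_seqs <- setdiff(unique(ri$window_pre_error[ri$type == "chimera"]),
                       names(cl_of))
  flagged <- report$sequence[report$status == "PCR chimera"]
  cand <- report$sequence[report$status %in%
                            c("PCR chimera", "putative allele")]
  chim_cand <- intersect(chim_seqs, cand)
  chimera_sensitivity <- if (length(chim_cand) == 0L) NA_real_
                         else mean(chim_cand %in% flagged)
  chimera_fdp <- if (length(flagged) == 0L) NA_real_
                 else mean(flagged %in% names(cl_of))

  # chimeric candidates guaranteed detectable: some true parent pair is
  # strictly more abundant in every examined amplicon, and the variant's
  # MPAF lies inside the exhaustively scanned zone
  guaranteed <- Filter(function(v) {
    mp <- report$mpaf[report$sequence == v]
    if (!(cfg$full_scan || mp < cfg$grey_zone_upper)) return(FALSE)
    evs <- unique(ri[ri$type == "chimera" & ri$window_pre_error == v,
                     c("template", "template2")])
    amps <- .top_amplicons(vt, v, cfg$n_check_amplicons)
    any(apply(evs, 1, function(e) {
      pa <- unname(true_windows[e[1]]); pb <- unname(true_windows[e[2]])
      if (!pa %in% rownames(vt$counts) || !pb %in% rownames(vt$counts))
        return(FALSE)
      all(vt$counts[pa, amps] > vt$counts[v, amps] &
            vt$counts[pb, amps] > vt$counts[v, amps])
    }))
  }, chim_cand)
  guaranteed <- unlist(guaranteed)
  guaranteed_flagged <- if (length(guaranteed) == 0L) NA_real_
                        else mean(guaranteed %in% flagged)

  accs <- vapply(colnames(vt$counts), function(amp) {
    who <- sim$sheet$individual[sim$sheet$amplicon == amp]
    ind_i <- as.integer(sub("^ind", "", who))
    true_set <- unname(true_windows[truth$genotypes[[ind_i]]])
    true_set <- true_set[true_set %in% rownames(vt$counts)]
    true_set <- true_set[vt$counts[true_set, amp] >= min_reads]
    called <- call_alleles(vt, alleles, amp, min_reads)$sequence
    u <- union(called, true_set)
    if (length(u) == 0L) return(1)
    length(intersect(called, true_set)) / length(u)
  }, numeric(1))

  list(recall = recall, precision = precision,
       chimera_sensitivity = chimera_sensitivity,
       chimera_fdp = chimera_fdp,
       guaranteed_chimeras = length(guaranteed),
       guaranteed_flagged_fraction = guaranteed_flagged,
       genotype_accuracy = mean(accs),
       n_detectable = length(detectable))
}
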