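# Independent oracle implementations used to verify the package's
# operations: deliberately brute-force and written without reference to the
# package internals.

BASES <- c("A", "C", "G", "T")

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = BASES)

rand_dna <- function(len) paste(sample(BASES, len, TRUE), collapse = "")

# exhaustive-offset primer search with per-position set membership
oracle_locate_primer <- function(read, primer) {
  rc <- strsplit(read, "")[[1]]
  pc <- strsplit(primer, "")[[1]]
  pl <- length(pc)
  if (length(rc) < pl) return(NA_integer_)
  for (off in 0:(length(rc) - pl)) {
    ok <- TRUE
    for (j in seq_len(pl)) {
      if (!(rc[off + j] %in% IUPAC_ORACLE[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) return(off + 1L)
  }
  NA_integer_
}

# enumerate every ordered parent pair and every breakpoint
oracle_chimera <- function(variant, parent_seqs) {
  L <- nchar(variant)
  for (a in parent_seqs) for (b in parent_seqs) {
    if (a == variant || b == variant) next
    for (k in 1:(L - 1)) {
      if (paste0(substr(a, 1, k), substr(b, k + 1, L)) == variant)
        return(TRUE)
    }
  }
  FALSE
}

# every sequence reachable from `seq` by one single-base insertion or
# deletion inside a homopolymer run of length >= min_run: full enumeration
# over edit positions, deduplicated
oracle_hp_edits <- function(seq, min_run = 3) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  r <- rle(ch)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  out <- character(0)
  for (p in seq_len(L)) {
    if (r$lengths[run_id[p]] >= min_run)
      out <- c(out, paste(ch[-p], collapse = ""))
  }
  for (g in 0:L) for (b in BASES) {
    rid <- NA
    if (g >= 1 && ch[g] == b) rid <- run_id[g]
    else if (g < L && ch[g + 1] == b) rid <- run_id[g + 1]
    if (!is.na(rid) && r$lengths[rid] >= min_run)
      out <- c(out, paste(c(head(ch, g), b,
                            if (g < L) ch[(g + 1):L]), collapse = ""))
  }
  unique(out)
}

# direct evaluation of the TN93 closed form from counted proportions
# (Tamura & Nei 1993, eq. for the total distance), pairwise deletion
oracle_tn93 <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  keep <- a %in% BASES & b %in% BASES
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  freq <- table(factor(c(a, b), levels = BASES)) / (2 * n)
  gA <- freq["A"]; gC <- freq["C"]; gG <- freq["G"]; gT <- freq["T"]
  gR <- gA + gG; gY <- gC + gT
  is_ts1 <- (a == "A" & b == "G") | (a == "G" & b == "A")  # purine ts
  is_ts2 <- (a == "C" & b == "T") | (a == "T" & b == "C")  # pyrimidine ts
  P1 <- sum(is_ts1) / n
  P2 <- sum(is_ts2) / n
  Q <- sum(a != b & !is_ts1 & !is_ts2) / n
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(Inf)
  as.numeric(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
}

# independent Nei-Gojobori pair counts: explicit permutation enumeration of
# mutational pathways with stop-codon pathways excluded
GC_ORACLE <- Biostrings::GENETIC_CODE

.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

oracle_ng_codon_pair <- function(c1, c2) {
  if (c1 == c2) return(c(nd = 0, sd = 0))
  x <- strsplit(c1, "")[[1]]; y <- strsplit(c2, "")[[1]]
  d <- which(x != y)
  tally <- list()
  for (path in .perms(d)) {
    cur <- x; nd <- 0; sd <- 0; blocked <- FALSE
    for (p in path) {
      from <- GC_ORACLE[[paste(cur, collapse = "")]]
      cur[p] <- y[p]
      to <- GC_ORACLE[[paste(cur, collapse = "")]]
      if (to == "*") { blocked <- TRUE; break }
      if (from == to) sd <- sd + 1 else nd <- nd + 1
    }
    if (!blocked) tally[[length(tally) + 1]] <- c(nd, sd)
  }
  if (length(tally) == 0) {
    # all pathways blocked: fall back to counting through stops, steps into
    # stops as nonsynonymous
    for (path in .perms(d)) {
      cur <- x; nd <- 0; sd <- 0
      for (p in path) {
        from <- GC_ORACLE[[paste(cur, collapse = "")]]
        cur[p] <- y[p]
        to <- GC_ORACLE[[paste(cur, collapse = "")]]
        if (from == to) sd <- sd + 1 else nd <- nd + 1
      }
      tally[[length(tally) + 1]] <- c(nd, sd)
    }
  }
  avg <- Reduce(`+`, tally) / length(tally)
  c(nd = avg[1], sd = avg[2])
}

oracle_ng_sites <- function(codon) {
  x <- strsplit(codon, "")[[1]]
  aa <- GC_ORACLE[[codon]]
  s <- 0; n <- 0
  for (pos in 1:3) for (b in setdiff(BASES, x[pos])) {
    m <- x; m[pos] <- b
    maa <- GC_ORACLE[[paste(m, collapse = "")]]
    if (maa == "*") next
    nb <- sum(vapply(setdiff(BASES, x[pos]), function(bb) {
      mm <- x; mm[pos] <- bb
      GC_ORACLE[[paste(mm, collapse = "")]] != "*"
    }, logical(1)))
    if (maa == aa) s <- s + 1 / nb else n <- n + 1 / nb
  }
  c(s = s, n = n)
}

oracle_pairwise_ng <- function(s1, s2) {
  c1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  c2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  sense <- names(GC_ORACLE)[GC_ORACLE != "*"]
  ok <- c1 %in% sense & c2 %in% sense
  Nd <- 0; Sd <- 0; n1 <- 0; s1s <- 0; n2 <- 0; s2s <- 0
  for (i in which(ok)) {
    pc <- oracle_ng_codon_pair(c1[i], c2[i])
    Nd <- Nd + pc["nd"]; Sd <- Sd + pc["sd"]
    sc1 <- oracle_ng_sites(c1[i]); sc2 <- oracle_ng_sites(c2[i])
    n1 <- n1 + sc1["n"]; s1s <- s1s + sc1["s"]
    n2 <- n2 + sc2["n"]; s2s <- s2s + sc2["s"]
  }
  list(Nd = unname(Nd), Sd = unname(Sd),
       n = unname((n1 + n2) / 2), s = unname((s1s + s2s) / 2))
}

# random sense-codon sequence
rand_coding <- function(n_codon) {
  sense <- names(GC_ORACLE)[GC_ORACLE != "*"]
  paste(sample(sense, n_codon, TRUE), collapse = "")
}

# neutral codon alignment: a shared ancestor plus, per sequence, `n_mut`
# accepted random single-base changes drawn uniformly over non-stop mutants
sim_neutral_alignment <- function(n_seq, n_codon, n_mut) {
  sense <- names(GC_ORACLE)[GC_ORACLE != "*"]
  anc <- sample(sense, n_codon, replace = TRUE)
  vapply(seq_len(n_seq), function(i) {
    s <- anc
    for (m in seq_len(n_mut)) {
      repeat {
        j <- sample.int(n_codon, 1)
        pos <- sample.int(3, 1)
        cd <- strsplit(s[j], "")[[1]]
        cd[pos] <- sample(setdiff(BASES, cd[pos]), 1)
        cand <- paste(cd, collapse = "")
        if (cand %in% sense) { s[j] <- cand; break }
      }
    }
    paste(s, collapse = "")
  }, character(1))
}

# alignment with elevated nonsynonymous acceptance at `hot` codons:
# synonymous changes at hot codons are accepted with probability 1/ratio
sim_selected_alignment <- function(n_seq, n_codon, n_mut, hot, ratio = 3) {
  sense <- names(GC_ORACLE)[GC_ORACLE != "*"]
  anc <- sample(sense, n_codon, replace = TRUE)
  vapply(seq_len(n_seq), function(i) {
    s <- anc
    done <- 0
    while (done < n_mut) {
      j <- sample.int(n_codon, 1)
      pos <- sample.int(3, 1)
      cd <- strsplit(s[j], "")[[1]]
      old_aa <- GC_ORACLE[[s[j]]]
      cd[pos] <- sample(setdiff(BASES, cd[pos]), 1)
      cand <- paste(cd, collapse = "")
      if (!cand %in% sense) next
      syn <- GC_ORACLE[[cand]] == old_aa
      if (j %in% hot && syn && runif(1) > 1 / ratio) next
      s[j] <- cand
      done <- done + 1
    }
    paste(s, collapse = "")
  }, character(1))
}

# build a variant_table from a list of per-amplicon named count vectors
# (names = sequences)
make_vt <- function(amplicons, totals = NULL) {
  seqs <- unique(unlist(lapply(amplicons, names)))
  m <- matrix(0L, length(seqs), length(amplicons),
              dimnames = list(seqs, names(amplicons)))
  for (a in names(amplicons)) m[names(amplicons[[a]]), a] <-
      as.integer(amplicons[[a]])
  if (is.null(totals)) variant_table(m) else variant_table(m, totals)
}
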