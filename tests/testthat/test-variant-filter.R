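test_that("replication criterion requires min_pcrs amplicons at min_copies", {
  vt <- make_vt(list(a1 = c(AAAA = 10, CCCC = 3, GGGG = 3),
                     a2 = c(CCCC = 3, GGGG = 2)))
  cand <- apply_replication_criterion(vt)
  expect_true("CCCC" %in% cand)        # 2 PCRs with >= 3 copies each
  expect_false("AAAA" %in% cand)       # one PCR only
  expect_false("GGGG" %in% cand)       # second amplicon below 3 copies
})

test_that("relaxing the replication criterion never shrinks the candidates", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rpois(60, 2), 12, 5,
                dimnames = list(replicate(12, rand_dna(8)), paste0("a", 1:5)))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    vt <- variant_table(m)
    base <- apply_replication_criterion(vt, filter_config(min_pcrs = 2,
                                                          min_copies = 3))
    expect_true(all(base %in% apply_replication_criterion(
      vt, filter_config(min_pcrs = 2, min_copies = 2))))
    expect_true(all(base %in% apply_replication_criterion(
      vt, filter_config(min_pcrs = 1, min_copies = 3))))
  }
})

test_that("MPAF is the maximum per-amplicon read fraction", {
  vt <- make_vt(list(a1 = c(AAAA = 5, TTTT = 495),
                     a2 = c(AAAA = 20, TTTT = 980)),
                totals = c(500, 1000))
  expect_equal(unname(compute_mpaf(vt, "AAAA")), 0.02)
  expect_equal(unname(compute_mpaf(vt, "GGGG")), 0)  # absent variant
})

test_that("chimera explanation agrees with the exhaustive pair oracle", {
  expect_false(explainable_as_chimera("AAAAAA", character(0)))
  r <- explainable_as_chimera("AATTTT", c("AAAAAA", "TTTTTT"))
  expect_true(r)
  w <- attr(r, "witness")
  expect_identical(paste0(substr(w$parent_a, 1, w$breakpoint),
                          substr(w$parent_b, w$breakpoint + 1, 6)),
                   "AATTTT")
  expect_false(explainable_as_chimera("AAGTTT", c("AAAAAA", "TTTTTT")))
  expect_error(explainable_as_chimera("AAAA", "AAAAAA"), "length")

  set.seed(33)
  for (i in 1:300) {
    L <- sample(6:12, 1)
    nvar <- sample(2:8, 1)
    seqs <- unique(replicate(nvar, paste(sample(c("A", "T"), L, TRUE),
                                         collapse = "")))
    v <- seqs[1]
    parents <- setdiff(seqs, v)
    got <- isTRUE(explainable_as_chimera(v, parents))
    expect_identical(got, oracle_chimera(v, parents))
    if (got) {
      w <- attr(explainable_as_chimera(v, parents), "witness")
      expect_identical(paste0(substr(w$parent_a, 1, w$breakpoint),
                              substr(w$parent_b, w$breakpoint + 1, L)), v)
    }
  }
})

test_that("the most abundant variant of an amplicon is never a chimera", {
  set.seed(9)
  for (i in 1:10) {
    amp <- setNames(sample(5:50, 6), replicate(6, rand_dna(10)))
    vt <- make_vt(list(a1 = amp, a2 = amp))
    cls <- classify_by_mpaf(vt, rownames(vt$counts),
                            filter_config(full_scan = TRUE))
    top <- names(amp)[which.max(amp)]
    expect_identical(cls$status[cls$sequence == top], "putative allele")
  }
})

test_that("classify_by_mpaf flags planted chimeras with valid witnesses", {
  A <- strrep("A", 12); B <- strrep("T", 12)
  V <- paste0(strrep("A", 5), strrep("T", 7))     # A x B chimera
  # V co-occurs with both, less abundant, in all three amplicons
  amps <- list(a1 = setNames(c(100, 90, 5), c(A, B, V)),
               a2 = setNames(c(80, 70, 4), c(A, B, V)),
               a3 = setNames(c(60, 50, 3), c(A, B, V)))
  vt <- make_vt(amps)
  cls <- classify_by_mpaf(vt, rownames(vt$counts),
                          filter_config(full_scan = TRUE))
  expect_identical(cls$status[cls$sequence == V], "PCR chimera")
  wrow <- cls[cls$sequence == V, ]
  expect_identical(paste0(substr(wrow$witness_a, 1, wrow$breakpoint),
                          substr(wrow$witness_b, wrow$breakpoint + 1, 12)),
                   V)
  expect_identical(cls$status[cls$sequence == A], "putative allele")
  # variant in fewer than three amplicons: all occupied amplicons examined
  vt2 <- make_vt(list(a1 = setNames(c(100, 90, 5), c(A, B, V)),
                      a2 = setNames(c(80, 70), c(A, B))))
  cls2 <- classify_by_mpaf(vt2, rownames(vt2$counts),
                           filter_config(full_scan = TRUE))
  expect_identical(cls2$status[cls2$sequence == V], "PCR chimera")
})

test_that("a chimera escaping explanation in one amplicon stays an allele", {
  A <- strrep("A", 12); B <- strrep("T", 12)
  V <- paste0(strrep("A", 5), strrep("T", 7))
  # in a3, parent B is absent: not explainable there
  vt <- make_vt(list(a1 = setNames(c(100, 90, 5), c(A, B, V)),
                     a2 = setNames(c(80, 70, 4), c(A, B, V)),
                     a3 = setNames(c(60, 5), c(A, V))))
  cls <- classify_by_mpaf(vt, rownames(vt$counts),
                          filter_config(full_scan = TRUE))
  expect_identical(cls$status[cls$sequence == V], "putative allele")
})

test_that("threshold derivation matches a brute-force scan of sorted MPAFs", {
  cls <- data.frame(
    sequence = paste0("s", 1:5),
    mpaf = c(0.006, 0.009, 0.0051, 0.0097, 0.02),
    status = c("PCR chimera", "PCR chimera", rep("putative allele", 3)))
  expect_equal(derive_threshold(cls), 0.0097)
  cls2 <- data.frame(sequence = c("a", "b"), mpaf = c(0.004, 0.01),
                     status = "putative allele")
  expect_equal(derive_threshold(cls2), 0.004)
  expect_error(derive_threshold(cls2[0, ]), "empty")

  set.seed(12)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    cl <- data.frame(sequence = paste0("s", 1:n),
                     mpaf = round(runif(n, 0.001, 0.05), 4),
                     status = sample(c("putative allele", "PCR chimera"),
                                     n, TRUE, prob = c(0.7, 0.3)))
    if (!any(cl$status == "putative allele")) next
    # brute force: smallest allele MPAF t with no chimera at or above t
    cand <- sort(cl$mpaf[cl$status == "putative allele"])
    ok <- cand[vapply(cand, function(t)
      !any(cl$mpaf[cl$status == "PCR chimera"] >= t), logical(1))]
    expected <- if (length(ok)) min(ok) else NA_real_
    expect_equal(derive_threshold(cl), expected)
  }
})

test_that("threshold scaling is proportional and exact", {
  expect_equal(round(100 * scale_threshold(0.0097, 0.164, 0.718), 2), 4.25)
  expect_equal(round(100 * scale_threshold(0.0097, 0.164, 0.118), 2), 0.70)
  expect_equal(scale_threshold(0.012, 0.3, 0.3), 0.012)
  # linear in the target proportion
  expect_equal(scale_threshold(0.01, 0.2, 0.6),
               3 * scale_threshold(0.01, 0.2, 0.2), tolerance = 1e-12)
  expect_error(scale_threshold(0.01, 0, 0.5), "proportions")
})

test_that("homopolymer-indel artifacts are detected against abundant parents", {
  expect_true(flag_homopolymer_indel("AAATG", "AAAATG"))
  expect_false(flag_homopolymer_indel("AAACTG", "AAAATG"))  # substitution
  expect_false(flag_homopolymer_indel("ACGT", "ACGTT"))     # run too short

  set.seed(77)
  for (i in 1:100) {
    parent <- paste(sample(BASES, 20, TRUE, prob = c(.4, .1, .1, .4)),
                    collapse = "")
    edits <- oracle_hp_edits(parent, 3)
    # every oracle edit must be flagged
    for (e in head(edits, 4))
      expect_true(flag_homopolymer_indel(e, parent))
    # a random double edit or substitution must not be
    if (length(edits) > 0) {
      sub <- .mutate <- strsplit(edits[1], "")[[1]]
      p <- sample(length(sub), 1)
      sub[p] <- sample(setdiff(BASES, sub[p]), 1)
      cand <- paste(sub, collapse = "")
      expect_identical(isTRUE(flag_homopolymer_indel(cand, parent)),
                       cand %in% oracle_hp_edits(parent, 3))
    }
  }
})

test_that("fixed-window homopolymer shifts are recognised", {
  parent <- paste0("ACGTAAAATCGT", "GC")     # run of 4 A's, window 14
  # template deletion: one A lost, downstream shifts left, new base enters
  del_win <- paste0("ACGTAAATCGTGC", "T")
  expect_true(flag_homopolymer_indel(del_win, parent))
  # template insertion: extra A, last base pushed out
  ins_win <- substr(paste0("ACGTAAAAATCGT", "GC"), 1, 14)
  expect_true(flag_homopolymer_indel(ins_win, parent))
  expect_false(flag_homopolymer_indel(parent, parent))
})

test_that("the full filter assigns one status to every variant", {
  set.seed(5)
  A <- strrep("A", 12); B <- strrep("T", 12)
  V <- paste0(strrep("A", 5), strrep("T", 7))
  H <- A; substr(H, 6, 6) <- "G"        # unrelated 1-sub variant
  amps <- list(a1 = setNames(c(200, 150, 5, 40), c(A, B, V, H)),
               a2 = setNames(c(180, 160, 4, 35), c(A, B, V, H)),
               a3 = setNames(c(90, 85, 3, 20), c(A, B, V, H)),
               a4 = setNames(c(2, 1), c(A, rand_dna(12))))
  rep_df <- filter_variants(make_vt(amps), filter_config(full_scan = TRUE))
  expect_setequal(rep_df$status[rep_df$sequence == V], "PCR chimera")
  expect_setequal(rep_df$status[rep_df$sequence %in% c(A, B, H)],
                  "putative allele")
  expect_true(all(rep_df$status[rep_df$n_amplicons == 1] ==
                    "below-threshold"))
  expect_equal(nrow(rep_df), nrow(make_vt(amps)$counts))
})

test_that("a true recombinant co-occurring with both parents is lost
           (documented failure mode)", {
  A <- strrep("A", 12); B <- strrep("T", 12)
  R <- paste0(strrep("A", 6), strrep("T", 6))   # true recombinant allele
  # R is a genuine allele, but it always co-occurs with its evolutionary
  # parents at lower abundance, so the single-crossover test cannot
  # distinguish it from a PCR chimera
  amps <- list(a1 = setNames(c(100, 90, 20), c(A, B, R)),
               a2 = setNames(c(95, 85, 18), c(A, B, R)),
               a3 = setNames(c(80, 75, 15), c(A, B, R)))
  rep_df <- filter_variants(make_vt(amps), filter_config(full_scan = TRUE))
  expect_identical(rep_df$status[rep_df$sequence == R], "PCR chimera")
})

test_that("filter bookkeeping percentages reproduce report arithmetic", {
  p <- filter_report_percentages(146, 157)
  expect_equal(round(p$retention_pct, 1), 93.0)
  expect_equal(round(filter_report_percentages(28, 225)$retention_pct, 1),
               12.4)
  expect_equal(round(filter_report_percentages(148, 159,
                                               11)$chimera_pct, 1), 6.9)
})
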