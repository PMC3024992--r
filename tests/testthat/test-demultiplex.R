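FWD <- "GAGTGTCHYTTCVTTAACGGCAC"      # degenerate forward primer
FWD_CONCRETE <- "GAGTGTCACTTCGTTAACGGCAC" # one IUPAC realisation

test_that("locate_primer finds the leftmost IUPAC-compatible match", {
  read <- paste0("ACGTGA", FWD_CONCRETE, "TTTTT")
  expect_identical(locate_primer(read, FWD), 7L)
  expect_true(is.na(locate_primer("ACGTACGTACGT", FWD)))
  expect_error(locate_primer("ACGT", "AXGT"), "non-IUPAC")
  # degenerate positions accept every base in their set (H -> T, Y -> C,
  # V -> A here)
  expect_identical(locate_primer("GAGTGTCTCTTCATTAACGGCAC", FWD), 1L)
})

test_that("locate_primer agrees with the exhaustive-offset oracle", {
  set.seed(101)
  primer <- "GAGTGTCHYTTCV"
  for (i in 1:1000) {
    off <- sample(0:40, 1)
    read <- paste0(rand_dna(off),
                   paste(vapply(strsplit(primer, "")[[1]], function(ch)
                     sample(IUPAC_ORACLE[[ch]], 1), character(1)),
                     collapse = ""),
                   rand_dna(20))
    expect_identical(locate_primer(read, primer),
                     oracle_locate_primer(read, primer))
  }
})

test_that("locate_primer tolerates configured mismatches", {
  read <- paste0("AAAA", FWD_CONCRETE, "GGG")
  bad <- read
  substr(bad, 10, 10) <- "N"   # corrupt one primer base
  expect_true(is.na(locate_primer(bad, FWD)))
  expect_identical(locate_primer(bad, FWD, max_mismatch = 1L), 5L)
})

.mini_sheet <- function(n = 4) {
  tag_sheet(generate_tag_set(n, 6, 3),
            individual = paste0("I", ceiling(seq_len(n) / 2)),
            replicate = rep(1:2, length.out = n))
}

test_that("demultiplex assigns reads by tag and conserves every read", {
  set.seed(7)
  sheet <- .mini_sheet()
  win <- 30L
  reads <- unlist(lapply(sheet$tag, function(tg)
    replicate(5, paste0(tg, FWD_CONCRETE, rand_dna(win)))))
  names(reads) <- paste0("r", seq_along(reads))
  d <- demultiplex(reads, sheet, FWD, window = win)
  expect_equal(nrow(d$assigned), 20)
  expect_equal(nrow(d$unassigned), 0)
  expect_equal(nrow(d$assigned) + nrow(d$unassigned), d$counts$total)
  expect_true(all(nchar(d$assigned$sequence) == win))
  expect_equal(as.vector(table(d$assigned$amplicon)[sheet$amplicon]),
               rep(5L, 4))
  # determinism
  expect_identical(d, demultiplex(reads, sheet, FWD, window = win))
})

test_that("unused tags, incomplete tags and short windows are reported", {
  sheet <- tag_sheet(c("AAAAAA", "CCCCCC"), c("a", "b"))
  reads <- c(ok = paste0("AAAAAA", FWD_CONCRETE, strrep("A", 30)),
             unused = paste0("GGGGGG", FWD_CONCRETE, strrep("A", 30)),
             incomplete = paste0("AAA", FWD_CONCRETE, strrep("A", 30)),
             short = paste0("CCCCCC", FWD_CONCRETE, strrep("A", 10)),
             noprimer = strrep("ACGT", 15))
  d <- demultiplex(reads, sheet, FWD, window = 30L)
  expect_equal(nrow(d$assigned), 1)
  expect_setequal(d$unassigned$reason,
                  c("unused_tag", "incomplete_tag", "short_window",
                    "no_primer"))
  expect_equal(d$counts$unused_tag, 1)
  expect_equal(nrow(d$assigned) + nrow(d$unassigned), length(reads))
})

test_that("reverse-complement reads are recovered when scanning is on", {
  sheet <- tag_sheet("ACGTCA", "a")
  fw <- paste0("ACGTCA", FWD_CONCRETE, strrep("AC", 15))
  rc <- revcomp(fw)
  d <- demultiplex(c(r1 = rc), sheet, FWD, window = 30L)
  expect_equal(nrow(d$assigned), 1)
  d2 <- demultiplex(c(r1 = rc), sheet, FWD, window = 30L,
                    scan_revcomp = FALSE)
  expect_equal(nrow(d2$assigned), 0)
})

test_that("misassignment arithmetic follows the tag-space bookkeeping", {
  m <- misassignment_summary(6, 35, 502, 152053, 541)
  expect_equal(round(100 * m$unused_tag_fraction_of_tag_space, 1), 99.1)
  expect_equal(round(100 * m$misassignment_rate_upper_bound, 2), 0.33)
  expect_lt(m$expected_misassigned_reads_per_amplicon, 2)
  z <- misassignment_summary(6, 35, 0, 1000, 500)
  expect_equal(z$misassignment_rate_upper_bound, 0)
  expect_equal(z$expected_misassigned_reads_per_amplicon, 0)
  expect_error(misassignment_summary(6, 35, 0, 0), "zero reads")
})

test_that("unused-tag fraction recovers the tag corruption rate", {
  set.seed(42)
  tags <- generate_tag_set(35, 6, 3)
  sheet <- tag_sheet(tags, paste0("I", seq_along(tags)))
  n <- 2e4
  win <- 20L
  base_reads <- paste0(sample(tags, n, TRUE), FWD_CONCRETE,
                       replicate(1, rand_dna(win)))
  observed <- vapply(c(0.002, 0.01, 0.05), function(r) {
    reads <- vapply(base_reads, function(rd) {
      nb <- rbinom(1, 6, r)
      if (nb == 0) return(rd)
      ch <- strsplit(substr(rd, 1, 6), "")[[1]]
      for (p in sample(6, nb)) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
      paste0(paste(ch, collapse = ""), substr(rd, 7, nchar(rd)))
    }, character(1), USE.NAMES = FALSE)
    names(reads) <- paste0("r", seq_len(n))
    d <- demultiplex(reads, sheet, FWD, window = win)
    estimate_misassignment(d)$misassignment_rate_upper_bound
  }, numeric(1))
  # used tags are >= 3 substitutions apart, so essentially every corrupted
  # tag is unused: expectation ~ 1 - (1 - r)^6, within binomial error
  expected <- 1 - (1 - c(0.002, 0.01, 0.05))^6
  tol <- 4 * sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(observed - expected) < tol + 2e-3))
  expect_true(all(diff(observed) > 0))   # monotone in the corruption rate
})

test_that("coverage summary reports means, singletons and unique variants", {
  sheet <- tag_sheet(c("AAAAAA", "CCCCCC", "GGGGGG"), c("a", "b", "c"))
  v1 <- strrep("AC", 15); v2 <- strrep("AG", 15); v3 <- strrep("AT", 15)
  reads <- c(rep(paste0("AAAAAA", FWD_CONCRETE, v1), 100),
             rep(paste0("CCCCCC", FWD_CONCRETE, v1), 150),
             rep(paste0("CCCCCC", FWD_CONCRETE, v2), 50),
             rep(paste0("GGGGGG", FWD_CONCRETE, v2), 299),
             paste0("GGGGGG", FWD_CONCRETE, v3))
  names(reads) <- paste0("r", seq_along(reads))
  cs <- coverage_summary(demultiplex(reads, sheet, FWD, window = 30L))
  expect_equal(unname(cs$mean_coverage), 200)
  expect_equal(unname(cs$min_coverage), 100)
  expect_equal(unname(cs$max_coverage), 300)
  expect_equal(cs$n_unique_variants, 3)
  expect_equal(cs$n_singletons, 1)
  expect_equal(cs$singleton_fraction, 1 / 600)
})

test_that("per-amplicon demultiplexed counts match simulator provenance", {
  cfg <- sim_config(n_individuals = 4, coverage_mean = 80, coverage_sd = 10,
                    n_expressed_loci = 2, n_cluster1_loci = 2,
                    n_iia_loci = 1, pool_expressed = 6, pool_cluster1 = 6,
                    pool_iia = 3, tag_corruption_rate = 0)
  sim <- simulate_run(cfg, seed = 5)
  d <- demultiplex(sim$reads, sim$sheet, cfg$primer_iupac,
                   window = cfg$window)
  expect_equal(nrow(d$unassigned), 0)
  truth_counts <- table(sim$truth$read_info$amplicon)
  got <- table(d$assigned$amplicon)
  expect_equal(as.vector(got[names(truth_counts)]),
               as.vector(truth_counts))
})
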