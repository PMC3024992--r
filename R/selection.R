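# Cached codon machinery: per-codon synonymous/nonsynonymous site counts and
# the pathway-averaged substitution counts for every sense-codon pair.
.pkg_env <- new.env(parent = emptyenv())

.codon_table <- function() Biostrings::GENETIC_CODE

.sense_codons <- function() {
  gc <- .codon_table()
  names(gc)[gc != "*"]
}

# site counts for one codon: each position contributes syn/denom and
# nonsyn/denom, where denom counts the non-stop single-base mutants at that
# position (stop targets are excluded from the three-way split).
.site_counts_one <- function(codon) {
  gc <- .codon_table()
  aa <- gc[[codon]]
  if (aa == "*") stop("stop codon has no site counts: ", codon,
                      call. = FALSE)
  chars <- strsplit(codon, "")[[1]]
  s <- 0; n <- 0
  for (pos in 1:3) {
    syn <- 0L; nonstop <- 0L
    for (b in setdiff(DNA_BASES, chars[pos])) {
      mut <- chars; mut[pos] <- b
      maa <- gc[[paste(mut, collapse = "")]]
      if (maa == "*") next
      nonstop <- nonstop + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (nonstop > 0L) {
      s <- s + syn / nonstop
      n <- n + (nonstop - syn) / nonstop
    }
  }
  c(s = s, n = n)
}

# pathway-averaged (Nd, Sd) for a codon pair: all orderings of the differing
# positions are weighted equally; pathways passing through a stop codon are
# excluded (if every pathway is blocked, all pathways are used with steps
# into stops counted as nonsynonymous).
.pair_counts_one <- function(c1, c2) {
  if (c1 == c2) return(c(nd = 0, sd = 0))
  gc <- .codon_table()
  x <- strsplit(c1, "")[[1]]
  y <- strsplit(c2, "")[[1]]
  diffs <- which(x != y)
  perms <- if (length(diffs) == 1L) list(diffs) else {
    pp <- list()
    gen <- function(rem, acc) {
      if (length(rem) == 0L) { pp[[length(pp) + 1L]] <<- acc; return() }
      for (i in seq_along(rem)) gen(rem[-i], c(acc, rem[i]))
    }
    gen(diffs, integer(0))
    pp
  }
  score <- function(path, allow_stop) {
    cur <- x; nd <- 0; sd <- 0
    for (p in path) {
      aa1 <- gc[[paste(cur, collapse = "")]]
      cur[p] <- y[p]
      aa2 <- gc[[paste(cur, collapse = "")]]
      if (aa2 == "*" && !allow_stop) return(NULL)
      if (identical(aa1, aa2)) sd <- sd + 1 else nd <- nd + 1
    }
    c(nd, sd)
  }
  res <- Filter(Negate(is.null), lapply(perms, score, allow_stop = FALSE))
  if (length(res) == 0L)
    res <- lapply(perms, score, allow_stop = TRUE)
  avg <- Reduce(`+`, res) / length(res)
  c(nd = avg[1], sd = avg[2])
}

.ng_tables <- function() {
  if (!is.null(.pkg_env$ng)) return(.pkg_env$ng)
  sense <- .sense_codons()
  site <- t(vapply(sense, .site_counts_one, c(s = 0, n = 0)))
  k <- length(sense)
  nd <- matrix(0, k, k, dimnames = list(sense, sense))
  sd <- nd
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pc <- .pair_counts_one(sense[i], sense[j])
    nd[i, j] <- nd[j, i] <- pc["nd"]
    sd[i, j] <- sd[j, i] <- pc["sd"]
  }
  .pkg_env$ng <- list(site = site, nd = nd, sd = sd)
  .pkg_env$ng
}

#' Nei-Gojobori synonymous and nonsynonymous site counts of a codon
#'
#' Each codon position contributes the fraction of its single-base changes
#' that are synonymous to the synonymous site count, with stop-codon targets
#' excluded from the denominator.
#'
#' @param codon one of the 61 sense codons
#' @return named numeric vector \code{c(s, n)}
#' @export
ng_site_counts <- function(codon) {
  codon <- toupper(codon)
  tabs <- .ng_tables()
  if (!codon %in% rownames(tabs$site))
    stop("not a sense codon: ", codon, call. = FALSE)
  tabs$site[codon, ]
}

.split_codons <- function(seq) {
  nc <- nchar(seq)
  if (nc %% 3L != 0L)
    stop("sequence length must be divisible by 3", call. = FALSE)
  substring(toupper(seq), seq(1L, nc, 3L), seq(3L, nc, 3L))
}

# per-codon contribution profile of one sequence pair; rows = codon sites,
# columns nd, sd, n1, s1, n2, s2. Codon pairs containing a gap, ambiguity or
# stop codon are zeroed out and flagged in the "used" column.
.ng_pair_profile <- function(seq1, seq2) {
  tabs <- .ng_tables()
  c1 <- .split_codons(seq1)
  c2 <- .split_codons(seq2)
  if (length(c1) != length(c2))
    stop("sequences must have equal codon counts", call. = FALSE)
  sense <- rownames(tabs$site)
  ok <- c1 %in% sense & c2 %in% sense
  m <- matrix(0, length(c1), 7,
              dimnames = list(NULL,
                              c("nd", "sd", "n1", "s1", "n2", "s2", "used")))
  if (any(ok)) {
    i1 <- c1[ok]; i2 <- c2[ok]
    m[ok, "nd"] <- tabs$nd[cbind(i1, i2)]
    m[ok, "sd"] <- tabs$sd[cbind(i1, i2)]
    m[ok, "n1"] <- tabs$site[i1, "n"]
    m[ok, "s1"] <- tabs$site[i1, "s"]
    m[ok, "n2"] <- tabs$site[i2, "n"]
    m[ok, "s2"] <- tabs$site[i2, "s"]
    m[ok, "used"] <- 1
  }
  m
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' @param p proportion of differences per site
#' @return corrected distance; \code{NA} (saturation) when \code{p >= 3/4}
#' @export
jc_correct <- function(p) {
  out <- p
  out[] <- NA_real_
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' Pairwise Nei-Gojobori dN and dS
#'
#' Site counts are averaged between the two sequences; observed differences
#' are partitioned into synonymous and nonsynonymous by equal-weight
#' averaging over all minimal mutational pathways (pathways through stop
#' codons excluded). Codon pairs containing gaps, ambiguities or stop codons
#' are excluded pairwise. With \code{jc_correction}, proportions are
#' transformed by the Jukes-Cantor formula; saturated proportions
#' (p >= 3/4) yield \code{NA} with a \code{saturated} flag.
#'
#' @param seq1,seq2 aligned coding sequences (lengths divisible by 3)
#' @param jc_correction apply the Jukes-Cantor correction (default TRUE)
#' @return list with \code{Nd}, \code{Sd}, \code{n}, \code{s} (mean site
#'   counts), \code{pN}, \code{pS}, \code{dN}, \code{dS},
#'   \code{n_codons_used}, \code{saturated}
#' @export
pairwise_ng <- function(seq1, seq2, jc_correction = TRUE) {
  prof <- .ng_pair_profile(seq1, seq2)
  Nd <- sum(prof[, "nd"]); Sd <- sum(prof[, "sd"])
  n <- (sum(prof[, "n1"]) + sum(prof[, "n2"])) / 2
  s <- (sum(prof[, "s1"]) + sum(prof[, "s2"])) / 2
  pN <- if (n > 0) Nd / n else NA_real_
  pS <- if (s > 0) Sd / s else NA_real_
  dN <- if (jc_correction) jc_correct(pN) else pN
  dS <- if (jc_correction) jc_correct(pS) else pS
  list(Nd = Nd, Sd = Sd, n = n, s = s, pN = pN, pS = pS,
       dN = dN, dS = dS,
       n_codons_used = sum(prof[, "used"]),
       saturated = jc_correction && (is.na(dN) || is.na(dS)))
}

# dN and dS means over all sequence pairs for a matrix of codon resampling
# weights (rows = resamples, columns = codon sites); returns a 2-column
# matrix (dN, dS) with one row per resample.
.rates_for_weights <- function(mats, W, jc_correction) {
  Nd <- W %*% mats$nd
  Sd <- W %*% mats$sd
  n <- W %*% mats$n
  s <- W %*% mats$s
  pN <- ifelse(n > 0, Nd / n, NA_real_)
  pS <- ifelse(s > 0, Sd / s, NA_real_)
  if (jc_correction) {
    pN <- jc_correct(pN)
    pS <- jc_correct(pS)
  }
  cbind(dN = rowMeans(pN, na.rm = TRUE), dS = rowMeans(pS, na.rm = TRUE))
}

#' Mean dN and dS over all sequence pairs, with bootstrap standard errors
#'
#' Means of pairwise Nei-Gojobori rates over all unordered sequence pairs,
#' restricted to a codon partition (e.g. antigen-binding sites). Standard
#' errors come from resampling codon columns within the partition.
#'
#' @param seqs character vector (>= 2) of aligned coding sequences
#' @param partition integer vector of codon indices to use, or NULL for all
#' @param bootstrap_reps bootstrap replicates (default 1000)
#' @param seed RNG seed for the bootstrap
#' @param jc_correction apply the Jukes-Cantor correction (default TRUE)
#' @return object of class \code{rate_estimate}: list with \code{dN},
#'   \code{dS}, \code{se_dN}, \code{se_dS}, \code{n_pairs},
#'   \code{n_codons}, \code{bootstrap_reps}
#' @export
mean_rates <- function(seqs, partition = NULL, bootstrap_reps = 1000L,
                       seed = NULL, jc_correction = TRUE) {
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  n_cod <- nchar(seqs[1]) %/% 3L
  if (is.null(partition)) partition <- seq_len(n_cod)
  if (length(partition) == 0L)
    stop("partition contains no codons", call. = FALSE)
  if (any(partition < 1L | partition > n_cod))
    stop("partition indices out of range", call. = FALSE)
  prs <- combn(length(seqs), 2)
  profiles <- lapply(seq_len(ncol(prs)), function(k)
    .ng_pair_profile(seqs[prs[1, k]], seqs[prs[2, k]])[partition, ,
                                                       drop = FALSE])
  m <- length(partition)
  # per-pair per-codon contribution matrices (codon sites x pairs)
  mats <- list(
    nd = vapply(profiles, function(p) p[, "nd"], numeric(m)),
    sd = vapply(profiles, function(p) p[, "sd"], numeric(m)),
    n = vapply(profiles, function(p) (p[, "n1"] + p[, "n2"]) / 2,
               numeric(m)),
    s = vapply(profiles, function(p) (p[, "s1"] + p[, "s2"]) / 2,
               numeric(m)))
  if (m == 1L) mats <- lapply(mats, matrix, nrow = 1L)
  pt <- .rates_for_weights(mats, matrix(1, 1, m), jc_correction)
  se <- c(dN = 0, dS = 0)
  if (bootstrap_reps > 0L) {
    if (!is.null(seed)) set.seed(seed)
    W <- t(stats::rmultinom(bootstrap_reps, m, rep(1 / m, m)))
    boots <- .rates_for_weights(mats, W, jc_correction)
    se <- c(dN = sd(boots[, "dN"], na.rm = TRUE),
            dS = sd(boots[, "dS"], na.rm = TRUE))
  }
  structure(list(dN = unname(pt[1, "dN"]), dS = unname(pt[1, "dS"]),
                 se_dN = unname(se["dN"]), se_dS = unname(se["dS"]),
                 n_pairs = ncol(prs), n_codons = m,
                 bootstrap_reps = as.integer(bootstrap_reps)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("dN = %.3f (%.3f), dS = %.3f (%.3f)  [%d pairs, %d codons]\n",
              x$dN, x$se_dN, x$dS, x$se_dS, x$n_pairs, x$n_codons))
  invisible(x)
}

#' Z-test of selection
#'
#' Z = (dN - dS) / sqrt(SE_dN^2 + SE_dS^2), referred to the standard normal
#' distribution. The one-tailed "positive" alternative tests dN > dS.
#'
#' @param est a \code{\link{mean_rates}} result (or any list with dN, dS,
#'   se_dN, se_dS)
#' @param alternative "positive" (dN > dS, one-tailed; default) or
#'   "two.sided"
#' @return list with \code{Z}, \code{P} and a \code{degenerate} flag (both
#'   SEs zero while dN differs from dS)
#' @export
z_test <- function(est, alternative = c("positive", "two.sided")) {
  alternative <- match.arg(alternative)
  denom <- sqrt(est$se_dN^2 + est$se_dS^2)
  diff <- est$dN - est$dS
  if (denom == 0) {
    if (isTRUE(all.equal(est$dN, est$dS)))
      return(list(Z = 0, P = 1, degenerate = FALSE))
    return(list(Z = NA_real_, P = NA_real_, degenerate = TRUE))
  }
  Z <- diff / denom
  P <- if (alternative == "positive") pnorm(Z, lower.tail = FALSE)
       else 2 * pnorm(abs(Z), lower.tail = FALSE)
  list(Z = Z, P = P, degenerate = FALSE)
}

#' Read antigen-binding-site codon positions from a configuration file
#'
#' One codon index per line (1-based, relative to the analysed alignment);
#' blank lines and lines starting with '#' are ignored. The positions ship
#' as editable configuration because antigen-binding-site inference depends
#' on the structural reference used.
#'
#' @param path file path (default: the configuration bundled with the
#'   package, derived from the human class II contact-site list)
#' @return integer vector of codon indices
#' @export
read_abs_positions <- function(path = system.file("extdata",
                                                  "abs_positions.txt",
                                                  package = "mhctyper")) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  as.integer(lines)
}

#' Selection summary table over site partitions
#'
#' Mean dN and dS with bootstrap SEs and the Z-test, for all sites, the
#' antigen-binding-site partition, and its complement.
#'
#' @param seqs aligned coding sequences
#' @param abs_codons integer vector of ABS codon indices
#' @param bootstrap_reps bootstrap replicates (default 1000)
#' @param seed RNG seed
#' @param alternative passed to \code{\link{z_test}}
#' @return data.frame with rows All / ABS / non-ABS and columns dN, se_dN,
#'   dS, se_dS, Z, P
#' @export
selection_table <- function(seqs, abs_codons, bootstrap_reps = 1000L,
                            seed = NULL,
                            alternative = c("positive", "two.sided")) {
  alternative <- match.arg(alternative)
  n_cod <- nchar(seqs[1]) %/% 3L
  parts <- list(All = seq_len(n_cod),
                ABS = sort(intersect(abs_codons, seq_len(n_cod))),
                `non-ABS` = setdiff(seq_len(n_cod), abs_codons))
  rows <- lapply(names(parts), function(nm) {
    est <- mean_rates(seqs, parts[[nm]], bootstrap_reps, seed = seed)
    zt <- z_test(est, alternative)
    data.frame(sites = nm, dN = est$dN, se_dN = est$se_dN,
               dS = est$dS, se_dS = est$se_dS, Z = zt$Z, P = zt$P,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
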