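# Small programmatic fixtures shared across test files.

make_haploid_dataset <- function(seqs, isolates = NULL, locus = "COI") {
  n <- length(seqs)
  if (is.null(isolates)) isolates <- rep("iso1", n)
  ids <- sprintf("ind%02d", seq_len(n))
  aligned_dataset(
    locus, "haploid",
    tibble::tibble(individual_id = ids, allele_index = 0L,
                   isolate_id = isolates, seq = seqs),
    tibble::tibble(individual_id = ids, isolate_id = isolates)
  )
}

# seqs: character vector of length 2*n (alleles interleaved per individual)
make_diploid_dataset <- function(seqs, isolates = NULL, locus = "Tpm") {
  n <- length(seqs) / 2
  if (is.null(isolates)) isolates <- rep("iso1", n)
  ids <- sprintf("ind%02d", seq_len(n))
  aligned_dataset(
    locus, "diploid",
    tibble::tibble(individual_id = rep(ids, each = 2),
                   allele_index = rep(0:1, n),
                   isolate_id = rep(isolates, each = 2),
                   seq = seqs),
    tibble::tibble(individual_id = ids, isolate_id = isolates)
  )
}

# Mutate a base string at 1-based positions to the given residues.
mutate_seq <- function(base, positions, residues) {
  s <- strsplit(base, "")[[1]]
  s[positions] <- residues
  paste0(s, collapse = "")
}

base_seq <- function(len, base = "A") strrep(base, len)

# Independent O(n^2) oracle for pairwise difference counts (N missing,
# optionally skipping gap positions).
oracle_pair_diffs <- function(seqs, gap_is_state = TRUE) {
  mats <- strsplit(seqs, "")
  n <- length(seqs)
  out <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- mats[[i]]; b <- mats[[j]]
      ok <- a != "N" & b != "N"
      if (!gap_is_state) ok <- ok & a != "-" & b != "-"
      out <- c(out, sum(a[ok] != b[ok]))
    }
  }
  out
}

# sample one integer from [lo, hi] without the 1:n expansion trap
sample_between <- function(lo, hi) {
  if (lo >= hi) lo else sample(seq(lo, hi), 1)
}

# Enumeration oracle for the two-tailed Fisher exact test on a 2x2 table
# with fixed margins: sum of probabilities of all tables with probability
# <= that of the observed table.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  p_of <- function(a) {
    stats::dhyper(a, r1, r2, c1)
  }
  p_obs <- p_of(tab[1, 1])
  sum(vapply(lo:hi, p_of, numeric(1))[vapply(lo:hi, p_of, numeric(1)) <= p_obs + 1e-12])
}

# Independent brute-force oracle for the two-level variance decomposition
# (direct mean-squares algebra, no shared code with amova_core).
oracle_two_level <- function(d, pop) {
  n <- nrow(d)
  pops <- unique(pop)
  ss_tot <- sum(d[upper.tri(d)]) / n
  ss_w <- sum(vapply(pops, function(p) {
    idx <- which(pop == p)
    if (length(idx) < 2) return(0)
    sub <- d[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  ss_a <- ss_tot - ss_w
  df_a <- length(pops) - 1
  df_w <- n - length(pops)
  sizes <- table(pop)
  n_c <- (n - sum(sizes^2) / n) / df_a
  s2_w <- ss_w / df_w
  s2_a <- (ss_a / df_a - s2_w) / n_c
  c(a = s2_a, w = s2_w)
}

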