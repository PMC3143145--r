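#' Per-site nucleotide diversity (Nei's unbiased estimator)
#'
#' Average proportion of differing sites between two sequences drawn from the
#' sample, with the small-sample correction of Nei's classical estimator
#' (equivalent to averaging over all unordered sequence pairs). `N` residues
#' are treated as missing with pairwise deletion; gaps are removed column-wide
#' in `ignore_gap_columns` mode or scored as a fifth state otherwise.
#'
#' @param seqs Character vector of aligned residue strings (the allele
#'   sequences of one analysis unit), or an [aligned_dataset()] (all of its
#'   allele sequences are used).
#' @param gap_mode `"ignore_gap_columns"` or `"fifth_state"`.
#' @return A single non-negative number.
#' @export
nucleotide_diversity <- function(seqs, gap_mode = "ignore_gap_columns") {
  mat <- unit_matrix(seqs, gap_mode)
  n <- nrow(mat)
  if (n < 2) abort("nucleotide_diversity requires at least 2 sequences.")
  gap_is_state <- check_gap_mode(gap_mode) == "fifth_state"
  # with complete data the pairwise average equals the column-frequency
  # form (n/(n-1)) * mean_col(1 - sum p^2); missing data forces the O(n^2)
  # pairwise-deletion path
  has_missing <- any(mat == "N") || (!gap_is_state && any(mat == "-"))
  if (!has_missing && ncol(mat) > 0) {
    het <- vapply(seq_len(ncol(mat)), function(j) {
      p <- tabulate(factor(mat[, j], levels = unique(mat[, j]))) / n
      1 - sum(p^2)
    }, numeric(1))
    return(n / (n - 1) * mean(het))
  }
  tot <- 0
  npairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pd <- pair_differences(mat[i, ], mat[j, ], gap_is_state)
      if (pd$compared > 0) tot <- tot + pd$diff / pd$compared
      npairs <- npairs + 1L
    }
  }
  tot / npairs
}

unit_matrix <- function(seqs, gap_mode) {
  if (inherits(seqs, "aligned_dataset")) seqs <- seqs$sequences$seq
  mat <- seq_char_matrix(seqs)
  apply_gap_mode(mat, gap_mode)$mat
}

#' Haplotype count and diversity for one unit
#'
#' `Hd = n/(n-1) * (1 - sum p_i^2)` over the haplotype frequencies of the
#' unit's allele sequences.
#'
#' @param table A [collapse_haplotypes()] result.
#' @param unit_id An isolate id present in the table, or `NULL` for the whole
#'   dataset.
#' @return A list with `h` (number of distinct haplotypes) and `Hd`.
#' @export
haplotype_diversity <- function(table, unit_id = NULL) {
  stopifnot(inherits(table, "haplotype_table"))
  if (is.null(unit_id)) {
    counts <- table$haplotypes$count
  } else {
    sub <- table$per_isolate[table$per_isolate$isolate_id == unit_id, ]
    if (nrow(sub) == 0) abort(paste0("Unit not present in table: ", unit_id))
    counts <- sub$count
  }
  n <- sum(counts)
  if (n < 2) abort("haplotype_diversity requires a unit with >= 2 sequences.")
  p <- counts / n
  list(h = length(counts), Hd = n / (n - 1) * (1 - sum(p^2)))
}

#' Tajima's D
#'
#' Standard normalized difference between the mean-pairwise-difference and
#' segregating-sites estimators of the population mutation rate. Returns `NA`
#' (never 0) when there are no segregating sites.
#'
#' @inheritParams nucleotide_diversity
#' @return A single number, or `NA_real_` when `S = 0`.
#' @export
tajimas_d <- function(seqs, gap_mode = "ignore_gap_columns") {
  mat <- unit_matrix(seqs, gap_mode)
  n <- nrow(mat)
  if (n < 2) abort("tajimas_d requires at least 2 sequences.")
  gap_is_state <- check_gap_mode(gap_mode) == "fifth_state"
  S <- count_segregating(mat, gap_is_state)
  if (S == 0) return(NA_real_)
  d <- pairwise_diff_matrix(mat, gap_is_state)
  khat <- sum(d[upper.tri(d)]) / choose(n, 2)

  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Diversity summary per unit
#'
#' Computes, for each isolate (or another metadata grouping), the number of
#' allele sequences, segregating sites `S`, haplotype count `h`, haplotype
#' diversity `Hd`, per-site nucleotide diversity `pi` and Tajima's D.
#'
#' @param dataset An [aligned_dataset()].
#' @param by Metadata column defining the units (default `"isolate_id"`).
#' @inheritParams nucleotide_diversity
#' @return A tibble with one row per unit.
#' @export
diversity_summary <- function(dataset, by = "isolate_id",
                              gap_mode = "ignore_gap_columns") {
  stopifnot(inherits(dataset, "aligned_dataset"))
  seqs <- dataset$sequences
  if (by != "isolate_id") {
    key <- dataset$samples[[by]]
    names(key) <- dataset$samples$individual_id
    seqs$unit <- unname(key[seqs$individual_id])
  } else {
    seqs$unit <- seqs$isolate_id
  }
  gap_is_state <- check_gap_mode(gap_mode) == "fifth_state"

  purrr::map_dfr(split(seqs, seqs$unit), function(s) {
    mat <- unit_matrix(s$seq, gap_mode)
    n <- nrow(mat)
    S <- count_segregating(mat, gap_is_state)
    norm <- collapse_char_matrix(mat)
    counts <- as.integer(table(norm))
    p <- counts / n
    tibble::tibble(
      unit_id = s$unit[1],
      locus_name = dataset$locus_name,
      n_alleles = n,
      S = as.integer(S),
      h = length(counts),
      Hd = if (n >= 2) n / (n - 1) * (1 - sum(p^2)) else NA_real_,
      pi = if (n >= 2) nucleotide_diversity(s$seq, gap_mode) else NA_real_,
      tajimas_D = if (n >= 2) tajimas_d(s$seq, gap_mode) else NA_real_
    )
  })
}

#' Mito/nuclear diversity ratio and secondary-contact flag
#'
#' The ratio of mitochondrial to nuclear per-site nucleotide diversity.
#' Because the mitochondrial genome has roughly a third (haplodiploids) or a
#' quarter (diplodiploids) of the nuclear effective size, this ratio stays
#' well below 0.5 in equilibrated populations; a value above 0.5 flags a unit
#' as a candidate for very recent secondary contact between divergent
#' mitochondrial lineages.
#'
#' @param mito,nuc Tibbles as returned by [diversity_summary()] for the
#'   mitochondrial and nuclear locus (matched on `unit_id`).
#' @param threshold Flagging threshold on the ratio (default 0.5).
#' @return A tibble with `unit_id`, `ratio` and `secondary_contact_flag`.
#' @export
pi_ratio_flag <- function(mito, nuc, threshold = 0.5) {
  m <- dplyr::select(tibble::as_tibble(mito), "unit_id", pi_mito = "pi")
  n <- dplyr::select(tibble::as_tibble(nuc), "unit_id", pi_nuc = "pi")
  if (!setequal(m$unit_id, n$unit_id)) {
    abort("mito and nuc summaries must cover the same units.")
  }
  dplyr::inner_join(m, n, by = "unit_id") |>
    dplyr::mutate(
      ratio = ifelse(.data$pi_nuc > 0, .data$pi_mito / .data$pi_nuc, NA_real_),
      secondary_contact_flag = !is.na(.data$ratio) & .data$ratio > threshold
    ) |>
    dplyr::select("unit_id", "ratio", "secondary_contact_flag")
}
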