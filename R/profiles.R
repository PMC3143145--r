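#' Segregating sites of the majority star-like haplotype group
#'
#' Within one isolate, the most frequent mitochondrial haplotype is taken as
#' the star center; the group is the center plus all haplotypes at most two
#' mutational steps away. When the group accounts for strictly more than
#' `min_freq` of the isolate's sequences, `S_maj` is the number of
#' segregating sites among the group's member haplotypes (0 for a single
#' haplotype); otherwise `NA` (no majority star group). A recent founder
#' expansion leaves a small star with low `S_maj`.
#'
#' @param table A [collapse_haplotypes()] result for the mitochondrial locus.
#' @param unit_id Isolate id.
#' @param min_freq Frequency threshold for the star group (strict, default
#'   0.6), on sequence abundance.
#' @param max_steps Maximum mutational distance from the center (default 2).
#' @return Integer count of segregating sites, or `NA_integer_`.
#' @export
s_maj <- function(table, unit_id, min_freq = 0.6, max_steps = 2) {
  stopifnot(inherits(table, "haplotype_table"))
  sub <- table$per_isolate[table$per_isolate$isolate_id == unit_id, ]
  if (nrow(sub) == 0) abort(paste0("Empty or unknown unit: ", unit_id))
  seqs <- table$haplotypes$seq[match(sub$haplotype_id,
                                     table$haplotypes$haplotype_id)]
  counts <- sub$count
  gap_is_state <- table$gap_mode == "fifth_state"

  # center: most frequent haplotype; ties broken by sequence string so the
  # result is invariant to haplotype relabeling
  best <- which(counts == max(counts))
  center <- best[order(seqs[best])][1]
  mat <- seq_char_matrix(seqs)
  dist_to_center <- vapply(seq_len(nrow(mat)), function(i) {
    pair_differences(mat[i, ], mat[center, ], gap_is_state)$diff
  }, numeric(1))
  grp <- which(dist_to_center <= max_steps)
  if (sum(counts[grp]) / sum(counts) <= min_freq) return(NA_integer_)
  as.integer(count_segregating(mat[grp, , drop = FALSE], gap_is_state))
}

#' Number of first-level nuclear clusters represented in an isolate
#'
#' Counts the clusters to which at least one individual of the isolate has
#' inferred ancestry at or above `presence_threshold` (default 0.4, which
#' captures both near-homozygous members and the components of half-and-half
#' inter-cluster heterozygotes).
#'
#' @param run A first-level nuclear [run_admixture()] result.
#' @param isolate_id Isolate to score.
#' @param presence_threshold Ancestry presence cutoff.
#' @return Integer count (>= 1 for a non-empty isolate).
#' @export
k_t1 <- function(run, isolate_id, presence_threshold = 0.4) {
  stopifnot(inherits(run, "cluster_run"))
  rows <- which(run$isolate_id == isolate_id)
  if (length(rows) == 0) abort(paste0("Isolate absent from run: ", isolate_id))
  sum(apply(run$Q[rows, , drop = FALSE] >= presence_threshold, 2, any))
}

#' Genetic-profile classification of isolates
#'
#' Rule cascade over the per-isolate summary statistics (mito/nuclear
#' diversity ratio, the two nucleotide diversities, the number of first-level
#' nuclear clusters `K_T1` and the signs of Tajima's D) that sorts isolates
#' into six demographic-scenario profiles:
#'
#' * `GP1` - two-lineage ancient hybrid in a large stable population: high
#'   nuclear diversity (`pi_nuc > 0.0150`), low mito diversity, `K_T1 = 2`.
#' * `GP2` - three-lineage mixture: `K_T1 = 3` with a low mito/nuclear
#'   diversity ratio (below 0.5) and low mito diversity.
#' * `GP3` - two-lineage mixture after founder bottleneck and expansion:
#'   `0.0015 < pi_nuc < 0.0120`, `K_T1 = 2`, both Tajima's D negative.
#' * `GP4` - mito diversity exceeding nuclear (`ratio > 1`), `K_T1 = 2`:
#'   strong founder effect followed by mitochondrial secondary contact.
#' * `GP5` - elevated ratio (`0.5 < ratio <= 1`) with `K_T1 = 3`: recent
#'   secondary contact layered on a three-lineage background.
#' * `GP6` - a single nuclear cluster (`K_T1 = 1`): long-isolated lineage.
#'
#' The point diversities printed for single-isolate profiles are treated as
#' observed exemplars, not thresholds: `GP4` is keyed on `ratio > 1` and
#' `GP6` on `K_T1 = 1`. Isolates matching several profiles return the
#' ambiguous set; isolates matching none return `NA`. The full criterion
#' trace is attached so every decision is auditable.
#'
#' @param summary A data frame with columns `unit_id`, `ratio`, `pi_mito`,
#'   `pi_nuc`, `k_t1`, `d_mito`, `d_nuc` (one row per isolate), e.g. built by
#'   [isolate_summary()].
#' @return A tibble with `unit_id`, `gp` (e.g. `"GP3"`, `"GP1|GP2"` for an
#'   ambiguous set, or `NA`), `ambiguous`, and a `trace` list-column of
#'   per-criterion records.
#' @export
classify_gp <- function(summary) {
  summary <- tibble::as_tibble(summary)
  required <- c("unit_id", "ratio", "pi_mito", "pi_nuc", "k_t1", "d_mito",
                "d_nuc")
  miss <- setdiff(required, names(summary))
  if (length(miss) > 0) {
    abort(paste0("Missing statistic column(s): ", paste(miss, collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(summary)), function(i) {
    row <- summary[i, ]
    gt <- function(x, thr) !is.na(x) & x > thr
    lt <- function(x, thr) !is.na(x) & x < thr
    rules <- list(
      GP6 = c(k_t1_is_1 = isTRUE(row$k_t1 == 1)),
      GP4 = c(k_t1_is_2 = isTRUE(row$k_t1 == 2),
              ratio_gt_1 = gt(row$ratio, 1.0)),
      GP5 = c(k_t1_is_3 = isTRUE(row$k_t1 == 3),
              ratio_gt_0.5 = gt(row$ratio, 0.5),
              ratio_le_1 = !is.na(row$ratio) & row$ratio <= 1.0),
      GP1 = c(k_t1_is_2 = isTRUE(row$k_t1 == 2),
              ratio_lt_0.5 = lt(row$ratio, 0.5),
              pi_mito_lt_0.005 = lt(row$pi_mito, 0.005),
              pi_nuc_gt_0.0150 = gt(row$pi_nuc, 0.0150)),
      # the printed pi_nuc range for this row is not discriminating within
      # the table (no other profile has K_T1 = 3 with a low ratio), so the
      # profile keys on the joint criteria alone
      GP2 = c(k_t1_is_3 = isTRUE(row$k_t1 == 3),
              ratio_lt_0.5 = lt(row$ratio, 0.5),
              pi_mito_lt_0.005 = lt(row$pi_mito, 0.005)),
      GP3 = c(k_t1_is_2 = isTRUE(row$k_t1 == 2),
              ratio_lt_0.5 = lt(row$ratio, 0.5),
              pi_mito_lt_0.005 = lt(row$pi_mito, 0.005),
              pi_nuc_gt_0.0015 = gt(row$pi_nuc, 0.0015),
              pi_nuc_lt_0.0120 = lt(row$pi_nuc, 0.0120),
              d_mito_neg = lt(row$d_mito, 0),
              d_nuc_neg = lt(row$d_nuc, 0))
    )
    matched <- names(rules)[vapply(rules, all, logical(1))]
    d_pattern <- if (is.na(row$d_mito) || is.na(row$d_nuc)) {
      "incomplete"
    } else if (row$d_mito < 0 && row$d_nuc < 0) {
      "both_negative"
    } else if (row$d_mito > 0 && row$d_nuc > 0) {
      "both_positive"
    } else {
      "diverse"
    }
    trace <- purrr::imap(rules, function(crit, gp) {
      tibble::tibble(profile = gp, criterion = names(crit), pass = unname(crit))
    })
    trace <- dplyr::bind_rows(trace)
    trace <- dplyr::bind_rows(
      trace,
      tibble::tibble(profile = "all", criterion = paste0("d_pattern_", d_pattern),
                     pass = NA)
    )
    tibble::tibble(
      unit_id = row$unit_id,
      gp = if (length(matched) == 0) NA_character_ else paste(matched, collapse = "|"),
      ambiguous = length(matched) > 1,
      trace = list(trace)
    )
  })
}

#' Per-isolate synthesis of diversity, demography and clustering statistics
#'
#' Assembles, for every isolate, the per-locus diversity summaries, the
#' mito/nuclear diversity ratio, the mismatch-shape labels, `S_maj` on the
#' mitochondrial haplotypes, `K_T1` from a first-level nuclear clustering
#' run, the isolate's majority mitochondrial cluster, and metadata context.
#'
#' @param mito,nuclear [aligned_dataset()] objects (haploid and diploid).
#' @param nuclear_run A first-level nuclear [run_admixture()] result.
#' @param mito_run Optional first-level mitochondrial `cluster_run` used for
#'   the majority-lineage label.
#' @param gap_mode Gap handling mode.
#' @param mismatch_bootstrap,seed Passed to [mismatch_gof()] (`0` skips the
#'   bootstrap P-values).
#' @return A tibble with one row per isolate.
#' @export
isolate_summary <- function(mito, nuclear, nuclear_run, mito_run = NULL,
                            gap_mode = "ignore_gap_columns",
                            mismatch_bootstrap = 0, seed = 1) {
  div_m <- diversity_summary(mito, gap_mode = gap_mode)
  div_n <- diversity_summary(nuclear, gap_mode = gap_mode)
  ratio <- pi_ratio_flag(div_m, div_n)
  hap_m <- collapse_haplotypes(mito, gap_mode)
  hap_n <- collapse_haplotypes(nuclear, gap_mode)
  isolates <- sort(intersect(div_m$unit_id, div_n$unit_id))

  purrr::map_dfr(isolates, function(iso) {
    dm <- div_m[div_m$unit_id == iso, ]
    dn <- div_n[div_n$unit_id == iso, ]
    rr <- ratio[ratio$unit_id == iso, ]
    prof <- function(dataset, hap) {
      sel <- dataset$sequences$isolate_id == iso
      if (sum(sel) < 2) return(list(profile = NA_character_, fit = NULL))
      dist <- mismatch_distribution(dataset$sequences$seq[sel], gap_mode,
                                    unit_id = iso)
      lab <- classify_mismatch_profile(dist, hap, iso)
      fit <- NULL
      if (mismatch_bootstrap > 0 && lab %in% c("uni", "bi")) {
        fit <- suppressWarnings(fit_sudden_expansion(dist))
        fit <- mismatch_gof(dist, fit, mismatch_bootstrap, seed)
      }
      list(profile = lab, fit = fit)
    }
    pm <- prof(mito, hap_m)
    pn <- prof(nuclear, hap_n)
    maj_lineage <- NA_character_
    if (!is.null(mito_run)) {
      rows <- which(mito_run$isolate_id == iso)
      if (length(rows) > 0) {
        maj <- max.col(mito_run$Q[rows, , drop = FALSE], ties.method = "first")
        maj_lineage <- paste0("cluster",
                              names(sort(table(maj), decreasing = TRUE))[1])
      }
    }
    hab <- mito$samples$habitat[match(iso, mito$samples$isolate_id)]
    tibble::tibble(
      unit_id = iso,
      n_individuals = sum(mito$sequences$isolate_id == iso),
      habitat = hab,
      pi_mito = dm$pi, pi_nuc = dn$pi,
      ratio = rr$ratio,
      secondary_contact_flag = rr$secondary_contact_flag,
      S_mito = dm$S, S_nuc = dn$S,
      h_mito = dm$h, h_nuc = dn$h,
      Hd_mito = dm$Hd, Hd_nuc = dn$Hd,
      d_mito = dm$tajimas_D, d_nuc = dn$tajimas_D,
      s_maj = s_maj(hap_m, iso),
      k_t1 = k_t1(nuclear_run, iso),
      majority_lineage = maj_lineage,
      mismatch_mito = pm$profile,
      mismatch_nuc = pn$profile,
      p_ssd_mito = if (!is.null(pm$fit)) pm$fit$p_ssd else NA_real_,
      p_ssd_nuc = if (!is.null(pn$fit)) pn$fit$p_ssd else NA_real_
    )
  })
}
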