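#' Run the full mito-nuclear analysis pipeline
#'
#' Orchestrates the complete analysis on a pair of alignments: haplotype
#' collapsing under both gap modes, LD screening with the filtered-variant
#' robustness check, hierarchical admixture clustering of the mitochondrial,
#' nuclear and combined matrices, inter-cluster heterozygote flagging,
#' F-statistics (per-grouping AMOVA, pairwise Phi_ST, per-isolate F_IS),
#' mismatch-distribution fits, and the per-isolate genetic-profile
#' classification. Results are returned as a list and, when `out_dir` is
#' given, written as TSV/JSON files together with a log of seeds and
#' settings.
#'
#' @param mito,nuclear [aligned_dataset()] objects (or paths may be given
#'   via `config`).
#' @param config Named list of settings; any subset of: `gap_mode`,
#'   `ld` (`threshold_r`, `alpha`), `clustering` (`k_range`, `replicates`,
#'   `burn_in`, `reps`, `thresholds`), `fstats` (`n_perm`, `groupings`),
#'   `mismatch` (`bootstrap`), `profile` (classifier thresholds), `seed`.
#'   Defaults are desk-scale and documented in the methods vignette.
#' @param out_dir Optional output directory.
#' @return A list (class `pipeline_result`) with elements `haplotypes`,
#'   `ld`, `clustering`, `concordance`, `heterozygotes`, `fstats`,
#'   `summary`, `profiles`, `config`.
#' @export
run_pipeline <- function(mito, nuclear, config = list(), out_dir = NULL) {
  stopifnot(inherits(mito, "aligned_dataset"),
            inherits(nuclear, "aligned_dataset"))
  cfg <- utils::modifyList(list(
    gap_mode = "fifth_state",
    ld = list(threshold_r = 0.5, alpha = 0.05),
    clustering = list(k_range = 1:4, replicates = 3, burn_in = 2000,
                      reps = 8000,
                      thresholds = c(mito = 0.8, nuclear = 0.6,
                                     combined = 0.7)),
    fstats = list(n_perm = 1000, groupings = "habitat"),
    mismatch = list(bootstrap = 100),
    # diversity statistics follow the "gaps unconsidered" convention so
    # encoded indel series never inflate pi
    summary_gap_mode = "ignore_gap_columns",
    seed = 1
  ), config)
  empty_iso <- setdiff(mito$samples$isolate_id,
                       mito$sequences$isolate_id)
  if (length(empty_iso) > 0) {
    abort(paste0("Isolate(s) without sequences: ",
                 paste(empty_iso, collapse = ", ")))
  }
  seed <- cfg$seed
  res <- list(config = cfg)

  # 1. haplotypes, both gap modes
  res$haplotypes <- list(
    mito = lapply(c(ignore_gap_columns = "ignore_gap_columns",
                    fifth_state = "fifth_state"),
                  function(gm) collapse_haplotypes(mito, gm)),
    nuclear = lapply(c(ignore_gap_columns = "ignore_gap_columns",
                       fifth_state = "fifth_state"),
                     function(gm) collapse_haplotypes(nuclear, gm))
  )

  # 2. LD screen and filtered variant
  ld_m <- pairwise_ld(mito, cfg$gap_mode, cfg$ld$alpha)
  ld_n <- pairwise_ld(nuclear, cfg$gap_mode, cfg$ld$alpha)
  filt_m <- exclude_linked_sites(ld_m, cfg$ld$threshold_r, cfg$ld$alpha)
  filt_n <- exclude_linked_sites(ld_n, cfg$ld$threshold_r, cfg$ld$alpha)
  res$ld <- list(mito = list(pairs = ld_m, filter = filt_m),
                 nuclear = list(pairs = ld_n, filter = filt_n))

  # 3. clustering hierarchy per matrix + full-vs-filtered concordance
  cl <- cfg$clustering
  mats <- list(
    mito = build_genotype_matrix(mito = mito, gap_mode = cfg$gap_mode),
    nuclear = build_genotype_matrix(nuclear = nuclear,
                                    gap_mode = cfg$gap_mode),
    combined = build_genotype_matrix(mito = mito, nuclear = nuclear,
                                     gap_mode = cfg$gap_mode)
  )
  res$clustering <- purrr::imap(mats, function(gm, nm) {
    hierarchical_analysis(gm, k_range = cl$k_range,
                          replicates = cl$replicates, burn_in = cl$burn_in,
                          reps = cl$reps, seed = seed,
                          threshold = cl$thresholds[[nm]])
  })

  filt_mats <- list(
    mito = build_genotype_matrix(mito = mito, gap_mode = cfg$gap_mode,
                                 site_filter = filt_m),
    nuclear = build_genotype_matrix(nuclear = nuclear,
                                    gap_mode = cfg$gap_mode,
                                    site_filter = filt_n)
  )
  res$concordance <- purrr::imap(filt_mats, function(gm, nm) {
    if (ncol(gm$geno) == 0) return(NULL)
    sel_full <- res$clustering[[nm]]$selection
    run_full <- res$clustering[[nm]]$run
    sel_filt <- select_k(gm, cl$k_range, cl$replicates, cl$burn_in, cl$reps,
                         seed = seed + 7)
    compare_clusterings(
      list(selection = sel_full, run = run_full),
      list(selection = sel_filt,
           run = sel_filt$runs[[as.character(sel_filt$chosen_K)]])
    )
  })

  # 4. inter-cluster heterozygotes on the first-level nuclear run
  nuc_run <- res$clustering$nuclear$run
  res$heterozygotes <- flag_intercluster_heterozygotes(nuc_run)

  # 5. F-statistics
  fs <- cfg$fstats
  res$fstats <- list(
    amova = purrr::map(setNames(fs$groupings, fs$groupings), function(g) {
      list(
        mito = amova(mito, grouping = g, gap_mode = cfg$gap_mode,
                     n_perm = fs$n_perm, seed = seed + 11),
        nuclear = amova(nuclear, grouping = g, gap_mode = cfg$gap_mode,
                        n_perm = fs$n_perm, seed = seed + 12)
      )
    }),
    pairwise = list(
      mito = pairwise_phist(mito, gap_mode = cfg$gap_mode,
                            n_perm = fs$n_perm, seed = seed + 13,
                            unit = "individual"),
      nuclear = pairwise_phist(nuclear, gap_mode = cfg$gap_mode,
                               n_perm = fs$n_perm, seed = seed + 14,
                               unit = "genotype")
    ),
    fis = fis(nuclear, gap_mode = cfg$gap_mode, n_perm = fs$n_perm,
              seed = seed + 15)
  )

  # 6. per-isolate synthesis and genetic profiles
  res$summary <- isolate_summary(mito, nuclear, nuc_run,
                                 mito_run = res$clustering$mito$run,
                                 gap_mode = cfg$summary_gap_mode,
                                 mismatch_bootstrap = cfg$mismatch$bootstrap,
                                 seed = seed + 21)
  res$profiles <- classify_gp(res$summary)

  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(res$ld$mito$pairs, "ld_mito.tsv")
  tsv(res$ld$nuclear$pairs, "ld_nuclear.tsv")
  tsv(res$heterozygotes, "intercluster_heterozygotes.tsv")
  tsv(res$fstats$pairwise$mito, "phist_mito.tsv")
  tsv(res$fstats$pairwise$nuclear, "phist_nuclear.tsv")
  tsv(res$fstats$fis, "fis_nuclear.tsv")
  tsv(res$summary, "isolate_summary.tsv")
  tsv(dplyr::select(res$profiles, -"trace"), "genetic_profiles.tsv")
  report <- list(
    config = res$config[setdiff(names(res$config), "seed")],
    seed = res$config$seed,
    chosen_K = purrr::map_int(res$clustering, function(x) x$selection$chosen_K),
    concordance = purrr::map(res$concordance, function(x) {
      if (is.null(x)) NULL else x[c("k_equal", "agreement")]
    }),
    n_heterozygotes = sum(res$heterozygotes$flagged),
    profiles = setNames(res$profiles$gp, res$profiles$unit_id)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  chosen K:",
      paste(names(x$clustering),
            purrr::map_int(x$clustering, function(z) z$selection$chosen_K),
            sep = "=", collapse = ", "), "\n")
  cat("  inter-cluster heterozygotes:", sum(x$heterozygotes$flagged), "\n")
  cat("  profiles:",
      paste(x$profiles$unit_id, x$profiles$gp, sep = ":", collapse = ", "),
      "\n")
  invisible(x)
}
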