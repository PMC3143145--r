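test_that("genotype matrices encode sites, filters and combined blocks", {
  base <- base_seq(20)
  mito_seqs <- c(rep(base, 4),
                 rep(mutate_seq(base, c(3, 11), c("T", "G")), 4))
  mito <- make_haploid_dataset(mito_seqs, locus = "COI")
  gm <- build_genotype_matrix(mito = mito)
  expect_equal(dim(gm$geno), c(8, 2))
  expect_equal(nrow(gm$loci), 2)
  expect_equal(gm$provenance, "mito_sites")

  # site filter drops excluded columns
  pairs <- pairwise_ld(mito)
  filt <- exclude_linked_sites(pairs, 0.5, 0.05)
  expect_setequal(filt$excluded_sites, c(3, 11))
  gm_f <- build_genotype_matrix(mito = mito, site_filter = filt)
  expect_equal(nrow(gm_f$loci), 0)

  # combined matrix: mito S + nuclear S (+ indel loci when enabled)
  nb <- base_seq(60)
  nuc_seqs <- rep(c(nb, mutate_seq(nb, c(7, 20, 33), c("T", "C", "G"))), 8)
  nuc <- make_diploid_dataset(nuc_seqs, locus = "Tpm")
  both <- build_genotype_matrix(mito = mito, nuclear = nuc)
  expect_equal(nrow(both$loci), 2 + 3)
  expect_equal(both$provenance, "combined")
  expect_equal(sum(both$loci$ploidy == 2), 3)

  withi <- build_genotype_matrix(mito = mito, nuclear = nuc,
                                 include_indels = TRUE,
                                 indel_intervals = list(c(40, 47), c(50, 55)))
  expect_equal(nrow(withi$loci), 2 + 3 + 2)

  # disjoint individual sets cannot combine
  nuc2 <- nuc
  nuc2$sequences$individual_id <- paste0("x", nuc2$sequences$individual_id)
  nuc2$samples$individual_id <- paste0("x", nuc2$samples$individual_id)
  expect_error(build_genotype_matrix(mito = mito, nuclear = nuc2),
               "disjoint")
})

test_that("the sampler recovers planted population structure", {
  sc <- sim_island_scenario(n_pop = 2, n_per = 15, t_split = 8000)
  s <- simulate_scenario(sc, seed = 5)
  gm <- build_genotype_matrix(nuclear = s$nuclear, gap_mode = "fifth_state")
  run <- run_admixture(gm, K = 2, burn_in = 800, reps = 3000, seed = 3)

  expect_true(all(abs(rowSums(run$Q) - 1) < 1e-9))
  expect_true(is.finite(run$lnPD))
  expect_gt(run$alpha, 0)

  truth <- s$truth$individuals
  maj <- max.col(run$Q)
  tab <- table(truth$deme[match(rownames(run$Q), truth$individual_id)], maj)
  agreement <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(agreement, 0.95)
  maj_q <- run$Q[cbind(seq_len(nrow(run$Q)), maj)]
  expect_gte(mean(maj_q > 0.9), 0.9)

  # K = 1 forces Q = 1 exactly
  run1 <- run_admixture(gm, K = 1, burn_in = 50, reps = 100, seed = 1)
  expect_true(all(run1$Q == 1))

  expect_error(run_admixture(gm, K = 0), "K must be")
  expect_error(run_admixture(gm, K = 99), "cannot exceed")
})

test_that("posterior ancestry matches enumeration on a two-individual toy", {
  # 2 haploid individuals, 1 biallelic locus, K = 2, lambda = 1, fixed
  # alpha: the marginal P(first allele copy assigned cluster 1) is 1/2 by
  # symmetry; the sampler must reproduce it within Monte-Carlo error,
  # and opposite-allele individuals must get anti-correlated ancestry
  base <- base_seq(6)
  ds <- make_haploid_dataset(c(base, mutate_seq(base, 2, "T")))
  gm <- build_genotype_matrix(mito = ds)
  run <- run_admixture(gm, K = 2, burn_in = 2000, reps = 20000, seed = 9)
  # symmetry: each individual's expected ancestry is (1/2, 1/2)
  expect_equal(unname(run$Q[1, 1]), 0.5, tolerance = 0.05)
  expect_equal(unname(run$Q[2, 1]), 0.5, tolerance = 0.05)
})

test_that("deltaK selects K by the second-difference rule", {
  # closed-form check of the deltaK computation on a constructed table
  # mean lnPD (-100, -50, -48, -47) for K = 1..4 with sd(L(2)) = 2:
  # deltaK(2) = |(-48) - 2(-50) + (-100)| / 2 = 24
  lnpd <- c(-100, -50, -48, -47)
  s2 <- 2
  dk2 <- abs(lnpd[3] - 2 * lnpd[2] + lnpd[1]) / s2
  expect_equal(dk2, 24)

  sc <- sim_island_scenario(n_pop = 3, n_per = 12, t_split = 10000)
  s <- simulate_scenario(sc, seed = 17)
  gm <- build_genotype_matrix(nuclear = s$nuclear, gap_mode = "fifth_state")
  sel <- select_k(gm, 1:5, replicates = 3, burn_in = 600, reps = 2000,
                  seed = 2)
  expect_equal(sel$chosen_K, 3)
  expect_false(sel$unreliable)

  expect_error(select_k(gm, 1:2), "4 consecutive")
  expect_error(select_k(gm, 1:4, replicates = 2), "replicates")
})

test_that("single panmictic population yields no dominant deltaK peak", {
  sc <- sim_island_scenario(n_pop = 2, n_per = 15, t_split = 1)
  s <- simulate_scenario(sc, seed = 23)
  gm <- build_genotype_matrix(nuclear = s$nuclear, gap_mode = "fifth_state")
  sel <- select_k(gm, 1:4, replicates = 3, burn_in = 500, reps = 1500,
                  seed = 4)
  expect_true(sel$unreliable)
  expect_match(sel$note, "unreliable")
})

test_that("inter-cluster heterozygote band flags F1s and spares parentals", {
  mk_run <- function(Q) {
    rownames(Q) <- sprintf("i%02d", seq_len(nrow(Q)))
    structure(list(K = ncol(Q), Q = Q,
                   isolate_id = rep("x", nrow(Q)),
                   individuals = rownames(Q), has_diploid = TRUE),
              class = "cluster_run")
  }
  Q <- rbind(c(0.5, 0.5, 0), c(0.9, 0.1, 0), c(0.45, 0.1, 0.45))
  fl <- flag_intercluster_heterozygotes(mk_run(Q))
  expect_equal(fl$flagged, c(TRUE, FALSE, TRUE))
  expect_equal(fl$cluster_a[1], 1)
  expect_equal(fl$cluster_b[1], 2)
  expect_equal(fl$cluster_a[3], 1)
  expect_equal(fl$cluster_b[3], 3)
})

test_that("hierarchical analysis recovers nested structure and stops at K=1", {
  # two super-groups, each of two subpopulations
  sc <- sim_scenario(
    "haplodiploid",
    demes = tibble::tibble(id = c("A", "B", "C", "D"), n_f = 500, n_m = 500),
    events = list(ev_split(8000, "A", "B"), ev_split(8001, "C", "D"),
                  ev_split(30000, "A", "C")),
    samples = tibble::tibble(deme = c("A", "B", "C", "D"), n = 12,
                             isolate = c("a", "b", "c", "d")),
    nuclear = list(length = 729, mu = 1e-6, n_indel_series = 0)
  )
  s <- simulate_scenario(sc, seed = 31)
  gm <- build_genotype_matrix(nuclear = s$nuclear, gap_mode = "fifth_state")
  hier <- hierarchical_analysis(gm, k_range = 1:4, replicates = 3,
                                burn_in = 500, reps = 1500, seed = 6,
                                threshold = 0.6, min_n = 14, max_depth = 2)
  expect_equal(hier$selection$chosen_K, 2)
  expect_equal(length(hier$children), 2)
  top_assign <- hier$assignments
  truth <- s$truth$individuals
  super <- ifelse(truth$deme %in% c("A", "B"), "AB", "CD")
  tab <- table(super[match(top_assign$individual_id, truth$individual_id)],
               top_assign$cluster)
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.95)
  for (child in hier$children) {
    expect_true(all(child$individuals %in% hier$individuals))
    expect_equal(child$selection$chosen_K, 2)
  }
})

test_that("homogeneous-isolate grouping assigns whole isolates by ancestry", {
  sc <- sim_island_scenario(n_pop = 2, n_per = 12, t_split = 10000)
  s <- simulate_scenario(sc, seed = 47)
  gm <- build_genotype_matrix(nuclear = s$nuclear, gap_mode = "fifth_state")
  hier <- hierarchical_analysis(gm, k_range = 1:4, replicates = 3,
                                burn_in = 400, reps = 1200, seed = 9,
                                rule = "homogeneous_isolates",
                                homogeneity = 0.9, min_n = 30, max_depth = 1)
  a <- hier$assignments
  # both isolates are internally homogeneous, so every individual is
  # assigned, isolate-wise, and the two isolates land in different clusters
  expect_true(all(!is.na(a$cluster)))
  iso <- s$truth$individuals$isolate_id[match(a$individual_id,
                                              s$truth$individuals$individual_id)]
  expect_equal(length(unique(a$cluster[iso == "isoA"])), 1)
  expect_equal(length(unique(a$cluster[iso == "isoB"])), 1)
  expect_false(a$cluster[iso == "isoA"][1] == a$cluster[iso == "isoB"][1])
})
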