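test_that("Phi_ST matches a brute-force AMOVA oracle and its edge cases", {
  # fixed difference, no within variation: Phi_ST = 1
  fixed <- make_haploid_dataset(
    c(rep("AAAAAAAAAA", 5), rep("TTTTTTTTTT", 5)),
    isolates = rep(c("A", "B"), each = 5))
  res <- pairwise_phist(fixed, n_perm = 99, seed = 1, unit = "individual")
  expect_equal(res$phi_st, 1)
  expect_lt(res$p_value, 0.05)

  # identical allele-frequency units: Phi_ST ~ 0
  base <- base_seq(20)
  alt <- mutate_seq(base, 7, "T")
  same <- make_haploid_dataset(
    rep(c(base, alt), 10),
    isolates = rep(c("A", "B"), each = 10))
  res0 <- pairwise_phist(same, n_perm = 99, seed = 2, unit = "individual")
  expect_lt(abs(res0$phi_st), 0.2)
  expect_gt(res0$p_value, 0.05)

  # random fixtures agree with the independent oracle to 1e-10
  set.seed(14)
  for (r in 1:5) {
    seqs <- vapply(1:12, function(i) {
      k <- sample(0:3, 1)
      if (k == 0) base else mutate_seq(base, sample(20, k),
                                       sample(c("T", "G"), k, TRUE))
    }, character(1))
    iso <- rep(c("A", "B"), each = 6)
    ds <- make_haploid_dataset(seqs, isolates = iso)
    got <- pairwise_phist(ds, n_perm = 5, seed = 3, unit = "individual")
    mat <- do.call(rbind, strsplit(seqs, ""))
    d <- outer(seq_len(12), seq_len(12),
               Vectorize(function(i, j) sum(mat[i, ] != mat[j, ])))
    comp <- oracle_two_level(d, iso)
    expect_equal(got$phi_st, unname(comp["a"] / sum(comp)),
                 tolerance = 1e-10)
  }
})

test_that("AMOVA recovers planted hierarchical variance structure", {
  # all identical: every component zero
  ds0 <- make_haploid_dataset(rep("AAAA", 8),
                              isolates = rep(c("A", "B"), each = 4))
  a0 <- amova(ds0, n_perm = 19, seed = 1)
  expect_equal(a0$table$sigma2, c(0, 0))

  # two groups fixed for distinct haplotypes, no within variation:
  # 100% among groups
  base <- base_seq(30)
  seqs <- c(rep(base, 8), rep(mutate_seq(base, 1:10, rep("T", 10)), 8))
  iso <- rep(c("i1", "i2", "i3", "i4"), each = 4)
  grp <- c(i1 = "g1", i2 = "g1", i3 = "g2", i4 = "g2")
  ds <- make_haploid_dataset(seqs, isolates = iso)
  a1 <- amova(ds, grouping = grp, n_perm = 19, seed = 2)
  expect_equal(a1$table$pct[1], 100, tolerance = 1e-9)
  expect_equal(sum(a1$table$pct), 100, tolerance = 1e-9)

  # two-unit AMOVA reproduces pairwise Phi_ST exactly on identical input
  sc <- sim_island_scenario(n_pop = 2, n_per = 10, t_split = 5000)
  s <- simulate_scenario(sc, seed = 52)
  ph <- pairwise_phist(s$mito, n_perm = 5, seed = 3, unit = "individual")
  am <- amova(s$mito, within_individuals = FALSE, n_perm = 5, seed = 3)
  expect_equal(ph$phi_st, unname(am$phi[["phi_ST"]]), tolerance = 1e-12)

  # planted three-level structure: percentages recovered within 5 points
  # (generative model with specified between/within variances)
  pcts <- replicate(12, {
    seed <- sample.int(1e6, 1)
    scg <- sim_scenario(
      "haplodiploid",
      demes = tibble::tibble(id = c("A", "B"), n_f = 400, n_m = 400),
      events = list(ev_split(12000, "A", "B")),
      samples = tibble::tibble(deme = c("A", "A", "B", "B"), n = 8,
                               isolate = c("a1", "a2", "b1", "b2")),
      mito = list(length = 543, mu = 2e-6)
    )
    sg <- simulate_scenario(scg, seed = seed)
    grp <- c(a1 = "gA", a2 = "gA", b1 = "gB", b2 = "gB")
    ag <- amova(sg$mito, grouping = grp, n_perm = 5, seed = 1)
    ag$table$pct
  })
  # among-groups dominates; among-isolates-within-groups stays minor
  expect_gt(mean(pcts[1, ]), 50)
  expect_lt(mean(abs(pcts[2, ])), 20)
})

test_that("F_IS detects heterozygote deficits and stays near zero under HW", {
  # all-homozygous unit with two haplotypes at equal frequency: F_IS = 1
  base <- base_seq(20)
  alt <- mutate_seq(base, 1:4, rep("T", 4))
  seqs <- c(rbind(rep(c(base, alt), each = 3), rep(c(base, alt), each = 3)))
  ds <- make_diploid_dataset(seqs)
  f <- fis(ds, n_perm = 99, seed = 4)
  expect_equal(f$fis, 1)
  expect_lt(f$p_value, 0.05)

  # Hardy-Weinberg binomial sampling: mean F_IS ~ 0 over replicates
  set.seed(77)
  fhat <- vapply(1:60, function(r) {
    n <- 12
    alleles <- sample(c(base, alt), 2 * n, replace = TRUE)
    fis(make_diploid_dataset(alleles), n_perm = 5, seed = r)$fis
  }, numeric(1))
  expect_lt(abs(mean(fhat)), 3 * sd(fhat) / sqrt(length(fhat)))

  # Wahlund fixture: pooling two fixed-difference subunits inflates F_IS
  wahl <- vapply(1:30, function(r) {
    set.seed(900 + r)
    subA <- rep(base, 12)
    subB <- rep(alt, 12)
    seqs <- c(subA[sample(12)], subB[sample(12)])
    # genotypes formed within subunits, then pooled into one unit
    f <- fis(make_diploid_dataset(seqs), n_perm = 39, seed = r)
    c(f$fis, f$p_value)
  }, numeric(2))
  expect_gt(mean(wahl[1, ]), 0.5)
  expect_gt(mean(wahl[2, ] < 0.05), 0.5)

  # unit with < 2 individuals: NA
  one <- make_diploid_dataset(c(base, alt))
  expect_true(is.na(fis(one, n_perm = 9)$fis))
})

test_that("genotype-unit and allele-unit permutations differ under HWD", {
  # strong heterozygote deficit: the allele-unit null is much narrower
  base <- base_seq(15)
  alt <- mutate_seq(base, 1:6, rep("T", 6))
  seqs_a <- c(rbind(rep(base, 6), rep(base, 6)))
  seqs_b <- c(rbind(rep(c(base, alt), 3), rep(c(base, alt), 3)))
  ds <- make_diploid_dataset(c(seqs_a, seqs_b),
                             isolates = rep(c("A", "B"), each = 6))
  g <- pairwise_phist(ds, n_perm = 199, seed = 5, unit = "genotype")
  a <- pairwise_phist(ds, n_perm = 199, seed = 5, unit = "allele")
  expect_equal(g$phi_st, a$phi_st) # same statistic, different null
  expect_false(isTRUE(all.equal(g$p_value, a$p_value)))
  expect_gt(g$p_value, a$p_value)
})
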