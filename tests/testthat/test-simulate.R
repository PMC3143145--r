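test_that("theoretical copy-number ratios follow the inheritance system", {
  one_deme <- function(inh, n_f, n_m) {
    sim_scenario(inh,
                 demes = tibble::tibble(id = "A", n_f = n_f, n_m = n_m),
                 samples = tibble::tibble(deme = "A", n = 5, isolate = "x"))
  }
  expect_equal(expected_ne_ratio(one_deme("haplodiploid", 500, 500)), 3)
  expect_equal(expected_ne_ratio(one_deme("diplodiploid", 500, 500)), 4)
  expect_equal(expected_ne_ratio(one_deme("haplodiploid", 500, 0)), 2)
  expect_error(expected_ne_ratio(one_deme("haplodiploid", 0, 10)),
               "positive")
})

test_that("identical scenario and seed give identical output", {
  sc <- sim_island_scenario(n_pop = 2, n_per = 6, t_split = 4000)
  a <- simulate_scenario(sc, seed = 99)
  b <- simulate_scenario(sc, seed = 99)
  expect_identical(a$mito$sequences, b$mito$sequences)
  expect_identical(a$nuclear$sequences, b$nuclear$sequences)
  expect_identical(a$truth$individuals, b$truth$individuals)
  c <- simulate_scenario(sc, seed = 100)
  expect_false(identical(a$mito$sequences$seq, c$mito$sequences$seq))
})

test_that("zero mutation rate yields identical unadmixed sequences", {
  sc <- sim_scenario(
    "haplodiploid",
    demes = tibble::tibble(id = "A", n_f = 100, n_m = 100),
    samples = tibble::tibble(deme = "A", n = 8, isolate = "x"),
    mito = list(length = 100, mu = 0),
    nuclear = list(length = 100, mu = 0, n_indel_series = 0)
  )
  s <- simulate_scenario(sc, seed = 3)
  expect_equal(length(unique(s$mito$sequences$seq)), 1)
  expect_equal(length(unique(s$nuclear$sequences$seq)), 1)
  expect_true(all(s$truth$individuals$hybrid_class == "unadmixed"))
})

test_that("deep splits without migration give near-complete differentiation", {
  phis <- vapply(1:10, function(r) {
    sc <- sim_island_scenario(n_pop = 2, n_per = 8, t_split = 30000,
                              mu = 2e-6)
    s <- simulate_scenario(sc, seed = 70 + r)
    pairwise_phist(s$mito, n_perm = 5, seed = 1,
                   unit = "individual")$phi_st
  }, numeric(1))
  expect_gt(mean(phis > 0.9), 0.8)
  expect_gt(min(phis), 0.75)
})

test_that("an F1 pulse one generation back creates hybrid truth by construction", {
  sc <- sim_island_scenario(n_pop = 2, n_per = 10, n_hybrid = 12,
                            t_split = 8000)
  s <- simulate_scenario(sc, seed = 41)
  tr <- s$truth$individuals
  hyb <- tr[tr$deme == "H", ]
  expect_true(all(hyb$hybrid_class == "F1"))
  expect_true(all(hyb$nuc_origin_a == "A"))
  expect_true(all(hyb$nuc_origin_b == "B"))
  # mito lineage drawn from both sources across seeds
  origins <- unlist(lapply(1:6, function(r) {
    simulate_scenario(sc, seed = 200 + r)$truth$individuals |>
      (\(x) x$mito_origin[x$deme == "H"])()
  }))
  expect_setequal(unique(origins), c("A", "B"))
  expect_gt(mean(origins == "A"), 0.25)
  expect_lt(mean(origins == "A"), 0.75)
})

test_that("sampling more individuals than a deme holds is rejected", {
  sc <- sim_scenario(
    "haplodiploid",
    demes = tibble::tibble(id = "A", n_f = 3, n_m = 2),
    samples = tibble::tibble(deme = "A", n = 10, isolate = "x")
  )
  expect_error(simulate_scenario(sc, seed = 1), "exceeds")
})

test_that("neutral diversity calibrates to 2 * copies * mu at both loci", {
  sc <- sim_scenario(
    "haplodiploid",
    demes = tibble::tibble(id = "A", n_f = 500, n_m = 500),
    samples = tibble::tibble(deme = "A", n = 15, isolate = "x"),
    mito = list(length = 543, mu = 1e-5),
    nuclear = list(length = 300, mu = 1e-5, n_indel_series = 0)
  )
  pm <- pn <- numeric(80)
  for (r in 1:80) {
    s <- simulate_scenario(sc, seed = 5000 + r)
    pm[r] <- nucleotide_diversity(s$mito$sequences$seq)
    pn[r] <- nucleotide_diversity(s$nuclear$sequences$seq)
  }
  expect_lt(abs(mean(pm) - 2 * 500 * 1e-5), 3 * sd(pm) / sqrt(80))
  expect_lt(abs(mean(pn) - 2 * 1500 * 1e-5), 3 * sd(pn) / sqrt(80))
})

test_that("mixed-lineage units show elevated mito/nuclear diversity ratio", {
  # two lineages at deep mito divergence merged into one unit: the mixed
  # unit's ratio exceeds the unmixed units' ratios (monotone property)
  ratios <- vapply(1:20, function(r) {
    sc <- sim_scenario(
      "haplodiploid",
      demes = tibble::tibble(id = c("A", "B", "M"), n_f = 500, n_m = 500),
      events = list(
        ev_pulse(1, "M", c("A", "B"), c(0.5, 0.5), pairing = "individual"),
        ev_split(15000, "A", "B"), ev_split(15001, "A", "M")),
      samples = tibble::tibble(deme = c("A", "B", "M"), n = 10,
                               isolate = c("a", "b", "m")),
      mito = list(length = 543, mu = 1e-6),
      nuclear = list(length = 729, mu = 1e-6, n_indel_series = 0)
    )
    s <- simulate_scenario(sc, seed = 3000 + r)
    dm <- diversity_summary(s$mito)
    dn <- diversity_summary(s$nuclear)
    fl <- pi_ratio_flag(dm, dn)
    ratio <- setNames(fl$ratio, fl$unit_id)
    c(mixed = unname(ratio[["m"]]),
      unmixed = mean(c(ratio[["a"]], ratio[["b"]]), na.rm = TRUE))
  }, numeric(2))
  # single-locus ratios are noisy per replicate; the mixed unit must beat
  # the unmixed average in most replicates and clearly on average
  expect_gt(mean(ratios["mixed", ] > ratios["unmixed", ]), 0.6)
  expect_gt(mean(ratios["mixed", ]), 1.5 * mean(ratios["unmixed", ]))
})
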