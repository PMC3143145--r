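test_that("mismatch distributions equal the brute-force pairwise oracle", {
  # identical sequences: all pairs at zero differences
  d0 <- mismatch_distribution(rep("ACGTACGT", 4))
  expect_equal(unname(d0$counts), 6)
  expect_equal(names(d0$counts), "0")

  # two sequences differing at 3 sites: single pair at j = 3
  d3 <- mismatch_distribution(c("AAAAAAAA", "TTTAAAAA"))
  expect_equal(unname(d3$counts), c(0, 0, 0, 1))

  # star-like expansion: unimodal, counts equal the O(n^2) oracle
  sc <- sim_scenario(
    "haplodiploid",
    demes = tibble::tibble(id = "A", n_f = 20000, n_m = 20000),
    events = list(ev_size_change(150, "A", 10, 10)),
    samples = tibble::tibble(deme = "A", n = 20, isolate = "iso1"),
    mito = list(length = 543, mu = 2e-5)
  )
  s <- simulate_scenario(sc, seed = 12)
  seqs <- s$mito$sequences$seq
  md <- mismatch_distribution(seqs)
  oracle <- oracle_pair_diffs(seqs)
  expect_equal(unname(md$counts),
               tabulate(oracle + 1L, nbins = max(oracle) + 1L))
  expect_equal(md$n_pairs, choose(20, 2))
  expect_error(mismatch_distribution("ACGT"), "at least 2")
})

test_that("the expansion curve normalizes and is recovered by the fitter", {
  # normalization on a parameter grid
  for (tau in c(0.5, 2, 8)) {
    for (th0 in c(0, 1, 5)) {
      for (th1 in c(10, 100, 1e4)) {
        expect_equal(sum(expected_mismatch(400, tau, th0, th1)), 1,
                     tolerance = 1e-8)
      }
    }
  }

  # all mass at j = 0: stationary zero-difference limit
  d <- structure(list(counts = c(`0` = 10), n_seq = 5, n_pairs = 10,
                      unit_id = NULL), class = "mismatch_distribution")
  f <- suppressWarnings(fit_sudden_expansion(d))
  expect_lt(f$tau, 0.05)
  expect_lt(f$ssd, 1e-6)

  # distribution generated from the model's own curve: tau within 10%
  truth <- expected_mismatch(40, tau = 4, theta0 = 1, theta1 = 100)
  counts <- round(truth * 1e6)
  d2 <- structure(list(counts = setNames(counts, 0:40), n_seq = 1000,
                       n_pairs = sum(counts), unit_id = NULL),
                  class = "mismatch_distribution")
  f2 <- fit_sudden_expansion(d2)
  expect_lt(abs(f2$tau - 4) / 4, 0.10)
  expect_lt(f2$ssd, 1e-6)
})

test_that("fitted tau tracks 2ut under a simulated instantaneous expansion", {
  # 100x expansion t generations ago; mutation rate u per locus
  t_exp <- 200; mu <- 2e-5; L <- 543
  sc <- sim_scenario(
    "haplodiploid",
    demes = tibble::tibble(id = "A", n_f = 30000, n_m = 30000),
    events = list(ev_size_change(t_exp, "A", 300, 300)),
    samples = tibble::tibble(deme = "A", n = 25, isolate = "iso1"),
    mito = list(length = L, mu = mu)
  )
  taus <- vapply(1:12, function(r) {
    s <- simulate_scenario(sc, seed = 400 + r)
    d <- mismatch_distribution(s$mito$sequences$seq)
    suppressWarnings(fit_sudden_expansion(d))$tau
  }, numeric(1))
  expected_tau <- 2 * mu * L * t_exp
  expect_lt(abs(mean(taus) - expected_tau), 3 * sd(taus) / sqrt(length(taus)) + 0.35)
})

test_that("SSD bootstrap flags model violations but not model-true data", {
  # perfect fit: observed equals expectation -> SSD ~ 0, p_ssd high
  truth <- expected_mismatch(30, tau = 3, theta0 = 0.5, theta1 = 1000)
  counts <- round(truth * 1e5)
  d <- structure(list(counts = setNames(counts, 0:30), n_seq = 30,
                      n_pairs = sum(counts), unit_id = NULL),
                 class = "mismatch_distribution")
  f <- fit_sudden_expansion(d)
  g <- mismatch_gof(d, f, n_bootstrap = 60, seed = 2)
  expect_lt(g$ssd, 1e-6)
  expect_gt(g$p_ssd, 0.5)
  expect_error(mismatch_gof(d, f, n_bootstrap = 0), "n_bootstrap")

  # two planted haplotype clouds far apart: sudden-expansion rejected in
  # the majority of replicates
  base <- base_seq(200)
  far <- mutate_seq(base, 1:25, rep("T", 25))
  rej <- vapply(1:8, function(r) {
    set.seed(700 + r)
    cloud <- function(anchor) {
      vapply(1:10, function(i) {
        pos <- sample(30:200, 2)
        mutate_seq(anchor, pos, sample(c("G", "C"), 2, TRUE))
      }, character(1))
    }
    seqs <- c(cloud(base), cloud(far))
    d2 <- mismatch_distribution(seqs)
    f2 <- suppressWarnings(fit_sudden_expansion(d2))
    g2 <- mismatch_gof(d2, f2, n_bootstrap = 60, seed = r)
    g2$p_ssd < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.5)
})

test_that("raggedness separates smooth from alternating distributions", {
  smooth <- 0.5^(1:10); smooth <- smooth / sum(smooth)
  alternating <- rep(c(0.18, 0.02), 5); alternating <- alternating / sum(alternating)
  expect_lt(raggedness_index(smooth), raggedness_index(alternating))
})

test_that("shape labels follow haplotype counts and modality", {
  base <- base_seq(100)
  ds1 <- make_haploid_dataset(rep(base, 6))
  t1 <- collapse_haplotypes(ds1, "fifth_state")
  d1 <- mismatch_distribution(rep(base, 6))
  expect_equal(classify_mismatch_profile(d1, t1, "iso1"), "1h")

  two <- c(rep(base, 4), rep(mutate_seq(base, c(4, 9), c("T", "T")), 3))
  ds2 <- make_haploid_dataset(two)
  t2 <- collapse_haplotypes(ds2, "fifth_state")
  d2 <- mismatch_distribution(two)
  expect_equal(classify_mismatch_profile(d2, t2, "iso1"), "2h")

  # two planted haplotype clouds ~20 mutations apart: bimodal
  far <- mutate_seq(base, 1:20, rep("T", 20))
  set.seed(31)
  cloud <- function(anchor) {
    vapply(1:8, function(i) {
      mutate_seq(anchor, sample(25:100, 1), "G")
    }, character(1))
  }
  seqs <- c(cloud(base), cloud(far))
  ds3 <- make_haploid_dataset(seqs)
  t3 <- collapse_haplotypes(ds3, "fifth_state")
  d3 <- mismatch_distribution(seqs)
  expect_equal(classify_mismatch_profile(d3, t3, "iso1"), "bi")

  # smooth single-mode distribution: unimodal
  sc <- sim_scenario(
    "haplodiploid",
    demes = tibble::tibble(id = "A", n_f = 20000, n_m = 20000),
    events = list(ev_size_change(150, "A", 10, 10)),
    samples = tibble::tibble(deme = "A", n = 20, isolate = "iso1"),
    mito = list(length = 543, mu = 2e-5)
  )
  s <- simulate_scenario(sc, seed = 13)
  t4 <- collapse_haplotypes(s$mito, "fifth_state")
  d4 <- mismatch_distribution(s$mito$sequences$seq)
  expect_true(classify_mismatch_profile(d4, t4, "iso1") %in% c("uni"))
})
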