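test_that("aligned datasets validate their invariants", {
  ds <- make_haploid_dataset(c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTTT"))
  expect_s3_class(ds, "aligned_dataset")
  expect_equal(ds$alignment_length, 10)
  expect_equal(nrow(ds$sequences), 3)

  # length-inconsistent records rejected
  expect_error(make_haploid_dataset(c("ACGT", "ACG")), "aligned length")
  # non-IUPAC residue rejected, naming the individual
  expect_error(make_haploid_dataset(c("ACGR", "ACGT")), "ind01")
  # diploid individual with a single allele record rejected
  expect_error(
    aligned_dataset("Tpm", "diploid",
                    tibble::tibble(individual_id = "a", allele_index = 0L,
                                   isolate_id = "x", seq = "ACGT"),
                    tibble::tibble(individual_id = "a", isolate_id = "x")),
    "exactly 2"
  )
  # missing metadata row names the individual
  expect_error(
    aligned_dataset("COI", "haploid",
                    tibble::tibble(individual_id = c("a", "b"),
                                   allele_index = 0L, isolate_id = "x",
                                   seq = "ACGT"),
                    tibble::tibble(individual_id = "a", isolate_id = "x")),
    "b"
  )
})

test_that("FASTA + metadata round-trips bit-exactly", {
  sc <- sim_island_scenario(n_pop = 2, n_per = 6, t_split = 4000)
  s <- simulate_scenario(sc, seed = 3)
  for (ds in list(s$mito, s$nuclear)) {
    fa <- tempfile(fileext = ".fasta")
    md <- tempfile(fileext = ".tsv")
    write_alignment(ds, fa, md)
    back <- read_alignment(fa, md, ds$ploidy, ds$locus_name)
    expect_equal(back$sequences, ds$sequences)
    expect_equal(back$alignment_length, ds$alignment_length)
    expect_equal(back$samples$individual_id, ds$samples$individual_id)
    expect_equal(back$samples$isolate_id, ds$samples$isolate_id)
  }
})

test_that("haplotype collapsing respects the gap mode", {
  # identical sequences collapse to one haplotype with no variation
  ds0 <- make_haploid_dataset(rep("ACGTACGT", 4))
  tab0 <- collapse_haplotypes(ds0, "fifth_state")
  expect_equal(tab0$h, 1)
  expect_equal(tab0$S, 0)

  # gap as fifth state separates haplotypes; ignoring gap columns merges them
  ds <- make_haploid_dataset(c("AC-A", "ACAA"))
  t5 <- collapse_haplotypes(ds, "fifth_state")
  tg <- collapse_haplotypes(ds, "ignore_gap_columns")
  expect_equal(t5$h, 2)
  expect_equal(t5$S, 1)
  expect_equal(tg$h, 1)
  expect_equal(tg$S, 0)

  # planted k distinct haplotypes recovered (string-dedup oracle)
  base <- base_seq(30)
  haps <- c(base,
            mutate_seq(base, 5, "T"),
            mutate_seq(base, c(5, 9), c("T", "C")),
            mutate_seq(base, 21, "G"))
  seqs <- rep(haps, times = c(4, 3, 2, 1))
  ds2 <- make_haploid_dataset(seqs)
  tab2 <- collapse_haplotypes(ds2, "fifth_state")
  expect_equal(tab2$h, length(unique(haps)))
  expect_equal(sum(tab2$haplotypes$count), length(seqs))
  # counts sorted decreasing and S counts the planted sites
  expect_equal(tab2$haplotypes$count, c(4, 3, 2, 1))
  expect_equal(tab2$S, 3)
})

test_that("haplotype collapse is order-independent and monotone in gap mode", {
  base <- base_seq(40)
  hap_pool <- c(base,
                mutate_seq(base, c(3, 17), c("T", "G")),
                mutate_seq(base, 25, "C"),
                mutate_seq(base, c(8, 9, 10), c("-", "-", "-")))
  set.seed(11)
  for (r in 1:5) {
    seqs <- sample(rep(hap_pool, times = sample(1:4, 4, replace = TRUE)))
    ds <- make_haploid_dataset(seqs)
    a <- collapse_haplotypes(ds, "fifth_state")
    ds_perm <- make_haploid_dataset(sample(seqs))
    b <- collapse_haplotypes(ds_perm, "fifth_state")
    # identical tables up to id relabeling: same (seq, count) multiset
    expect_equal(a$haplotypes[order(a$haplotypes$seq), c("seq", "count")],
                 b$haplotypes[order(b$haplotypes$seq), c("seq", "count")])
    expect_gte(a$S, collapse_haplotypes(ds, "ignore_gap_columns")$S)
  }
})

test_that("indel series encode presence/absence with interval validation", {
  base <- base_seq(60)
  gapped <- mutate_seq(base, 11:18, rep("-", 8))
  seqs <- c(base, base, gapped, gapped, base, gapped)
  ds <- make_diploid_dataset(seqs)
  im <- encode_indel_series(ds, list(c(11, 18), c(31, 40)))
  expect_equal(im$n_loci, 2)
  expect_equal(im$states$indel1, c(1L, 1L, 0L, 0L, 1L, 0L))
  expect_equal(im$states$indel2, rep(1L, 6))
  expect_false(im$series$monomorphic[1])
  expect_true(im$series$monomorphic[2])

  expect_error(encode_indel_series(ds, list(c(55, 61))), "outside")
  expect_error(encode_indel_series(ds, list(c(5, 12), c(10, 20))),
               "non-overlapping")
})

test_that("simulator-emitted indel series match the encoded matrix", {
  sc <- sim_scenario(
    "haplodiploid",
    demes = tibble::tibble(id = "A", n_f = 300, n_m = 300),
    samples = tibble::tibble(deme = "A", n = 10, isolate = "iso1"),
    nuclear = list(length = 200, mu = 1e-5, n_indel_series = 3,
                   indel_mu = 5e-4)
  )
  s <- simulate_scenario(sc, seed = 9)
  iv <- s$truth$indel_intervals
  im <- encode_indel_series(s$nuclear, iv)
  # direct interval inspection of the emitted sequences
  mat <- do.call(rbind, strsplit(s$nuclear$sequences$seq, ""))
  for (r in seq_len(nrow(iv))) {
    manual <- apply(mat[, iv$start[r]:iv$end[r], drop = FALSE], 1,
                    function(x) as.integer(!all(x == "-")))
    expect_equal(im$states[[iv$series_id[r]]], manual)
  }
})
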