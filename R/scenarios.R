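#' Scripted demographic scenarios matching the six genetic profiles
#'
#' Returns parameterized haplodiploid scenarios whose summary-statistic
#' signatures are designed to land in the six genetic-profile windows used
#' by [classify_gp()], plus a `motley` scenario of very recent secondary
#' contact (two unadmixed mitochondrial clusters co-occurring in one
#' isolate). Each scenario samples the focal isolate together with pure
#' reference isolates from every ancestral lineage so that first-level
#' nuclear clustering is anchored. The intended profile is stored in the
#' `intended_gp` attribute of each scenario.
#'
#' Sketches (all times in generations pastward, sizes in individuals; both
#' loci share the per-site mutation rate `mu` unless a scenario states
#' otherwise):
#'
#' * `gp1` - two lineages deeply diverged (T = 26000) hybridize into a
#'   swarm 100 generations ago, founding mothers from one lineage: very high
#'   nuclear diversity, low mito diversity, two nuclear clusters.
#' * `gp2` - three lineages (T = 5700) mix into a farm population, mothers
#'   from one lineage: intermediate nuclear diversity, three clusters.
#' * `gp3` - founder bottleneck 350 generations ago seeded 87/13 from two
#'   moderately diverged lineages (T = 4500) through a female-skewed founder
#'   group (3 females, 60 males), then expansion: low diversities, two
#'   clusters, negative Tajima's D at both loci.
#' * `gp4` - strong nuclear founder effect with balanced mitochondrial
#'   secondary contact (mothers 50/50, nuclear 93/7): mito diversity exceeds
#'   nuclear.
#' * `gp5` - three deeply diverged lineages (T = 20000) mix, founding
#'   mothers drawn evenly from all three; the scenario's mitochondrial clock
#'   runs slightly slower than the nuclear one, leaving the mito/nuclear
#'   diversity ratio elevated but below one, with three nuclear clusters.
#' * `gp6` - long-isolated small sibling lineage (T = 20000): a single
#'   nuclear cluster.
#' * `motley` - two deeply diverged demes merged one generation before
#'   sampling with whole individuals from either source: unadmixed
#'   individuals of both origins side by side, mito/nuclear diversity ratio
#'   above 0.5.
#'
#' @param n_focal Individuals sampled from the focal isolate.
#' @param n_ref Individuals sampled per reference isolate.
#' @param mu Per-site per-generation substitution rate for both loci.
#' @return Named list of [sim_scenario()] objects.
#' @export
scripted_scenarios <- function(n_focal = 24, n_ref = 12, mu = 1e-6) {
  mk <- function(demes, events, samples, intended,
                 inheritance = "haplodiploid", mito_mu = mu) {
    sc <- sim_scenario(
      inheritance = inheritance,
      demes = demes,
      events = events,
      samples = samples,
      mito = list(length = 543, mu = mito_mu),
      nuclear = list(length = 729, mu = mu, n_indel_series = 8,
                     indel_mu = mu * 20)
    )
    attr(sc, "intended_gp") <- intended
    sc
  }
  ref2 <- function(extra = NULL) {
    tibble::tibble(
      deme = c("F", "A", "B", extra),
      n = c(n_focal, rep(n_ref, 2 + length(extra))),
      isolate = c("focal", "refA", "refB", if (!is.null(extra)) "refC")
    )
  }
  # moderate source demes keep some within-lineage diversity (stabilising
  # cluster identity) without inflating divergence variance; the focal deme
  # is large so sampled lineages do not collapse between the founding pulse
  # and sampling
  d3 <- function(n = 500, nf = 3000) {
    tibble::tibble(id = c("A", "B", "F"), n_f = c(n, n, nf),
                   n_m = c(n, n, nf))
  }
  d4 <- function(n = 500, nf = 3000) {
    tibble::tibble(id = c("A", "B", "C", "F"), n_f = c(n, n, n, nf),
                   n_m = c(n, n, n, nf))
  }

  list(
    gp1 = mk(
      d3(),
      list(ev_pulse(100, "F", c("A", "B"), c(0.5, 0.5), mothers_from = "A"),
           ev_split(26000, "A", "B"),
           ev_split(26001, "A", "F")),
      ref2(), "GP1"
    ),
    gp2 = mk(
      d4(),
      list(ev_pulse(100, "F", c("A", "B", "C"), rep(1 / 3, 3),
                    mothers_from = "A"),
           ev_split(5700, "A", "B"),
           ev_split(5701, "A", "C"),
           ev_split(5702, "A", "F"),
           ev_size_change(5750, "A", 150, 150)),
      ref2("C"), "GP2"
    ),
    gp3 = mk(
      tibble::tibble(id = c("A", "B", "F"), n_f = c(400, 400, 3000),
                     n_m = c(400, 400, 3000)),
      # female-skewed founder group: nuclear copies survive the bottleneck
      # while the mitochondrial pool collapses to the few founding mothers
      list(ev_bottleneck(348, "F", 3, 60, 2),
           ev_pulse(350, "F", c("A", "B"), c(0.87, 0.13),
                    mothers_from = "A"),
           ev_split(4500, "A", "B"),
           ev_split(4501, "A", "F"),
           ev_size_change(4550, "A", 150, 150)),
      ref2(), "GP3"
    ),
    gp4 = mk(
      d3(),
      list(ev_pulse(50, "F", c("A", "B"), c(0.93, 0.07),
                    mito_proportions = c(0.5, 0.5)),
           ev_split(12000, "A", "B"),
           ev_split(12001, "A", "F")),
      ref2(), "GP4"
    ),
    gp5 = mk(
      d4(),
      list(ev_pulse(100, "F", c("A", "B", "C"), rep(1 / 3, 3),
                    mito_proportions = rep(1 / 3, 3)),
           ev_split(20000, "A", "B"),
           ev_split(20001, "A", "C"),
           ev_split(20002, "A", "F"),
           ev_size_change(20050, "A", 150, 150)),
      ref2("C"), "GP5", mito_mu = 0.7 * mu
    ),
    gp6 = mk(
      d3(nf = 200),
      list(ev_split(8000, "A", "B"),
           ev_split(20000, "A", "F")),
      ref2(), "GP6"
    ),
    motley = mk(
      d3(nf = 3000),
      list(ev_pulse(1, "F", c("A", "B"), c(0.5, 0.5), pairing = "individual"),
           ev_split(15000, "A", "B"),
           ev_split(15001, "A", "F")),
      ref2(), "motley"
    )
  )
}

#' Two- or three-population test scenario
#'
#' Convenience generator of well-separated populations (optionally with an
#' F1-hybrid deme) used throughout the package's validation: demes split
#' `t_split` generations ago, no migration afterwards, optionally a hybrid
#' deme founded one generation ago with one parent from each source.
#'
#' @param n_pop Number of source populations (2 or 3).
#' @param n_per Individuals sampled per population.
#' @param n_hybrid Individuals sampled from an F1 deme (0 disables it).
#' @param t_split Split time in generations.
#' @param n_f,n_m Deme sizes.
#' @param mu Per-site substitution rate.
#' @return A [sim_scenario()].
#' @export
sim_island_scenario <- function(n_pop = 2, n_per = 15, n_hybrid = 0,
                                t_split = 8000, n_f = 500, n_m = 500,
                                mu = 1e-6) {
  stopifnot(n_pop %in% 2:3)
  ids <- LETTERS[seq_len(n_pop)]
  demes <- tibble::tibble(id = c(ids, if (n_hybrid > 0) "H"),
                          n_f = n_f, n_m = n_m)
  events <- purrr::map(ids[-1], function(x) {
    ev_split(t_split + match(x, ids), "A", x)
  })
  if (n_hybrid > 0) {
    events <- c(list(ev_pulse(1, "H", c("A", "B"), c(0.5, 0.5),
                              pairing = "f1")), events)
    events <- c(events, list(ev_split(t_split + n_pop + 1, "A", "H")))
  }
  samples <- tibble::tibble(
    deme = c(ids, if (n_hybrid > 0) "H"),
    n = c(rep(n_per, n_pop), if (n_hybrid > 0) n_hybrid),
    isolate = c(paste0("iso", ids), if (n_hybrid > 0) "isoH")
  )
  sim_scenario("haplodiploid", demes, events, samples,
               mito = list(length = 543, mu = mu),
               nuclear = list(length = 729, mu = mu, n_indel_series = 0,
                              indel_mu = 0))
}
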