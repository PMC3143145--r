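# Structured-coalescent simulator of mito-nuclear scenarios: radiations into
# incipient species, hybridization pulses, secondary contact and founder
# bottlenecks, with haplodiploid or diplodiploid inheritance. Time is in
# generations pastward from sampling (t = 0); population sizes are counts of
# individuals (females and males separately). Per-deme effective gene-copy
# numbers follow the inheritance system: mitochondria are transmitted by
# females only (N_f copies); nuclear autosomes have 2*N_f + N_m copies in
# haplodiploids (males are haploid) and 2*(N_f + N_m) in diplodiploids.

#' Demographic event constructors for simulation scenarios
#'
#' * `ev_split(t, parent, child)` - pastward of `t`, deme `child` merges into
#'   `parent` (forward in time: `child` was founded from `parent` at `t`).
#' * `ev_pulse(t, target, sources, proportions, pairing, mothers_from)` - the
#'   `target` deme is founded/replaced at `t` by migrants from `sources` in
#'   the given proportions (pastward, every lineage in `target` jumps to a
#'   source). `pairing = "f1"` (two sources) routes allele copy 0 of every
#'   individual to the first source and copy 1 to the second, producing
#'   first-generation hybrids by construction; `mothers_from` pins all
#'   mitochondrial lineages to one source.
#' * `ev_bottleneck(t, deme, n_f, n_m, duration)` - sizes reduced to
#'   `(n_f, n_m)` during `[t, t + duration)` pastward.
#' * `ev_size_change(t, deme, n_f, n_m)` - sizes become `(n_f, n_m)` for all
#'   times pastward of `t`.
#'
#' @param t Event time in generations before sampling (>= 0).
#' @param parent,child,target,deme Deme ids.
#' @param sources Character vector of source deme ids.
#' @param proportions Numeric vector summing to 1.
#' @param pairing `"random"` or `"f1"`.
#' @param mothers_from Optional source deme for all mito lineages.
#' @param n_f,n_m Female and male counts.
#' @param duration Bottleneck duration in generations.
#' @return An event object (a classed list).
#' @name sim_events
NULL

#' @rdname sim_events
#' @export
ev_split <- function(t, parent, child) {
  structure(list(type = "split", t = t, parent = parent, child = child),
            class = "sim_event")
}

#' @rdname sim_events
#' @param mito_proportions Optional separate source proportions for the
#'   mitochondrial locus (e.g. founding mothers drawn evenly from two
#'   lineages while nuclear ancestry is skewed).
#' @export
ev_pulse <- function(t, target, sources, proportions,
                     pairing = c("random", "f1", "individual"),
                     mothers_from = NULL, mito_proportions = NULL) {
  pairing <- match.arg(pairing)
  if (abs(sum(proportions) - 1) > 1e-9) abort("Pulse proportions must sum to 1.")
  if (pairing == "f1" && length(sources) != 2) {
    abort("pairing = 'f1' requires exactly two sources.")
  }
  structure(list(type = "pulse", t = t, target = target, sources = sources,
                 proportions = proportions, pairing = pairing,
                 mothers_from = mothers_from,
                 mito_proportions = mito_proportions),
            class = "sim_event")
}

#' @rdname sim_events
#' @export
ev_bottleneck <- function(t, deme, n_f, n_m, duration) {
  structure(list(type = "bottleneck", t = t, deme = deme, n_f = n_f,
                 n_m = n_m, duration = duration),
            class = "sim_event")
}

#' @rdname sim_events
#' @export
ev_size_change <- function(t, deme, n_f, n_m) {
  structure(list(type = "size_change", t = t, deme = deme, n_f = n_f,
                 n_m = n_m),
            class = "sim_event")
}

#' Define a simulation scenario
#'
#' @param inheritance `"haplodiploid"` or `"diplodiploid"`.
#' @param demes Data frame with columns `id`, `n_f`, `n_m`.
#' @param events List of event objects (see [sim_events]).
#' @param samples Data frame with columns `deme`, `n` (individuals sampled)
#'   and `isolate` (label), optionally `habitat`.
#' @param mito,nuclear Locus settings: lists with `length` (columns) and `mu`
#'   (per-site per-generation substitution rate); `nuclear` additionally
#'   takes `n_indel_series` (default 8) and `indel_mu` (per-series toggle
#'   rate, default 0).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(inheritance = c("haplodiploid", "diplodiploid"),
                         demes, events = list(), samples,
                         mito = list(length = 543, mu = 1e-5),
                         nuclear = list(length = 729, mu = 1e-5,
                                        n_indel_series = 8, indel_mu = 0)) {
  inheritance <- match.arg(inheritance)
  demes <- tibble::as_tibble(demes)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("id", "n_f", "n_m") %in% names(demes)),
            all(c("deme", "n", "isolate") %in% names(samples)))
  if (!"habitat" %in% names(samples)) samples$habitat <- "domestic"
  if (any(!samples$deme %in% demes$id)) abort("Sampling from unknown deme.")
  tt <- vapply(events, function(e) e$t, numeric(1))
  if (length(tt) > 0) events <- events[order(tt)]
  mito <- utils::modifyList(list(length = 543, mu = 1e-5), mito)
  nuclear <- utils::modifyList(list(length = 729, mu = 1e-5,
                                    n_indel_series = 8, indel_mu = 0),
                               nuclear)
  structure(list(inheritance = inheritance, demes = demes, events = events,
                 samples = samples, mito = mito, nuclear = nuclear),
            class = "sim_scenario")
}

#' Theoretical nuclear/mito effective-copy ratio of a single-deme scenario
#'
#' `(2*N_f + N_m) / N_f` for haplodiploids, `2*(N_f + N_m) / N_f` for
#' diplodiploids - e.g. 3 and 4 with equal numbers of females and males,
#' the classic 3-fold (resp. 4-fold) effective-size difference between
#' nuclear and mitochondrial genomes.
#'
#' @param scenario A single-deme [sim_scenario()].
#' @return A positive number.
#' @export
expected_ne_ratio <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (nrow(scenario$demes) != 1) abort("expected_ne_ratio requires a single-deme scenario.")
  n_f <- scenario$demes$n_f[1]
  n_m <- scenario$demes$n_m[1]
  if (n_f <= 0) abort("N_f must be positive.")
  if (scenario$inheritance == "haplodiploid") {
    (2 * n_f + n_m) / n_f
  } else {
    2 * (n_f + n_m) / n_f
  }
}

# Effective gene-copy number of a deme at pastward time t.
deme_copies <- function(scenario, deme, t, locus) {
  n_f <- scenario$demes$n_f[scenario$demes$id == deme]
  n_m <- scenario$demes$n_m[scenario$demes$id == deme]
  best_t <- -Inf
  for (e in scenario$events) {
    if (e$type == "size_change" && e$deme == deme && e$t <= t && e$t > best_t) {
      n_f <- e$n_f; n_m <- e$n_m; best_t <- e$t
    }
  }
  for (e in scenario$events) {
    if (e$type == "bottleneck" && e$deme == deme && e$t <= t &&
        t < e$t + e$duration) {
      n_f <- e$n_f; n_m <- e$n_m
    }
  }
  if (locus == "mito") {
    n_f
  } else if (scenario$inheritance == "haplodiploid") {
    2 * n_f + n_m
  } else {
    2 * (n_f + n_m)
  }
}

# Structured-coalescent gene tree for one locus.
# copies_meta: tibble(copy_id, individual_id, allele_index, deme).
# Returns parent pointers, node times, and per-copy origin deme (the deme a
# sampled copy's lineage first jumped to at a redistribution event, or its
# sampling deme if it never crossed one).
sim_gene_tree <- function(scenario, copies_meta, locus) {
  n <- nrow(copies_meta)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  t_node <- numeric(n_nodes)
  lin_id <- seq_len(n)
  lin_deme <- copies_meta$deme
  members <- as.list(seq_len(n))
  origin <- rep(NA_character_, n)
  nxt <- n + 1L
  t <- 0

  crit <- sort(unique(unlist(lapply(scenario$events, function(e) {
    if (e$type == "bottleneck") c(e$t, e$t + e$duration) else e$t
  }))))
  ev_queue <- scenario$events

  repeat {
    if (length(lin_id) <= 1) break
    demes_now <- unique(lin_deme)
    k_per <- table(lin_deme)
    rates <- vapply(demes_now, function(dm) {
      k <- k_per[[dm]]
      if (k < 2) return(0)
      k * (k - 1) / (2 * deme_copies(scenario, dm, t, locus))
    }, numeric(1))
    R <- sum(rates)
    nxt_crit <- crit[crit > t]
    t_next <- if (length(nxt_crit) > 0) nxt_crit[1] else Inf
    wait <- if (R > 0) stats::rexp(1, R) else Inf
    if (t + wait < t_next) {
      t <- t + wait
      dm <- sample(demes_now, 1, prob = rates)
      idx <- which(lin_deme == dm)
      pair <- sample(idx, 2)
      parent[lin_id[pair]] <- nxt
      t_node[nxt] <- t
      merged <- c(members[[pair[1]]], members[[pair[2]]])
      lin_id <- c(lin_id[-pair], nxt)
      lin_deme <- c(lin_deme[-pair], dm)
      members <- c(members[-pair], list(merged))
      nxt <- nxt + 1L
    } else {
      if (!is.finite(t_next)) {
        if (length(unique(lin_deme)) > 1) {
          abort("Lineages remain in separate demes with no further events; the scenario must merge all demes.")
        }
        next
      }
      t <- t_next
      for (e in ev_queue) {
        if (abs(e$t - t) > 1e-12) next
        if (e$type == "split") {
          # ancestral merger: lineage origins are not rewritten (origins
          # track recent redistribution pulses, not deep ancestry)
          hit <- lin_deme == e$child
          if (any(hit)) lin_deme[hit] <- e$parent
        } else if (e$type == "pulse") {
          hit <- which(lin_deme == e$target)
          if (length(hit) > 0) {
            first_tip <- vapply(members[hit], `[`, integer(1), 1)
            if (locus == "mito" && !is.null(e$mothers_from)) {
              dest <- rep(e$mothers_from, length(hit))
            } else if (e$pairing == "f1" && locus == "nuclear") {
              dest <- ifelse(copies_meta$allele_index[first_tip] == 0,
                             e$sources[1], e$sources[2])
            } else if (e$pairing == "individual" && !is.null(e$assign_map)) {
              dest <- unname(e$assign_map[copies_meta$individual_id[first_tip]])
              dest[is.na(dest)] <- sample(e$sources, sum(is.na(dest)),
                                          replace = TRUE, prob = e$proportions)
            } else if (locus == "mito" && !is.null(e$mito_proportions)) {
              dest <- sample(e$sources, length(hit), replace = TRUE,
                             prob = e$mito_proportions)
            } else {
              dest <- sample(e$sources, length(hit), replace = TRUE,
                             prob = e$proportions)
            }
            lin_deme[hit] <- dest
            for (q in seq_along(hit)) {
              origin <- record_origin(origin, members, hit[q], dest[q])
            }
          }
        }
      }
    }
  }
  origin[is.na(origin)] <- copies_meta$deme[is.na(origin)]
  root <- lin_id[1]
  list(parent = parent, t_node = t_node, n_tips = n, root = root,
       origin = origin)
}

record_origin <- function(origin, members, lin_rows, deme) {
  for (r in lin_rows) {
    tips <- members[[r]]
    origin[tips[is.na(origin[tips])]] <- if (length(deme) == 1) deme else deme[1]
  }
  origin
}

# Drop infinite-sites substitutions on a gene tree and build sequences.
# `allowed_cols` restricts mutable columns. Returns character matrix of rows
# = tips.
tree_sequences <- function(tree, mu_site, n_cols, allowed_cols, ancestral) {
  n_nodes <- 2L * tree$n_tips - 1L
  blen <- numeric(n_nodes)
  for (v in seq_len(n_nodes)) {
    if (tree$parent[v] > 0) blen[v] <- tree$t_node[tree$parent[v]] - tree$t_node[v]
  }
  total_len <- sum(blen)
  n_mut <- stats::rpois(1, mu_site * length(allowed_cols) * total_len)
  n_mut <- min(n_mut, length(allowed_cols)) # infinite-sites guard
  mut_cols <- if (n_mut > 0) sample(allowed_cols, n_mut) else integer()
  mut_branch <- if (n_mut > 0 && total_len > 0) {
    sample(n_nodes, n_mut, replace = TRUE, prob = blen)
  } else {
    integer()
  }
  seqs <- matrix(rep(ancestral, each = tree$n_tips), nrow = tree$n_tips)
  if (n_mut > 0) {
    below <- tips_below(tree)
    for (m in seq_len(n_mut)) {
      anc <- ancestral[mut_cols[m]]
      derived <- sample(setdiff(BASES, anc), 1)
      seqs[below[[mut_branch[m]]], mut_cols[m]] <- derived
    }
  }
  seqs
}

# tips below each node (including itself for tips)
tips_below <- function(tree) {
  n_nodes <- 2L * tree$n_tips - 1L
  below <- vector("list", n_nodes)
  for (v in seq_len(tree$n_tips)) below[[v]] <- v
  ord <- order(tree$t_node[seq(tree$n_tips + 1L, n_nodes)])
  for (v in seq(tree$n_tips + 1L, n_nodes)[ord]) {
    kids <- which(tree$parent == v)
    below[[v]] <- unlist(below[kids])
  }
  below
}

# Two-state indel presence along the tree: ancestral present, parity of
# Poisson toggle events per branch.
tree_indel_states <- function(tree, rate) {
  n_nodes <- 2L * tree$n_tips - 1L
  blen <- numeric(n_nodes)
  for (v in seq_len(n_nodes)) {
    if (tree$parent[v] > 0) blen[v] <- tree$t_node[tree$parent[v]] - tree$t_node[v]
  }
  toggles <- stats::rpois(n_nodes, rate * blen)
  state <- integer(n_nodes)
  order_nodes <- order(tree$t_node, decreasing = TRUE)
  state[tree$root] <- 1L
  for (v in order_nodes) {
    if (v == tree$root || tree$parent[v] == 0) next
    state[v] <- (state[tree$parent[v]] + toggles[v]) %% 2L
  }
  state[seq_len(tree$n_tips)]
}

#' Simulate a mito-nuclear dataset under a demographic scenario
#'
#' Draws structured-coalescent gene trees for the mitochondrial (one copy
#' per individual, maternally inherited) and nuclear (two copies per
#' individual) loci with per-deme effective copy numbers given by the
#' inheritance system, drops infinite-sites substitutions (colliding columns
#' re-drawn), toggles indel series by a two-state process on designated
#' intervals, and emits the two aligned datasets plus per-individual truth.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed; identical scenario and seed give identical
#'   output.
#' @return A list with `mito` and `nuclear` ([aligned_dataset()] objects),
#'   and `truth`: a list with `individuals` (tibble: deme, isolate, per-copy
#'   origin demes, nuclear ancestry fractions, mito origin, hybrid class)
#'   and `ne` (per-deme copy numbers at sampling time and their ratio).
#' @export
simulate_scenario <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(seed, {
    smp <- scenario$samples
    for (r in seq_len(nrow(smp))) {
      cap <- scenario$demes$n_f[scenario$demes$id == smp$deme[r]] +
        scenario$demes$n_m[scenario$demes$id == smp$deme[r]]
      if (smp$n[r] > cap) {
        abort(sprintf("Sampling %d individuals exceeds deme %s size %d.",
                      smp$n[r], smp$deme[r], cap))
      }
    }
    ind <- tibble::tibble(
      individual_id = unlist(purrr::map(seq_len(nrow(smp)), function(r) {
        sprintf("%s_%02d", smp$isolate[r], seq_len(smp$n[r]))
      })),
      isolate_id = rep(smp$isolate, smp$n),
      deme = rep(smp$deme, smp$n),
      habitat = rep(smp$habitat, smp$n)
    )
    n_ind <- nrow(ind)

    # per-individual source assignment for "individual"-pairing pulses is
    # drawn once so both loci of an individual trace to the same source
    scenario$events <- lapply(scenario$events, function(e) {
      if (e$type == "pulse" && e$pairing == "individual") {
        e$assign_map <- setNames(
          sample(e$sources, n_ind, replace = TRUE, prob = e$proportions),
          ind$individual_id)
      }
      e
    })

    # --- mito: one copy per individual
    mito_meta <- tibble::tibble(copy_id = seq_len(n_ind),
                                individual_id = ind$individual_id,
                                allele_index = 0L, deme = ind$deme)
    mito_tree <- sim_gene_tree(scenario, mito_meta, "mito")
    anc_m <- sample(BASES, scenario$mito$length, replace = TRUE)
    mseq <- tree_sequences(mito_tree, scenario$mito$mu, scenario$mito$length,
                           seq_len(scenario$mito$length), anc_m)

    # --- nuclear: two copies per individual; indel series reserve columns
    nuc_meta <- tibble::tibble(
      copy_id = seq_len(2L * n_ind),
      individual_id = rep(ind$individual_id, each = 2L),
      allele_index = rep(0:1, n_ind),
      deme = rep(ind$deme, each = 2L)
    )
    nuc_tree <- sim_gene_tree(scenario, nuc_meta, "nuclear")
    L <- scenario$nuclear$length
    n_ser <- scenario$nuclear$n_indel_series
    intervals <- default_indel_intervals(L, n_ser)
    indel_cols <- unlist(purrr::map(seq_len(nrow(intervals)), function(r) {
      seq(intervals$start[r], intervals$end[r])
    }))
    allowed <- setdiff(seq_len(L), indel_cols)
    anc_n <- sample(BASES, L, replace = TRUE)
    nseq <- tree_sequences(nuc_tree, scenario$nuclear$mu, L, allowed, anc_n)
    if (n_ser > 0 && scenario$nuclear$indel_mu > 0) {
      for (r in seq_len(nrow(intervals))) {
        st <- tree_indel_states(nuc_tree, scenario$nuclear$indel_mu)
        gap_rows <- which(st == 0L)
        if (length(gap_rows) > 0) {
          nseq[gap_rows, seq(intervals$start[r], intervals$end[r])] <- "-"
        }
      }
    }

    meta <- tibble::tibble(
      individual_id = ind$individual_id, isolate_id = ind$isolate_id,
      habitat = ind$habitat, bird_type = NA_character_,
      country = NA_character_, region = NA_character_,
      sampling_point = NA_character_
    )
    mito_ds <- aligned_dataset(
      "mito", "haploid",
      tibble::tibble(individual_id = mito_meta$individual_id,
                     allele_index = 0L,
                     isolate_id = ind$isolate_id,
                     seq = collapse_char_matrix(mseq)),
      meta
    )
    nuc_ds <- aligned_dataset(
      "nuclear", "diploid",
      tibble::tibble(individual_id = nuc_meta$individual_id,
                     allele_index = nuc_meta$allele_index,
                     isolate_id = rep(ind$isolate_id, each = 2L),
                     seq = collapse_char_matrix(nseq)),
      meta
    )

    org_a <- nuc_tree$origin[nuc_meta$allele_index == 0L]
    org_b <- nuc_tree$origin[nuc_meta$allele_index == 1L]
    recent_f1 <- any(vapply(scenario$events, function(e) {
      e$type == "pulse" && e$pairing == "f1" && e$t <= 1
    }, logical(1)))
    truth_ind <- ind |>
      dplyr::mutate(
        mito_origin = mito_tree$origin,
        nuc_origin_a = org_a,
        nuc_origin_b = org_b,
        hybrid_class = dplyr::case_when(
          org_a == org_b ~ "unadmixed",
          recent_f1 ~ "F1",
          TRUE ~ "admixed"
        )
      )
    demes_ne <- scenario$demes |>
      dplyr::mutate(
        mito_copies = purrr::map_dbl(.data$id, deme_copies,
                                     scenario = scenario, t = 0, locus = "mito"),
        nuclear_copies = purrr::map_dbl(.data$id, deme_copies,
                                        scenario = scenario, t = 0,
                                        locus = "nuclear"),
        ratio = .data$nuclear_copies / .data$mito_copies
      )
    list(mito = mito_ds, nuclear = nuc_ds,
         truth = list(individuals = truth_ind, ne = demes_ne,
                      indel_intervals = intervals))
  })
}

#' Default indel-series intervals
#'
#' Evenly spaced intervals of width 8 across the alignment, used by the
#' simulator and reusable with [encode_indel_series()].
#'
#' @param alignment_length Number of alignment columns.
#' @param n_series Number of series.
#' @return A tibble with `series_id`, `start`, `end`.
#' @export
default_indel_intervals <- function(alignment_length = 729, n_series = 8) {
  if (n_series == 0) {
    return(tibble::tibble(series_id = character(), start = integer(),
                          end = integer()))
  }
  width <- 8L
  gap <- floor((alignment_length - n_series * width) / (n_series + 1))
  start <- gap + (seq_len(n_series) - 1L) * (width + gap) + 1L
  tibble::tibble(series_id = paste0("indel", seq_len(n_series)),
                 start = as.integer(start),
                 end = as.integer(start + width - 1L))
}
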