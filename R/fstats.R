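# AMOVA machinery on matrices of pairwise sequence differences. The number
# of differing sites between two allele sequences plays the role of the
# squared Euclidean distance, the classical choice for haplotype AMOVA.

# Nested analysis of molecular variance on a distance matrix.
# d: n x n matrix of (squared) distances between allele copies.
# strata: named list of factors over copies, ordered top -> bottom; each must
# be nested within the previous. Returns one row per variance line.
amova_core <- function(d, strata) {
  n <- nrow(d)
  levels_list <- list()
  key <- rep("", n)
  for (s in seq_along(strata)) {
    key <- paste(key, as.character(strata[[s]]), sep = "\r")
    levels_list[[s]] <- key
  }
  L <- length(strata) + 1L # + copies level

  ssw_sum <- function(classes) {
    tot <- 0
    for (cl in split(seq_len(n), classes)) {
      if (length(cl) > 1) {
        tot <- tot + sum(d[cl, cl]) / (2 * length(cl))
      }
    }
    tot
  }
  m <- c(1L, vapply(levels_list, function(x) length(unique(x)), integer(1)), n)
  ssd <- c(sum(d) / (2 * n),
           vapply(levels_list, ssw_sum, numeric(1)),
           0)

  SS <- -diff(ssd)          # lines 1..L
  df <- diff(m)

  # tr(P_l B_v): l indexes 0..L (grand..copies), v indexes 1..L
  class_at <- function(l) {
    if (l == 0) rep(1L, n)
    else if (l <= length(strata)) as.integer(factor(levels_list[[l]]))
    else seq_len(n)
  }
  trPB <- function(l, v) {
    cl <- class_at(l)
    cv <- class_at(v)
    tot <- 0
    for (idx in split(seq_len(n), cl)) {
      tot <- tot + sum(table(cv[idx])^2) / length(idx)
    }
    tot
  }
  Kmat <- matrix(0, L, L)
  for (u in seq_len(L)) {
    for (v in u:L) {
      Kmat[u, v] <- trPB(u, v) - trPB(u - 1L, v)
    }
  }
  sigma2 <- backsolve(Kmat, SS)
  tot <- sum(sigma2)
  tibble::tibble(
    level = c(names(strata), "within"),
    df = df,
    SS = SS,
    MS = ifelse(df > 0, SS / df, NA_real_),
    sigma2 = sigma2,
    pct = if (tot == 0) rep(0, length(sigma2)) else 100 * sigma2 / tot
  )
}

# Pairwise difference matrix for a dataset's allele sequences.
dataset_distances <- function(dataset, gap_mode) {
  mat <- unit_matrix(dataset$sequences$seq, gap_mode)
  gap_is_state <- check_gap_mode(gap_mode) == "fifth_state"
  pairwise_diff_matrix(mat, gap_is_state)
}

#' Pairwise Phi_ST between units with permutation test
#'
#' Phi_ST from the two-level AMOVA decomposition of the pairwise-difference
#' matrix, for every unordered pair of units. Because nuclear alleles of one
#' individual are not independent under Hardy-Weinberg disequilibrium, the
#' default randomization unit is the genotype: both alleles of an individual
#' move together in permutations (`"allele"` permutes single copies;
#' `"individual"` is the haploid equivalent of `"genotype"`).
#'
#' @param dataset An [aligned_dataset()].
#' @param by Metadata column defining units (default `"isolate_id"`), or
#'   ignored when `units` is given.
#' @param units Optional named character vector mapping `individual_id` to a
#'   unit label (individuals mapped to `NA` are dropped).
#' @param gap_mode Gap handling mode.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param unit Randomization unit: `"genotype"`, `"allele"` or
#'   `"individual"`.
#' @return A tibble with `unit_a`, `unit_b`, `phi_st`, `p_value`, `n_perm`,
#'   `randomization_unit`.
#' @export
pairwise_phist <- function(dataset, by = "isolate_id", units = NULL,
                           gap_mode = "ignore_gap_columns", n_perm = 10000,
                           seed = 1,
                           unit = c("genotype", "allele", "individual")) {
  unit <- match.arg(unit)
  if (n_perm < 1) abort("n_perm must be >= 1.")
  seqs <- dataset$sequences
  memb <- membership_of(dataset, by, units)
  d <- dataset_distances(dataset, gap_mode)
  labs <- sort(unique(stats::na.omit(memb)))
  if (length(labs) < 2) abort("Need at least two units.")
  pairs <- utils::combn(labs, 2)
  res <- with_seed(seed, purrr::map_dfr(seq_len(ncol(pairs)), function(q) {
    ua <- pairs[1, q]; ub <- pairs[2, q]
    rows <- which(!is.na(memb) & memb %in% c(ua, ub))
    sub_d <- d[rows, rows, drop = FALSE]
    sub_m <- memb[rows]
    sub_ind <- seqs$individual_id[rows]
    obs <- amova_core(sub_d, list(pop = sub_m))$sigma2
    phi <- phi_from(obs)
    perm_stats <- replicate(n_perm, {
      pm <- permute_membership(sub_m, sub_ind, unit,
                               diploid = dataset$ploidy == "diploid")
      phi_from(amova_core(sub_d, list(pop = pm))$sigma2)
    })
    tibble::tibble(unit_a = ua, unit_b = ub, phi_st = phi,
                   p_value = perm_p(perm_stats, phi),
                   n_perm = as.integer(n_perm),
                   randomization_unit = unit)
  }))
  res
}

phi_from <- function(sigma2) {
  tot <- sum(sigma2)
  if (tot == 0) 0 else sigma2[1] / tot
}

# standard unbiased permutation P-value: (1 + #{perm >= observed}) / (B + 1);
# exactly uniform on {1/(B+1), ..., 1} under exchangeability, never zero
perm_p <- function(perm_stats, obs) {
  (1 + sum(perm_stats >= obs - 1e-12)) / (length(perm_stats) + 1)
}

membership_of <- function(dataset, by, units) {
  seqs <- dataset$sequences
  if (!is.null(units)) {
    unname(units[seqs$individual_id])
  } else if (by == "isolate_id") {
    seqs$isolate_id
  } else {
    key <- dataset$samples[[by]]
    names(key) <- dataset$samples$individual_id
    unname(key[seqs$individual_id])
  }
}

# Permute unit labels over copies, keeping both copies of a genotype
# together when unit = "genotype"/"individual" on diploid data.
permute_membership <- function(memb, ind, unit, diploid) {
  if (unit == "allele" || !diploid) {
    if (unit == "allele") return(sample(memb))
    # haploid: one copy per individual, so individual == allele permutation
    return(sample(memb))
  }
  ids <- unique(ind)
  per_ind <- memb[match(ids, ind)]
  shuffled <- sample(per_ind)
  shuffled[match(ind, ids)]
}

#' Hierarchical AMOVA
#'
#' Excoffier-style nested variance decomposition on the matrix of pairwise
#' sequence differences, with up to four levels: among groups, among isolates
#' within groups, among individuals within isolates (diploid loci only) and
#' within individuals. Negative variance components are retained and
#' reported, never truncated. Permutation P-values use the standard
#' level-specific schemes: whole isolates among groups, individuals among
#' isolates within groups, and allele copies among individuals within
#' isolates (which tests the heterozygote-deficit component behind `F_IS`).
#'
#' @inheritParams pairwise_phist
#' @param grouping Optional metadata column name (or named vector
#'   `isolate_id -> group`) defining groups of isolates; a single group drops
#'   that level with a note.
#' @param within_individuals Include the within-individual level (requires a
#'   diploid dataset).
#' @return An object of class `amova_fit`: list with `table` (tibble `level`,
#'   `df`, `SS`, `sigma2`, `pct`, `phi`, `p_value`), `phi` (named vector of
#'   Phi/F statistics), `note`.
#' @export
amova <- function(dataset, grouping = NULL, gap_mode = "ignore_gap_columns",
                  within_individuals = dataset$ploidy == "diploid",
                  n_perm = 10000, seed = 1) {
  if (within_individuals && dataset$ploidy != "diploid") {
    abort("within_individuals requires a diploid dataset.")
  }
  seqs <- dataset$sequences
  d <- dataset_distances(dataset, gap_mode)
  iso <- seqs$isolate_id
  ind <- seqs$individual_id
  note <- character()

  grp <- NULL
  if (!is.null(grouping)) {
    if (length(grouping) == 1 && is.character(grouping) &&
        grouping %in% names(dataset$samples)) {
      key <- dataset$samples[[grouping]]
      names(key) <- dataset$samples$individual_id
      grp <- unname(key[seqs$individual_id])
    } else {
      grp <- unname(grouping[iso])
    }
    if (length(unique(grp)) < 2) {
      note <- c(note, "single group; among-groups level omitted")
      grp <- NULL
    }
  }
  # a level that repartitions nothing (each group holding exactly one
  # isolate) would make the design matrix singular; it is dropped with a note
  iso_redundant <- !is.null(grp) &&
    length(unique(iso)) == length(unique(grp))
  if (iso_redundant) {
    note <- c(note, "each group holds exactly one isolate; among-isolates level omitted")
  }

  strata <- list()
  if (!is.null(grp)) strata$among_groups <- grp
  if (is.null(grp) || !iso_redundant) strata$among_isolates <- iso
  if (within_individuals) strata$among_individuals <- ind
  tab <- amova_core(d, strata)

  lv <- names(strata)
  n_lines <- nrow(tab)
  has_g <- "among_groups" %in% lv
  has_i <- "among_isolates" %in% lv
  gi <- match("among_groups", lv)
  ii <- match("among_isolates", lv)
  di <- match("among_individuals", lv)

  s2 <- tab$sigma2
  tot <- sum(s2)
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  phi <- c()
  pop_idx <- if (has_i) ii else gi
  if (has_g) phi["phi_CT"] <- sdiv(s2[gi], tot)
  if (has_g && has_i) phi["phi_SC"] <- sdiv(s2[ii], sum(s2[ii:n_lines]))
  phi["phi_ST"] <- sdiv(sum(s2[seq_len(pop_idx)]), tot)
  if (within_individuals) {
    phi["F_IS"] <- sdiv(s2[di], sum(s2[di:n_lines]))
    phi["F_IT"] <- sdiv(sum(s2[seq_len(di)]), tot)
  }

  pretty <- c(
    among_groups = "among_groups",
    among_isolates = if (has_g) "among_isolates_within_groups" else "among_isolates",
    among_individuals = if (has_i) "among_individuals_within_isolates" else "among_individuals_within_groups"
  )
  residual <- if (within_individuals) {
    "within_individuals"
  } else if (has_i) {
    "within_isolates"
  } else {
    "within_groups"
  }
  tab$level <- c(unname(pretty[lv]), residual)

  p <- rep(NA_real_, n_lines)
  with_seed(seed, {
    if (has_g) {
      obs <- if (has_i) phi[["phi_CT"]] else phi[["phi_ST"]]
      stat <- if (has_i) {
        # permute whole isolates among groups
        iso_ids <- unique(iso)
        iso_grp <- grp[match(iso_ids, iso)]
        replicate(n_perm, {
          g2 <- sample(iso_grp)[match(iso, iso_ids)]
          st <- list(among_groups = g2, among_isolates = iso)
          if (within_individuals) st$among_individuals <- ind
          s <- amova_core(d, st)$sigma2
          sdiv(s[1], sum(s))
        })
      } else {
        # groups act as the populations: permute genotypes among groups
        ids <- unique(ind)
        ind_grp <- grp[match(ids, ind)]
        replicate(n_perm, {
          g2 <- sample(ind_grp)[match(ind, ids)]
          st <- list(among_groups = g2)
          if (within_individuals) st$among_individuals <- ind
          s <- amova_core(d, st)$sigma2
          sdiv(s[1], sum(s))
        })
      }
      p[gi] <- perm_p(stat, obs)
    }
    if (has_i) {
      # permute individuals among isolates within their group
      obs <- if (has_g) phi[["phi_SC"]] else phi[["phi_ST"]]
      ids <- unique(ind)
      ind_iso <- iso[match(ids, ind)]
      ind_grp <- if (has_g) grp[match(ids, ind)] else rep(1, length(ids))
      stat <- replicate(n_perm, {
        new_iso <- ind_iso
        for (gg in unique(ind_grp)) {
          sel <- which(ind_grp == gg)
          new_iso[sel] <- sample(ind_iso[sel])
        }
        iso2 <- new_iso[match(ind, ids)]
        st <- list()
        if (has_g) st$among_groups <- grp
        st$among_isolates <- iso2
        if (within_individuals) st$among_individuals <- ind
        s <- amova_core(d, st)$sigma2
        if (has_g) sdiv(s[2], sum(s[-1])) else sdiv(s[1], sum(s))
      })
      p[ii] <- perm_p(stat, obs)
    }
    if (within_individuals) {
      # permute allele copies among individuals within the lowest units
      obs <- phi[["F_IS"]]
      unit_vec <- if (has_i) iso else grp
      stat <- replicate(n_perm, {
        ind2 <- ind
        for (u in unique(unit_vec)) {
          sel <- which(unit_vec == u)
          ind2[sel] <- sample(ind[sel])
        }
        st <- list()
        if (has_g) st$among_groups <- grp
        if (has_i) st$among_isolates <- iso
        st$among_individuals <- ind2
        s <- amova_core(d, st)$sigma2
        w <- length(s)
        sdiv(s[w - 1], sum(s[(w - 1):w]))
      })
      p[di] <- perm_p(stat, obs)
    }
  })

  line_phi <- rep(NA_real_, n_lines)
  if (has_g) line_phi[gi] <- if (has_i) phi[["phi_CT"]] else phi[["phi_ST"]]
  if (has_i) line_phi[ii] <- if (has_g) phi[["phi_SC"]] else phi[["phi_ST"]]
  if (within_individuals) line_phi[di] <- phi[["F_IS"]]
  tab$phi <- line_phi
  tab$p_value <- p
  if (sum(tab$sigma2) != 0 && abs(sum(tab$pct) - 100) > 0.01) {
    note <- c(note, "percentages do not sum to 100 (degenerate input)")
  }
  structure(list(table = tab, phi = phi, note = paste(note, collapse = "; "),
                 n_perm = as.integer(n_perm)),
            class = "amova_fit")
}

#' @export
print.amova_fit <- function(x, ...) {
  cat("<amova_fit>\n")
  print(as.data.frame(x$table), digits = 4)
  if (nzchar(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Inbreeding coefficient F_IS per unit
#'
#' `F_IS` from the AMOVA decomposition of within-unit distances into
#' among-individual and within-individual components; significance by
#' permuting allele copies among the unit's individuals. Positive values
#' indicate a heterozygote deficit (e.g. a Wahlund effect after pooling
#' differentiated subunits).
#'
#' @inheritParams pairwise_phist
#' @return A tibble with `unit_id`, `n_individuals`, `fis`, `p_value`
#'   (`NA` for units with fewer than 2 individuals).
#' @export
fis <- function(dataset, by = "isolate_id", units = NULL,
                gap_mode = "ignore_gap_columns", n_perm = 10000, seed = 1) {
  if (dataset$ploidy != "diploid") abort("F_IS requires a diploid dataset.")
  if (n_perm < 1) abort("n_perm must be >= 1.")
  seqs <- dataset$sequences
  memb <- membership_of(dataset, by, units)
  d <- dataset_distances(dataset, gap_mode)
  labs <- sort(unique(stats::na.omit(memb)))
  with_seed(seed, purrr::map_dfr(labs, function(u) {
    rows <- which(!is.na(memb) & memb == u)
    ind <- seqs$individual_id[rows]
    n_ind <- length(unique(ind))
    if (n_ind < 2) {
      return(tibble::tibble(unit_id = u, n_individuals = n_ind,
                            fis = NA_real_, p_value = NA_real_))
    }
    sub <- d[rows, rows, drop = FALSE]
    fis_of <- function(ind_vec) {
      s <- amova_core(sub, list(among_individuals = ind_vec))$sigma2
      if (sum(s) == 0) 0 else s[1] / sum(s)
    }
    obs <- fis_of(ind)
    stat <- replicate(n_perm, fis_of(sample(ind)))
    tibble::tibble(unit_id = u, n_individuals = n_ind, fis = obs,
                   p_value = perm_p(stat, obs))
  }))
}
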