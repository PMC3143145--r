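#' Pairwise linkage disequilibrium between polymorphic sites
#'
#' For every unordered pair of polymorphic alignment columns, computes
#' `r_LD`, the absolute correlation between the major-allele indicators of
#' the two sites across allele sequences, and a two-tailed Fisher exact
#' P-value on the corresponding 2x2 haplotype-count table. Sites with more
#' than two states are dichotomized major-allele-vs-rest. Gap characters
#' participate only in `fifth_state` mode; `N` is always missing.
#'
#' @param x An [aligned_dataset()] or a [collapse_haplotypes()] result
#'   (haplotypes are expanded by their counts).
#' @param gap_mode `"ignore_gap_columns"` or `"fifth_state"`.
#' @param alpha Significance level for the `significant` column.
#' @return A tibble with columns `site_a`, `site_b` (1-based alignment
#'   columns, `site_a < site_b`), `r_ld`, `p_value`, `significant`, plus
#'   attributes `polymorphic_sites` and `n_tests`.
#' @export
pairwise_ld <- function(x, gap_mode = "fifth_state", alpha = 0.05) {
  gap_mode <- check_gap_mode(gap_mode)
  if (inherits(x, "haplotype_table")) {
    mat <- seq_char_matrix(rep(x$haplotypes$seq, x$haplotypes$count))
    cols <- x$kept_columns
  } else if (inherits(x, "aligned_dataset")) {
    full <- seq_char_matrix(x$sequences$seq)
    gm <- apply_gap_mode(full, gap_mode)
    mat <- gm$mat
    cols <- gm$kept_columns
  } else {
    abort("x must be an aligned_dataset or haplotype_table.")
  }
  gap_is_state <- gap_mode == "fifth_state"
  drop_states <- if (gap_is_state) "N" else c("N", "-")

  poly <- which(vapply(seq_len(ncol(mat)), function(j) {
    length(column_states(mat[, j], gap_is_state)) >= 2L
  }, logical(1)))
  poly_sites <- cols[poly]

  empty <- tibble::tibble(site_a = integer(), site_b = integer(),
                          r_ld = numeric(), p_value = numeric(),
                          significant = logical())
  if (length(poly) < 2) {
    attr(empty, "polymorphic_sites") <- poly_sites
    attr(empty, "n_tests") <- 0L
    return(empty)
  }

  # major-allele indicator per site (ties broken alphabetically)
  ind <- matrix(NA, nrow(mat), length(poly))
  for (k in seq_along(poly)) {
    col <- mat[, poly[k]]
    obs <- col[!col %in% drop_states]
    tab <- sort(table(obs), decreasing = TRUE)
    major <- names(tab)[tab == max(tab)]
    major <- sort(major)[1]
    v <- ifelse(col %in% drop_states, NA, as.integer(col == major))
    ind[, k] <- v
  }

  pairs <- utils::combn(seq_along(poly), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(q) {
    a <- pairs[1, q]; b <- pairs[2, q]
    ok <- !is.na(ind[, a]) & !is.na(ind[, b])
    xa <- ind[ok, a]; xb <- ind[ok, b]
    tab <- table(factor(xa, levels = 0:1), factor(xb, levels = 0:1))
    r <- if (sd(xa) == 0 || sd(xb) == 0) 0 else abs(stats::cor(xa, xb))
    p <- if (sum(tab) == 0) 1 else stats::fisher.test(tab)$p.value
    tibble::tibble(site_a = poly_sites[a], site_b = poly_sites[b],
                   r_ld = r, p_value = p, significant = p < alpha)
  })
  attr(res, "polymorphic_sites") <- poly_sites
  attr(res, "n_tests") <- nrow(res)
  res
}

#' Exclude sites participating in strong significant LD
#'
#' Both members of every pair with a significant Fisher exact test and
#' `r_LD` above the threshold are excluded, producing the "filtered" dataset
#' variant used to check clustering robustness.
#'
#' @param pairs Result of [pairwise_ld()].
#' @param threshold_r Exclusion threshold on `r_LD` (default 0.5, strict
#'   inequality).
#' @param alpha Significance level re-applied to the stored P-values.
#' @return An object of class `site_filter`: list with `excluded_sites`,
#'   `retained_sites`, `threshold_r`, `alpha`, `n_tests`.
#' @export
exclude_linked_sites <- function(pairs, threshold_r = 0.5, alpha = 0.05) {
  poly <- attr(pairs, "polymorphic_sites")
  if (is.null(poly)) abort("pairs must come from pairwise_ld().")
  hit <- pairs$p_value < alpha & pairs$r_ld > threshold_r
  excluded <- sort(unique(c(pairs$site_a[hit], pairs$site_b[hit])))
  structure(
    list(excluded_sites = excluded,
         retained_sites = setdiff(poly, excluded),
         threshold_r = threshold_r,
         alpha = alpha,
         n_tests = attr(pairs, "n_tests") %||% nrow(pairs)),
    class = "site_filter"
  )
}

#' @export
print.site_filter <- function(x, ...) {
  cat(sprintf("<site_filter> %d excluded / %d polymorphic sites (r > %g, alpha = %g, %d tests)\n",
              length(x$excluded_sites),
              length(x$excluded_sites) + length(x$retained_sites),
              x$threshold_r, x$alpha, x$n_tests))
  invisible(x)
}

#' Concordance between two clustering runs
#'
#' Compares a clustering of the full dataset with one of an LD-filtered (or
#' otherwise perturbed) variant covering the same individuals: are the
#' selected numbers of clusters equal, what is the best label-permutation
#' agreement of majority assignments, and which individuals change majority
#' cluster?
#'
#' @param full,filtered [run_admixture()] results (`cluster_run`), or lists
#'   with elements `selection` (a `k_selection`) and `run` (a `cluster_run`).
#' @return A list with `k_equal` (`NA` when no `k_selection` was supplied),
#'   `agreement` (best label-permutation fraction of individuals whose
#'   majority cluster agrees), and `changed_individuals`.
#' @export
compare_clusterings <- function(full, filtered) {
  unpack <- function(x) {
    if (inherits(x, "cluster_run")) list(sel = NULL, run = x)
    else list(sel = x$selection, run = x$run)
  }
  a <- unpack(full); b <- unpack(filtered)
  if (!setequal(rownames(a$run$Q), rownames(b$run$Q))) {
    abort("The two runs must cover the same individuals.")
  }
  Qa <- a$run$Q
  Qb <- b$run$Q[rownames(Qa), , drop = FALSE]
  la <- max.col(Qa, ties.method = "first")
  lb <- max.col(Qb, ties.method = "first")
  K <- max(ncol(Qa), ncol(Qb))
  perms <- all_permutations(K)
  best <- -1
  best_perm <- NULL
  for (p in perms) {
    agree <- mean(la == p[lb])
    if (agree > best) {
      best <- agree
      best_perm <- p
    }
  }
  changed <- rownames(Qa)[la != best_perm[lb]]
  k_equal <- if (!is.null(a$sel) && !is.null(b$sel)) {
    a$sel$chosen_K == b$sel$chosen_K
  } else {
    NA
  }
  list(k_equal = k_equal, agreement = best, changed_individuals = changed)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
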