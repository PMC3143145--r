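#' Observed mismatch distribution of one unit
#'
#' Counts of pairwise nucleotide differences over all unordered pairs of
#' allele sequences (sequences, not collapsed haplotypes, so haplotype
#' frequencies weight the distribution).
#'
#' @inheritParams nucleotide_diversity
#' @param unit_id Optional label stored with the distribution.
#' @return An object of class `mismatch_distribution`: list with `counts`
#'   (integer vector indexed by difference `j = 0..max`), `n_seq`, `n_pairs`
#'   and `unit_id`.
#' @export
mismatch_distribution <- function(seqs, gap_mode = "ignore_gap_columns",
                                  unit_id = NULL) {
  mat <- unit_matrix(seqs, gap_mode)
  n <- nrow(mat)
  if (n < 2) abort("mismatch_distribution requires at least 2 sequences.")
  gap_is_state <- check_gap_mode(gap_mode) == "fifth_state"
  d <- pairwise_diff_matrix(mat, gap_is_state)
  diffs <- d[upper.tri(d)]
  counts <- tabulate(diffs + 1L, nbins = max(diffs) + 1L)
  names(counts) <- seq_along(counts) - 1L
  structure(
    list(counts = counts, n_seq = n, n_pairs = length(diffs),
         unit_id = unit_id),
    class = "mismatch_distribution"
  )
}

#' @export
print.mismatch_distribution <- function(x, ...) {
  cat(sprintf("<mismatch_distribution>%s %d pairs from %d sequences, max difference %d\n",
              if (is.null(x$unit_id)) "" else paste0(" ", x$unit_id),
              x$n_pairs, x$n_seq, length(x$counts) - 1L))
  invisible(x)
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' Probability of observing `j` pairwise differences for a population that
#' changed instantaneously from mutation-scaled size `theta0` to `theta1` at
#' mutational time `tau = 2ut` before present (Li's transient solution, the
#' curve fitted by the classical mismatch analysis). The equilibrium
#' distribution is geometric, `F_j(theta) = theta^j / (1+theta)^(j+1)`.
#'
#' @param j_max Highest difference class to evaluate (classes `0..j_max`).
#' @param tau,theta0,theta1 Model parameters, all non-negative.
#' @return Numeric vector of length `j_max + 1`; sums to 1 as `j_max` grows.
#' @export
expected_mismatch <- function(j_max, tau, theta0, theta1) {
  j <- 0:j_max
  feq <- function(theta) {
    if (theta <= 0) return(c(1, rep(0, j_max)))
    exp(j * log(theta) - (j + 1) * log1p(theta))
  }
  f1 <- feq(theta1)
  f0 <- feq(theta0)
  if (tau <= 0) return(f1)
  # convolution of (f0 - f1) with Poisson(tau), damped by post-change
  # coalescence exp(-tau*(theta1+1)/theta1)
  pois <- exp(-tau + j * log(tau) - lgamma(j + 1)) # includes e^-tau
  delta <- f0 - f1
  conv <- if (j_max == 0) {
    pois * delta
  } else {
    stats::convolve(delta, rev(pois), type = "open")[1:(j_max + 1)]
  }
  # pois already carries e^-tau; remaining damping is exp(-tau/theta1)
  extra <- if (theta1 > 0) exp(-tau / theta1) else 1
  f1 + extra * conv
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of the expected mismatch curve to the observed
#' normalized frequencies over the observed difference classes. The
#' optimisation is a deterministic multi-start bounded Nelder-Mead search on
#' log-transformed parameters; `theta1` is capped (default `1e5`, an
#' effectively infinite post-expansion size) because the surface is
#' ridge-shaped in `(theta1, tau)`.
#'
#' @param dist A [mismatch_distribution()].
#' @param theta1_max Upper bound for `theta1`.
#' @param thorough Use the full multi-start search (default). The bootstrap
#'   refits inside [mismatch_gof()] use the light search.
#' @return An object of class `mismatch_fit`: list with `tau`, `theta0`,
#'   `theta1`, `ssd`, `observed` (normalized frequencies), `expected`,
#'   `dist`.
#' @export
fit_sudden_expansion <- function(dist, theta1_max = 1e5, thorough = TRUE) {
  stopifnot(inherits(dist, "mismatch_distribution"))
  f_obs <- dist$counts / sum(dist$counts)
  j_max <- length(f_obs) - 1L
  mean_j <- sum((0:j_max) * f_obs)
  if (j_max == 0 || sum(f_obs > 0) < 2) {
    # degenerate: all mass at a single class j0. For j0 = 0 the limit is a
    # stationary population of vanishing size (tau = theta = 0); otherwise
    # an old burst of exactly j0 differences (tau = j0, theta0 = 0).
    warn("Degenerate mismatch distribution; fitting with tau at its mode.")
    j0 <- which.max(f_obs) - 1L
    if (j0 == 0) {
      exp_f <- c(1, rep(0, j_max))
      return(structure(list(tau = 0, theta0 = 0, theta1 = 0,
                            ssd = sum((f_obs - exp_f)^2), observed = f_obs,
                            expected = exp_f, dist = dist),
                       class = "mismatch_fit"))
    }
    tau <- j0
    exp_f <- expected_mismatch(j_max, tau, 0, theta1_max)
    return(structure(list(tau = tau, theta0 = 0, theta1 = theta1_max,
                          ssd = sum((f_obs - exp_f)^2), observed = f_obs,
                          expected = exp_f, dist = dist),
                     class = "mismatch_fit"))
  }

  obj <- function(par) {
    tau <- exp(par[1])
    theta0 <- exp(par[2])
    theta1 <- theta1_max * stats::plogis(par[3])
    f_exp <- expected_mismatch(j_max, tau, theta0, theta1)
    sum((f_obs - f_exp)^2)
  }
  starts <- list()
  if (thorough) {
    for (tau0 in unique(c(max(mean_j, 0.5), max(j_max / 2, 1)))) {
      for (th0 in c(0.05, 1)) {
        starts[[length(starts) + 1]] <- c(log(tau0), log(th0),
                                          stats::qlogis(0.99))
        starts[[length(starts) + 1]] <- c(log(tau0), log(th0),
                                          stats::qlogis(0.01))
      }
    }
  } else {
    starts[[1]] <- c(log(max(mean_j, 0.5)), log(0.05), stats::qlogis(0.99))
    starts[[2]] <- c(log(max(mean_j, 0.5)), log(1), stats::qlogis(0.01))
  }
  maxit <- if (thorough) 600 else 300
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  tau <- exp(best$par[1])
  theta0 <- exp(best$par[2])
  theta1 <- theta1_max * stats::plogis(best$par[3])
  exp_f <- expected_mismatch(j_max, tau, theta0, theta1)
  structure(
    list(tau = tau, theta0 = theta0, theta1 = theta1,
         ssd = sum((f_obs - exp_f)^2), observed = f_obs, expected = exp_f,
         dist = dist),
    class = "mismatch_fit"
  )
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("<mismatch_fit> tau = %.3f, theta0 = %.3g, theta1 = %.3g, SSD = %.4g\n",
              x$tau, x$theta0, x$theta1, x$ssd))
  if (!is.null(x$p_ssd)) {
    cat(sprintf("  P(ssd) = %.3f, raggedness = %.4f (P = %.3f), B = %d\n",
                x$p_ssd, x$raggedness, x$p_raggedness, x$n_bootstrap))
  }
  invisible(x)
}

# Coalescent sample of pairwise-difference counts under the fitted
# sudden-expansion history, in mutational time units (tau = 2ut): pairwise
# coalescence rate 2/theta(t), mutation rate 1 per lineage per unit time.
sim_expansion_mismatch <- function(n, tau, theta0, theta1) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  t_node <- numeric(n_nodes)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  t_change <- tau / 2 # lineage-pair divergence tau corresponds to t = tau/2
  while (length(active) > 1) {
    k <- length(active)
    theta_now <- if (t < t_change) theta1 else theta0
    rate <- k * (k - 1) / max(theta_now, 1e-12)
    wait <- stats::rexp(1, rate)
    if (t < t_change && t + wait > t_change) {
      t <- t_change
      next
    }
    t <- t + wait
    pair <- sample(length(active), 2)
    parent[active[pair]] <- nxt
    t_node[nxt] <- t
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  muts <- integer(n_nodes)
  for (v in seq_len(n_nodes - 1L)) {
    if (parent[v] > 0) {
      muts[v] <- stats::rpois(1, max(t_node[parent[v]] - t_node[v], 0))
    }
  }
  path_to_root <- function(v) {
    out <- integer(0)
    while (parent[v] > 0) {
      out <- c(out, v)
      v <- parent[v]
    }
    out
  }
  paths <- lapply(seq_len(n), path_to_root)
  diffs <- integer(n * (n - 1) / 2)
  idx <- 1L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      edges <- c(setdiff(paths[[i]], shared), setdiff(paths[[j]], shared))
      diffs[idx] <- sum(muts[edges])
      idx <- idx + 1L
    }
  }
  diffs
}

#' Goodness of fit of the sudden-expansion model
#'
#' Computes Harpending's raggedness index of the observed distribution and
#' parametric-bootstrap P-values for both the sum of squared deviations and
#' the raggedness: samples of the same size are simulated by coalescent under
#' the fitted expansion history, each is refitted, and `P` is the fraction of
#' simulated statistics at least as large as the observed one.
#'
#' @param dist A [mismatch_distribution()].
#' @param fit A [fit_sudden_expansion()] result.
#' @param n_bootstrap Number of bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return The `fit`, augmented with `raggedness`, `p_ssd`, `p_raggedness`
#'   and `n_bootstrap`.
#' @export
mismatch_gof <- function(dist, fit, n_bootstrap = 200, seed = 1) {
  stopifnot(inherits(dist, "mismatch_distribution"),
            inherits(fit, "mismatch_fit"))
  if (n_bootstrap < 1) abort("n_bootstrap must be >= 1.")
  rag_obs <- raggedness_index(dist$counts / sum(dist$counts))
  n <- dist$n_seq
  ssd_sim <- rag_sim <- numeric(n_bootstrap)
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      diffs <- sim_expansion_mismatch(n, fit$tau, fit$theta0, fit$theta1)
      counts <- tabulate(diffs + 1L, nbins = max(diffs) + 1L)
      dist_b <- structure(list(counts = counts, n_seq = n,
                               n_pairs = length(diffs), unit_id = NULL),
                          class = "mismatch_distribution")
      fit_b <- suppressWarnings(fit_sudden_expansion(dist_b, thorough = FALSE))
      ssd_sim[b] <- fit_b$ssd
      rag_sim[b] <- raggedness_index(counts / sum(counts))
    }
  })
  fit$raggedness <- rag_obs
  # unbiased bootstrap P: (1 + #{sim >= observed}) / (B + 1)
  fit$p_ssd <- (1 + sum(ssd_sim >= fit$ssd)) / (n_bootstrap + 1)
  fit$p_raggedness <- (1 + sum(rag_sim >= rag_obs)) / (n_bootstrap + 1)
  fit$n_bootstrap <- as.integer(n_bootstrap)
  fit
}

#' Harpending's raggedness index
#'
#' `r = sum over classes of the squared successive-frequency differences`,
#' including the closing step from the last observed class to zero. Smooth
#' unimodal (expansion-like) distributions give small values; ragged,
#' multimodal ones give large values.
#'
#' @param freqs Normalized mismatch frequencies over classes `0..d`.
#' @return A non-negative number.
#' @export
raggedness_index <- function(freqs) {
  x <- c(freqs, 0)
  sum(diff(x)^2)
}

#' Classify the shape of a mismatch distribution
#'
#' Labels a unit `"1h"` (a single haplotype), `"2h"` (exactly two
#' haplotypes), and otherwise `"uni"` or `"bi"` by counting local maxima of
#' the 3-bin moving-average-smoothed frequencies whose prominence is at least
#' `min_prominence` of the total mass.
#'
#' @param dist A [mismatch_distribution()].
#' @param table A [collapse_haplotypes()] result for the same locus.
#' @param unit_id Isolate id (or `NULL` for the whole table) used to count
#'   haplotypes.
#' @param min_prominence Prominence threshold (fraction of total mass).
#' @return One of `"1h"`, `"2h"`, `"uni"`, `"bi"`.
#' @export
classify_mismatch_profile <- function(dist, table, unit_id = NULL,
                                      min_prominence = 0.05) {
  stopifnot(inherits(dist, "mismatch_distribution"))
  hd <- if (is.null(unit_id)) {
    list(h = table$h)
  } else {
    sub <- table$per_isolate[table$per_isolate$isolate_id == unit_id, ]
    list(h = nrow(sub))
  }
  if (hd$h == 1) return("1h")
  if (hd$h == 2) return("2h")
  f <- dist$counts / sum(dist$counts)
  sm <- stats::filter(c(f[1], f, f[length(f)]), rep(1 / 3, 3), sides = 2)
  sm <- as.numeric(sm)[seq_along(f) + 1L]
  if (n_prominent_peaks(sm, min_prominence) >= 2) "bi" else "uni"
}

# Count local maxima with prominence >= threshold (classic walk-out rule:
# prominence = peak height minus the highest of the two key saddles toward
# higher ground; for the global maximum, minus the global minimum = itself).
n_prominent_peaks <- function(x, threshold) {
  n <- length(x)
  if (n == 0) return(0L)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i == 1) -Inf else x[i - 1]
    right <- if (i == n) -Inf else x[i + 1]
    x[i] > left && x[i] >= right
  }, logical(1))
  peaks <- which(is_peak)
  count <- 0L
  for (p in peaks) {
    higher_left <- which(x[seq_len(p - 1)] > x[p])
    higher_right <- which(x[seq(p, n)] > x[p]) + p - 1L
    sl <- if (length(higher_left) > 0) min(x[seq(max(higher_left), p)]) else min(x[seq_len(p)])
    sr <- if (length(higher_right) > 0) min(x[seq(p, min(higher_right))]) else min(x[seq(p, n)])
    key <- if (length(higher_left) == 0 && length(higher_right) == 0) {
      min(x)
    } else if (length(higher_left) == 0) {
      sr
    } else if (length(higher_right) == 0) {
      sl
    } else {
      max(sl, sr)
    }
    if (x[p] - key >= threshold) count <- count + 1L
  }
  count
}
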