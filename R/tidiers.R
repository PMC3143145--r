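# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @method tidy cluster_run
#' @export
tidy.cluster_run <- function(x, ...) {
  Q <- x$Q
  tibble::tibble(
    individual_id = rep(rownames(Q), ncol(Q)),
    isolate_id = rep(x$isolate_id, ncol(Q)),
    cluster = rep(seq_len(ncol(Q)), each = nrow(Q)),
    ancestry = as.vector(Q)
  )
}

#' @method glance cluster_run
#' @export
glance.cluster_run <- function(x, ...) {
  tibble::tibble(K = x$K, alpha = x$alpha, lnPD = x$lnPD,
                 n_individuals = nrow(x$Q),
                 burn_in = x$mcmc[["burn_in"]], reps = x$mcmc[["reps"]])
}

#' @method tidy k_selection
#' @export
tidy.k_selection <- function(x, ...) {
  means <- tapply(x$lnpd$lnPD, x$lnpd$K, mean)
  sds <- tapply(x$lnpd$lnPD, x$lnpd$K, sd)
  out <- tibble::tibble(K = as.integer(names(means)),
                        mean_lnPD = as.numeric(means),
                        sd_lnPD = as.numeric(sds))
  dplyr::left_join(out, x$deltak, by = "K")
}

#' @method glance k_selection
#' @export
glance.k_selection <- function(x, ...) {
  tibble::tibble(chosen_K = x$chosen_K, unreliable = x$unreliable,
                 note = x$note)
}

#' @method tidy mismatch_fit
#' @export
tidy.mismatch_fit <- function(x, ...) {
  tibble::tibble(j = seq_along(x$observed) - 1L,
                 observed = x$observed,
                 expected = x$expected)
}

#' @method glance mismatch_fit
#' @export
glance.mismatch_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, theta0 = x$theta0, theta1 = x$theta1,
                 ssd = x$ssd,
                 p_ssd = x$p_ssd %||% NA_real_,
                 raggedness = x$raggedness %||% NA_real_,
                 p_raggedness = x$p_raggedness %||% NA_real_)
}

#' @method tidy amova_fit
#' @export
tidy.amova_fit <- function(x, ...) {
  x$table
}

#' @method glance amova_fit
#' @export
glance.amova_fit <- function(x, ...) {
  tibble::as_tibble(as.list(x$phi)) |>
    dplyr::mutate(n_perm = x$n_perm, note = x$note)
}

#' Ancestry bar plot of a clustering run
#'
#' The classic stacked-bar plot: one vertical bar per individual, segment
#' heights giving inferred ancestry per cluster, individuals grouped by
#' isolate.
#'
#' @param object A [run_admixture()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_run
#' @export
autoplot.cluster_run <- function(object, ...) {
  df <- tidy(object)
  df$individual_id <- factor(df$individual_id,
                             levels = unique(df$individual_id[order(df$isolate_id)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$individual_id,
                                   y = .data$ancestry,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~isolate_id, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "Inferred ancestry", fill = "Cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Delta-K profile of a model-choice run
#'
#' @param object A [select_k()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot k_selection
#' @export
autoplot.k_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!is.na(df$deltaK), ],
                  ggplot2::aes(x = .data$K, y = .data$deltaK)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_K, linetype = 2) +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' Observed vs fitted mismatch distribution
#'
#' @param object A [fit_sudden_expansion()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mismatch_fit
#' @export
autoplot.mismatch_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected), colour = "black") +
    ggplot2::labs(x = "Pairwise differences", y = "Frequency") +
    ggplot2::theme_minimal()
}
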