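#' Tidy a kinetics call into one row per KDE peak
#'
#' @param x An `fq_kinetics_call`.
#' @param ... Unused.
#' @return A tibble with columns `peak`, `position`, `height`, `n_pairs`.
#' @export
tidy.fq_kinetics_call <- function(x, ...) {
  k <- length(x$peaks)
  counts <- tabulate(x$assignment$peak, nbins = k)
  tibble(peak = seq_len(k), position = x$peaks,
         height = x$peak_heights, n_pairs = counts)
}

#' One-row summary of a kinetics call
#'
#' @param x An `fq_kinetics_call`.
#' @param ... Unused.
#' @return A tibble: `label`, `n_peaks`, `onset`, `bandwidth`,
#'   `n_included`, `n_excluded`.
#' @export
glance.fq_kinetics_call <- function(x, ...) {
  tibble(label = x$label, n_peaks = length(x$peaks), onset = x$onset,
         bandwidth = x$bandwidth, n_included = x$n_included,
         n_excluded = length(x$excluded_pairs))
}

#' Tidy an evaluation report into one row per metric
#'
#' @param x An `fq_evaluation`.
#' @param ... Unused.
#' @return A tibble `method`, `metric`, `value` mirroring a metrics table
#'   with unsupervised/supervised accuracy and F1, AUROC and the length
#'   baseline.
#' @export
tidy.fq_evaluation <- function(x, ...) {
  rows <- list(
    tibble(method = "decoy_fraction", metric = "unsupervised_accuracy",
           value = x$unsupervised$balanced_accuracy),
    tibble(method = "decoy_fraction", metric = "unsupervised_f1",
           value = x$unsupervised$f1),
    tibble(method = "decoy_fraction", metric = "auroc", value = x$auroc),
    tibble(method = "length_baseline", metric = "auroc",
           value = x$baseline$auroc)
  )
  if (!is.null(x$supervised)) {
    rows <- c(rows, list(
      tibble(method = "decoy_fraction", metric = "supervised_accuracy",
             value = x$supervised$balanced_accuracy),
      tibble(method = "decoy_fraction", metric = "supervised_f1",
             value = x$supervised$f1)
    ))
  }
  if (!is.null(x$baseline$cv)) {
    rows <- c(rows, list(
      tibble(method = "length_baseline", metric = "supervised_accuracy",
             value = x$baseline$cv$balanced_accuracy),
      tibble(method = "length_baseline", metric = "supervised_f1",
             value = x$baseline$cv$f1)
    ))
  }
  bind_rows(rows)
}

#' One-row summary of an evaluation
#'
#' @param x An `fq_evaluation`.
#' @param ... Unused.
#' @return A tibble with the headline metrics and test p-values.
#' @export
glance.fq_evaluation <- function(x, ...) {
  tibble(
    unsupervised_accuracy = x$unsupervised$balanced_accuracy,
    unsupervised_f1 = x$unsupervised$f1,
    supervised_accuracy = if (!is.null(x$supervised))
      x$supervised$balanced_accuracy else NA_real_,
    supervised_f1 = if (!is.null(x$supervised)) x$supervised$f1 else NA_real_,
    auroc = x$auroc,
    baseline_auroc = x$baseline$auroc,
    p_bootstrap_vs_random = x$bootstrap$p_value,
    p_permutation_vs_length = x$permutation_vs_length$p_value,
    n_proteins = nrow(x$per_protein),
    seed = x$config$seed
  )
}

#' Tidy an onset-vs-rate statistic
#'
#' @param x An `fq_onset_stat`.
#' @param ... Unused.
#' @return The per-protein tibble (`protein_id`, `mean_onset`, `n_decoys`,
#'   `ln_kf`).
#' @export
tidy.fq_onset_stat <- function(x, ...) x$data

#' @export
glance.fq_onset_stat <- function(x, ...) {
  tibble(rho = x$rho, p_value = x$p_value, n_proteins = nrow(x$data),
         n_dropped = x$n_dropped)
}

#' Plot Q time series per element pair
#'
#' @param object An `fq_qseries`.
#' @param ... Unused.
#' @return A ggplot: Q against frame, one facet per SSE element pair, with
#'   the smoothed derivative overlaid when available.
#' @export
autoplot.fq_qseries <- function(object, ...) {
  df <- mutate(as_tibble(object),
               pair = paste(.data$elem_i, .data$elem_j, sep = " - "))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q), colour = "grey30") +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "frame", y = "fraction of native contacts Q") +
    ggplot2::theme_minimal()
  if ("dq_smooth" %in% names(df)) {
    scale <- max(abs(df$dq_smooth)) * 1.05
    if (scale > 0) {
      p <- p + ggplot2::geom_line(
        ggplot2::aes(y = .data$dq_smooth / scale),
        colour = "firebrick", linetype = 2)
    }
  }
  p
}

#' Plot the transition-time density and peaks of a kinetics call
#'
#' @param object An `fq_kinetics_call`.
#' @param ... Unused.
#' @return A ggplot of the KDE with transition-time rug and peak markers.
#' @export
autoplot.fq_kinetics_call <- function(object, ...) {
  ggplot2::ggplot(object$density, ggplot2::aes(x = .data$t, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = object$assignment,
                      ggplot2::aes(x = .data$t_star), inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = object$peaks, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "transition time (fraction of trajectory)",
                  y = "density",
                  title = sprintf("%s (%d peak%s)", object$label,
                                  length(object$peaks),
                                  if (length(object$peaks) == 1) "" else "s")) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep grid
#'
#' @param object An `fq_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot tile map of unsupervised balanced accuracy over the
#'   (cutoff, xi) grid.
#' @export
autoplot.fq_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$cutoff),
                                       y = factor(.data$xi),
                                       fill = .data$balanced_accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$balanced_accuracy)), colour = "white") +
    ggplot2::labs(x = "contact cutoff (Å)", y = "flexibility ξ",
                  fill = "balanced\naccuracy") +
    ggplot2::theme_minimal()
}

#' Plot folding-event onset against the folding rate constant
#'
#' @param object An `fq_onset_stat`.
#' @param ... Unused.
#' @return A ggplot scatter of per-protein mean onset vs `ln k_f`.
#' @export
autoplot.fq_onset_stat <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean_onset,
                                            y = .data$ln_kf)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean folding-event onset (fraction of trajectory)",
                  y = expression(ln ~ k[f]),
                  subtitle = sprintf("Spearman rho = %.2f, p = %.3g",
                                     object$rho, object$p_value)) +
    ggplot2::theme_minimal()
}
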