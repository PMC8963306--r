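#' Relative contact order from a native contact set
#'
#' `RCO = 1 / (L * N) * sum |sep(a, b)|` over the `N` contacts, with `L` the
#' chain length and `sep` the sequence separation in residues (sequential
#' positions, not author numbering). Uses the same inter-element Cb contact
#' set as the kinetics analysis so one contact definition serves the whole
#' pipeline; a classic all-heavy-atom variant is deliberately not offered.
#'
#' @param contacts An `fq_contacts` table (carries the chain length).
#' @param chain_length Override for the chain length `L`.
#' @return The relative contact order (dimensionless).
#' @examples
#' nat <- make_native(4, seed = 1)
#' contact_order(native_contacts(nat$structure, nat$sse))
#' @export
contact_order <- function(contacts, chain_length = NULL) {
  stopifnot(inherits(contacts, "fq_contacts"))
  n <- nrow(contacts)
  if (n == 0) abort("Contact set is empty.", class = "foldq_error")
  L <- chain_length %||% attr(contacts, "chain_length")
  sum(abs(contacts$pos_a - contacts$pos_b)) / (L * n)
}

#' Jaccard similarity of two binary vectors
#'
#' Intersection over union of the supports; defined as 1 when both vectors
#' are all-zero (two empty predictions agree perfectly).
#'
#' @param u,v Binary vectors of equal length.
#' @return A number in \[0, 1\].
#' @examples
#' jaccard(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
jaccard <- function(u, v) {
  if (length(u) != length(v)) {
    abort("Vectors must have equal length.", class = "foldq_error")
  }
  u <- as.logical(u); v <- as.logical(v)
  uni <- sum(u | v)
  if (uni == 0) return(1)
  sum(u & v) / uni
}

#' Mean pairwise Jaccard similarity across decoys
#'
#' Consistency of intermediate predictions between independent decoys of the
#' same protein: the average Jaccard similarity over all unordered pairs of
#' predicted binary vectors.
#'
#' @param vectors List of >= 2 binary vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
decoy_consistency <- function(vectors) {
  k <- length(vectors)
  if (k < 2) abort("Need at least 2 vectors.", class = "foldq_error")
  pairs <- utils::combn(k, 2)
  mean(apply(pairs, 2, function(p) jaccard(vectors[[p[1]]], vectors[[p[2]]])))
}

#' First-intermediate contact vector of a multistate call
#'
#' Binary vector over all native SSE pairs: 1 for pairs assigned to the
#' first KDE peak cluster (pairs already docked in the first intermediate),
#' 0 otherwise; excluded pairs are 0. Proteins with several intermediates
#' are compared on the first one only.
#'
#' @param call An `fq_kinetics_call`.
#' @param which Which intermediate; only `"first"` is supported.
#' @return Named integer vector.
#' @export
intermediate_vector <- function(call, which = "first") {
  stopifnot(inherits(call, "fq_kinetics_call"))
  if (!identical(which, "first")) {
    abort("Only the first intermediate is supported.", class = "foldq_error")
  }
  if (call$label != "multistate") {
    abort("Two-state call has no intermediate.", class = "foldq_error")
  }
  call$intermediate_vectors[[1]]
}

#' Folding-event onset versus folding rate constant
#'
#' For each protein, the mean onset fraction over its two-state decoy calls
#' (multistate decoys are discarded; proteins with no two-state decoy or no
#' rate constant are dropped), paired with `ln k_f` and tested by Spearman
#' rank correlation.
#'
#' @param calls An `fq_calls` tibble (or any data frame with `protein_id`,
#'   `label`, `onset`).
#' @param records An `fq_protein_table` with `ln_kf`.
#' @return A list of class `fq_onset_stat`: `data` (tibble `protein_id`,
#'   `mean_onset`, `n_decoys`, `ln_kf`), `rho`, `p_value`, `n_dropped`.
#' @export
onset_statistic <- function(calls, records) {
  per_protein <- calls |>
    filter(.data$label == "two_state") |>
    group_by(.data$protein_id) |>
    summarise(mean_onset = mean(.data$onset), n_decoys = dplyr::n(),
              .groups = "drop")
  joined <- per_protein |>
    left_join(as_tibble(records)[, c("id", "ln_kf")],
              by = c(protein_id = "id")) |>
    filter(is.finite(.data$ln_kf))
  n_dropped <- nrow(records) - nrow(joined)
  if (nrow(joined) == 0) {
    abort("No protein with two-state decoys and a rate constant.",
          class = "foldq_error")
  }
  ct <- if (nrow(joined) >= 4) {
    spearman_cor(joined$mean_onset, joined$ln_kf)
  } else {
    list(rho = NA_real_, p_value = NA_real_)
  }
  structure(list(data = joined, rho = ct$rho, p_value = ct$p_value,
                 n_dropped = n_dropped), class = "fq_onset_stat")
}

#' @export
print.fq_onset_stat <- function(x, ...) {
  cat(sprintf("<fq_onset_stat> %d proteins (%d dropped); Spearman rho = %.3f, p = %.3g\n",
              nrow(x$data), x$n_dropped, x$rho, x$p_value))
  invisible(x)
}

#' Compare predicted intermediate vectors against an HDX vector
#'
#' Aggregates the per-decoy binary predictions of a protein into per-pair
#' probabilities (share of multistate decoys marking the pair formed), then
#' scores against the observed HDX-derived vector: balanced accuracy, F1 and
#' Jaccard on the majority-vote binarization (probability >= 0.5), AUROC on
#' the probabilities, and a fair-coin Monte-Carlo baseline.
#'
#' @param predicted List of binary vectors (one per multistate decoy),
#'   aligned on the same native SSE pairs as `observed`.
#' @param observed Binary vector from HDX annotation.
#' @param n_draws Monte-Carlo draws for the coin baseline.
#' @param seed Seed for the baseline draws (recorded in the result).
#' @return A list of class `fq_intermediate_comparison` with fields
#'   `balanced_accuracy`, `f1`, `jaccard_score`, `auroc`, `baseline`
#'   (tibble of coin means) and `n_decoys`.
#' @export
compare_to_hdx <- function(predicted, observed, n_draws = 10000L, seed = 1L) {
  if (length(predicted) == 0) {
    abort("No multistate decoys to compare.", class = "foldq_error")
  }
  len <- length(observed)
  if (any(lengths(predicted) != len)) {
    abort("Predicted and observed vectors differ in length.",
          class = "foldq_error")
  }
  prob <- colMeans(do.call(rbind, lapply(predicted, as.numeric)))
  vote <- as.integer(prob >= 0.5)
  obs <- as.integer(as.logical(observed))
  both_classes <- length(unique(obs)) == 2
  metrics <- list(
    balanced_accuracy = if (both_classes)
      balanced_accuracy(obs, vote) else NA_real_,
    f1 = f1_score(obs, vote, positive = 1L),
    jaccard_score = jaccard(vote, obs),
    auroc = if (both_classes) auroc(obs, prob, positive = 1L) else NA_real_
  )
  set.seed(seed)
  coin <- matrix(rbinom(n_draws * len, 1L, 0.5), n_draws, len)
  base_acc <- if (both_classes) {
    mean(apply(coin, 1, function(p) balanced_accuracy(obs, p)))
  } else NA_real_
  base_f1 <- mean(apply(coin, 1, function(p) f1_score(obs, p, positive = 1L)))
  base_jac <- mean(apply(coin, 1, function(p) jaccard(p, obs)))
  structure(c(metrics, list(
    baseline = tibble(balanced_accuracy = base_acc, f1 = base_f1,
                      jaccard_score = base_jac, n_draws = n_draws,
                      seed = seed),
    n_decoys = length(predicted)
  )), class = "fq_intermediate_comparison")
}

#' @export
print.fq_intermediate_comparison <- function(x, ...) {
  cat(sprintf("<fq_intermediate_comparison> acc %.3f, F1 %.3f, Jaccard %.3f, AUROC %.3f (n = %d decoys)\n",
              x$balanced_accuracy, x$f1, x$jaccard_score, x$auroc, x$n_decoys))
  invisible(x)
}
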