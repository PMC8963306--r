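#' Evaluate kinetics calls against reference labels
#'
#' The full formal-kinetics evaluation: per-protein two-state decoy
#' fractions, the unsupervised majority rule, supervised repeated
#' cross-validated logistic regression, AUROC, the chain-length baseline,
#' a bootstrap test against a random classifier and a paired permutation
#' test against the length baseline.
#'
#' @param calls A data frame with `protein_id` and `label` per decoy.
#' @param records An `fq_protein_table` for the same proteins.
#' @param config An [fq_config()]; `cv_repeats`, `folds`, `n_boot`, `n_perm`,
#'   `cv_feature` and `seed` are honoured.
#' @param cv Whether to run the (comparatively slow) supervised CV.
#' @return A list of class `fq_evaluation`; see [tidy.fq_evaluation()].
#' @export
evaluate_kinetics <- function(calls, records, config = fq_config(), cv = TRUE) {
  per_protein <- calls |>
    group_by(.data$protein_id) |>
    summarise(fraction_two_state = mean(.data$label == "two_state"),
              n_decoys = dplyr::n(), .groups = "drop")
  orphans <- setdiff(per_protein$protein_id, records$id)
  if (length(orphans) > 0) {
    abort(paste0("Calls reference unknown proteins: ",
                 paste(orphans, collapse = ", ")), class = "foldq_error")
  }
  df <- per_protein |>
    left_join(as_tibble(records)[, c("id", "length", "kinetics_label")],
              by = c(protein_id = "id"))
  y <- df$kinetics_label
  if (length(unique(y)) < 2) {
    abort("Reference labels contain a single class; evaluation undefined.",
          class = "foldq_error")
  }
  yhat_unsup <- unsupervised_call(1 - df$fraction_two_state)
  score <- df$fraction_two_state
  len_sc <- length_score(df$length)
  feature <- if (config$cv_feature == "binary") {
    as.integer(yhat_unsup == "two_state")
  } else {
    score
  }
  sup <- base_cv <- NULL
  if (cv) {
    sup <- repeated_cv_logistic(feature, y, folds = config$folds,
                                repeats = config$cv_repeats, seed = config$seed)
    base_cv <- repeated_cv_logistic(df$length, y, folds = config$folds,
                                    repeats = config$cv_repeats,
                                    seed = config$seed)
  }
  boot <- bootstrap_auroc_test(y, score, n_boot = config$n_boot,
                               seed = config$seed)
  perm <- permutation_compare(y, score, len_sc, n_perm = config$n_perm,
                              seed = config$seed)
  structure(list(
    per_protein = df,
    unsupervised = list(
      balanced_accuracy = balanced_accuracy(y, yhat_unsup),
      f1 = f1_score(y, yhat_unsup)
    ),
    supervised = sup,
    auroc = auroc(y, score),
    baseline = list(
      auroc = auroc(y, len_sc),
      cv = base_cv
    ),
    bootstrap = boot,
    permutation_vs_length = perm,
    config = config
  ), class = "fq_evaluation")
}

#' @export
print.fq_evaluation <- function(x, ...) {
  cat("<fq_evaluation>\n")
  cat(sprintf("  unsupervised: accuracy %.3f, F1 %.3f\n",
              x$unsupervised$balanced_accuracy, x$unsupervised$f1))
  if (!is.null(x$supervised)) {
    cat(sprintf("  supervised:   accuracy %.3f, F1 %.3f (%d x %d-fold CV)\n",
                x$supervised$balanced_accuracy, x$supervised$f1,
                x$supervised$repeats, x$supervised$folds))
  }
  cat(sprintf("  AUROC %.3f (length baseline %.3f)\n", x$auroc, x$baseline$auroc))
  cat(sprintf("  bootstrap p vs 0.5: %.4g; permutation p vs length: %.4g\n",
              x$bootstrap$p_value, x$permutation_vs_length$p_value))
  invisible(x)
}

#' Compare predicted intermediates with HDX annotations across proteins
#'
#' For every protein with HDX annotation, aggregates the first-intermediate
#' vectors of its multistate decoy calls and scores them against the
#' observed vector with [compare_to_hdx()]; proteins without any multistate
#' decoy are skipped and counted.
#'
#' @param calls An `fq_calls` tibble (with `first_intermediate` list column).
#' @param hdx An `fq_hdx` tibble (first intermediate rows are used).
#' @param n_draws,seed Passed to [compare_to_hdx()].
#' @return A list of class `fq_hdx_evaluation`: `per_protein` tibble of
#'   metrics, `mean` row, `n_skipped`.
#' @export
evaluate_intermediates <- function(calls, hdx, n_draws = 10000L, seed = 1L) {
  hdx1 <- hdx |> filter(.data$intermediate_index == 1L)
  ids <- unique(hdx1$id)
  rows <- list()
  n_skipped <- 0L
  for (pid in ids) {
    h <- hdx1[hdx1$id == pid, ]
    observed <- setNames(h$formed, paste(h$pair_i, h$pair_j, sep = "|"))
    sub <- calls[calls$protein_id == pid & calls$label == "multistate", ]
    preds <- purrr::compact(sub$first_intermediate)
    preds <- purrr::keep(preds, ~ all(names(observed) %in% names(.x)))
    if (length(preds) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    preds <- lapply(preds, function(v) v[names(observed)])
    cmp <- compare_to_hdx(preds, observed, n_draws = n_draws, seed = seed)
    rows[[pid]] <- tibble(
      protein_id = pid,
      balanced_accuracy = cmp$balanced_accuracy,
      f1 = cmp$f1, jaccard_score = cmp$jaccard_score, auroc = cmp$auroc,
      baseline_accuracy = cmp$baseline$balanced_accuracy,
      baseline_f1 = cmp$baseline$f1,
      baseline_jaccard = cmp$baseline$jaccard_score,
      n_decoys = cmp$n_decoys
    )
  }
  if (length(rows) == 0) {
    abort("No protein had both HDX annotation and multistate decoys.",
          class = "foldq_error")
  }
  per_protein <- bind_rows(rows)
  structure(list(
    per_protein = per_protein,
    mean = per_protein |>
      summarise(dplyr::across(c("balanced_accuracy", "f1", "jaccard_score",
                                "auroc", "baseline_accuracy", "baseline_f1",
                                "baseline_jaccard"),
                              ~ mean(.x, na.rm = TRUE))),
    n_skipped = n_skipped
  ), class = "fq_hdx_evaluation")
}

#' Per-protein decoy consistency of predicted intermediates
#'
#' Mean pairwise Jaccard similarity between the first-intermediate vectors
#' of a protein's multistate decoys (proteins with fewer than two such
#' decoys are dropped).
#'
#' @param calls An `fq_calls` tibble.
#' @return A tibble `protein_id`, `consistency`, `n_multistate`.
#' @export
consistency_by_protein <- function(calls) {
  calls |>
    filter(.data$label == "multistate") |>
    group_by(.data$protein_id) |>
    summarise(n_multistate = dplyr::n(),
              consistency = {
                vs <- purrr::compact(.data$first_intermediate)
                if (length(vs) >= 2) decoy_consistency(vs) else NA_real_
              },
              .groups = "drop") |>
    filter(!is.na(.data$consistency))
}
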