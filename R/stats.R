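#' Unsupervised kinetics call from decoy fractions
#'
#' A protein is called multistate when at least `threshold` (default 50%) of
#' its decoys display multistate kinetics, otherwise two-state; the boundary
#' is inclusive on the multistate side.
#'
#' @param fraction_multistate Numeric vector of per-protein multistate decoy
#'   fractions in \[0, 1\].
#' @param threshold Decision boundary.
#' @return Character vector of `"two_state"` / `"multistate"`.
#' @examples
#' unsupervised_call(c(0.50, 0.49, 0))
#' @export
unsupervised_call <- function(fraction_multistate, threshold = 0.5) {
  if (any(fraction_multistate < 0 | fraction_multistate > 1)) {
    abort("Fractions must lie in [0, 1].", class = "foldq_error")
  }
  ifelse(fraction_multistate >= threshold, "multistate", "two_state")
}

#' Balanced accuracy (mean per-class recall)
#'
#' Robust to class imbalance: the recall of every class present in `y` is
#' computed and averaged. A constant predictor scores exactly 0.5 on a
#' two-class problem regardless of the balance.
#'
#' @param y True labels (both classes must be present).
#' @param yhat Predicted labels.
#' @return A number in \[0, 1\].
#' @export
balanced_accuracy <- function(y, yhat) {
  classes <- unique(y)
  if (length(classes) < 2) {
    abort("Both classes must be present in `y`.", class = "foldq_error")
  }
  recalls <- vapply(classes, function(cl) mean(yhat[y == cl] == cl), numeric(1))
  mean(recalls)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' @param y True labels.
#' @param yhat Predicted labels.
#' @param positive The positive class (for kinetics work: `"two_state"`, the
#'   dataset majority).
#' @return A number in \[0, 1\]; 0 by convention when precision + recall = 0.
#' @export
f1_score <- function(y, yhat, positive = "two_state") {
  if (!positive %in% y) {
    abort("Positive class absent from `y`.", class = "foldq_error")
  }
  tp <- sum(y == positive & yhat == positive)
  fp <- sum(y != positive & yhat == positive)
  fn <- sum(y == positive & yhat != positive)
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)` over all positive/negative
#' pairs — the probability that a uniformly drawn positive (two-state)
#' protein scores higher than a uniformly drawn negative one. Invariant
#' under strictly monotone transforms of the score.
#'
#' @param y True labels.
#' @param score Numeric score, larger = more positive-like.
#' @param positive The positive class.
#' @return A number in \[0, 1\].
#' @export
auroc <- function(y, score, positive = "two_state") {
  pos <- y == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be present in `y`.", class = "foldq_error")
  }
  r <- rank(score)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Length-based score for the chain-length baseline
#'
#' Min-max projection of chain lengths to \[0, 1\], oriented so shorter
#' chains score toward the two-state (positive) class.
#'
#' @param lengths Per-protein chain lengths (>= 2 distinct values).
#' @return Numeric scores in \[0, 1\].
#' @examples
#' length_score(c(50, 100, 150))
#' @export
length_score <- function(lengths) {
  rng <- range(lengths)
  if (rng[1] == rng[2]) {
    abort("All lengths equal: projection undefined.", class = "foldq_error")
  }
  1 - (lengths - rng[1]) / (rng[2] - rng[1])
}

#' Repeated stratified cross-validated logistic regression
#'
#' Fits a logistic regression of the kinetics label on one or more features
#' under repeated stratified k-fold cross-validation: every repeat redraws
#' the fold assignment (stratified within class so each training fold sees
#' both classes), refits the model per fold, pools the held-out predictions
#' of the repeat and scores them; means and standard deviations over repeats
#' are reported.
#'
#' @param features Numeric vector or data frame of per-protein features.
#' @param y True labels (character, two classes).
#' @param folds Number of folds.
#' @param repeats Number of repeats.
#' @param positive Positive class for F1.
#' @param seed Integer seed.
#' @return A list of class `fq_cv`: `balanced_accuracy`, `f1` (means),
#'   `sd_balanced_accuracy`, `sd_f1`, `repeats`, `folds`, `seed`.
#' @export
repeated_cv_logistic <- function(features, y, folds = 5L, repeats = 1000L,
                                 positive = "two_state", seed = 1L) {
  X <- if (is.data.frame(features)) as.matrix(features) else
    matrix(as.numeric(features), ncol = 1L)
  n <- length(y)
  if (n < folds) abort("Fewer samples than folds.", class = "foldq_error")
  classes <- unique(y)
  if (length(classes) != 2) {
    abort("Need exactly two classes.", class = "foldq_error")
  }
  ybin <- as.integer(y == positive)
  set.seed(seed)
  acc <- numeric(repeats)
  f1v <- numeric(repeats)
  df <- data.frame(.y = ybin, X)
  for (r in seq_len(repeats)) {
    fold <- integer(n)
    for (cl in classes) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    pred <- integer(n)
    for (k in seq_len(folds)) {
      test <- fold == k
      fit <- suppressWarnings(
        glm(.y ~ ., data = df[!test, , drop = FALSE], family = binomial()))
      p <- predict(fit, newdata = df[test, , drop = FALSE], type = "response")
      pred[test] <- as.integer(p >= 0.5)
    }
    yhat <- ifelse(pred == 1L, positive, setdiff(classes, positive))
    acc[r] <- balanced_accuracy(y, yhat)
    f1v[r] <- f1_score(y, yhat, positive = positive)
  }
  structure(list(
    balanced_accuracy = mean(acc), f1 = mean(f1v),
    sd_balanced_accuracy = sd(acc), sd_f1 = sd(f1v),
    repeats = repeats, folds = folds, seed = seed
  ), class = "fq_cv")
}

#' Bootstrap test of AUROC against a null value
#'
#' Resamples proteins with replacement, recomputes the AUROC per resample
#' and reports the fraction of bootstrap AUROCs at or below the null
#' (default 0.5, a random classifier). Resamples missing a class are
#' redrawn and counted.
#'
#' @param y True labels.
#' @param score Numeric score per protein.
#' @param n_boot Bootstrap replicates.
#' @param null Null AUROC value.
#' @param positive Positive class.
#' @param seed Integer seed.
#' @return A list of class `fq_boot`: `p_value`, `auroc` (observed),
#'   `n_boot`, `n_redrawn`, `seed`.
#' @export
bootstrap_auroc_test <- function(y, score, n_boot = 100000L, null = 0.5,
                                 positive = "two_state", seed = 1L) {
  if (n_boot < 1) abort("`n_boot` must be >= 1.", class = "foldq_error")
  obs <- auroc(y, score, positive = positive)
  n <- length(y)
  pos <- y == positive
  set.seed(seed)
  stat <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(pos[idx]) && any(!pos[idx])) break
      n_redrawn <- n_redrawn + 1L
    }
    r <- rank(score[idx])
    p <- pos[idx]
    np <- sum(p)
    stat[b] <- (sum(r[p]) - np * (np + 1) / 2) / (np * (n - np))
  }
  structure(list(p_value = mean(stat <= null), auroc = obs,
                 n_boot = n_boot, n_redrawn = n_redrawn, seed = seed),
            class = "fq_boot")
}

#' Paired permutation test comparing two classifiers' AUROC
#'
#' The two score vectors are paired on the same proteins; under the null of
#' exchangeable classifiers, each permutation swaps the two scores of a
#' protein with probability 1/2. The statistic is `AUROC(A) - AUROC(B)`;
#' the two-sided p-value is the fraction of permuted statistics at least as
#' extreme as the observed one.
#'
#' @param y True labels.
#' @param score_a,score_b Paired scores.
#' @param n_perm Permutations (a warning is logged below 100).
#' @param positive Positive class.
#' @param seed Integer seed.
#' @return A list of class `fq_perm`: `p_value`, `statistic`, `n_perm`,
#'   `seed`.
#' @export
permutation_compare <- function(y, score_a, score_b, n_perm = 10000L,
                                positive = "two_state", seed = 1L) {
  if (length(score_a) != length(score_b) || length(score_a) != length(y)) {
    abort("Scores must be aligned on the same proteins.", class = "foldq_error")
  }
  if (n_perm < 100) warn("Fewer than 100 permutations: p-value is coarse.")
  obs <- auroc(y, score_a, positive) - auroc(y, score_b, positive)
  n <- length(y)
  set.seed(seed)
  null_stat <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, score_b, score_a)
    b <- ifelse(swap, score_a, score_b)
    null_stat[i] <- auroc(y, a, positive) - auroc(y, b, positive)
  }
  structure(list(p_value = mean(abs(null_stat) >= abs(obs)),
                 statistic = obs, n_perm = n_perm, seed = seed),
            class = "fq_perm")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks for ties; the p-value uses the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, length >= 4.
#' @return A list: `rho`, `p_value`, `n`.
#' @examples
#' spearman_cor(1:4, c(1, 3, 2, 4))
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n < 4) abort("Need at least 4 observations.", class = "foldq_error")
  if (length(y) != n) abort("`x` and `y` lengths differ.", class = "foldq_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Constant input: rank correlation undefined.", class = "foldq_error")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
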