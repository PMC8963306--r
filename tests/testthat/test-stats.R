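test_that("unsupervised rule is inclusive at the 50% boundary", {
  expect_equal(unsupervised_call(c(0.50, 0.49, 0, 1)),
               c("multistate", "two_state", "two_state", "multistate"))
  expect_error(unsupervised_call(1.2), class = "foldq_error")
})

test_that("balanced accuracy equals mean per-class recall", {
  y <- c(rep("two_state", 90), rep("multistate", 80))
  expect_equal(balanced_accuracy(y, y), 1)
  # constant predictor: exactly 0.5 regardless of class balance
  expect_identical(balanced_accuracy(y, rep("two_state", 170)), 0.5)
  expect_identical(balanced_accuracy(y, rep("multistate", 170)), 0.5)
  # unbiased coin: 0.5 in expectation
  withr::local_seed(5)
  accs <- replicate(2000, {
    yhat <- sample(c("two_state", "multistate"), 170, replace = TRUE)
    balanced_accuracy(y, yhat)
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.01)
  expect_error(balanced_accuracy(rep("two_state", 5), rep("two_state", 5)),
               "Both classes", class = "foldq_error")
})

test_that("F1 matches direct arithmetic and its conventions", {
  y <- c(rep("pos", 4), rep("neg", 3))
  yhat <- c("pos", "pos", "pos", "neg", "pos", "neg", "neg")
  # TP = 3, FP = 1, FN = 1 -> P = R = 0.75
  expect_equal(f1_score(y, yhat, positive = "pos"), 0.75)
  expect_equal(f1_score(y, y, positive = "pos"), 1)
  expect_equal(f1_score(y, rep("neg", 7), positive = "pos"), 0)
  expect_error(f1_score(rep("neg", 3), rep("neg", 3), positive = "pos"),
               "absent", class = "foldq_error")
})

test_that("AUROC has the Mann-Whitney tie and separation behaviour", {
  y <- c(rep("two_state", 3), rep("multistate", 3))
  expect_equal(auroc(y, c(4, 5, 6, 1, 2, 3)), 1)
  expect_equal(auroc(y, rep(2, 6)), 0.5)
  s <- c(0.9, 0.4, 0.8, 0.5, 0.3, 0.7)
  expect_equal(auroc(y, s), auroc(y, exp(5 * s)))
  expect_equal(auroc(y, s), 1 - auroc(y, -s))
  expect_error(auroc(rep("two_state", 4), 1:4), "Both classes",
               class = "foldq_error")
  # uniform scores: 0.500 in expectation
  withr::local_seed(8)
  y170 <- c(rep("two_state", 90), rep("multistate", 80))
  aucs <- replicate(1000, auroc(y170, runif(170)))
  expect_equal(mean(aucs), 0.5, tolerance = 0.01)
})

test_that("length scores project to [0,1] with short chains positive", {
  expect_equal(length_score(c(50, 100, 150)), c(1, 0.5, 0))
  expect_setequal(length_score(c(80, 120)), c(1, 0))
  # AUROC on length scores is invariant under monotone transforms of length
  withr::local_seed(1)
  len <- sample(50:200, 30)
  y <- sample(c("two_state", "multistate"), 30, replace = TRUE,
              prob = c(0.5, 0.5))
  expect_equal(auroc(y, length_score(len)), auroc(y, length_score(len^2)))
  expect_error(length_score(c(70, 70)), "All lengths equal",
               class = "foldq_error")
})

test_that("repeated CV separates separable data and not permuted data", {
  withr::local_seed(3)
  n <- 80
  y <- rep(c("two_state", "multistate"), each = n / 2)
  x_sep <- ifelse(y == "two_state", 1, 0) + rnorm(n, sd = 0.05)
  cv <- repeated_cv_logistic(x_sep, y, folds = 5, repeats = 20, seed = 4)
  expect_gte(cv$balanced_accuracy, 0.99)
  y170 <- rep(c("two_state", "multistate"), times = c(90, 80))
  x_null <- rnorm(170)
  cv0 <- repeated_cv_logistic(x_null, y170, folds = 5, repeats = 60, seed = 4)
  expect_lt(abs(cv0$balanced_accuracy - 0.5), 0.05)
  # determinism under a fixed seed
  cv_a <- repeated_cv_logistic(x_sep, y, folds = 5, repeats = 5, seed = 9)
  cv_b <- repeated_cv_logistic(x_sep, y, folds = 5, repeats = 5, seed = 9)
  expect_identical(cv_a, cv_b)
  expect_error(repeated_cv_logistic(1:3, y[1:3], folds = 5),
               "Fewer samples", class = "foldq_error")
})

test_that("bootstrap AUROC test flags a perfect separator", {
  y <- c(rep("two_state", 40), rep("multistate", 40))
  score <- ifelse(y == "two_state", 1, 0)
  bt <- bootstrap_auroc_test(y, score, n_boot = 2000, seed = 5)
  expect_lt(bt$p_value, 0.01)
  expect_equal(bt$auroc, 1)
  # uninformative score: p typically large
  withr::local_seed(6)
  bt0 <- bootstrap_auroc_test(y, rnorm(80), n_boot = 2000, seed = 7)
  expect_gt(bt0$p_value, 0.01)
  # reproducible bit for bit
  bt2 <- bootstrap_auroc_test(y, score, n_boot = 500, seed = 11)
  bt3 <- bootstrap_auroc_test(y, score, n_boot = 500, seed = 11)
  expect_identical(bt2, bt3)
  expect_error(bootstrap_auroc_test(y, score, n_boot = 0),
               class = "foldq_error")
})

test_that("permutation comparison is symmetric and detects separation", {
  withr::local_seed(12)
  y <- c(rep("two_state", 30), rep("multistate", 30))
  a <- ifelse(y == "two_state", 1, 0) + rnorm(60, sd = 0.1)
  b <- -a
  pt <- permutation_compare(y, a, b, n_perm = 2000, seed = 3)
  expect_lt(pt$p_value, 0.01)
  # identical scores: statistic 0, p = 1
  pt_same <- permutation_compare(y, a, a, n_perm = 500, seed = 3)
  expect_equal(pt_same$statistic, 0)
  expect_equal(pt_same$p_value, 1)
  # swapping the roles gives the same two-sided p
  pt_ab <- permutation_compare(y, a, b, n_perm = 1000, seed = 8)
  pt_ba <- permutation_compare(y, b, a, n_perm = 1000, seed = 8)
  expect_equal(pt_ab$p_value, pt_ba$p_value)
  expect_warning(permutation_compare(y, a, b, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("permutation null p-values are roughly uniform", {
  withr::local_seed(21)
  y <- c(rep("two_state", 20), rep("multistate", 20))
  pvals <- replicate(60, {
    a <- rnorm(40)
    b <- rnorm(40)
    permutation_compare(y, a, b, n_perm = 200, seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("spearman correlation matches rank arithmetic and cor.test", {
  expect_equal(spearman_cor(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_cor(1:6, -(1:6))$rho, -1)
  ct <- spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(ct$rho, 0.8)
  withr::local_seed(31)
  x <- rnorm(25)
  y <- x + rnorm(25)
  ours <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "Constant",
               class = "foldq_error")
  expect_error(spearman_cor(1:3, 1:3), "at least 4", class = "foldq_error")
})
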