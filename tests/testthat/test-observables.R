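# A contact table fixed by hand, for metric identities.
toy_contacts <- function(pos_a, pos_b, L) {
  out <- tibble::tibble(
    elem_i = "A", elem_j = "B",
    pos_a = pos_a, pos_b = pos_b,
    res_a = pos_a, res_b = pos_b,
    native_dist = 5
  )
  attr(out, "chain_length") <- L
  attr(out, "cutoff") <- 8
  class(out) <- c("fq_contacts", class(out))
  out
}

test_that("relative contact order matches hand-worked values", {
  # L = 4, contacts (1,4) and (2,4): separations 3 and 2 -> 5 / (4 * 2)
  expect_equal(contact_order(toy_contacts(c(1, 2), c(4, 4), L = 4)), 0.625)
  # constant separation s: RCO = s / L
  expect_equal(contact_order(toy_contacts(1:5, 8:12, L = 20)), 7 / 20)
  # duplicating every contact leaves the mean unchanged
  ct <- toy_contacts(c(1, 2), c(4, 4), L = 4)
  ct2 <- toy_contacts(c(1, 2, 1, 2), c(4, 4, 4, 4), L = 4)
  expect_equal(contact_order(ct2), contact_order(ct))
})

test_that("contact order is invariant under rigid motion of the structure", {
  nat <- make_native(4, seed = 5)
  ct1 <- native_contacts(nat$structure, nat$sse)
  moved <- nat$structure
  # rotate 90 degrees about z and translate
  xy <- cbind(moved$x, moved$y)
  moved$x <- -xy[, 2] + 100
  moved$y <- xy[, 1] - 42
  moved$z <- moved$z + 7
  ct2 <- native_contacts(moved, nat$sse)
  expect_equal(contact_order(ct2), contact_order(ct1), tolerance = 1e-12)
})

test_that("jaccard similarity handles the standard and degenerate cases", {
  expect_equal(jaccard(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccard(c(1, 0), c(0, 1)), 0)
  expect_equal(jaccard(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(jaccard(c(0, 0), c(0, 0)), 1)
  expect_error(jaccard(c(1, 0), c(1, 0, 0)), "equal length",
               class = "foldq_error")
})

test_that("jaccard is symmetric and bounded on random vectors", {
  withr::local_seed(13)
  for (i in 1:25) {
    u <- rbinom(12, 1, 0.4)
    v <- rbinom(12, 1, 0.4)
    j <- jaccard(u, v)
    expect_identical(j, jaccard(v, u))
    expect_gte(j, 0)
    expect_lte(j, 1)
  }
})

test_that("decoy consistency matches the combinatorial closed form", {
  u <- c(1, 1, 0, 0)
  v <- c(0, 0, 1, 1)
  expect_equal(decoy_consistency(list(u, u, u)), 1)
  expect_equal(decoy_consistency(list(u, v)), 0)
  for (k in c(2, 3, 5)) {
    vecs <- c(rep(list(u), k), rep(list(v), k))
    expect_equal(decoy_consistency(vecs), (k - 1) / (2 * k - 1))
  }
  # invariant under reordering
  withr::local_seed(2)
  vecs <- replicate(6, rbinom(8, 1, 0.5), simplify = FALSE)
  expect_equal(decoy_consistency(sample(vecs)), decoy_consistency(vecs))
  expect_error(decoy_consistency(list(u)), "at least 2",
               class = "foldq_error")
})

test_that("intermediate vectors come from the first peak cluster only", {
  tt <- make_transitions(rep(c(0.1, 0.5, 0.9), each = 16))
  call <- kde_phases(tt)
  expect_equal(call$label, "multistate")
  expect_length(call$peaks, 3)
  iv <- intermediate_vector(call, "first")
  expect_equal(unname(iv), rep(c(1L, 0L, 0L), each = 16))
  two <- kde_phases(make_transitions(rep(0.5, 5)))
  expect_error(intermediate_vector(two), "no intermediate",
               class = "foldq_error")
})

test_that("onset statistic averages two-state decoys and drops the rest", {
  calls <- tibble::tibble(
    protein_id = c(rep("a", 3), rep("b", 2), rep("c", 2)),
    label = c("two_state", "two_state", "two_state",
              "multistate", "multistate", "two_state", "two_state"),
    onset = c(0.40, 0.42, 0.44, 0.2, 0.25, 0.3, 0.5))
  records <- protein_table(tibble::tibble(
    id = c("a", "b", "c", "d"), length = c(60, 70, 80, 90),
    kinetics_label = c("two_state", "multistate", "two_state", "two_state"),
    ln_kf = c(5, 4, NA, 2)))
  os <- onset_statistic(calls, records)
  expect_equal(os$data$protein_id, "a")
  expect_equal(os$data$mean_onset, 0.42)
  # b (all multistate), c (no rate), d (no decoys) are all dropped
  expect_equal(os$n_dropped, 3)
  expect_true(is.na(os$rho))
})

test_that("planted negative onset slope is recovered with confidence", {
  b <- make_benchmark(n_proteins = 60, decoys_per_protein = 2,
                      p_two_state = 1, kf_model = list(a = 2, b = -8, sd = 1),
                      seed = 31)
  calls <- benchmark_calls(b)
  os <- onset_statistic(calls, b$table)
  expect_lt(os$rho, 0)
  expect_lt(os$p_value, 0.05)
})

test_that("HDX comparison scores perfect, disjoint and coin predictions", {
  observed <- c(1, 1, 0, 0, 1, 0)
  perfect <- compare_to_hdx(rep(list(observed), 4), observed, n_draws = 200)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$jaccard_score, 1)
  expect_equal(perfect$auroc, 1)
  flipped <- compare_to_hdx(list(1 - observed), observed, n_draws = 200)
  expect_equal(flipped$jaccard_score, 0)
  # unbiased coin: balanced accuracy 0.5 in expectation
  withr::local_seed(17)
  coin_preds <- replicate(400, rbinom(6, 1, 0.5), simplify = FALSE)
  accs <- vapply(coin_preds, function(p) balanced_accuracy(observed, p),
                 numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.05)
  expect_error(compare_to_hdx(list(), observed), "No multistate",
               class = "foldq_error")
  expect_error(compare_to_hdx(list(c(1, 0)), observed), "length",
               class = "foldq_error")
})
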