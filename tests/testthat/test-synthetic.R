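test_that("make_native packs rods that share contacts under 8 A", {
  nat <- make_native(n_elements = 4, element_len = 5, spacing = 6, seed = 1)
  expect_equal(nrow(nat$structure), 4 * 5 + 3 * 2)
  expect_equal(nrow(nat$sse), 4)
  # brute-force distance scan: every grid-neighbouring rod pair (6 A apart
  # in the packing) shares at least one bead pair under 8 A, and every
  # element takes part in at least one inter-element contact
  xyz <- as.matrix(nat$structure[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  rows_of <- function(k) nat$sse$start[k]:nat$sse$end[k]
  for (pr in list(c(1, 2), c(1, 3), c(2, 4), c(3, 4))) {
    expect_lt(min(d[rows_of(pr[1]), rows_of(pr[2])]), 8.0)
  }
  ct <- native_contacts(nat$structure, nat$sse)
  expect_setequal(unique(c(ct$elem_i, ct$elem_j)), nat$sse$element_id)
  expect_error(make_native(4, element_len = 3), "at least 4",
               class = "foldq_error")
  expect_error(make_native(1), "at least 2", class = "foldq_error")
  # determinism
  nat2 <- make_native(4, element_len = 5, spacing = 6, seed = 1)
  expect_identical(nat$structure, nat2$structure)
})

test_that("phase schedules validate their invariants", {
  g <- setNames(c(1L, 1L, 2L), c("E1", "E2", "E3"))
  sched <- phase_schedule(g, c(0.3, 0.7))
  expect_equal(sched$min_gap, 0.4)
  expect_error(phase_schedule(g, c(0.7, 0.3)), "strictly increasing",
               class = "foldq_error")
  expect_error(phase_schedule(g, c(0.02, 0.7), transition_width = 0.03),
               "truncated", class = "foldq_error")
  expect_error(phase_schedule(setNames(3L, "E1"), c(0.3, 0.7)),
               "index into", class = "foldq_error")
})

test_that("single-phase simulation goes from no contacts to all contacts", {
  nat <- make_native(4, seed = 2)
  ct <- native_contacts(nat$structure, nat$sse)
  sched <- phase_schedule(setNames(rep(1L, 4), nat$sse$element_id), 0.5,
                          transition_width = 0.03)
  sim <- simulate_trajectory(nat$structure, nat$sse, sched, n_frames = 200,
                             noise_sd = 0.1, seed = 5)
  qs <- q_timeseries(sim$trajectory, ct, xi = 1.2)
  nf <- attr(qs, "n_frames")
  expect_true(all(qs$q[qs$frame == 1] == 0))
  expect_true(all(qs$q[qs$frame == nf] == 1))
  expect_equal(sim$truth$kinetics_class, "two_state")
})

test_that("contact count is conserved on the final frame at low noise", {
  nat <- make_native(6, seed = 3)
  ct <- native_contacts(nat$structure, nat$sse)
  sched <- phase_schedule(setNames(rep(1L, 6), nat$sse$element_id), 0.4)
  sim <- simulate_trajectory(nat$structure, nat$sse, sched, n_frames = 100,
                             noise_sd = 0.2, seed = 8)
  qs <- q_timeseries(sim$trajectory, ct, xi = 1.2)
  q_final <- qs$q[qs$frame == 100]
  n_pairs <- length(q_final)
  # every pair fully formed: simulated native contacts equal native count
  expect_equal(sum(q_final), n_pairs)
})

test_that("two-phase ground truth matches a brute-force formation scan", {
  nat <- make_native(6, seed = 4)
  ct <- native_contacts(nat$structure, nat$sse)
  el <- nat$sse$element_id
  sched <- phase_schedule(setNames(c(1L, 1L, 1L, 1L, 2L, 2L), el),
                          c(0.25, 0.75), transition_width = 0.03)
  sim <- simulate_trajectory(nat$structure, nat$sse, sched, n_frames = 200,
                             noise_sd = 0.1, seed = 9)
  qs <- q_timeseries(sim$trajectory, ct, xi = 1.2)
  truth <- sim$truth$formation_time
  first_formed <- qs |>
    dplyr::group_by(elem_i, elem_j) |>
    dplyr::summarise(first = (min(frame[q >= 0.5]) - 1) / (200 - 1),
                     .groups = "drop") |>
    dplyr::mutate(pair = paste(elem_i, elem_j, sep = "|"))
  # the half-formation frame lies within one transition width of the
  # scheduled docking time, for every pair
  expect_true(all(abs(first_formed$first - truth[first_formed$pair]) <=
                    0.03 + 2 / 200))
  # pairs within the early group form near 0.25, cross-group pairs near 0.75
  expect_equal(unname(truth[c("E1|E2", "E1|E3")]), c(0.25, 0.25))
  expect_true(all(truth[grepl("E5|E6", names(truth))] == 0.75))
})

test_that("noiseless simulation with equal seeds is bitwise identical", {
  nat <- make_native(4, seed = 2)
  sched <- phase_schedule(setNames(rep(1L, 4), nat$sse$element_id), 0.5)
  s1 <- simulate_trajectory(nat$structure, nat$sse, sched, noise_sd = 0,
                            seed = 11)
  s2 <- simulate_trajectory(nat$structure, nat$sse, sched, noise_sd = 0,
                            seed = 11)
  expect_identical(s1$trajectory$xyz, s2$trajectory$xyz)
  expect_error(simulate_trajectory(nat$structure, nat$sse, sched,
                                   n_frames = 10),
               "n_frames", class = "foldq_error")
})

test_that("multistate truth never marks the last boundary all-formed", {
  nat <- make_native(5, seed = 6)
  el <- nat$sse$element_id
  sched <- phase_schedule(setNames(c(1L, 1L, 1L, 2L, 2L), el), c(0.3, 0.7))
  sim <- simulate_trajectory(nat$structure, nat$sse, sched, seed = 3)
  iv_last <- sim$truth$intermediate_vectors[[length(sim$truth$intermediate_vectors)]]
  expect_lt(sum(iv_last), length(iv_last))
})

test_that("benchmark generation honours its statistical couplings", {
  # degenerate: all two-state, single-phase schedules
  b1 <- make_benchmark(n_proteins = 5, decoys_per_protein = 2,
                       p_two_state = 1, seed = 21)
  expect_true(all(b1$table$kinetics_label == "two_state"))
  expect_true(all(vapply(b1$proteins,
                         function(p) all(p$plan$class == "two_state"),
                         logical(1))))
  # zero coupling: no significant length-class association over 400 proteins
  b0 <- make_benchmark(n_proteins = 400, decoys_per_protein = 1,
                       coupling = 0, seed = 22)
  tab <- table(b0$table$kinetics_label,
               b0$table$length > median(b0$table$length))
  expect_gt(stats::chisq.test(tab)$p.value, 0.05)
  # negative onset slope in the rate model shows up as negative rank
  # correlation between scheduled onset and ln k_f
  b2 <- make_benchmark(n_proteins = 120, decoys_per_protein = 1,
                       p_two_state = 1,
                       kf_model = list(a = 2, b = -8, sd = 1), seed = 23)
  ct <- spearman_cor(b2$true_onset, b2$table$ln_kf)
  expect_lt(ct$rho, 0)
  expect_lt(ct$p_value, 0.05)
  expect_error(make_benchmark(n_proteins = 1), "at least 2",
               class = "foldq_error")
})

test_that("class counts stay inside the binomial 99% band", {
  p <- 0.53
  n <- 170
  b <- make_benchmark(n_proteins = n, decoys_per_protein = 1,
                      p_two_state = p, seed = 24)
  k <- sum(b$table$kinetics_label == "two_state")
  band <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("per-decoy seeds are recorded and reproducible", {
  b <- make_benchmark(n_proteins = 3, decoys_per_protein = 2, seed = 30)
  s1 <- simulate_decoy(b, "P001", 1)
  s2 <- simulate_decoy(b, "P001", 1)
  expect_equal(s1$trajectory$xyz, s2$trajectory$xyz)
  expect_equal(s1$truth$seed, b$proteins$P001$plan$seed[1])
  expect_error(simulate_decoy(b, "nope", 1), "Unknown protein",
               class = "foldq_error")
})
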