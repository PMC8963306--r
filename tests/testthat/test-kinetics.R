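test_that("transition time of a clean sigmoid sits at its midpoint", {
  n <- 200
  tfrac <- (seq_len(n) - 1) / (n - 1)
  q <- stats::plogis((tfrac - 0.5) / 0.02)
  qs <- tibble::tibble(elem_i = "A", elem_j = "B",
                       frame = seq_len(n), q = q)
  attr(qs, "n_frames") <- n
  class(qs) <- c("fq_qseries", class(qs))
  tt <- transition_times(add_derivatives(qs))
  expect_equal(tt$t_star, 0.5, tolerance = 0.02)
  expect_true(tt$included)
})

test_that("pairs without folding signal are excluded; all-excluded errors", {
  n <- 100
  mk <- function(qa, qb) {
    qs <- tibble::tibble(
      elem_i = rep(c("A", "B"), each = n),
      elem_j = rep(c("X", "Y"), each = n),
      frame = rep(seq_len(n), 2),
      q = c(qa, qb))
    attr(qs, "n_frames") <- n
    class(qs) <- c("fq_qseries", class(qs))
    add_derivatives(qs)
  }
  tfrac <- (seq_len(n) - 1) / (n - 1)
  sig <- stats::plogis((tfrac - 0.5) / 0.02)
  tt <- transition_times(mk(sig, rep(1, n)), activity_threshold = 0.2)
  expect_equal(tt$included, c(TRUE, FALSE))
  expect_error(transition_times(mk(rep(1, n), rep(0.5, n))),
               "No folding signal", class = "foldq_error")
  expect_error(transition_times(mk(sig, sig)[, -(5:6)]),
               "add_derivatives", class = "foldq_error")
})

test_that("identical pairs get identical transition times", {
  fx <- tiny_two_state_sim(n_elements = 4, noise_sd = 0)
  qs <- add_derivatives(q_timeseries(fx$trajectory, fx$contacts))
  tt1 <- transition_times(qs)
  tt2 <- transition_times(qs)
  expect_identical(tt1, tt2)
})

test_that("KDE phase clustering implements the single-peak rule", {
  # all transitions at the same point: one peak, two-state, onset there
  tt <- make_transitions(rep(0.5, 8))
  call <- kde_phases(tt)
  expect_equal(call$label, "two_state")
  expect_length(call$peaks, 1)
  expect_equal(call$peaks, 0.5, tolerance = 0.01)
  expect_equal(call$onset, 0.5)
  expect_length(call$intermediate_vectors, 0)
})

test_that("two well-separated clusters give a multistate call with the
           first cluster as intermediate", {
  tt <- make_transitions(rep(c(0.1, 0.9), each = 10))
  call <- kde_phases(tt)
  expect_equal(call$label, "multistate")
  expect_length(call$peaks, 2)
  expect_equal(call$peaks, c(0.1, 0.9), tolerance = 0.02)
  iv <- call$intermediate_vectors[[1]]
  expect_equal(unname(iv), rep(c(1L, 0L), each = 10))
  expect_equal(call$onset, 0.1)
  # peak assignment splits at the density minimum
  expect_equal(call$assignment$peak, rep(c(1L, 2L), each = 10))
})

test_that("Scott bandwidth follows sigma * m^(-1/5) with a grid floor", {
  withr::local_seed(3)
  t_star <- pmin(pmax(rnorm(100, 0.5, 0.1), 0), 1)
  tt <- make_transitions(t_star)
  call <- kde_phases(tt)
  expect_equal(call$bandwidth, sd(t_star) * 100^(-1 / 5), tolerance = 1e-12)
  # degenerate sample: bandwidth floored at one grid spacing, still 1 peak
  call1 <- kde_phases(make_transitions(0.4), grid_points = 512)
  expect_equal(call1$bandwidth, 1 / 512)
  expect_equal(call1$label, "two_state")
})

test_that("KDE density is a probability density on the grid", {
  tt <- make_transitions(c(0.35, 0.4, 0.45, 0.5, 0.55, 0.6, 0.65))
  call <- kde_phases(tt)
  grid <- call$density$t
  integral <- sum(call$density$density) * (grid[2] - grid[1])
  expect_equal(integral, 1, tolerance = 1e-3)
})

test_that("excluded pairs do not shape the call but appear as zeros", {
  tt <- make_transitions(c(rep(0.1, 4), rep(0.9, 4), 0.5),
                         included = c(rep(TRUE, 8), FALSE))
  call <- kde_phases(tt)
  expect_equal(call$n_included, 8)
  expect_length(call$excluded_pairs, 1)
  iv <- call$intermediate_vectors[[1]]
  expect_equal(unname(iv), c(rep(1L, 4), rep(0L, 4), 0L))
})

test_that("fraction of two-state trajectories is a simple ratio", {
  calls <- data.frame(label = c(rep("two_state", 150), rep("multistate", 50)))
  expect_equal(fraction_two_state(calls), 0.75)
  expect_equal(fraction_two_state(data.frame(label = rep("multistate", 5))), 0)
  # the single-trajectory case still yields a fraction
  expect_equal(fraction_two_state(data.frame(label = "two_state")), 1)
  expect_error(fraction_two_state(data.frame(label = character(0))),
               "No kinetics calls", class = "foldq_error")
})

test_that("prepending static frames shifts transition times, not labels", {
  fx <- tiny_two_state_sim(n_elements = 6, tau = 0.6, noise_sd = 0.1)
  call0 <- analyze_trajectory(fx$trajectory, fx$contacts)
  n <- fx$trajectory$n_frames
  pad <- 100L
  first <- fx$trajectory$xyz[rep(1L, pad), , drop = FALSE]
  traj2 <- fq_trajectory(rbind(first, fx$trajectory$xyz), "padded")
  call2 <- analyze_trajectory(traj2, fx$contacts)
  expect_equal(call2$label, call0$label)
  # onset in frame units shifts by the pad length
  frame0 <- call0$onset * (n - 1) + 1
  frame2 <- call2$onset * (n + pad - 1) + 1
  expect_equal(frame2 - frame0, pad, tolerance = 6)
})
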